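---
title: "Elastic-network bond-breaking simulations of protein unfolding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic-network bond-breaking simulations of protein unfolding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enmunfold)
```

## The model

A protein is coarse-grained to its C-alpha trace and treated as a bead-spring
network, the Gaussian Network Model (GNM). Two residues are connected by a
spring when their native separation is below a cutoff `r_c` (7 Å by default);
backbone neighbours are always connected and carry a stiffer spring, `c`
times the contact spring constant `kappa`. The topology is encoded in the
Kirchhoff matrix Γ: off-diagonal entries are `-c` for backbone pairs, `-1`
for non-covalent contacts, 0 otherwise, and each diagonal entry is minus its
row's off-diagonal sum, so rows sum to zero.

Thermal fluctuations of the inter-residue distances follow from Γ:

    <ΔR_ij²> = (3 kBT / kappa) (Γ⁺_ii + Γ⁺_jj − 2 Γ⁺_ij)

Γ is singular (at least one zero mode per connected component), so Γ⁻¹ is
taken as the Moore–Penrose pseudoinverse, computed by symmetric
eigendecomposition with eigenvalues below `1e-10 · λ_max` treated as zero.
This is the standard GNM practice and remains well defined however many
bonds have been removed.

### Bond-breaking unfolding

Unfolding is simulated by iterated bond removal:

* **Thermal mode** — at each step, the intact non-covalent bond with the
  largest distance fluctuation `<ΔR_ij²>` is broken, and Γ is updated
  (`Γ_ij → Γ_ij + 1`, diagonals decremented). Rising temperature is modelled
  by the *ordering* of ruptures, not by an explicit temperature parameter.
* **Force mode** — unit forces along x are applied at the termini
  (`F_x(1) = −1`, `F_x(N) = +1`), the static displacements solve the Hooke
  law `kappa Γ u = F` componentwise via the pseudoinverse, and the bond with
  the largest relative displacement `|u_i − u_j|` (3-D norm over the three
  componentwise solves) is broken.

One bond breaks per step. Exact ties — which occur on toy networks with
graph automorphisms — resolve to the lexicographically smallest `(i, j)`;
candidates within a relative `1e-9` of the maximum count as tied, so the
rule is stable against rounding noise in the eigendecomposition. Runs are
therefore fully deterministic. After every event the trajectory records the
fraction of intact native contacts Q (dropping by exactly `1/N_native` per
event), the mean coordination number `<z> = 2·bonds/N` (dropping by exactly
`2/N`), and the floppy-mode count.

Backbone bonds never break, so the network always remains connected; the
balanced-force check and per-component solves still guard the general case
of hand-built disconnected networks.

### Floppy modes

The directional counterpart (the Anisotropic Network Model) gives a
`3N × 3N` Hessian built from the *current* connectivity at the *native*
geometry: off-diagonal blocks `kappa Γ_ij n_ij n_ijᵀ` with `n_ij` the native
bond direction, diagonal blocks closing the row sums. A mode is *floppy*
when its eigenvalue falls below `1e-4` (an absolute threshold in the units
in which `kappa` scales the Hessian; configurable). Rigid-body symmetry
guarantees six floppy modes; every additional one is an internal zero-energy
motion, so the count is a global order parameter of rigidity. It is
non-decreasing along a run (eigenvalue interlacing under constraint
removal), climbing slowly while redundant bonds are consumed and steeply
once `<z>` falls below ≈ 3. Both the absolute count and the fraction
`f = f_abs / 3N` are exposed; curves use the absolute count by default.

### Shear fields

Soft modes are converted into a per-residue *shear energy* that localizes
the floppy regions. For a displacement field u, the local deformation
gradient at residue m is the weighted least-squares fit

    F_m = A_m D_m⁻¹,  A_m = Σ_n w_mn Δx'_mn Δx_mnᵀ,  D_m = Σ_n w_mn Δx_mn Δx_mnᵀ

over all neighbours with positive weight: w = 1 within 6 Å, ramping
linearly to 0 between 6 and 8 Å. The Eulerian strain
`ε = (I − (FFᵀ)⁻¹)/2` is exactly zero for rigid motions; its deviatoric
part `γ = ε − tr(ε)/3 · I` gives the shear energy `s_m = Σ_ij γ_ij²`.
The field sums `s_m` over all soft modes (unit-norm eigenvectors applied at
a fixed 1 Å amplitude). Since the field is used comparatively — peaks and
rank correlations — the amplitude only sets an overall scale at leading
order (`s` is quadratic in amplitude, verified to ≈ 5 % at small
amplitudes); it is still exposed as a parameter.

Two numerical guards: a residue whose weighted neighbourhood is coplanar or
collinear (typically chain termini of sparse toys) gets a ridge of
`1e-8 · tr(D)/3` added to `D_m` and is flagged; and residues with shear
below `1e-300` are excluded (and counted) before taking logarithms in
correlations.

**Soft-mode set of a native structure.** A well-packed native network may
have *only* the six rigid-body modes below the threshold, which would make
the native shear field identically zero. Two behaviours are supported: the
default falls back to the lowest 20 non-floppy modes (flagging the field as
`"lowlying"`), which reads the near-rigid structure's softest deformations;
`fallback_k = 0` instead returns the zero field with a warning. The
fallback is the default because the native-state shear of real proteins is
manifestly non-trivial — the low-lying spectrum carries the signal even
when no strict zero modes exist. Every result records which path was taken.

The headline diagnostic is the Pearson correlation between `log(s_m)` in
the native state and the per-residue mean bond-breaking order: strongly
negative values mean high-shear regions lose their bonds early, i.e. the
native shear field predicts where unfolding starts.

### Pathway encoding and family comparison

To compare *how* two proteins unfold, each breaking event is assigned to a
region — an unordered pair of secondary-structure elements — and the length
`N_b` event sequence becomes an `N_b × N_r` one-hot matrix, flattened to a
vector. Stacking the vectors of `N_p` family members gives an
`N_p × N_b N_r` matrix whose row covariance and correlation matrices
quantify pathway similarity (both are emitted, since either normalization
is defensible). Members with fewer than `N_b` contacts are padded with
all-zero rows and logged.

Three region schemes ship:

* `ci2` — the five canonical regions of the chymotrypsin-inhibitor fold
  (N-terminus–β3, α–loop2, β1–β2, β2–β3, rest);
* `barnase` — all unordered pairs of the nine elements (N-terminus, three
  α-helices, three β-strands, two loops) that are populated by native
  contacts, capped at 29 plus a rest region (N_r ≤ 30). The cap keeps the
  encoding comparable across members; the enumeration is a documented
  reconstruction, since a clustering of the contact map is not reproducible
  from a verbal description;
* `generic` — all unordered element pairs present in the annotation, plus
  rest.

Secondary-structure labels come from a plain annotation (two-column TSV or
a character vector), not from a DSSP run, keeping the package free of
structure-annotation dependencies.

Structural similarity is scored with the TM-score on a *user-supplied*
residue correspondence, `d0 = 1.24 (L − 15)^{1/3} − 1.8` (floored at 0.5),
maximized over superpositions by iterative-cut Kabsch refinement: several
fragment seeds are superimposed, scored over all pairs, and re-fit on the
pairs within a growing distance cut until stable. Alignment *search*
(TM-align style) is deliberately out of scope; correspondences come from a
sequence alignment or, for synthetic families, the identity.

Families whose floppy-mode curves `f(<z>)` diverge are flagged by a
divergence ranking: curves are interpolated onto a shared `<z>` grid and
each member is scored by its maximum pairwise L2 distance. The ranking is
an artifact-level definition — the divergence of such curves is a visual
notion in the literature and is not otherwise quantified.

## Synthetic structures: what they emulate and what they do not

`make_toy()` builds structures with *analytically known* rigidity:

| kind | construction | known property |
|------|--------------|----------------|
| `chain` | straight, 3.8 Å spacing | no contacts at 7 Å; `2N + 1` floppy modes |
| `helix` | ideal α-helix trace | (i, i+2), (i, i+3) contacts |
| `triangle` | tetrahelix, all consecutive triples at one edge length | isostatic rigid body: exactly 6 floppy modes |
| `hinge` | two rigid tetrahelix wings sharing an edge | exactly 7 floppy modes; shear peaks at the shared edge |
| `lattice` | serpentine walk on a cubic lattice + seeded jitter | compact, contact-rich protein-like fold |

The hinge uses a 6 Å edge: at 5 Å the best achievable wing separation sits
within numerical noise of the 7 Å cutoff, so the larger edge keeps the two
wings cleanly decoupled. It is a rigidity toy, not a realistic backbone.

`make_family()` emulates a protein family by displacing a controlled
fraction (`rewiring_rate`) of a template's residues with Gaussian noise
(default sd 1 Å). At rates 0 → 0.5 this spans identity-correspondence
TM-scores from 1 down to ≈ 0.47, matching the range seen across real
single-domain families; pathway correlations degrade alongside. What the
toys do *not* capture: real secondary-structure geometry, sequence effects,
experimental B-factor noise, chain breaks, or the contact anisotropy of
real folds. Green tests on synthetic families therefore demonstrate the
machinery and its monotone structure–pathway relationship, not quantitative
agreement with any particular crystal structure; analyses of real PDB
entries require the user to supply those files.

## Parameters that matter

| parameter | meaning | default | note |
|-----------|---------|---------|------|
| `r_c` | contact cutoff (Å) | 7 | standard GNM value |
| `c` | backbone/contact stiffness ratio | 9.3 | chymotrypsin-inhibitor family; 2.3 for the barnase family |
| `kappa` | contact spring constant (kBT/Å²) | 0.493 | 0.945 for the barnase family |
| `stop_after` | bonds to break | all | 110 (CI2-family protocol) or 200 (barnase) |
| `floppy_threshold` | floppy eigenvalue cut | 1e-4 | absolute |
| `amplitude` | shear mode amplitude (Å) | 1 | affects scale, not ranking |
| `fallback_k` | low-lying modes when only rigid modes are soft | 20 | 0 → zero field |

`fit_bfactors()` recovers `(c, kappa)` from experimental B-factors when
wanted: a grid over `c` (1–20, step 0.1; correlation is invariant to
`kappa`), with `kappa` from a closed-form least-squares scale match at each
grid point. The published family constants are the defaults, so fitting is
optional.

## A worked example

```{r example}
fold <- make_toy("lattice", n = 27, seed = 1, ss_segments = 3)
net <- elastic_network(fold)
glance(net)

traj <- run_unfolding(net, mode = "thermal", stop_after = 40)
glance(traj)

shear <- softmode_shear_field(net)
shear_order_correlation(shear, bond_breaking_order(traj))
```

The negative correlation says bonds at high-shear residues break earlier.
Family-level comparison on a synthetic family:

```{r family}
fam <- make_family(fold, n_variants = 3, rewiring_rate = 0.2, seed = 7)
res <- cmd_family(fam, stop_after = 25, track_floppy = FALSE)
glance(res$comparison)
```

## Problem sizes and limitations

The examples, tests and the acceptance script run on synthetic folds of
27–64 residues with runs of 25–110 events — sizes chosen so the whole
analysis reproduces in seconds while still exercising every code path at
full depth (the algorithms scale to real single-domain proteins without
modification; a 110-event run on a 65-residue protein is the published
protocol). Known limitations: harmonic springs only (no anharmonicity, no
distance-dependent constants); no bond re-formation, so unfolding is
irreversible by construction; the thermal mode is temperature-ordered, not
temperature-calibrated; mmCIF input is limited to what `bio3d` converts;
multi-model files use the first model; and the TM-score requires a supplied
correspondence.
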