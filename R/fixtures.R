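# Boerdijk-Coxeter tetrahelix: n beads, every (i,i+1), (i,i+2), (i,i+3)
# pair at exactly `edge`; a generically rigid, isostatic cluster.
tetrahelix_coords <- function(n, edge) {
  k <- seq_len(n) - 1
  r <- edge * 3 * sqrt(3) / 10
  theta <- acos(-2 / 3)
  h <- edge / sqrt(10)
  cbind(x = r * cos(k * theta), y = r * sin(k * theta), z = k * h)
}

as_structure <- function(xyz, ss = NULL, b_factor = NA_real_) {
  n <- nrow(xyz)
  new_calpha_structure(tibble::tibble(
    residue = seq_len(n), residue_id = seq_len(n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    b_factor = rep_len(b_factor, n), chain = "A",
    ss = if (is.null(ss)) NA_character_ else ss
  ))
}

segment_labels <- function(n, ss_segments) {
  if (is.null(ss_segments) || ss_segments < 1) return(NULL)
  paste0("s", ceiling(seq_len(n) / (n / ss_segments)))
}

#' Generate a synthetic bead-spring structure
#'
#' Deterministic toy structures with analytically known elastic-network
#' properties, so every stage of the pipeline is testable without external
#' structure files:
#'
#' * `"chain"` -- straight chain along x; at the default 3.8 Angstrom
#'   spacing it has no non-covalent contacts at the 7 Angstrom cutoff, so
#'   its ANM has exactly `2N + 1` floppy modes.
#' * `"helix"` -- ideal alpha-helix trace (radius 2.3 Angstrom, rise 1.5,
#'   100 degrees per residue); picks up (i, i+2) and (i, i+3) contacts.
#' * `"triangle"` -- tetrahelix cluster with all consecutive-triple
#'   distances equal to `spacing` (default 5 Angstrom): isostatic and
#'   rigid, exactly 6 floppy modes for any `n >= 3` (an equilateral
#'   triangle at `n = 3`).
#' * `"hinge"` -- two rigid tetrahelix wings sharing an edge (the two
#'   middle residues): exactly one internal hinge-rotation mode, 7 floppy
#'   modes in total. Built at a 6 Angstrom edge so the wings stay clear of
#'   the contact cutoff; a rigidity toy, not a realistic backbone.
#' * `"lattice"` -- compact serpentine fold through a cubic lattice
#'   (3.8 Angstrom spacing) with seeded coordinate jitter: a protein-like
#'   toy with a rich contact map for unfolding runs.
#'
#' @param kind One of `"chain"`, `"helix"`, `"triangle"`, `"hinge"`,
#'   `"lattice"` (aliases `"triangle-cluster"`, `"lattice-fold"` accepted).
#' @param n Number of residues (>= 3; `"hinge"` needs >= 4).
#' @param seed Integer seed for the jitter of `"lattice"`; generation is
#'   reproducible from `(kind, n, seed, ...)`.
#' @param spacing Backbone spacing in Angstrom (edge length for
#'   `"triangle"`/`"hinge"`, default 5 there; 3.8 elsewhere).
#' @param noise Jitter half-width in Angstrom for `"lattice"` (default 0.3).
#' @param ss_segments Optionally annotate the chain with this many equal
#'   consecutive secondary-structure segments labelled `s1, s2, ...`.
#' @return A `calpha_structure`.
#' @examples
#' make_toy("hinge", n = 10)
#' @export
make_toy <- function(kind = c("chain", "helix", "triangle", "hinge",
                              "lattice", "triangle-cluster", "lattice-fold"),
                     n = 12, seed = 1, spacing = NULL, noise = 0.3,
                     ss_segments = NULL) {
  kind <- match.arg(kind)
  kind <- c("triangle-cluster" = "triangle", "lattice-fold" = "lattice")[kind] %|na|% kind
  if (n < 3) stop("a toy structure needs n >= 3", call. = FALSE)
  ss <- segment_labels(n, ss_segments)
  xyz <- switch(
    kind,
    chain = {
      a <- spacing %||% 3.8
      cbind(x = a * (seq_len(n) - 1), y = 0, z = 0)
    },
    helix = {
      a <- spacing %||% 3.8
      scale <- a / 3.8
      k <- seq_len(n) - 1
      cbind(x = 2.3 * scale * cos(k * 100 * pi / 180),
            y = 2.3 * scale * sin(k * 100 * pi / 180),
            z = 1.5 * scale * k)
    },
    triangle = tetrahelix_coords(n, spacing %||% 5),
    hinge = hinge_coords(n, spacing %||% 6),
    lattice = {
      a <- spacing %||% 3.8
      xyz <- lattice_snake(n) * a
      withr::with_seed(seed, xyz + matrix(stats::runif(3 * n, -noise, noise), n, 3))
    }
  )
  as_structure(xyz, ss = ss)
}

`%|na|%` <- function(a, b) if (is.na(a)) b else unname(a)

lattice_snake <- function(n) {
  s <- ceiling(n^(1 / 3))
  s2 <- s * s
  k <- seq_len(n) - 1
  z <- k %/% s2
  r <- k %% s2
  r <- ifelse(z %% 2 == 1, s2 - 1 - r, r)
  y <- r %/% s
  x <- r %% s
  x <- ifelse(y %% 2 == 1, s - 1 - x, x)
  cbind(x = x, y = y, z = z)
}

# Complete a tetrahedron: the two points at distance `edge` from p1, p2, p3.
tetra_complete <- function(p1, p2, p3, edge) {
  cen <- (p1 + p2 + p3) / 3
  v1 <- p2 - p1; v2 <- p3 - p1
  nrm <- c(v1[2] * v2[3] - v1[3] * v2[2],
           v1[3] * v2[1] - v1[1] * v2[3],
           v1[1] * v2[2] - v1[2] * v2[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  # circumradius of the (equilateral) base triangle, apex height above centroid
  rc <- sqrt(sum((p1 - cen)^2))
  hh <- sqrt(edge^2 - rc^2)
  list(cen + hh * nrm, cen - hh * nrm)
}

# Two rigid tetrahelix wings sharing the edge (m, m+1), m = floor(n/2):
# wing A = beads 1..m+1, wing B = beads m..n. The first wing-B bead is
# placed on the circle equidistant from the shared edge at the dihedral
# angle that maximizes clearance from wing A; later beads complete
# tetrahedra on their three predecessors, taking the mirror branch with the
# larger clearance from wing A. Cross-wing clearance beyond the 7 A contact
# cutoff is asserted, so the two wings stay separate rigid clusters.
hinge_coords <- function(n, edge) {
  if (n < 4) stop("a hinge toy needs n >= 4", call. = FALSE)
  m <- n %/% 2
  xyz <- matrix(NA_real_, n, 3)
  xyz[1:(m + 1), ] <- tetrahelix_coords(m + 1, edge)
  p_a <- xyz[m, ]; p_b <- xyz[m + 1, ]
  mid <- (p_a + p_b) / 2
  ax <- (p_b - p_a) / sqrt(sum((p_b - p_a)^2))
  e1 <- c(ax[2], -ax[1], 0)
  if (sum(e1^2) < 1e-8) e1 <- c(1, 0, 0)
  e1 <- e1 - sum(e1 * ax) * ax; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(ax[2] * e1[3] - ax[3] * e1[2],
          ax[3] * e1[1] - ax[1] * e1[3],
          ax[1] * e1[2] - ax[2] * e1[1])
  rho <- edge * sqrt(3) / 2
  left <- xyz[1:(m + 1), , drop = FALSE]
  clearance <- function(p, exclude_rows) {
    ref <- left[setdiff(seq_len(m + 1), exclude_rows), , drop = FALSE]
    if (nrow(ref) == 0) return(Inf)
    min(sqrt(rowSums(sweep(ref, 2, p)^2)))
  }
  if (n >= m + 2) {
    psi <- seq(0, 2 * pi, length.out = 73)[-73]
    cand <- t(vapply(psi, function(a) mid + rho * (cos(a) * e1 + sin(a) * e2),
                     numeric(3)))
    scores <- apply(cand, 1, clearance, exclude_rows = c(m, m + 1))
    grow_wing <- function(first) {
      xyz[m + 2, ] <- first
      if (n >= m + 3) {
        for (k in (m + 3):n) {
          sols <- tetra_complete(xyz[k - 3, ], xyz[k - 2, ], xyz[k - 1, ], edge)
          ok <- vapply(sols, function(p) {
            prev <- xyz[seq_len(k - 1), , drop = FALSE]
            clearance(p, c(m, m + 1)) > 7.1 &&
              min(sqrt(rowSums(sweep(prev, 2, p)^2))) > 0.5 * edge
          }, logical(1))
          if (!any(ok)) return(NULL)
          cl <- vapply(sols, clearance, numeric(1), exclude_rows = c(m, m + 1))
          cl[!ok] <- -Inf
          xyz[k, ] <- sols[[which.max(cl)]]
        }
      }
      xyz
    }
    done <- NULL
    for (idx in order(-scores)) {
      if (scores[idx] <= 7.1) break
      done <- grow_wing(cand[idx, ])
      if (!is.null(done)) break
    }
    if (is.null(done)) {
      stop("hinge construction failed: wings cannot keep clear of the ",
           "contact cutoff; reduce n or increase spacing", call. = FALSE)
    }
    xyz <- done
  }
  xyz
}

#' Generate a synthetic structural family
#'
#' Variants of a template structure with a controlled fraction of residues
#' displaced, emulating a protein family whose members share a fold but
#' differ in local contact topology. A rewiring rate of 0 reproduces the
#' template exactly; larger rates displace more residues, lowering both the
#' pairwise TM-score (on the identity correspondence) and, downstream, the
#' similarity of unfolding pathways -- monotonically in expectation.
#'
#' @param template A `calpha_structure` (e.g. from [make_toy()]).
#' @param n_variants Number of family members to generate.
#' @param rewiring_rate Fraction of residues displaced, in [0, 1].
#' @param seed Integer seed; the family is reproducible from
#'   `(template, n_variants, rewiring_rate, seed)`.
#' @param sd Displacement standard deviation in Angstrom (default 1,
#'   which spans roughly the TM-score range seen across real single-domain
#'   families as the rewiring rate goes from 0 to 0.5).
#' @return A list of `calpha_structure` objects (secondary-structure labels
#'   inherited from the template).
#' @examples
#' fam <- make_family(make_toy("lattice", n = 27), 3, rewiring_rate = 0.2)
#' @export
make_family <- function(template, n_variants, rewiring_rate, seed = 1,
                        sd = 1) {
  stopifnot(rewiring_rate >= 0, rewiring_rate <= 1, n_variants >= 1)
  n <- nrow(template)
  k <- ceiling(rewiring_rate * n)
  withr::with_seed(seed, {
    purrr::map(seq_len(n_variants), function(v) {
      out <- template
      if (k > 0) {
        pick <- sample.int(n, k)
        out$x[pick] <- out$x[pick] + stats::rnorm(k, sd = sd)
        out$y[pick] <- out$y[pick] + stats::rnorm(k, sd = sd)
        out$z[pick] <- out$z[pick] + stats::rnorm(k, sd = sd)
      }
      out
    })
  })
}
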