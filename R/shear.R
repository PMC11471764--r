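#' Radial neighbourhood weight for the local deformation gradient
#'
#' Piecewise-linear weight of a neighbour at native distance `r`: 1 inside
#' 6 Angstrom, ramping linearly to 0 between 6 and 8 Angstrom, 0 beyond.
#'
#' @param r Native distance(s) in Angstrom.
#' @return Weight(s) in [0, 1].
#' @export
shear_weight <- function(r) {
  stopifnot(all(r >= 0))
  pmin(1, pmax(0, 1 - 0.5 * (r - 6)))
}

#' Local deformation gradient at one residue
#'
#' Weighted least-squares estimate of the 3x3 linear map carrying the native
#' neighbourhood of residue `m` onto its displaced image:
#' `F_m = A_m D_m^{-1}` with
#' `A_m = sum_n w_mn dx'_mn dx_mn^T`, `D_m = sum_n w_mn dx_mn dx_mn^T`.
#' Exact for globally affine displacement fields. A nearly singular `D_m`
#' (coplanar or collinear neighbourhood, typically chain termini) is
#' regularized with a small ridge and flagged.
#'
#' @param coords0 `N x 3` native coordinates.
#' @param coords1 `N x 3` displaced coordinates.
#' @param m Residue index.
#' @param weights Length-N weight vector (weight of each residue as a
#'   neighbour of `m`; the self-weight is ignored). Defaults to
#'   [shear_weight()] of the native distances.
#' @param ridge Relative ridge added when `D_m` is ill-conditioned.
#' @return A 3x3 matrix with attribute `"regularized"` (logical).
#' @export
deformation_gradient <- function(coords0, coords1, m, weights = NULL,
                                 ridge = 1e-8) {
  dx0 <- sweep(coords0, 2, coords0[m, ])
  dx1 <- sweep(coords1, 2, coords1[m, ])
  if (is.null(weights)) weights <- shear_weight(sqrt(rowSums(dx0^2)))
  weights[m] <- 0
  nb <- which(weights > 0)
  if (length(nb) < 3L) {
    stop("residue ", m, " has fewer than 3 weighted neighbours", call. = FALSE)
  }
  w <- weights[nb]
  x0 <- dx0[nb, , drop = FALSE]
  x1 <- dx1[nb, , drop = FALSE]
  D <- crossprod(x0, x0 * w)
  A <- crossprod(x1, x0 * w)
  regularized <- FALSE
  if (rcond(D) < 1e-10) {
    D <- D + diag(ridge * sum(diag(D)) / 3, 3)
    regularized <- TRUE
  }
  f <- A %*% solve(D)
  attr(f, "regularized") <- regularized
  f
}

#' Shear energy of a local deformation gradient
#'
#' Eulerian finite strain `eps = (I - (F F^T)^{-1}) / 2`, its deviatoric
#' (traceless) part `gamma = eps - tr(eps)/3 * I`, and the shear energy
#' `s = sum_ij gamma_ij^2`. Exactly zero for rigid motions (rotations and
#' translations).
#'
#' @param F A 3x3 deformation gradient.
#' @return List with `strain` (eps), `deviatoric` (gamma) and `s` (scalar).
#' @export
shear_energy <- function(F) {
  b_inv <- tryCatch(solve(F %*% t(F)),
                    error = function(e) stop("singular deformation gradient",
                                             call. = FALSE))
  eps <- 0.5 * (diag(3) - b_inv)
  dev <- eps - (sum(diag(eps)) / 3) * diag(3)
  list(strain = eps, deviatoric = dev, s = sum(dev^2))
}

#' Per-residue shear field of the soft modes
#'
#' For every soft mode (ANM eigenvector with eigenvalue below the floppy
#' threshold), the mode is applied as a displacement of the native
#' coordinates and the resulting shear energy is accumulated residue by
#' residue; the total field highlights the floppy regions where unfolding
#' initiates.
#'
#' Eigenvectors are unit-normalized over the 3N components and applied at a
#' fixed amplitude (default 1 Angstrom times the unit vector); the field is
#' used comparatively (peaks, correlations), so the ranking is insensitive
#' to the amplitude choice. If the soft set holds nothing beyond the six
#' rigid-body modes the field would vanish identically; the default then
#' falls back to the lowest `fallback_k` non-floppy modes and flags the run
#' (set `fallback_k = 0` to get the zero field with a warning instead).
#'
#' @param net An `elastic_network`.
#' @param modes Optional precomputed `mode_set` for the current state.
#' @param amplitude Mode displacement amplitude in Angstrom.
#' @param floppy_threshold Floppy-mode eigenvalue threshold.
#' @param fallback_k Number of low-lying non-floppy modes used when only
#'   rigid-body modes are soft (default 20).
#' @return A `shear_field`: tibble with columns `residue`, `s` and
#'   `regularized` (deformation-gradient ridge flag), with attributes
#'   `q` (native-contact fraction of the state), `modes_used`, and
#'   `mode_path` (`"soft"` or `"lowlying"`).
#' @examples
#' net <- elastic_network(make_toy("lattice", n = 27))
#' softmode_shear_field(net)
#' @export
softmode_shear_field <- function(net, modes = NULL, amplitude = 1,
                                 floppy_threshold = 1e-4, fallback_k = 20) {
  if (is.null(modes)) modes <- floppy_modes(net, threshold = floppy_threshold)
  if (is.null(modes$vectors)) {
    stop("mode set was computed without eigenvectors", call. = FALSE)
  }
  n <- net$n
  use <- which(modes$values < floppy_threshold)
  mode_path <- "soft"
  if (length(use) <= 6L) {
    if (fallback_k > 0) {
      extra <- setdiff(order(modes$values), use)
      extra <- extra[seq_len(min(fallback_k, length(extra)))]
      use <- c(use, extra)
      mode_path <- "lowlying"
      warning("only rigid-body modes are soft; falling back to the ",
              length(extra), " lowest non-floppy modes", call. = FALSE)
    } else {
      warning("only rigid-body modes are soft; shear field is zero",
              call. = FALSE)
      out <- tibble::tibble(residue = seq_len(n), s = 0, regularized = FALSE)
      return(structure(out,
                       class = c("shear_field", class(tibble::tibble())),
                       q = native_fraction(net), modes_used = 0L,
                       mode_path = "rigid_only", amplitude = amplitude))
    }
  }
  d <- as.matrix(stats::dist(net$coords0))
  w0 <- matrix(shear_weight(d), n, n)
  diag(w0) <- 0
  s <- numeric(n)
  regularized <- logical(n)
  for (k in use) {
    v <- modes$vectors[, k]
    u <- matrix(v / sqrt(sum(v^2)), ncol = 3, byrow = TRUE) * amplitude
    coords1 <- net$coords0 + u
    for (m in seq_len(n)) {
      f <- deformation_gradient(net$coords0, coords1, m, weights = w0[m, ])
      s[m] <- s[m] + shear_energy(f)$s
      regularized[m] <- regularized[m] || attr(f, "regularized")
    }
  }
  out <- tibble::tibble(residue = seq_len(n), s = s, regularized = regularized)
  structure(out,
            class = c("shear_field", class(tibble::tibble())),
            q = native_fraction(net), modes_used = length(use),
            mode_path = mode_path, amplitude = amplitude)
}

#' Correlation between native shear and bond-breaking order
#'
#' Pearson correlation between the logarithm of the native-state per-residue
#' shear and the mean bond-breaking order from an unfolding run. A strong
#' negative value means high-shear (floppy) regions lose their bonds early.
#' Residues with no broken bonds or numerically zero shear are excluded and
#' counted.
#'
#' @param shear A `shear_field` (native state).
#' @param orders Output of [bond_breaking_order()].
#' @return One-row tibble with `r` (Pearson correlation), `n_used`,
#'   `n_excluded`.
#' @export
shear_order_correlation <- function(shear, orders) {
  joined <- dplyr::inner_join(tibble::as_tibble(shear),
                              tibble::as_tibble(orders), by = "residue")
  ok <- !is.na(joined$mean_order) & joined$s > 1e-300
  if (sum(ok) < 3L) {
    stop("fewer than 3 residues with defined order and positive shear",
         call. = FALSE)
  }
  tibble::tibble(
    r = stats::cor(log(joined$s[ok]), joined$mean_order[ok]),
    n_used = sum(ok),
    n_excluded = sum(!ok)
  )
}
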