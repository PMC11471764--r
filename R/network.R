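#' Build an elastic network from a structure
#'
#' Constructs the Gaussian-network Kirchhoff matrix for a C-alpha structure:
#' off-diagonal entries are `-c` for backbone pairs, `-1` for non-covalent
#' contacts within the cutoff, 0 otherwise; the diagonal is minus the row sum
#' of the off-diagonals, so every row sums to zero. The native coordinates
#' are retained for the anisotropic (ANM) Hessian.
#'
#' @param structure A `calpha_structure`.
#' @param c Backbone-to-contact spring-constant ratio (dimensionless).
#'   Default 9.3, the published value for the CI2 family; the Barnase family
#'   uses 2.3.
#' @param kappa Contact spring constant in kBT/Angstrom^2. Default 0.493
#'   (CI2); Barnase uses 0.945.
#' @param r_c Contact cutoff in Angstrom (default 7).
#' @param contacts Optional precomputed bond list from [contact_list()].
#' @return An `elastic_network` object: list with the Kirchhoff matrix
#'   `gamma`, native coordinates `coords0`, the bond table `bonds` (with an
#'   `intact` flag), parameters `c`, `kappa`, `r_c`, and the ordered list of
#'   `broken` bonds.
#' @examples
#' net <- elastic_network(make_toy("lattice", n = 27))
#' mean_coordination(net)
#' @export
elastic_network <- function(structure, c = 9.3, kappa = 0.493, r_c = 7,
                            contacts = NULL) {
  if (is.null(contacts)) contacts <- contact_list(structure, r_c = r_c)
  n <- nrow(structure)
  gamma <- build_gamma(contacts, c = c, n = n)
  structure(
    list(
      gamma = gamma,
      coords0 = coords_matrix(structure),
      bonds = dplyr::mutate(contacts, intact = TRUE),
      broken = tibble::tibble(i = integer(), j = integer()),
      c = c, kappa = kappa, r_c = r_c,
      residue_id = structure$residue_id,
      n = n
    ),
    class = "elastic_network"
  )
}

#' Assemble a Kirchhoff matrix from a bond list
#'
#' @param contacts Bond table as returned by [contact_list()] (columns `i`,
#'   `j`, `class`).
#' @param c Backbone spring-constant ratio.
#' @param n Number of residues.
#' @return An `n x n` Kirchhoff matrix with zero row sums.
#' @export
build_gamma <- function(contacts, c, n) {
  stopifnot(c > 0)
  g <- matrix(0, n, n)
  w <- ifelse(contacts$class == "backbone", c, 1)
  for (k in seq_len(nrow(contacts))) {
    i <- contacts$i[k]; j <- contacts$j[k]
    g[i, j] <- g[i, j] - w[k]
    g[j, i] <- g[j, i] - w[k]
  }
  diag(g) <- -rowSums(g)
  g
}

#' @export
print.elastic_network <- function(x, ...) {
  nb <- sum(x$bonds$intact)
  cat("<elastic_network> ", x$n, " residues, ", nb, " intact bonds (",
      sum(x$bonds$intact & x$bonds$class == "noncovalent"),
      " non-covalent), ", nrow(x$broken), " broken\n", sep = "")
  cat("  c = ", x$c, ", kappa = ", x$kappa, " kBT/A^2, r_c = ", x$r_c,
      " A, <z> = ", round(mean_coordination(x), 3), "\n", sep = "")
  invisible(x)
}

#' Break one non-covalent bond of the network
#'
#' Applies the bond-removal update to the Kirchhoff matrix
#' (`gamma[i,j] -> gamma[i,j] + 1`, diagonal entries decremented) and records
#' the event. Backbone bonds cannot be broken.
#'
#' @param net An `elastic_network`.
#' @param i,j Residue indices of the bond (i < j).
#' @return The updated network.
#' @export
break_bond <- function(net, i, j) {
  if (i > j) { tmp <- i; i <- j; j <- tmp }
  k <- which(net$bonds$i == i & net$bonds$j == j)
  if (length(k) != 1L || !net$bonds$intact[k]) {
    stop("no intact bond (", i, ", ", j, ")", call. = FALSE)
  }
  if (net$bonds$class[k] == "backbone") {
    stop("backbone bond (", i, ", ", j, ") cannot be broken", call. = FALSE)
  }
  net$gamma[i, j] <- net$gamma[i, j] + 1
  net$gamma[j, i] <- net$gamma[j, i] + 1
  net$gamma[i, i] <- net$gamma[i, i] - 1
  net$gamma[j, j] <- net$gamma[j, j] - 1
  net$bonds$intact[k] <- FALSE
  net$broken <- dplyr::bind_rows(net$broken, tibble::tibble(i = i, j = j))
  net
}

#' Mean coordination number of the current network state
#'
#' `<z> = 2 * (intact bonds) / N`, counting backbone and non-covalent bonds.
#'
#' @param net An `elastic_network`.
#' @return A single number.
#' @export
mean_coordination <- function(net) 2 * sum(net$bonds$intact) / net$n

#' Fraction of native non-covalent contacts intact
#' @param net An `elastic_network`.
#' @return Q in [0, 1]; 1 when no native contact has been broken. Networks
#'   with no non-covalent contacts report Q = 1.
#' @export
native_fraction <- function(net) {
  nc <- net$bonds$class == "noncovalent"
  if (!any(nc)) return(1)
  sum(net$bonds$intact[nc]) / sum(nc)
}

# Moore-Penrose pseudoinverse of a symmetric matrix by eigendecomposition,
# zeroing eigenvalues below tol * max|eigenvalue|.
sym_pinv <- function(m, tol = 1e-10) {
  e <- eigen(m, symmetric = TRUE)
  lmax <- max(abs(e$values))
  keep <- abs(e$values) > tol * max(lmax, .Machine$double.eps)
  if (!any(keep)) return(matrix(0, nrow(m), ncol(m)))
  v <- e$vectors[, keep, drop = FALSE]
  v %*% (t(v) / e$values[keep])
}

# Connected components of the current spring graph (union-find over the
# nonzero off-diagonal entries of the Kirchhoff matrix).
network_components <- function(net) {
  n <- net$n
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  edges <- which(net$gamma != 0 & upper.tri(net$gamma), arr.ind = TRUE)
  for (k in seq_len(nrow(edges))) {
    ri <- find(edges[k, 1]); rj <- find(edges[k, 2])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_len(n), function(x) as.integer(find(x)), integer(1))
  match(roots, unique(roots))
}

#' Mean-square distance fluctuations of the network
#'
#' The thermal fluctuation of the inter-residue distance vector for every
#' pair: `(3 kBT / kappa) * (Gp[i,i] + Gp[j,j] - 2 Gp[i,j])` with `Gp` the
#' Moore-Penrose pseudoinverse of the Kirchhoff matrix.
#'
#' @param net An `elastic_network`.
#' @param kBT Thermal energy unit (default 1, i.e. fluctuations in units of
#'   kBT/kappa).
#' @return An `N x N` symmetric matrix; entries on intact bonded pairs are
#'   the bond-breaking criterion of the thermal algorithm.
#' @export
pair_fluctuations <- function(net, kBT = 1) {
  gp <- sym_pinv(net$gamma)
  d <- diag(gp)
  (3 * kBT / net$kappa) * (outer(d, rep(1, net$n)) + outer(rep(1, net$n), d) - 2 * gp)
}

#' Per-residue mean-square fluctuations and predicted B-factors
#'
#' `<dR_i^2> = (3 kBT / kappa) Gp[i,i]`; the crystallographic B-factor is
#' `B_i = (8 pi^2 / 3) <dR_i^2>`.
#'
#' @inheritParams pair_fluctuations
#' @return A tibble with columns `residue`, `msf`, `b_pred`.
#' @export
residue_fluctuations <- function(net, kBT = 1) {
  gp <- sym_pinv(net$gamma)
  msf <- (3 * kBT / net$kappa) * diag(gp)
  tibble::tibble(residue = seq_len(net$n), msf = msf,
                 b_pred = (8 * pi^2 / 3) * msf)
}

#' Static displacements under an applied force field
#'
#' Solves the Hooke law `kappa * Gamma * u = F` componentwise with the
#' pseudoinverse of the Kirchhoff matrix. The net force on every connected
#' component of the network must vanish (componentwise), otherwise no static
#' solution exists.
#'
#' @param net An `elastic_network`.
#' @param forces `N x 3` matrix of forces (kBT/Angstrom).
#' @return `N x 3` matrix of displacements in Angstrom; within each
#'   connected component the mean displacement is zero.
#' @export
force_displacements <- function(net, forces) {
  forces <- as.matrix(forces)
  stopifnot(nrow(forces) == net$n, ncol(forces) == 3)
  comp <- network_components(net)
  for (cc in unique(comp)) {
    nf <- colSums(forces[comp == cc, , drop = FALSE])
    if (any(abs(nf) > 1e-8)) {
      stop("unbalanced force on fragment (component ", cc,
           " has net force ", paste(signif(nf, 3), collapse = ", "), ")",
           call. = FALSE)
    }
  }
  gp <- sym_pinv(net$gamma)
  (gp %*% forces) / net$kappa
}

#' End-pulling force field along x
#'
#' The canonical loading for force-induced unfolding: unit force along the x
#' axis at the two chain termini, `F_x(1) = -1`, `F_x(N) = +1`, zero
#' elsewhere.
#'
#' @param n Number of residues.
#' @return An `n x 3` force matrix.
#' @export
terminal_pull_forces <- function(n) {
  f <- matrix(0, n, 3)
  f[1, 1] <- -1
  f[n, 1] <- 1
  f
}

#' Anisotropic-network Hessian of the current network state
#'
#' `3N x 3N` Hessian built from the current Kirchhoff connectivity (broken
#' bonds excluded) and the native geometry: off-diagonal 3x3 blocks are
#' `kappa * Gamma[i,j] * n_ij n_ij^T` with `n_ij` the native bond unit
#' vector; diagonal blocks are minus the sum of the off-diagonal blocks in
#' their row.
#'
#' @param net An `elastic_network`.
#' @return A symmetric positive-semidefinite `3N x 3N` matrix.
#' @export
anm_hessian <- function(net) {
  n <- net$n
  h <- matrix(0, 3 * n, 3 * n)
  b <- net$bonds[net$bonds$intact, ]
  for (k in seq_len(nrow(b))) {
    i <- b$i[k]; j <- b$j[k]
    rij <- net$coords0[j, ] - net$coords0[i, ]
    rn <- sqrt(sum(rij^2))
    if (rn < 1e-8) {
      stop("coincident positions for bonded pair (", i, ", ", j, ")",
           call. = FALSE)
    }
    nij <- rij / rn
    blk <- net$kappa * net$gamma[i, j] * tcrossprod(nij)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    h[ii, jj] <- h[ii, jj] + blk
    h[jj, ii] <- h[jj, ii] + blk
    h[ii, ii] <- h[ii, ii] - blk
    h[jj, jj] <- h[jj, jj] - blk
  }
  h
}

#' Normal modes and floppy-mode count of an ANM Hessian
#'
#' Eigendecomposition of the Hessian with eigenvalues sorted ascending. A
#' mode is floppy when its eigenvalue falls below the threshold; rigid-body
#' translations and rotations always contribute six floppy modes, any excess
#' signals internal zero-energy motions (an under-constrained network).
#'
#' @param H A symmetric `3N x 3N` ANM Hessian, or an `elastic_network`
#'   (the Hessian is built on the fly).
#' @param threshold Floppy-mode eigenvalue threshold (default `1e-4`,
#'   absolute, in the units in which `kappa` scales the Hessian).
#' @param vectors Keep eigenvectors (default TRUE; set FALSE when only the
#'   count is needed).
#' @return A `mode_set`: list with `values` (ascending), `vectors`
#'   (3N x 3N, or NULL), `f_abs` (floppy count), `f_fraction` (`f_abs / 3N`),
#'   `n` (residue count) and `threshold`.
#' @export
floppy_modes <- function(H, threshold = 1e-4, vectors = TRUE) {
  if (inherits(H, "elastic_network")) H <- anm_hessian(H)
  e <- eigen(H, symmetric = TRUE, only.values = !vectors)
  ord <- order(e$values)
  values <- e$values[ord]
  vecs <- if (vectors) e$vectors[, ord, drop = FALSE] else NULL
  f_abs <- sum(values < threshold)
  structure(
    list(values = values, vectors = vecs, f_abs = f_abs,
         f_fraction = f_abs / length(values), n = length(values) / 3,
         threshold = threshold),
    class = "mode_set"
  )
}

#' @export
print.mode_set <- function(x, ...) {
  cat("<mode_set> 3N = ", length(x$values), " modes, ", x$f_abs,
      " floppy (fraction ", signif(x$f_fraction, 4), ") at threshold ",
      x$threshold, "\n", sep = "")
  invisible(x)
}

#' Fit the elastic-network spring parameters to experimental B-factors
#'
#' Scans a grid of backbone-stiffness ratios `c`; at each `c` the spring
#' constant `kappa` follows in closed form from a least-squares scale match
#' of predicted to experimental B-factors, and the returned pair maximizes
#' the Pearson correlation between prediction and experiment (the
#' correlation is invariant to `kappa`). The published constants
#' (c, kappa) = (9.3, 0.493) for the CI2 family and (2.3, 0.945) for the
#' Barnase family are sensible defaults when fitting is skipped.
#'
#' @param structure A `calpha_structure` with experimental B-factors.
#' @param r_c Contact cutoff (Angstrom).
#' @param c_grid Grid of candidate `c` values.
#' @param kBT Thermal energy unit.
#' @return A one-row tibble with `c`, `kappa`, `correlation` and the grid
#'   search trace as attribute `"trace"`.
#' @export
fit_bfactors <- function(structure, r_c = 7, c_grid = seq(1, 20, by = 0.1),
                         kBT = 1) {
  b <- structure$b_factor
  if (any(is.na(b))) stop("experimental B-factors missing", call. = FALSE)
  if (stats::sd(b) == 0) {
    stop("constant B-factors: correlation undefined", call. = FALSE)
  }
  contacts <- contact_list(structure, r_c = r_c)
  n <- nrow(structure)
  trace <- purrr::map_dfr(c_grid, function(cc) {
    g <- build_gamma(contacts, c = cc, n = n)
    p <- diag(sym_pinv(g))          # B_i = (8 pi^2 kBT / kappa) * p_i
    scale <- sum(p * b) / sum(p^2)  # least-squares slope of b ~ p
    tibble::tibble(c = cc,
                   kappa = 8 * pi^2 * kBT / scale,
                   correlation = stats::cor(p, b))
  })
  best <- trace[which.max(trace$correlation), ]
  attr(best, "trace") <- trace
  best
}
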