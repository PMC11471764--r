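#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an unfolding trajectory into its event table
#' @param x An `unfolding_trajectory`.
#' @param ... Unused.
#' @return A tibble with one row per bond-breaking event (`step`, `i`, `j`,
#'   `criterion`, `q`, `z`, `f`).
#' @method tidy unfolding_trajectory
#' @export
tidy.unfolding_trajectory <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of an unfolding run
#' @param x An `unfolding_trajectory`.
#' @param ... Unused.
#' @method glance unfolding_trajectory
#' @export
glance.unfolding_trajectory <- function(x, ...) {
  ev <- tibble::as_tibble(x)
  tibble::tibble(
    mode = attr(x, "mode"),
    n_residues = attr(x, "n_residues"),
    n_native = attr(x, "n_native"),
    n_events = nrow(ev),
    q_final = if (nrow(ev)) ev$q[nrow(ev)] else 1,
    z_final = if (nrow(ev)) ev$z[nrow(ev)] else NA_real_,
    f_final = if (nrow(ev)) ev$f[nrow(ev)] else NA_integer_
  )
}

#' Tidy a mode set into an eigenvalue table
#' @param x A `mode_set`.
#' @param ... Unused.
#' @method tidy mode_set
#' @export
tidy.mode_set <- function(x, ...) {
  tibble::tibble(mode = seq_along(x$values), eigenvalue = x$values,
                 floppy = x$values < x$threshold)
}

#' One-row summary of a mode set
#' @param x A `mode_set`.
#' @param ... Unused.
#' @method glance mode_set
#' @export
glance.mode_set <- function(x, ...) {
  tibble::tibble(n_modes = length(x$values), f_abs = x$f_abs,
                 f_fraction = x$f_fraction, threshold = x$threshold,
                 lambda_max = max(x$values))
}

#' Tidy a shear field
#' @param x A `shear_field`.
#' @param ... Unused.
#' @return Per-residue tibble with the network-state label `q` attached.
#' @method tidy shear_field
#' @export
tidy.shear_field <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x), q = attr(x, "q"))
}

#' Tidy the current bond table of an elastic network
#' @param x An `elastic_network`.
#' @param ... Unused.
#' @method tidy elastic_network
#' @export
tidy.elastic_network <- function(x, ...) x$bonds

#' One-row summary of an elastic network state
#' @param x An `elastic_network`.
#' @param ... Unused.
#' @method glance elastic_network
#' @export
glance.elastic_network <- function(x, ...) {
  tibble::tibble(n_residues = x$n,
                 n_bonds = sum(x$bonds$intact),
                 n_noncovalent = sum(x$bonds$intact &
                                       x$bonds$class == "noncovalent"),
                 n_broken = nrow(x$broken),
                 q = native_fraction(x), z = mean_coordination(x),
                 c = x$c, kappa = x$kappa, r_c = x$r_c)
}

#' Tidy a family comparison into a pairwise table
#' @param x A `family_comparison`.
#' @param ... Unused.
#' @return Long tibble with one row per unordered protein pair.
#' @method tidy family_comparison
#' @export
tidy.family_comparison <- function(x, ...) {
  ids <- x$protein_ids
  idx <- which(upper.tri(x$correlation), arr.ind = TRUE)
  out <- tibble::tibble(
    protein_a = ids[idx[, 1]], protein_b = ids[idx[, 2]],
    covariance = x$covariance[idx], correlation = x$correlation[idx]
  )
  if (!is.null(x$tm_scores)) out$tm_score <- x$tm_scores[idx]
  out
}

#' One-row summary of a family comparison
#' @param x A `family_comparison`.
#' @param ... Unused.
#' @method glance family_comparison
#' @export
glance.family_comparison <- function(x, ...) {
  ut <- upper.tri(x$correlation)
  tibble::tibble(
    n_proteins = length(x$protein_ids),
    mean_correlation = mean(x$correlation[ut]),
    mean_tm_score = if (is.null(x$tm_scores)) NA_real_
                    else mean(x$tm_scores[ut])
  )
}
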