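# Argmax over bond criteria with a deterministic tie rule: candidates within
# a small relative tolerance of the maximum (exact graph symmetries produce
# equal criteria up to rounding) resolve to the lexicographically smallest
# (i, j).
pick_max_pair <- function(crit, i, j, tol = 1e-9) {
  ties <- which(max(crit) - crit <= tol * max(abs(crit)))
  ties[order(i[ties], j[ties])][1]
}

#' Select the next bond to break under thermal unfolding
#'
#' Among the intact non-covalent bonds, finds the pair with the largest
#' mean-square distance fluctuation. Ties (possible on symmetric toy
#' networks) are broken toward the lexicographically smallest (i, j), so
#' runs are deterministic.
#'
#' @param net An `elastic_network`.
#' @param kBT Thermal energy unit.
#' @return A one-row tibble (`i`, `j`, `criterion`), or `NULL` when no
#'   non-covalent bond remains.
#' @export
thermal_step <- function(net, kBT = 1) {
  b <- net$bonds[net$bonds$intact & net$bonds$class == "noncovalent", ]
  if (nrow(b) == 0L) return(NULL)
  fl <- pair_fluctuations(net, kBT = kBT)
  crit <- fl[cbind(b$i, b$j)]
  best <- pick_max_pair(crit, b$i, b$j)
  tibble::tibble(i = b$i[best], j = b$j[best], criterion = crit[best])
}

#' Select the next bond to break under force-induced unfolding
#'
#' Solves the static displacements for the applied force with the current
#' connectivity and breaks the intact non-covalent bond with the largest
#' relative displacement magnitude `|u_i - u_j|` (3-D norm over the three
#' componentwise Hooke-law solves).
#'
#' @param net An `elastic_network`.
#' @param forces `N x 3` force matrix; defaults to the terminal x-pull
#'   `F_x(1) = -1`, `F_x(N) = +1`.
#' @return A one-row tibble (`i`, `j`, `criterion`), or `NULL` when no
#'   non-covalent bond remains.
#' @export
force_step <- function(net, forces = terminal_pull_forces(net$n)) {
  b <- net$bonds[net$bonds$intact & net$bonds$class == "noncovalent", ]
  if (nrow(b) == 0L) return(NULL)
  if (all(forces == 0)) {
    stop("zero force field: bond-stretch criterion undefined", call. = FALSE)
  }
  u <- force_displacements(net, forces)
  du <- u[b$i, , drop = FALSE] - u[b$j, , drop = FALSE]
  crit <- sqrt(rowSums(du^2))
  best <- pick_max_pair(crit, b$i, b$j)
  tibble::tibble(i = b$i[best], j = b$j[best], criterion = crit[best])
}

#' Run a bond-breaking unfolding simulation
#'
#' Repeats the thermal or force-induced bond-breaking step until the
#' requested number of bonds is broken or every non-covalent bond is gone.
#' After every event the fraction of native contacts Q, the mean
#' coordination number `<z>` and (optionally) the floppy-mode count of the
#' ANM Hessian at native geometry are recorded. Runs are fully
#' deterministic.
#'
#' @param net An `elastic_network` (native state).
#' @param mode `"thermal"` or `"force"`.
#' @param stop_after Maximum number of bonds to break (default: all
#'   non-covalent bonds). The published protocol stops CI2-family runs after
#'   110 events and Barnase-family runs after 200.
#' @param forces Force field for `mode = "force"`; defaults to the terminal
#'   x-pull.
#' @param kBT Thermal energy unit for the fluctuation criterion.
#' @param track_floppy Record the floppy-mode count after every event
#'   (one `3N x 3N` eigendecomposition per event; set FALSE for speed in
#'   large family sweeps).
#' @param floppy_threshold Floppy-mode eigenvalue threshold.
#' @return An `unfolding_trajectory`: a tibble of events with columns
#'   `step`, `i`, `j`, `criterion`, `q`, `z`, `f` (NA when not tracked),
#'   carrying the final network as attribute `"net"` and run settings as
#'   attributes.
#' @examples
#' traj <- run_unfolding(elastic_network(make_toy("lattice", n = 27)),
#'                       mode = "thermal", stop_after = 10)
#' traj
#' @export
run_unfolding <- function(net, mode = c("thermal", "force"),
                          stop_after = Inf,
                          forces = terminal_pull_forces(net$n),
                          kBT = 1, track_floppy = TRUE,
                          floppy_threshold = 1e-4) {
  mode <- match.arg(mode)
  net0 <- net
  n_native <- sum(net$bonds$class == "noncovalent")
  n_events <- min(stop_after, n_native)
  rows <- vector("list", n_events)
  step <- 0L
  while (step < n_events) {
    ev <- switch(mode,
                 thermal = thermal_step(net, kBT = kBT),
                 force = force_step(net, forces = forces))
    if (is.null(ev)) break
    step <- step + 1L
    net <- break_bond(net, ev$i, ev$j)
    f <- if (track_floppy) {
      floppy_modes(net, threshold = floppy_threshold, vectors = FALSE)$f_abs
    } else NA_integer_
    rows[[step]] <- tibble::tibble(
      step = step, i = ev$i, j = ev$j, criterion = ev$criterion,
      q = native_fraction(net), z = mean_coordination(net), f = f
    )
  }
  out <- dplyr::bind_rows(rows)
  structure(out,
            class = c("unfolding_trajectory", class(tibble::tibble())),
            net = net, net0 = net0, mode = mode, n_residues = net$n,
            n_native = n_native, kBT = kBT,
            floppy_threshold = floppy_threshold)
}

#' Final network state of a trajectory
#' @param traj An `unfolding_trajectory`.
#' @return The `elastic_network` after the last recorded event.
#' @export
final_network <- function(traj) attr(traj, "net")

#' Per-residue mean bond-breaking order
#'
#' For every residue, the mean of the 1-based ranks of the breaking events
#' involving it. Residues whose bonds never break in the recorded window get
#' `NA` and are excluded from downstream correlations.
#'
#' @param traj An `unfolding_trajectory`.
#' @return A tibble with columns `residue`, `mean_order`, `n_events`,
#'   covering all residues of the structure.
#' @export
bond_breaking_order <- function(traj) {
  n <- attr(traj, "n_residues")
  ev <- tibble::as_tibble(traj)
  long <- dplyr::bind_rows(
    dplyr::select(ev, residue = "i", "step"),
    dplyr::select(ev, residue = "j", "step")
  )
  agg <- long |>
    dplyr::group_by(.data$residue) |>
    dplyr::summarise(mean_order = mean(.data$step),
                     n_events = dplyr::n(), .groups = "drop")
  tibble::tibble(residue = seq_len(n)) |>
    dplyr::left_join(agg, by = "residue") |>
    dplyr::mutate(n_events = tidyr::replace_na(.data$n_events, 0L))
}
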