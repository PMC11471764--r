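#' Network state at an intermediate point of a trajectory
#'
#' Replays the first `step` bond-breaking events of a recorded trajectory
#' on the native network.
#'
#' @param traj An `unfolding_trajectory`.
#' @param step Number of events to replay (0 = native state).
#' @return An `elastic_network`.
#' @export
network_at <- function(traj, step) {
  net <- attr(traj, "net0")
  ev <- tibble::as_tibble(traj)
  stopifnot(step >= 0, step <= nrow(ev))
  for (k in seq_len(step)) net <- break_bond(net, ev$i[k], ev$j[k])
  net
}

#' Shear fields at checkpoints along an unfolding run
#'
#' Recomputes the soft-mode shear field at a set of trajectory snapshots
#' (given as event counts), e.g. to build the residue-vs-Q heat map.
#'
#' @param traj An `unfolding_trajectory`.
#' @param at_steps Integer vector of event counts (0 = native). Default:
#'   five evenly spaced checkpoints from native to the final state.
#' @param ... Passed to [softmode_shear_field()].
#' @return A list of `shear_field` objects.
#' @export
shear_snapshots <- function(traj, at_steps = NULL, ...) {
  n_ev <- nrow(tibble::as_tibble(traj))
  if (is.null(at_steps)) at_steps <- unique(round(seq(0, n_ev, length.out = 5)))
  purrr::map(at_steps, function(k) {
    suppressWarnings(softmode_shear_field(network_at(traj, k), ...))
  })
}

#' Divergence ranking of floppy-mode curves across a family
#'
#' Interpolates each trajectory's floppy-mode count as a function of the
#' mean coordination number onto a common grid and ranks proteins by the
#' maximum pairwise L2 distance between curves; proteins whose curves
#' diverge most tend to be the ones with distinct unfolding pathways.
#'
#' @param trajectories List of `unfolding_trajectory` objects (floppy
#'   tracking on).
#' @param ids Protein identifiers.
#' @param grid_size Number of grid points on the shared z range.
#' @return A tibble (`protein`, `divergence`) sorted descending, with the
#'   full pairwise distance matrix as attribute `"distances"`.
#' @export
floppy_divergence <- function(trajectories, ids = NULL, grid_size = 50) {
  stopifnot(length(trajectories) >= 2L)
  if (is.null(ids)) ids <- paste0("protein_", seq_along(trajectories))
  evs <- purrr::map(trajectories, tibble::as_tibble)
  if (any(vapply(evs, function(e) anyNA(e$f), logical(1)))) {
    stop("floppy counts missing; rerun with track_floppy = TRUE",
         call. = FALSE)
  }
  zmin <- max(vapply(evs, function(e) min(e$z), numeric(1)))
  zmax <- min(vapply(evs, function(e) max(e$z), numeric(1)))
  grid <- seq(zmin, zmax, length.out = grid_size)
  curves <- vapply(evs, function(e) {
    stats::approx(e$z, e$f, xout = grid, rule = 2, ties = mean)$y
  }, numeric(grid_size))
  np <- length(trajectories)
  d <- matrix(0, np, np, dimnames = list(ids, ids))
  for (i in seq_len(np - 1)) {
    for (j in (i + 1):np) {
      d[i, j] <- d[j, i] <- sqrt(mean((curves[, i] - curves[, j])^2))
    }
  }
  out <- tibble::tibble(protein = ids,
                        divergence = unname(apply(d, 1, max))) |>
    dplyr::arrange(dplyr::desc(.data$divergence))
  attr(out, "distances") <- d
  out
}

#' Run the full single-protein unfolding pipeline
#'
#' Reads (or accepts) a structure, builds the elastic network, runs the
#' bond-breaking simulation, computes shear fields at checkpoints and the
#' native-shear vs bond-breaking-order correlation, and (optionally) writes
#' `events.csv`, `shear.csv`, `shear_order.csv`, `floppy_curve.csv` and
#' `meta.json` to an output directory. Outputs are deterministic given the
#' inputs and configuration.
#'
#' @param pdb A `calpha_structure` or a path to a PDB file.
#' @param chain Chain identifier (when reading from file).
#' @param ss Optional secondary-structure annotation (see [set_ss()]).
#' @param mode `"thermal"` or `"force"`.
#' @param c,kappa,r_c Elastic-network parameters (defaults are the
#'   published CI2-family constants; use 2.3/0.945 for Barnase-family runs).
#' @param stop_after Number of bonds to break (default all; 110 for the
#'   CI2-family protocol, 200 for Barnase).
#' @param floppy_threshold Floppy-mode eigenvalue threshold.
#' @param amplitude Shear-field mode amplitude (Angstrom).
#' @param n_checkpoints Number of shear snapshots along the run.
#' @param kBT Thermal energy unit.
#' @param out_dir Output directory (created); `NULL` to skip writing.
#' @return Invisibly, a list with `structure`, `network`, `trajectory`,
#'   `shear_native`, `snapshots`, `orders`, `shear_order`, and `config`.
#' @export
cmd_run <- function(pdb, chain = NULL, ss = NULL,
                    mode = c("thermal", "force"),
                    c = 9.3, kappa = 0.493, r_c = 7,
                    stop_after = Inf, floppy_threshold = 1e-4,
                    amplitude = 1, n_checkpoints = 5, kBT = 1,
                    out_dir = NULL) {
  mode <- match.arg(mode)
  s <- if (inherits(pdb, "calpha_structure")) pdb else read_calpha(pdb, chain, ss = ss)
  if (!is.null(ss) && inherits(pdb, "calpha_structure")) s <- set_ss(s, ss)
  net <- elastic_network(s, c = c, kappa = kappa, r_c = r_c)
  traj <- run_unfolding(net, mode = mode, stop_after = stop_after,
                        kBT = kBT, floppy_threshold = floppy_threshold)
  shear_native <- suppressWarnings(
    softmode_shear_field(net, amplitude = amplitude,
                         floppy_threshold = floppy_threshold))
  snaps <- shear_snapshots(
    traj, at_steps = unique(round(seq(0, nrow(traj), length.out = n_checkpoints))),
    amplitude = amplitude, floppy_threshold = floppy_threshold)
  orders <- bond_breaking_order(traj)
  so <- shear_order_correlation(shear_native, orders)
  config <- list(mode = mode, chain = chain, c = c, kappa = kappa, r_c = r_c,
                 stop_after = if (is.finite(stop_after)) stop_after else "all",
                 floppy_threshold = floppy_threshold, amplitude = amplitude,
                 kBT = kBT, n_residues = nrow(s),
                 force_frame = if (mode == "force") "input x axis" else NULL,
                 shear_mode_path = attr(shear_native, "mode_path"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tidy(traj), file.path(out_dir, "events.csv"),
                     row.names = FALSE)
    utils::write.csv(purrr::map_dfr(snaps, tidy),
                     file.path(out_dir, "shear.csv"), row.names = FALSE)
    utils::write.csv(dplyr::bind_cols(so), file.path(out_dir, "shear_order.csv"),
                     row.names = FALSE)
    utils::write.csv(dplyr::select(tidy(traj), "z", "f"),
                     file.path(out_dir, "floppy_curve.csv"), row.names = FALSE)
    jsonlite::write_json(config, file.path(out_dir, "meta.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  invisible(list(structure = s, network = net, trajectory = traj,
                 shear_native = shear_native, snapshots = snaps,
                 orders = orders, shear_order = so, config = config))
}

#' Compare unfolding pathways across a family of structures
#'
#' Runs the bond-breaking simulation for every member, encodes the
#' bond-breaking sequences under a shared region scheme, and assembles the
#' pathway covariance/correlation matrices, pairwise TM-scores (identity
#' correspondence; equal-length members) and the floppy-curve divergence
#' ranking.
#'
#' @param structures List of `calpha_structure` objects.
#' @param ids Protein identifiers.
#' @param scheme A `region_scheme` shared by the family; default: generic
#'   scheme built from the first member's annotation.
#' @param n_bonds Common event count `N_b`; default: the smallest member's
#'   non-covalent contact count, capped by `stop_after`.
#' @param mode,c,kappa,r_c,stop_after,kBT As in [cmd_run()].
#' @param track_floppy Record floppy counts (needed for the divergence
#'   ranking; default TRUE).
#' @param tm Compute pairwise TM-scores (default TRUE; requires equal
#'   lengths for the identity correspondence).
#' @param out_dir Output directory; `NULL` to skip writing.
#' @return Invisibly, a list with `comparison` (a `family_comparison`),
#'   `trajectories`, `encodings`, and `divergence` (or NULL).
#' @export
cmd_family <- function(structures, ids = NULL, scheme = NULL, n_bonds = NULL,
                       mode = "thermal", c = 9.3, kappa = 0.493, r_c = 7,
                       stop_after = Inf, kBT = 1, track_floppy = TRUE,
                       tm = TRUE, out_dir = NULL) {
  stopifnot(length(structures) >= 2L)
  if (is.null(ids)) ids <- paste0("protein_", seq_along(structures))
  if (is.null(scheme)) scheme <- default_region_scheme(structures[[1]])
  trajs <- purrr::map(structures, function(s) {
    run_unfolding(elastic_network(s, c = c, kappa = kappa, r_c = r_c),
                  mode = mode, stop_after = stop_after, kBT = kBT,
                  track_floppy = track_floppy)
  })
  if (is.null(n_bonds)) {
    n_bonds <- min(vapply(trajs, nrow, numeric(1)))
  }
  encodings <- purrr::map2(trajs, ids, function(tr, id) {
    encode_pathway(tr, scheme, n_bonds = n_bonds, protein_id = id)
  })
  comparison <- family_covariance(encodings)
  if (tm) comparison <- add_tm_scores(comparison, structures)
  divergence <- if (track_floppy) floppy_divergence(trajs, ids) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_named_matrix <- function(m, file) {
      utils::write.csv(as.data.frame(m), file.path(out_dir, file))
    }
    write_named_matrix(comparison$correlation, "pathway_correlation.csv")
    write_named_matrix(comparison$covariance, "pathway_covariance.csv")
    if (!is.null(comparison$tm_scores)) {
      write_named_matrix(comparison$tm_scores, "tm_scores.csv")
    }
    ev <- purrr::map2_dfr(trajs, ids, function(tr, id) {
      dplyr::mutate(tidy(tr),
                    protein = id,
                    region_label = scheme$labels[assign_region(scheme, .data$i,
                                                               .data$j)])
    })
    utils::write.csv(ev, file.path(out_dir, "pathways.csv"), row.names = FALSE)
    if (!is.null(divergence)) {
      utils::write.csv(divergence, file.path(out_dir, "divergence.csv"),
                       row.names = FALSE)
    }
  }
  invisible(list(comparison = comparison, trajectories = trajs,
                 encodings = encodings, divergence = divergence,
                 scheme = scheme, n_bonds = n_bonds))
}

#' Write a synthetic fixture structure to a PDB file
#'
#' @inheritParams make_toy
#' @param out Output PDB path.
#' @return The structure, invisibly.
#' @export
cmd_fixtures <- function(kind, n, seed = 1, out = NULL, ...) {
  s <- make_toy(kind, n = n, seed = seed, ...)
  if (!is.null(out)) write_calpha_pdb(s, out)
  invisible(s)
}

#' Fit spring parameters to B-factors and report the result
#'
#' @param pdb A `calpha_structure` or PDB path.
#' @param chain Chain identifier.
#' @param r_c Contact cutoff.
#' @param out Optional CSV path for the fit and its grid trace.
#' @return The one-row fit tibble (see [fit_bfactors()]), invisibly.
#' @export
cmd_fit_bfactors <- function(pdb, chain = NULL, r_c = 7, out = NULL) {
  s <- if (inherits(pdb, "calpha_structure")) pdb else read_calpha(pdb, chain)
  fit <- fit_bfactors(s, r_c = r_c)
  if (!is.null(out)) {
    utils::write.csv(attr(fit, "trace"), out, row.names = FALSE)
  }
  invisible(fit)
}
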