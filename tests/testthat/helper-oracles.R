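# Independent oracles and tiny fixtures shared across the suite.
# Everything here deliberately avoids the package's own linear-algebra path:
# pseudoinverses go through MASS::ginv (SVD), networks are rebuilt from
# scratch at every step.

# Random bead-spring toy: a 3-D random walk chain with 3.8 A steps,
# regenerated until it has between 1 and max_contacts non-covalent contacts.
random_toy_structure <- function(n, seed, r_c = 7, max_contacts = 10) {
  withr::with_seed(seed, {
    for (attempt in 1:50) {
      dirs <- matrix(stats::rnorm(3 * (n - 1)), ncol = 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      xyz <- rbind(0, apply(dirs * 3.8, 2, cumsum))
      d <- as.matrix(stats::dist(xyz))
      sep <- abs(row(d) - col(d)) > 1
      nc <- sum(d[sep & upper.tri(d)] < r_c)
      clash <- min(d[upper.tri(d)]) < 1
      if (nc >= 1 && nc <= max_contacts && !clash) break
    }
    tibble::tibble(
      residue = seq_len(n), residue_id = seq_len(n),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      b_factor = NA_real_, chain = "A", ss = NA_character_
    ) |> structure(class = c("calpha_structure", class(tibble::tibble())))
  })
}

# From-scratch thermal bond-breaking sequence: rebuilds the Kirchhoff matrix
# from the surviving contact set at every step and uses an SVD pseudoinverse.
oracle_thermal_sequence <- function(structure, c, kappa = 1, r_c = 7,
                                    stop_after = Inf) {
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  backbone <- pairs[pairs[, 2] - pairs[, 1] == 1, , drop = FALSE]
  noncov <- pairs[pairs[, 2] - pairs[, 1] > 1 & d[pairs] < r_c, , drop = FALSE]
  events <- list()
  while (nrow(noncov) > 0 && length(events) < stop_after) {
    g <- matrix(0, n, n)
    for (k in seq_len(nrow(backbone))) {
      i <- backbone[k, 1]; j <- backbone[k, 2]
      g[i, j] <- g[j, i] <- -c
    }
    for (k in seq_len(nrow(noncov))) {
      i <- noncov[k, 1]; j <- noncov[k, 2]
      g[i, j] <- g[j, i] <- -1
    }
    diag(g) <- -rowSums(g)
    gp <- MASS::ginv(g)
    crit <- vapply(seq_len(nrow(noncov)), function(k) {
      i <- noncov[k, 1]; j <- noncov[k, 2]
      (3 / kappa) * (gp[i, i] + gp[j, j] - 2 * gp[i, j])
    }, numeric(1))
    best <- which(max(crit) - crit <= 1e-9 * max(abs(crit)))
    if (length(best) > 1) {
      best <- best[order(noncov[best, 1], noncov[best, 2])][1]
    }
    events[[length(events) + 1]] <- noncov[best, ]
    noncov <- noncov[-best, , drop = FALSE]
  }
  do.call(rbind, events)
}

# Four-bead square toy: backbone 1-2-3-4 plus contacts (1,3), (2,4), (1,4).
# Coordinates on a 4.8 A square so the diagonals (6.79 A) sit under the
# 7 A cutoff; optionally perturbed to break the symmetry degeneracy.
square_toy <- function(perturb = 0.1) {
  a <- 4.8
  xyz <- rbind(c(0, 0, 0), c(a, 0, 0), c(a, a, 0), c(0, a, 0))
  xyz[3, 1] <- xyz[3, 1] + perturb
  tibble::tibble(
    residue = 1:4, residue_id = 1:4,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    b_factor = NA_real_, chain = "A", ss = NA_character_
  ) |> structure(class = c("calpha_structure", class(tibble::tibble())))
}

# Minimal stand-in network for unit tests that exercise the linear algebra
# on hand-written Kirchhoff matrices (no geometry needed).
fake_net <- function(gamma, kappa = 1, bonds = NULL, coords0 = NULL) {
  structure(list(gamma = gamma, kappa = kappa, n = nrow(gamma),
                 bonds = bonds, coords0 = coords0, c = NA, r_c = NA,
                 broken = tibble::tibble(i = integer(), j = integer())),
            class = "elastic_network")
}

rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  k <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * k + (1 - cos(angle)) * (k %*% k)
}

rotate_structure <- function(structure, rot) {
  xyz <- as.matrix(structure[, c("x", "y", "z")]) %*% t(rot)
  structure$x <- xyz[, 1]; structure$y <- xyz[, 2]; structure$z <- xyz[, 3]
  structure
}
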