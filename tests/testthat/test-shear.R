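test_that("the neighbourhood weight ramps from 1 to 0 between 6 and 8 A", {
  expect_equal(shear_weight(5), 1)
  expect_equal(shear_weight(7), 0.5)
  expect_equal(shear_weight(9), 0)
  expect_equal(shear_weight(6), 1)
  expect_equal(shear_weight(8), 0)
  r <- seq(0, 10, by = 0.01)
  w <- shear_weight(r)
  expect_true(all(w >= 0 & w <= 1))
  expect_true(all(diff(w) <= 1e-12))
})

test_that("the deformation gradient reproduces affine maps exactly", {
  withr::with_seed(11, {
    coords0 <- matrix(stats::rnorm(60, sd = 3), 20, 3)
    m_aff <- diag(3) + matrix(stats::rnorm(9, sd = 0.1), 3, 3)
    coords1 <- coords0 %*% t(m_aff)
    for (m in 1:20) {
      f <- deformation_gradient(coords0, coords1, m)
      expect_equal(unclass(f), m_aff, tolerance = 1e-10,
                   ignore_attr = TRUE)
    }
    # identity displacement
    f0 <- deformation_gradient(coords0, coords0, 5)
    expect_equal(unclass(f0), diag(3), tolerance = 1e-12, ignore_attr = TRUE)
  })
})

test_that("the deformation gradient matches a weighted least-squares oracle", {
  withr::with_seed(12, {
    coords0 <- matrix(stats::rnorm(60, sd = 3), 20, 3)
    # smooth nonlinear displacement field
    u <- 0.2 * sin(coords0 / 4) + 0.05 * coords0^2 / 10
    coords1 <- coords0 + u
    for (m in c(1, 7, 20)) {
      f <- deformation_gradient(coords0, coords1, m)
      dx0 <- sweep(coords0, 2, coords0[m, ])
      w <- shear_weight(sqrt(rowSums(dx0^2))); w[m] <- 0
      nb <- which(w > 0)
      # independent route: three weighted linear model fits, one per
      # displaced component, no intercept
      f_ref <- t(vapply(1:3, function(comp) {
        dx1 <- coords1[nb, comp] - coords1[m, comp]
        stats::lm.wfit(dx0[nb, , drop = FALSE], dx1, w[nb])$coefficients
      }, numeric(3)))
      expect_equal(unclass(f), unname(f_ref), tolerance = 1e-8,
                   ignore_attr = TRUE)
    }
  })
})

test_that("ill-conditioned neighbourhoods are ridge-regularized and flagged", {
  # all neighbours in the z = 0 plane: D_m is singular
  coords0 <- cbind(c(0, 3, 0, -3, 0), c(0, 0, 3, 0, -3), 0)
  f <- deformation_gradient(coords0, coords0 * 1.1, 1)
  expect_true(attr(f, "regularized"))
})

test_that("shear energy follows the Eulerian strain formulas", {
  expect_equal(shear_energy(diag(3))$s, 0)
  rot <- rotation_matrix(c(1, 1, 0), 0.8)
  expect_equal(shear_energy(rot)$s, 0, tolerance = 1e-14)

  # isochoric stretch diag(l, 1/l, 1): independent closed-form evaluation
  l <- 1.1
  f <- diag(c(l, 1 / l, 1))
  eps <- diag((1 - c(l, 1 / l, 1)^-2) / 2)
  gam <- eps - (sum(diag(eps)) / 3) * diag(3)
  expect_equal(shear_energy(f)$s, sum(gam^2), tolerance = 1e-14)
  expect_equal(shear_energy(f)$strain, eps, tolerance = 1e-14)

  expect_error(shear_energy(matrix(0, 3, 3)), "singular")
})

test_that("rigid-body motions carry vanishing shear relative to floppy modes", {
  h <- make_toy("hinge", n = 12)
  net <- elastic_network(h)
  n <- net$n
  field_total <- function(coords1) {
    sum(vapply(seq_len(n), function(m) {
      shear_energy(deformation_gradient(net$coords0, coords1, m))$s
    }, numeric(1)))
  }
  # exact rigid motions: translations along each axis, rotations about the
  # centroid about each axis
  cen <- colMeans(net$coords0)
  displaced <- c(
    lapply(1:3, function(axis) {
      t <- c(0, 0, 0); t[axis] <- 1.5
      sweep(net$coords0, 2, t, "+")
    }),
    lapply(list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), function(axis) {
      rot <- rotation_matrix(axis, 0.05)
      sweep(sweep(net$coords0, 2, cen) %*% t(rot), 2, cen, "+")
    })
  )
  s_rigid <- vapply(displaced, field_total, numeric(1))
  s_floppy_max <- max(softmode_shear_field(net)$s)
  expect_true(all(s_rigid < 1e-8 * s_floppy_max))
})

test_that("the soft-mode field peaks at the hinge residues", {
  for (n in c(8, 12, 16)) {
    h <- make_toy("hinge", n = n)
    sf <- softmode_shear_field(elastic_network(h))
    expect_equal(attr(sf, "mode_path"), "soft")
    m <- n %/% 2
    expect_true(which.max(sf$s) %in% c(m, m + 1))
    expect_true(all(sf$s >= 0))
  }
})

test_that("shear is invariant under a consistent global rotation", {
  # rotating the native frame and the displacement field together must
  # leave every residue's shear unchanged
  h <- make_toy("hinge", n = 10)
  net <- elastic_network(h)
  modes <- floppy_modes(net)
  v <- modes$vectors[, 7]
  u <- matrix(v / sqrt(sum(v^2)), ncol = 3, byrow = TRUE)
  rot <- rotation_matrix(c(2, -1, 1), 1.1)
  c0 <- net$coords0; c1 <- c0 + u
  s_orig <- vapply(seq_len(net$n), function(m) {
    shear_energy(deformation_gradient(c0, c1, m))$s
  }, numeric(1))
  s_rot <- vapply(seq_len(net$n), function(m) {
    shear_energy(deformation_gradient(c0 %*% t(rot), c1 %*% t(rot), m))$s
  }, numeric(1))
  expect_equal(s_rot, s_orig, tolerance = 1e-9)
})

test_that("mode amplitude scales shear quadratically at leading order", {
  h <- make_toy("hinge", n = 10)
  net <- elastic_network(h)
  modes <- floppy_modes(net)
  s_small <- softmode_shear_field(net, modes = modes, amplitude = 0.01)
  s_double <- softmode_shear_field(net, modes = modes, amplitude = 0.02)
  ratio <- sum(s_double$s) / sum(s_small$s)
  expect_equal(ratio, 4, tolerance = 0.05)
})

test_that("rigid-only mode sets fall back or return a zero field", {
  tri <- elastic_network(make_toy("triangle", n = 8))
  expect_warning(sf <- softmode_shear_field(tri), "falling back")
  expect_equal(attr(sf, "mode_path"), "lowlying")
  expect_true(any(sf$s > 0))
  expect_warning(sf0 <- softmode_shear_field(tri, fallback_k = 0),
                 "zero")
  expect_equal(sf0$s, rep(0, 8))
  expect_equal(attr(sf0, "mode_path"), "rigid_only")
})

test_that("shear-order correlation handles exact and null relations", {
  sf <- tibble::tibble(residue = 1:50, s = exp(seq(0.1, 5, length.out = 50)),
                       regularized = FALSE)
  attr(sf, "q") <- 1
  class(sf) <- c("shear_field", class(tibble::tibble()))
  # orders exactly linear in log(s): r = 1; anti-monotone: r = -1
  up <- tibble::tibble(residue = 1:50, mean_order = 2 + 3 * log(sf$s),
                       n_events = 1L)
  dn <- tibble::tibble(residue = 1:50, mean_order = 2 - 3 * log(sf$s),
                       n_events = 1L)
  expect_equal(shear_order_correlation(sf, up)$r, 1, tolerance = 1e-12)
  expect_equal(shear_order_correlation(sf, dn)$r, -1, tolerance = 1e-12)

  # permutation null: mean correlation ~ 0 within 3 standard errors
  rs <- withr::with_seed(21, {
    vapply(1:1000, function(k) {
      shuffled <- up; shuffled$mean_order <- sample(up$mean_order)
      shear_order_correlation(sf, shuffled)$r
    }, numeric(1))
  })
  expect_lt(abs(mean(rs)), 3 * stats::sd(rs) / sqrt(length(rs)))

  few <- tibble::tibble(residue = 1:2, mean_order = 1:2, n_events = 1L)
  expect_error(shear_order_correlation(sf[1:2, ], few), "fewer than 3")
})
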