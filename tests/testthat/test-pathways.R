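# hand-built trajectory stub: only i/j/step are consulted by the encoder
fake_traj <- function(i, j) {
  out <- tibble::tibble(step = seq_along(i), i = i, j = j, criterion = 1,
                        q = 1, z = 1, f = NA_integer_)
  class(out) <- c("unfolding_trajectory", class(tibble::tibble()))
  out
}

# CI2-like annotated structure: a lattice fold whose residues are labelled
# with the canonical secondary-structure elements
ci2_like_structure <- function() {
  s <- make_toy("lattice", n = 35, seed = 9)
  set_ss(s, rep(c("N-terminus", "beta1", "alpha", "loop1", "beta2",
                  "loop2", "beta3"), each = 5))
}

test_that("the CI2 scheme has the five canonical regions", {
  s <- ci2_like_structure()
  scheme <- default_region_scheme(s, family = "ci2")
  expect_equal(scheme$n_regions, 5)
  expect_equal(scheme$labels,
               c("N-terminus-beta3", "alpha-loop2", "beta1-beta2",
                 "beta2-beta3", "rest"))
  # a bond between a beta1 residue and a beta2 residue maps to region 3
  b1 <- which(s$ss == "beta1")[1]; b2 <- which(s$ss == "beta2")[1]
  expect_equal(assign_region(scheme, b1, b2), 3)
  # order of the pair does not matter
  expect_equal(assign_region(scheme, b2, b1), 3)
  # anything unnamed falls into rest (region 5)
  a <- which(s$ss == "alpha")[1]
  expect_equal(assign_region(scheme, a, a + 1), 5)
})

test_that("the barnase scheme enumerates populated element pairs up to 30", {
  s <- make_toy("lattice", n = 63, seed = 10)
  s <- set_ss(s, rep(c("N-terminus", "alpha1", "loop1", "beta1", "alpha2",
                       "loop2", "beta2", "alpha3", "beta3"), each = 7))
  scheme <- default_region_scheme(s, family = "barnase")
  expect_lte(scheme$n_regions, 30)
  expect_equal(scheme$labels[scheme$n_regions], "rest")
  # every region except rest is populated by at least one native contact
  cl <- contact_list(s)
  nc <- cl[cl$class == "noncovalent", ]
  regions <- assign_region(scheme, nc$i, nc$j)
  expect_true(all(seq_len(scheme$n_regions - 1) %in% regions))
})

test_that("a generic scheme with two elements yields four regions", {
  s <- make_toy("lattice", n = 27, seed = 1, ss_segments = 2)
  scheme <- default_region_scheme(s)
  expect_equal(scheme$n_regions, 4)
})

test_that("schemes require an annotation", {
  s <- make_toy("lattice", n = 27, seed = 1)
  expect_error(default_region_scheme(s), "set_ss")
})

test_that("pathway encoding produces one-hot rows in event order", {
  s <- ci2_like_structure()
  scheme <- default_region_scheme(s, family = "ci2")
  nt <- which(s$ss == "N-terminus")[1]; b3 <- which(s$ss == "beta3")[1]
  traj <- fake_traj(i = rep(nt, 3), j = rep(b3, 3))
  enc <- encode_pathway(traj, scheme, protein_id = "toy")
  expect_equal(enc$flat, rep(c(1, 0, 0, 0, 0), 3))
  expect_equal(rowSums(enc$matrix), rep(1, 3))
  # identical trajectories encode identically
  enc2 <- encode_pathway(traj, scheme, protein_id = "toy")
  expect_identical(enc$matrix, enc2$matrix)
  # decode (row argmax) recovers the region sequence
  expect_equal(apply(enc$matrix, 1, which.max), enc$regions)
})

test_that("short trajectories pad with zero rows to the family bond count", {
  s <- ci2_like_structure()
  scheme <- default_region_scheme(s, family = "ci2")
  traj <- fake_traj(i = c(1, 2), j = c(10, 12))
  expect_message(enc <- encode_pathway(traj, scheme, n_bonds = 4), "padding")
  expect_equal(nrow(enc$matrix), 4)
  expect_equal(rowSums(enc$matrix), c(1, 1, 0, 0))
  expect_equal(enc$n_padded, 2)
})

test_that("family covariance matches a hand computation and is PSD", {
  enc <- function(regions, id, n_r = 2) {
    m <- matrix(0L, length(regions), n_r)
    m[cbind(seq_along(regions), regions)] <- 1L
    structure(list(matrix = m, flat = as.vector(t(m)), regions = regions,
                   n_b = length(regions), n_r = n_r, n_padded = 0,
                   protein_id = id), class = "pathway_encoding")
  }
  a <- enc(c(1, 1, 2), "a")
  b <- enc(c(1, 2, 2), "b")
  cmp <- family_covariance(list(a, b))
  # hand computation: flat_a = 100110 -> (1,0,1,0,0,1); flat_b = (1,0,0,1,0,1)
  fa <- c(1, 0, 1, 0, 0, 1); fb <- c(1, 0, 0, 1, 0, 1)
  expect_equal(cmp$covariance[1, 2], stats::cov(fa, fb), tolerance = 1e-12)
  expect_equal(cmp$correlation[1, 2], stats::cor(fa, fb), tolerance = 1e-12)
  expect_equal(diag(cmp$correlation), c(a = 1, b = 1), ignore_attr = TRUE)

  # identical pathways correlate at exactly 1; fully displaced ones below 1
  cmp2 <- family_covariance(list(a, enc(c(1, 1, 2), "a2")))
  expect_equal(cmp2$correlation[1, 2], 1)
  cmp3 <- family_covariance(list(a, enc(c(2, 2, 1), "flip")))
  expect_lt(cmp3$correlation[1, 2], 1)

  # PSD: Gram structure of the centered rows
  ev <- eigen(cmp$covariance, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= -1e-10))

  # input order only permutes rows/columns
  cmp_rev <- family_covariance(list(b, a))
  expect_equal(cmp_rev$correlation[2, 1], cmp$correlation[1, 2])

  expect_error(family_covariance(list(a, enc(c(1, 2), "short"))),
               "N_b, N_r")
})

test_that("TM-score is exact on identity and rigid rotation", {
  s <- make_toy("lattice", n = 27, seed = 1)
  expect_equal(tm_score(s, s), 1, tolerance = 1e-9)
  s2 <- rotate_structure(s, rotation_matrix(c(1, 2, -1), 1.3))
  s2$x <- s2$x + 20
  expect_equal(tm_score(s, s2), 1, tolerance = 1e-9)
  expect_error(tm_score(s, make_toy("lattice", n = 20)), "correspondence")
})

test_that("TM-score matches closed form when one point is displaced far", {
  # four points, one moved 25 A away: the optimal superposition aligns the
  # congruent triple exactly, the outlier contributes 1/(1 + (25/d0)^2)
  xyz <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(1.9, 3.3, 0), c(1.9, 1.1, 3.1))
  a <- xyz
  b <- xyz; b[4, ] <- b[4, ] + c(0, 0, 25)
  d0 <- 0.5  # L = 4 uses the floor value
  expected <- (3 + 1 / (1 + (25 / d0)^2)) / 4
  got <- tm_score(a, b)
  expect_equal(got, expected, tolerance = 1e-6)
  # brute-force rotation-grid oracle can only do worse or equal
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  best <- 0
  for (ax in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))) {
    for (ang in grid) {
      rot <- rotation_matrix(ax, ang)
      ar <- sweep(a, 2, colMeans(a)) %*% t(rot)
      br <- sweep(b, 2, colMeans(b))
      d <- sqrt(rowSums((ar - br)^2))
      best <- max(best, mean(1 / (1 + (d / d0)^2)))
    }
  }
  expect_gte(got + 1e-9, best)
})

test_that("pathway correlation co-varies with structural similarity", {
  # synthetic families: higher rewiring -> lower TM-score and lower pathway
  # correlation; their pooled association is positive
  template <- make_toy("lattice", n = 27, seed = 1, ss_segments = 3)
  scheme <- default_region_scheme(template)
  stats_at <- function(rate, seed) {
    fam <- make_family(template, 3, rate, seed = seed)
    res <- suppressMessages(
      cmd_family(fam, scheme = scheme, stop_after = 25, track_floppy = FALSE))
    glance(res$comparison)
  }
  pts <- purrr::map_dfr(1:6, function(seed) {
    purrr::map_dfr(c(0, 0.5), function(rate) {
      dplyr::mutate(stats_at(rate, seed), rate = rate)
    })
  })
  expect_gt(stats::cor(pts$mean_tm_score, pts$mean_correlation,
                       method = "spearman"), 0)
  agg <- dplyr::summarise(dplyr::group_by(pts, rate),
                          corr = mean(mean_correlation),
                          tm = mean(mean_tm_score))
  expect_gt(agg$corr[agg$rate == 0], agg$corr[agg$rate == 0.5])
  expect_gt(agg$tm[agg$rate == 0], agg$tm[agg$rate == 0.5])
})
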