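test_that("radius of gyration matches closed-form cases", {
  expect_equal(radius_of_gyration(matrix(c(4, 5, 6), 1, 3), 2), 0)
  expect_equal(
    radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0)), c(1, 1)), 1)
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_equal(radius_of_gyration(sq, rep(1, 4)), 0.70711,
    tolerance = 1e-5)
  # agreement with explicit-sum oracle on random weighted clouds
  set.seed(5)
  for (rep in 1:5) {
    coords <- matrix(rnorm(30), 10, 3)
    m <- runif(10, 0.5, 3)
    expect_equal(radius_of_gyration(coords, m), oracle_rg(coords, m),
      tolerance = 1e-12)
  }
  expect_error(radius_of_gyration(sq, c(1, 1, -1, 1)), "masses")
})

test_that("R_g is rigid-motion invariant and scales linearly", {
  set.seed(7)
  coords <- matrix(rnorm(60, sd = 4), 20, 3)
  m <- runif(20, 50, 200)
  rg0 <- radius_of_gyration(coords, m)
  for (rep in 1:5) {
    rot <- random_rotation_matrix()
    shift <- rnorm(3, sd = 20)
    moved <- sweep(coords %*% rot, 2, shift, "+")
    expect_equal(radius_of_gyration(moved, m), rg0, tolerance = 1e-9)
  }
  expect_equal(radius_of_gyration(coords * 2.5, m), 2.5 * rg0,
    tolerance = 1e-9)
})

test_that("rg_series follows frames, selections, and generator labels", {
  ens <- sample_chain(chain_model(n_residues = 10), n_frames = 4, seed = 2)
  # constant-conformation ensemble gives a constant series
  const <- conformer_ensemble(ens$atoms, rep(ens$frames[1], 4))
  sr <- rg_series(const)
  expect_equal(sr$rg, rep(sr$rg[1], 4))
  expect_equal(sr$frame, 1:4)

  # a rigidly rotated frame copy has an identical value
  set.seed(13)
  rot_frames <- list(ens$frames[[1]], ens$frames[[1]] %*%
    random_rotation_matrix())
  rot <- conformer_ensemble(ens$atoms, rot_frames)
  srr <- rg_series(rot)$rg
  expect_equal(srr[1], srr[2], tolerance = 1e-9)

  # two-state mixture: compact-labelled frames are smaller on average
  mix <- mixture_ensemble(0.5, n_frames = 80, seed = 5)
  labels <- attr(mix, "labels")
  rg <- rg_series(mix)$rg
  expect_gt(mean(rg[labels == "extended"]), mean(rg[labels == "compact"]))

  expect_error(rg_series(ens, residues = 999), "no atoms")
})

test_that("rg_histogram normalizes, counts, and refines consistently", {
  # all-identical values occupy a single bin with frequency 1
  h1 <- rg_histogram(rep(12.3, 50))
  expect_equal(sum(h1$frequency), 1)
  expect_equal(sum(h1$frequency > 0), 1L)
  expect_equal(h1$frequency[h1$bin_lo == 12], 1)

  # seeded uniform sample: frequencies match direct counting
  set.seed(31)
  x <- runif(500, 3, 27)
  h <- rg_histogram(x, bin_width = 1)
  for (k in sample(nrow(h), 10)) {
    direct <- sum(x >= h$bin_lo[k] & x < h$bin_hi[k]) / length(x)
    expect_equal(h$frequency[k], direct)
  }

  # total mass conserved under bin refinement
  h2 <- rg_histogram(x, bin_width = 0.25)
  expect_equal(sum(h2$frequency), 1)
  coarse_mass <- sum(h$frequency[h$bin_lo >= 10 & h$bin_hi <= 20])
  fine_mass <- sum(h2$frequency[h2$bin_lo >= 10 & h2$bin_hi <= 20])
  expect_equal(coarse_mass, fine_mass, tolerance = 1e-12)

  expect_error(rg_histogram(x, bin_width = 0), "bin_width")
  expect_error(rg_histogram(numeric(0)), "at least one")
})

test_that("KS statistic matches the brute-force ECDF sweep and ks.test", {
  expect_equal(ks_statistic(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_statistic(c(1, 2, 3), c(10, 11, 12)), 1)

  set.seed(17)
  for (rep in 1:8) {
    a <- rnorm(40, mean = runif(1, 10, 15), sd = runif(1, 1, 4))
    b <- rnorm(55, mean = runif(1, 10, 20), sd = runif(1, 1, 4))
    d <- ks_statistic(a, b)
    expect_equal(d, oracle_ks(a, b), tolerance = 1e-12)
    expect_equal(d, unname(stats::ks.test(a, b)$statistic),
      tolerance = 1e-12)
    expect_equal(d, ks_statistic(b, a)) # symmetry
  }

  # triangle-like bound on ECDF distances
  set.seed(19)
  a <- rnorm(30); b <- rnorm(30, 1); c <- rnorm(30, 2)
  expect_lte(ks_statistic(a, c),
    ks_statistic(a, b) + ks_statistic(b, c) + 1e-12)
})

test_that("spread statistics behave on constant, Gaussian, and duplicated data", {
  cs <- spread_stats(rep(9.5, 20))
  expect_equal(cs$sd, 0)
  expect_equal(cs$iqr, 0)
  expect_equal(cs$width_p5_p95, 0)

  set.seed(23)
  x <- rnorm(4000, mean = 14, sd = 2.5)
  gs <- spread_stats(x)
  expect_lt(abs(gs$mean - 14), 3 * 2.5 / sqrt(4000))
  expect_lt(abs(gs$sd - 2.5), 3 * 2.5 / sqrt(2 * 4000))

  dup <- spread_stats(c(x, x))
  expect_equal(dup$mean, gs$mean)
  expect_equal(dup$iqr, gs$iqr, tolerance = 1e-9)
  expect_equal(dup$frac_above, gs$frac_above)
})

test_that("switch statistic flags planted compaction and only that", {
  set.seed(29)
  ref <- rg_series(mixture_ensemble(0.5, n_frames = 150, seed = 41))
  pert_same <- ref

  sw0 <- switch_statistic(ref, pert_same)
  expect_equal(sw0$mean_shift, 0)
  expect_equal(sw0$spread_reduction, 0)
  expect_equal(sw0$tail_depletion, 0)
  expect_equal(sw0$ks_D, 0)
  expect_false(sw0$flagged)

  # mixture reference vs compact-only perturbed is flagged
  pert <- rg_series(sample_chain(compact_chain_model(), 150, seed = 43))
  sw1 <- switch_statistic(ref, pert)
  expect_true(sw1$flagged)
  expect_gt(sw1$mean_shift, 0)

  # exchanged arguments negate the mean shift
  sw2 <- switch_statistic(pert, ref)
  expect_equal(sw2$mean_shift, -sw1$mean_shift)

  # degenerate reference reports spread_reduction 0 with a warning
  expect_warning(swd <- switch_statistic(rep(10, 30), rnorm(30, 10)),
    "IQR")
  expect_equal(swd$spread_reduction, 0)
  expect_true(swd$degenerate_reference)
  expect_false(swd$flagged)
})

test_that("two compact draws with different seeds rarely flag (null calibration)", {
  flags <- vapply(1:40, function(s) {
    a <- rg_series(sample_chain(compact_chain_model(), 120,
      seed = 60000 + s))
    b <- rg_series(sample_chain(compact_chain_model(), 120,
      seed = 70000 + s))
    switch_statistic(a, b)$flagged
  }, logical(1))
  expect_lte(mean(flags), 0.05)
})

test_that("landscape normalization follows the declared domain", {
  ls <- rg_landscape(c(10, 20), c(-100, -50))
  expect_equal(ls$energy_norm, c(0, 1))

  # affine transforms of the energies leave normalized values unchanged
  set.seed(37)
  rg <- runif(40, 8, 30)
  e <- rnorm(40, -500, 40)
  base <- rg_landscape(rg, e)$energy_norm
  expect_equal(rg_landscape(rg, 3.2 * e + 77)$energy_norm, base,
    tolerance = 1e-12)

  # joint vs separate normalization on four hand-checked points
  rg4 <- c(10, 12, 20, 22)
  e4 <- c(-10, -6, -4, 0)
  cond <- c("w", "w", "p", "p")
  joint <- rg_landscape(rg4, e4, cond, domain = "joint")
  expect_equal(joint$energy_norm, c(0, 0.4, 0.6, 1))
  sep <- rg_landscape(rg4, e4, cond, domain = "separate")
  expect_equal(sep$energy_norm, c(0, 1, 0, 1))

  expect_warning(flat <- rg_landscape(c(1, 2), c(5, 5)), "identical")
  expect_equal(flat$energy_norm, c(0, 0))
  expect_error(rg_landscape(1:3, 1:4), "equal length")
})
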