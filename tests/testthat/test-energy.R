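no_salt <- gb_settings(salt_molar = 0)

test_that("isolated-atom SASA matches the analytic sphere area", {
  a <- sasa(matrix(0, 1, 3), 1.7, gb_settings())
  expect_equal(a, 4 * pi * 3.1^2, tolerance = 0.01)

  # far-separated atoms keep their isolated areas
  coords <- rbind(c(0, 0, 0), c(50, 0, 0))
  a2 <- sasa(coords, c(1.7, 1.4), gb_settings())
  expect_equal(a2[1], 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-9)
  expect_equal(a2[2], 4 * pi * (1.4 + 1.4)^2, tolerance = 1e-9)

  # a small atom fully inside a large sphere has zero area
  a3 <- sasa(rbind(c(0, 0, 0), c(0.5, 0, 0)), c(0.5, 6), gb_settings())
  expect_equal(a3[1], 0)

  expect_error(sasa(matrix(0, 1, 3), -1), "radii")
})

test_that("SASA is exactly invariant under rigid motion", {
  set.seed(41)
  coords <- matrix(rnorm(24, sd = 3), 8, 3)
  radii <- runif(8, 1.2, 2.5)
  a0 <- sasa(coords, radii)
  for (rep in 1:3) {
    rot <- random_rotation_matrix()
    moved <- sweep(coords %*% rot, 2, rnorm(3, sd = 10), "+")
    expect_equal(sasa(moved, radii), a0, tolerance = 1e-9)
  }
})

test_that("Born radii match the isolated limit, monotonicity, and the oracle", {
  st <- gb_settings()
  expect_equal(born_radii(matrix(0, 1, 3), 2.0, st), 2.0 - 0.09)

  # approaching neighbour increases the effective radius monotonically
  prev <- 0
  for (d in c(8, 6, 5, 4, 3.5)) {
    r <- born_radii(rbind(c(0, 0, 0), c(d, 0, 0)), c(2, 2), st)[1]
    expect_gt(r, prev)
    prev <- r
  }
  expect_gt(prev, 2.0 - 0.09)

  # 5-atom cluster agrees with the literal-transcription oracle
  set.seed(43)
  for (rep in 1:3) {
    coords <- matrix(rnorm(15, sd = 2.5), 5, 3)
    rho <- runif(5, 1.4, 2.4)
    expect_equal(born_radii(coords, rho, st),
      oracle_obc_radii(coords, rho), tolerance = 1e-8)
  }
})

test_that("GB polar energy reproduces the analytic Born limits", {
  # single +1e charge, R = 2 A, eps 80, no salt
  e <- gb_polar_energy(matrix(0, 1, 3), 1, 2.0, no_salt)
  expect_equal(e, -0.5 * (1 - 1 / 80) * 332.0637 / 2, tolerance = 1e-9)
  expect_equal(e, -81.98, tolerance = 0.01)

  # all charges zero
  expect_equal(
    gb_polar_energy(matrix(rnorm(9), 3, 3), rep(0, 3), rep(2, 3), no_salt),
    0)

  # distant unit charges: pair term approaches -(1-1/eps) k / r
  r <- 80
  coords <- rbind(c(0, 0, 0), c(r, 0, 0))
  reff <- born_radii(coords, c(2, 2), no_salt)
  e_pair <- gb_polar_energy(coords, c(1, 1), reff, no_salt) -
    2 * gb_polar_energy(matrix(0, 1, 3), 1, reff[1], no_salt)
  expect_equal(e_pair, -(1 - 1 / 80) * 332.0637 / r,
    tolerance = abs(e_pair) * 0.001)

  # magnitude decreases with increasing effective radius
  e_small <- gb_polar_energy(matrix(0, 1, 3), 1, 1.5, no_salt)
  e_big <- gb_polar_energy(matrix(0, 1, 3), 1, 3.0, no_salt)
  expect_lt(abs(e_big), abs(e_small))
  expect_lt(e_small, 0)
  expect_lt(e_big, 0)
})

test_that("salt screens charge-charge interactions and deepens ion solvation", {
  salty <- gb_settings(salt_molar = 0.15)

  # the solvent-screened interaction between two like charges (Coulomb
  # plus GB cross term) is attenuated by salt
  interaction <- function(settings, r = 10) {
    coords <- rbind(c(0, 0, 0), c(r, 0, 0))
    at <- tibble::tibble(residue_name = "BED", name = "BB",
      charge = c(1, 1), lj_epsilon = c(0, 0), lj_rmin_half = c(1, 1))
    reff <- born_radii(coords, c(2, 2), settings)
    cross_gb <- gb_polar_energy(coords, c(1, 1), reff, settings) -
      gb_polar_energy(matrix(0, 1, 3), 1, reff[1], settings) -
      gb_polar_energy(matrix(0, 1, 3), 1, reff[2], settings)
    mm_terms(coords, at, settings = settings)$e_ele + cross_gb
  }
  i0 <- interaction(no_salt)
  i150 <- interaction(salty)
  expect_gt(i0, 0) # like charges still repel in solvent
  expect_lt(i150, i0) # but less so with mobile ions

  # the Born self-energy of a single ion deepens (slightly) with salt, the
  # standard behaviour of the Debye-screened GB pair expression
  e0 <- gb_polar_energy(matrix(0, 1, 3), 1, 2.0, no_salt)
  e150 <- gb_polar_energy(matrix(0, 1, 3), 1, 2.0, salty)
  expect_lt(e150, e0)
  expect_lt(abs(e150 - e0), 0.02 * abs(e0))
})

test_that("MM terms match closed forms and the brute-force pair loop", {
  # two neutral atoms at the LJ minimum distance
  at <- tibble::tibble(residue_name = "BED", name = "BB",
    charge = c(0, 0), lj_epsilon = c(0.3, 0.3), lj_rmin_half = c(1.6, 1.6))
  mm <- mm_terms(rbind(c(0, 0, 0), c(3.2, 0, 0)), at)
  expect_equal(mm$e_vdw, -0.3, tolerance = 1e-12)
  expect_equal(mm$e_bon, 0)

  # two +1e charges at 3.320637 A give +100 kcal/mol
  at2 <- tibble::tibble(residue_name = "BED", name = "BB",
    charge = c(1, 1), lj_epsilon = c(0, 0), lj_rmin_half = c(1, 1))
  mm2 <- mm_terms(rbind(c(0, 0, 0), c(3.320637, 0, 0)), at2)
  expect_equal(mm2$e_ele, 100, tolerance = 0.01)

  # toy dimer vs brute-force double loop
  set.seed(53)
  for (rep in 1:3) {
    n <- 7
    coords <- matrix(rnorm(3 * n, sd = 4), n, 3)
    at3 <- tibble::tibble(residue_name = "BED", name = "BB",
      charge = rnorm(n, sd = 0.5), lj_epsilon = runif(n, 0.05, 0.4),
      lj_rmin_half = runif(n, 1.5, 2.5))
    mm3 <- mm_terms(coords, at3)
    o <- oracle_mm(coords, at3$charge, at3$lj_epsilon, at3$lj_rmin_half)
    expect_equal(mm3$e_vdw, o$e_vdw, tolerance = 1e-9)
    expect_equal(mm3$e_ele, o$e_ele, tolerance = 1e-9)
  }

  bad <- at2
  bad$charge[2] <- NA
  expect_error(mm_terms(rbind(c(0, 0, 0), c(3, 0, 0)), bad), "atom 2")
})

test_that("bonded topology excludes 1-2/1-3 pairs and scales 1-4", {
  # linear 4-atom chain: 1-2/2-3/3-4 bonded, 1-4 scaled
  coords <- cbind(c(0, 2, 4, 6), 0, 0)
  at <- tibble::tibble(residue_name = "BED", name = "BB",
    charge = c(1, 0, 0, 1), lj_epsilon = rep(0, 4),
    lj_rmin_half = rep(1, 4))
  topo <- list(bonds = tibble::tibble(i = 1:3, j = 2:4, k = 0, r0 = 2))
  mm <- mm_terms(coords, at, topo)
  # only the 1-4 electrostatic pair survives, scaled by 1/1.2
  expect_equal(mm$e_ele, 332.0637 / 6 / 1.2, tolerance = 1e-9)
  expect_equal(mm$e_bon, 0) # bonds at their rest length

  topo$bonds$r0 <- 1.5
  topo$bonds$k <- 10
  mm2 <- mm_terms(coords, at, topo)
  expect_equal(mm2$e_bon, 3 * 10 * 0.5^2, tolerance = 1e-9)
})

test_that("total energy composes its parts and is rigid-motion invariant", {
  tc <- toy_complex(seed = 2, n_frames = 1)
  f <- tc$frames[[1]]

  # component sum equals the total
  te <- total_energy(f, tc$atoms, no_salt)
  expect_equal(te$g_total,
    te$e_bon + te$e_vdw + te$e_ele + te$e_pol + te$e_npol,
    tolerance = 1e-9)

  # zero-charge, gamma = 0 system reduces to vdW
  st0 <- gb_settings(salt_molar = 0, surface_tension = 0)
  atoms0 <- tc$atoms
  atoms0$charge <- 0
  te0 <- total_energy(f, atoms0, st0)
  expect_equal(te0$g_total, te0$e_vdw, tolerance = 1e-9)
  expect_equal(te0$e_pol, 0)

  # isolated charged atom reproduces Born + gamma * 4 pi (r + w)^2
  at1 <- tc$atoms[3, ]
  te1 <- total_energy(matrix(0, 1, 3), at1, no_salt)
  expect_equal(te1$e_pol,
    -0.5 * (1 - 1 / 80) * 332.0637 / (at1$gb_radius - 0.09),
    tolerance = 1e-6)
  expect_equal(te1$e_npol, 0.0072 * 4 * pi * (at1$gb_radius + 1.4)^2,
    tolerance = 0.0072 * 4 * pi * (at1$gb_radius + 1.4)^2 * 0.01)

  # rigid rotation + translation leaves every component unchanged
  set.seed(59)
  rot <- random_rotation_matrix()
  te_m <- total_energy(sweep(f %*% rot, 2, c(30, -12, 7), "+"), tc$atoms,
    no_salt)
  expect_equal(unlist(te_m), unlist(te), tolerance = 1e-6)
})

test_that("full frame energy matches the composed brute-force oracle", {
  tc <- toy_complex(seed = 3, n_frames = 2)
  for (k in 1:2) {
    f <- tc$frames[[k]]
    te <- total_energy(f, tc$atoms, no_salt)
    g_oracle <- oracle_frame_g(f, tc$atoms)
    expect_equal(te$g_total, g_oracle, tolerance = 1e-6)
  }
})

test_that("binding energy matches oracles and trivial limits", {
  tc <- toy_complex(seed = 4, n_frames = 5)
  sel_a <- atom_indices(tc, chains = "A")
  sel_b <- atom_indices(tc, chains = "B")

  # zeroed interactions, far-separated parts give exactly zero
  null_ens <- tc
  null_ens$atoms$charge <- 0
  null_ens$atoms$lj_epsilon <- 0
  null_ens$frames <- purrr::map(null_ens$frames, function(f) {
    f[sel_b, 1] <- f[sel_b, 1] + 500
    f
  })
  st0 <- gb_settings(salt_molar = 0, surface_tension = 0)
  ba0 <- binding_energy(null_ens, sel_a, sel_b, st0)
  expect_equal(ba0$delta_g$mean, 0, tolerance = 1e-6)

  # delta G equals oracle complex minus oracle part energies per frame
  ba <- binding_energy(tc, sel_a, sel_b, no_salt)
  for (k in c(1, 3)) {
    f <- tc$frames[[k]]
    dg_oracle <- oracle_frame_g(f, tc$atoms) -
      oracle_frame_g(f[sel_a, ], tc$atoms[sel_a, ]) -
      oracle_frame_g(f[sel_b, ], tc$atoms[sel_b, ])
    expect_equal(ba$per_frame$delta_g[k], dg_oracle, tolerance = 1e-6)
  }

  # duplicating every frame leaves the mean unchanged exactly and the
  # sample SD unchanged up to its n-1 denominator
  dup <- conformer_ensemble(tc$atoms, c(tc$frames, tc$frames))
  ba_dup <- binding_energy(dup, sel_a, sel_b, no_salt)
  expect_equal(ba_dup$delta_g$mean, ba$delta_g$mean, tolerance = 1e-9)
  n <- ba$n_frames
  expect_equal(ba_dup$delta_g$sd,
    ba$delta_g$sd * sqrt(((n - 1) / n) * (2 * n / (2 * n - 1))),
    tolerance = 1e-9)

  expect_error(binding_energy(tc, sel_a, c(sel_a[1], sel_b)), "overlap")
  expect_error(binding_energy(tc, sel_a, sel_b[-1]), "partition")
})

test_that("per-residue decomposition conserves totals and finds planted contacts", {
  tc <- toy_complex(seed = 5, n_frames = 5)
  ba <- binding_energy(tc, atom_indices(tc, chains = "A"),
    atom_indices(tc, chains = "B"))

  expect_equal(sum(ba$per_residue$mean), ba$delta_g$mean,
    tolerance = 0.05)

  report <- residue_decomposition(ba)
  expect_true(all(c(3, 9) %in% report$residue_id))
  expect_true(all(report$mean <= -2))

  # a residue with all parameters zeroed contributes nothing
  zeroed <- tc
  zeroed$atoms$charge[5] <- 0
  zeroed$atoms$lj_epsilon[5] <- 0
  st0 <- gb_settings(salt_molar = 0, surface_tension = 0)
  ba_z <- binding_energy(zeroed, atom_indices(tc, chains = "A"),
    atom_indices(tc, chains = "B"), st0)
  contrib5 <- ba_z$per_residue$mean[ba_z$per_residue$residue_id == 5]
  expect_equal(contrib5, 0, tolerance = 1e-6)

  # glance/tidy accessors
  g <- glance(ba)
  expect_equal(g$n_residues, 11L)
  expect_equal(nrow(tidy(ba)), 11L)
})

test_that("energy series subsamples frames evenly", {
  tc <- toy_complex(seed = 6, n_frames = 8)
  es <- energy_series(tc, no_salt, n_sample = 4)
  expect_equal(nrow(es), 4L)
  expect_equal(es$frame, c(1, 3, 6, 8))
  expect_equal(es$g_total,
    es$e_bon + es$e_vdw + es$e_ele + es$e_pol + es$e_npol,
    tolerance = 1e-9)
})
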