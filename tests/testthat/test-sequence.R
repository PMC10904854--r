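test_that("tiling reproduces the published tile inventories", {
  scaffold <- myc_scaffold_synthetic()
  expect_equal(length(scaffold), 439L)

  tiles <- tile_sequence(scaffold, window = 50, step = 50)
  expect_equal(nrow(tiles), 9L)
  expect_equal(tiles$start, seq(1, 401, by = 50))
  expect_equal(tiles$end, c(seq(50, 400, by = 50), 439))
  expect_equal(nchar(tiles$sequence[9]), 39L)
  expect_true(all(nchar(tiles$sequence[1:8]) == 50L))
  expect_equal(tiles$name[3], "MYC_scaffold_synthetic_101-150")
  expect_equal(tiles$sequence[3],
    paste(residues(coremyc_sequence()), collapse = ""))

  offs <- tile_sequence(scaffold, window = 50, step = 50, offset = 24,
    keep_partial = FALSE)
  expect_equal(nrow(offs), 8L)
  expect_equal(offs$start, seq(25, 375, by = 50))
  expect_equal(offs$end, seq(74, 424, by = 50))
})

test_that("tiling identity and error cases behave", {
  s <- coremyc_sequence()
  one <- tile_sequence(s, window = 50, step = 50)
  expect_equal(nrow(one), 1L)
  expect_equal(one$sequence, paste(residues(s), collapse = ""))
  expect_equal(one$start, 101L) # parent coordinates respected
  expect_equal(one$end, 150L)

  expect_error(tile_sequence(s, window = 0), "window")
  expect_error(tile_sequence(s, window = 10, step = 0), "window")
  expect_error(tile_sequence(s, window = 10, offset = 50), "offset")
  expect_error(tile_sequence(s, window = 10, offset = -1), "offset")
})

test_that("tiling with step = window partitions the sequence", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(20:200, 1)
    w <- sample(3:60, 1)
    seq_str <- paste(sample(names(hydropathy_scale("miyazawa")), n,
      replace = TRUE), collapse = "")
    s <- protein_sequence(seq_str, id = "p")
    tiles <- tile_sequence(s, window = w, step = w, keep_partial = TRUE)
    expect_equal(paste(tiles$sequence, collapse = ""), seq_str)
    expect_equal(tiles$end - tiles$start + 1L, nchar(tiles$sequence))
  }
})

test_that("hydropathy profile matches a hand-computed sliding mean", {
  s <- coremyc_sequence()
  scale <- hydropathy_scale("miyazawa")
  prof <- hydropathy_profile(s, "miyazawa", window = 9)
  raw <- unname(scale[residues(s)])
  ref <- oracle_sliding_mean(raw, 9)
  for (pos in c(1, 5, 17, 25, 50)) {
    expect_equal(prof$value[pos], ref[pos], tolerance = 1e-12)
  }
  expect_equal(prof$position, 101:150)

  # window = 1 returns raw scores; whole-length odd window gives the mean
  expect_equal(hydropathy_profile(s, window = 1)$value, raw)
  polyg <- protein_sequence(strrep("G", 15))
  expect_equal(hydropathy_profile(polyg, window = 1)$value,
    rep(scale[["G"]], 15))
  expect_equal(hydropathy_profile(polyg, "miyazawa", window = 15)$value,
    rep(scale[["G"]], 15))

  expect_error(hydropathy_profile(s, window = 4), "odd")
  expect_error(hydropathy_profile(s, scale = c(A = 1)), "residue")
  expect_error(protein_sequence("MVXL"), "position 3")
})

test_that("hydrophobic fraction reproduces the 50% coreMYC composition", {
  expect_equal(hydrophobic_fraction(coremyc_sequence()), 0.5)
  expect_identical(
    sum(residues(coremyc_sequence()) %in% hydrophobic_residues()), 25L)

  expect_equal(hydrophobic_fraction(protein_sequence(strrep("G", 8))), 0)
  expect_equal(hydrophobic_fraction(protein_sequence(strrep("L", 8))), 1)

  # invariant under sequence reversal
  set.seed(3)
  for (rep in 1:5) {
    res <- sample(names(hydropathy_scale("miyazawa")), 40, replace = TRUE)
    fwd <- protein_sequence(paste(res, collapse = ""))
    rev <- protein_sequence(paste(base::rev(res), collapse = ""))
    expect_equal(hydrophobic_fraction(fwd), hydrophobic_fraction(rev))
  }
})

test_that("disorder proxy orders charged/hydrophilic above hydrophobic", {
  poly_e <- disorder_proxy(protein_sequence(strrep("E", 20)))
  poly_i <- disorder_proxy(protein_sequence(strrep("I", 20)))
  expect_true(all(poly_e$value > 0)) # disordered half
  expect_true(all(poly_i$value < 0)) # ordered half
  expect_true(all(poly_e$value > poly_i$value))

  # coreMYC (hydrophobic epitope) is more ordered than an IDP-like stretch
  core <- mean(disorder_proxy(coremyc_sequence())$value)
  filler <- protein_sequence(
    substr(paste(residues(myc_scaffold_synthetic()), collapse = ""), 201, 250))
  expect_lt(core, mean(disorder_proxy(filler)$value))

  # deterministic
  expect_identical(disorder_proxy(coremyc_sequence()),
    disorder_proxy(coremyc_sequence()))
})

test_that("profile correlation matches the textbook formula and is symmetric", {
  s <- coremyc_sequence()
  hyd <- hydropathy_profile(s, window = 9)
  dis <- disorder_proxy(s, window = 9)

  expect_equal(profile_correlation(hyd, hyd), 1)
  neg <- hyd
  neg$value <- -neg$value
  expect_equal(profile_correlation(hyd, neg), -1)

  set.seed(21)
  for (rep in 1:5) {
    a <- hyd
    b <- hyd
    a$value <- rnorm(nrow(a))
    b$value <- rnorm(nrow(b))
    r <- profile_correlation(a, b)
    expect_equal(r, oracle_pearson(a$value, b$value), tolerance = 1e-12)
    expect_equal(r, profile_correlation(b, a))
    expect_lte(abs(r), 1)
  }

  # hydropathy and the disorder proxy are inversely correlated by design
  expect_lt(profile_correlation(hyd, dis), 0)

  short <- hyd[1:10, ]
  expect_error(profile_correlation(hyd, short), "aligned")
  flat <- hyd
  flat$value <- 1
  expect_error(profile_correlation(hyd, flat), "zero variance")
})

test_that("peptide masses and m/z follow residue-mass bookkeeping", {
  expect_equal(peptide_average_mass(protein_sequence("G")), 75.07,
    tolerance = 0.0002)
  s <- coremyc_sequence()
  expect_equal(
    peptide_average_mass(s, cterm = "amide") - peptide_average_mass(s),
    -0.98, tolerance = 0.01)

  # additivity: mass(AB) = mass(A) + mass(B) - water
  set.seed(8)
  for (rep in 1:5) {
    aa <- names(hydropathy_scale("miyazawa"))
    a <- paste(sample(aa, 12, replace = TRUE), collapse = "")
    b <- paste(sample(aa, 7, replace = TRUE), collapse = "")
    expect_equal(
      peptide_average_mass(protein_sequence(paste0(a, b))),
      peptide_average_mass(protein_sequence(a)) +
        peptide_average_mass(protein_sequence(b)) - 18.0153,
      tolerance = 0.01)
  }

  expect_equal(mz_series(1000, 1)$mz, 1001.007, tolerance = 0.001)
  expect_equal(mz_series(10000, 5)$mz, 2001.007, tolerance = 0.001)
  mz <- mz_series(25000, 1:30)$mz
  expect_true(all(diff(mz) < 0)) # monotone decreasing in charge
  expect_true(all(mz > 25000 / (1:30))) # bounded below by mass/z
  expect_error(mz_series(-5, 1), "mass")
  expect_error(mz_series(100, 0), "charges")
})

test_that("the 1:1 switch-partner complex lands in the published m/z window", {
  m_core <- peptide_average_mass(coremyc_sequence(tagged = TRUE))
  m_trrap <- peptide_average_mass(trrap_sequence(), nterm = "acetyl",
    cterm = "amide")
  mz6 <- mz_series(m_core + m_trrap, 6)$mz
  expect_gt(mz6, 1800)
  expect_lt(mz6, 2000)
})

test_that("FASTA round-trips protein sequences", {
  skip_if_not_installed("Biostrings")
  path <- withr::local_tempfile(fileext = ".fasta")
  seqs <- list(coremyc_sequence(), trrap_sequence())
  write_fasta(seqs, path)
  back <- read_fasta(path)
  expect_equal(names(back), c("coreMYC", "TRRAP_2038-2087"))
  expect_equal(residues(back[[1]]), residues(seqs[[1]]))
  expect_equal(residues(back[[2]]), residues(seqs[[2]]))
})

test_that("disorder CSV reader accepts position,score tables", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# external predictor output", "position,score",
    "1,0.9", "2,0.8", "3,0.95"), path)
  d <- read_disorder_csv(path)
  expect_equal(d$position, 1:3)
  expect_equal(d$value, c(0.9, 0.8, 0.95))
})
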