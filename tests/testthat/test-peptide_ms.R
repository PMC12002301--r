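test_that("residue masses and modification deltas match the elemental oracle", {
  # glycine free acid
  expect_equal(peptide_mass("G"), 75.03203, tolerance = 1e-4)
  expect_equal(peptide_mass("G"), oracle_peptide_mass("G"), tolerance = 1e-4)
  # every residue against the composition oracle
  for (aa in names(RESIDUE_MASS_MONO))
    expect_equal(RESIDUE_MASS_MONO[[aa]], oracle_residue_mass(aa),
                 tolerance = 1e-4, label = aa)
  # amide and pGlu deltas
  p <- "EPRRNYNRVFGPTY"
  expect_equal(peptide_mass(p, c_term = "amide") - peptide_mass(p),
               -0.98402, tolerance = 1e-5)
  expect_equal(peptide_mass(p, c_term = "amide"),
               oracle_peptide_mass(p, c_term = "amide"), tolerance = 1e-3)
  q <- "QQRLGNQWAVGHLM"
  expect_equal(peptide_mass(q, n_term = "pyroglutamate") - peptide_mass(q),
               -17.02655, tolerance = 1e-5)
  expect_equal(peptide_mass(q, c_term = "amide", n_term = "pyroglutamate"),
               oracle_peptide_mass(q, "amide", "pyroglutamate"),
               tolerance = 1e-3)
  expect_error(peptide_mass("AZA"), "unknown")
  expect_error(peptide_mass("ANA", n_term = "pyroglutamate"), "Q")
})

test_that("mass additivity and mono < average hold", {
  set.seed(8)
  for (r in 1:20) {
    a <- random_peptide(sample(2:10, 1)); b <- random_peptide(sample(2:10, 1))
    expect_equal(peptide_mass(paste0(a, b)),
                 peptide_mass(a) + peptide_mass(b) - 18.010565,
                 tolerance = 1e-9)
    expect_lt(peptide_mass(a), peptide_mass(a, kind = "average"))
  }
})

test_that("b/y conservation identity holds for 1000 random peptides", {
  set.seed(101)
  worst <- 0
  for (r in 1:1000) {
    p <- random_peptide(sample(3:20, 1))
    ct <- sample(c("free_acid", "amide"), 1)
    nt <- if (substr(p, 1, 1) == "Q") sample(c("free", "pyroglutamate"), 1)
          else "free"
    M <- peptide_mass(p, c_term = ct, n_term = nt)
    fi <- fragment_ions(p, c_term = ct, n_term = nt, max_charge = 1)
    b <- fi$mz[fi$series == "b"] - 1.007276
    y <- rev(fi$mz[fi$series == "y"] - 1.007276)
    worst <- max(worst, max(abs(b + y - M)))
  }
  expect_lt(worst, 1e-9)
})

test_that("fragment series shift correctly under modifications", {
  # y ions of an amide are uniformly -0.98402 vs the free acid
  fa <- fragment_ions("EPRRNYNRVFGPTY", c_term = "free_acid", max_charge = 1)
  am <- fragment_ions("EPRRNYNRVFGPTY", c_term = "amide", max_charge = 1)
  dy <- am$mz[am$series == "y"] - fa$mz[fa$series == "y"]
  expect_equal(dy, rep(-0.98402, length(dy)), tolerance = 1e-6)
  expect_equal(am$mz[am$series == "b"], fa$mz[fa$series == "b"])
  # b ions of a pGlu peptide are uniformly -17.02655 vs unmodified
  f0 <- fragment_ions("QWAVGHLM", max_charge = 1)
  fq <- fragment_ions("QWAVGHLM", n_term = "pyroglutamate", max_charge = 1)
  db <- fq$mz[fq$series == "b"] - f0$mz[f0$series == "b"]
  expect_equal(db, rep(-17.02655, length(db)), tolerance = 1e-6)
  # dipeptide: y1 - b1 = water + c-term delta (here free acid)
  gg <- fragment_ions("GG", max_charge = 1)
  expect_equal(gg$mz[gg$series == "y" & gg$index == 1] -
               gg$mz[gg$series == "b" & gg$index == 1],
               18.010565, tolerance = 1e-6)
  # doubly charged m/z
  f2 <- fragment_ions("QWAVGHLM", max_charge = 2)
  b1 <- f2[f2$series == "b" & f2$index == 2, ]
  expect_equal(b1$mz[b1$charge == 2],
               (b1$mz[b1$charge == 1] - 1.007276 + 2 * 1.007276) / 2,
               tolerance = 1e-9)
})

test_that("spectrum matching achieves full coverage on clean planted spectra", {
  sp <- make_spectrum("EPRRNYNRVFGPTY", c_term = "amide", n_noise_peaks = 0)
  mm <- match_spectrum(sp, "EPRRNYNRVFGPTY", c_term = "amide", tol_ppm = 10)
  expect_equal(mm$coverage, 1)
  expect_true(all(abs(mm$matched$ppm_error) <= 10))
  # peaks shifted by +10 ppm cannot match at 1 ppm
  sp_off <- sp; sp_off$mz <- sp_off$mz * (1 + 10e-6)
  mm_off <- match_spectrum(sp_off, "EPRRNYNRVFGPTY", c_term = "amide",
                           tol_ppm = 1)
  expect_equal(nrow(mm_off$matched), 0L)
  expect_equal(mm_off$coverage, 0)
  # empty peak list
  expect_equal(match_spectrum(data.frame(mz = numeric(),
                                         intensity = numeric()),
                              "GAVLK")$coverage, 0)
})

test_that("decoy peptides score below the planted peptide on its own spectrum", {
  set.seed(33)
  sp <- make_spectrum("EPRRNYNRVFGPTY", c_term = "amide", n_noise_peaks = 20,
                      seed = 1)
  true_cov <- match_spectrum(sp, "EPRRNYNRVFGPTY", c_term = "amide",
                             tol_ppm = 10)$coverage
  for (r in 1:20) {
    decoy <- random_peptide(14)
    cov <- match_spectrum(sp, decoy, c_term = "amide", tol_ppm = 10)$coverage
    expect_lt(cov, true_cov)
  }
})
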