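test_that("luminescence normalization is per-experiment and scale-invariant", {
  tab <- data.frame(experiment = c(1, 1, 1, 2, 2),
                    response = c(2, 4, 8, 10, 40))
  out <- normalize_luminescence(tab)
  expect_equal(out$response_pct, c(25, 50, 100, 25, 100))
  # multiplying one experiment by a constant changes nothing
  tab2 <- tab; tab2$response[tab2$experiment == 1] <-
    tab2$response[tab2$experiment == 1] * 37
  expect_equal(normalize_luminescence(tab2)$response_pct, out$response_pct)
  expect_error(normalize_luminescence(
    data.frame(experiment = 1, response = 0)), "positive")
})

test_that("noise-free 4PL data are recovered to optimizer tolerance", {
  dr <- make_dose_response(logEC50 = -9, hill = 1, bottom = 0, top = 100,
                           cv = 0, seed = 1)
  f <- fit_4pl(dr$concentration, dr$response)
  expect_equal(f$log_ec50, -9, tolerance = 1e-6)
  expect_equal(f$hill, 1, tolerance = 1e-6)
  expect_equal(f$bottom, 0, tolerance = 1e-4)
  expect_equal(f$top, 100, tolerance = 1e-4)
  # insufficient support / degenerate inputs refuse
  expect_error(fit_4pl(rep(1e-9, 5), rnorm(5)), "distinct")
  expect_error(fit_4pl(10^(-12:-5), rep(7, 8)), "degenerate")
})

test_that("4PL fit is equivariant under response scaling", {
  dr <- make_dose_response(cv = 0.03, n_reps = 3, seed = 5)
  f1 <- fit_4pl(dr$concentration, dr$response)
  f2 <- fit_4pl(dr$concentration, dr$response * 3.5)
  expect_equal(f2$log_ec50, f1$log_ec50, tolerance = 1e-6)
  expect_equal(f2$hill, f1$hill, tolerance = 1e-6)
  expect_equal(f2$top, 3.5 * f1$top, tolerance = 1e-4)
})

test_that("Monte-Carlo EC50 recovery at 5% cv is accurate and nearly unbiased", {
  true_log <- log10(1.69e-11)
  errs <- vapply(1:200, function(s) {
    d <- make_dose_response(cv = 0.05, n_reps = 4, seed = s)
    fit_4pl(d$concentration, d$response)$log_ec50 - true_log
  }, 0)
  expect_gte(mean(abs(errs) < 0.1), 0.95)
  expect_lt(abs(mean(errs)), 0.02)
})

test_that("contraction normalization reports percent of reference and flags", {
  rec <- data.frame(prep_id = c("p1", "p1", "p2"),
                    agent = "peptide",
                    concentration = c(1e-7, 1e-6, 1e-6),
                    amplitude = c(5, 8, 3),
                    reference_amplitude = c(10, 10, 10),
                    protocol = "washed")
  out <- normalize_contraction(rec)
  expect_equal(out$records$pct, c(50, 80, 30))
  s <- out$summary
  expect_equal(s$mean[s$concentration == 1e-6], mean(c(80, 30)))
  expect_equal(s$n[s$concentration == 1e-6], 2L)
  # cumulative series (10, 30, 25)%: reported as measured, flagged
  cum <- data.frame(prep_id = "c1", agent = "peptide",
                    concentration = c(1e-8, 1e-7, 1e-6),
                    amplitude = c(1, 3, 2.5),
                    reference_amplitude = 10, protocol = "cumulative")
  oc <- normalize_contraction(cum)
  expect_equal(oc$records$pct, c(10, 30, 25))
  expect_true(all(oc$records$non_monotone))
  expect_error(normalize_contraction(transform(rec, reference_amplitude = 0)),
               "prep")
})

test_that("area time course normalizes to the pre-injection measurement", {
  areas <- expand.grid(animal = 1:3, group = c("water", "peptide"),
                       time = c(0, 2, 4))
  areas$area <- 10
  areas$area[areas$group == "peptide" & areas$time == 4] <- 5
  out <- area_timecourse(areas, t_inject = 0)
  s <- out$summary
  expect_equal(s$mean[s$group == "water"], rep(100, 3))
  expect_equal(s$mean[s$group == "peptide" & s$time == 4], 50)
  expect_error(area_timecourse(transform(areas, area = 0), 0), "positive")
})

test_that("two-sample comparison matches the textbook pooled t", {
  r <- compare_groups(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$t, -1.224745, tolerance = 1e-6)
  expect_equal(r$df, 4)
  expect_equal(r$p, 2 * stats::pt(-abs(r$t), 4), tolerance = 1e-12)
  # identical groups
  expect_equal(compare_groups(c(5, 5, 5), c(5, 5, 5))$p, 1)
  d <- compare_groups(c(5, 5), c(6, 6))
  expect_equal(d$p, 0)
  expect_true(d$degenerate)
})

test_that("t-test p agrees with a permutation oracle on synthetic data", {
  set.seed(99)
  x <- rnorm(12, 0, 1); y <- rnorm(12, 0.8, 1)
  r <- compare_groups(x, y)
  pooled <- c(x, y)
  obs <- abs(mean(x) - mean(y))
  perm <- replicate(4000, {
    idx <- sample(24, 12)
    abs(mean(pooled[idx]) - mean(pooled[-idx]))
  })
  p_perm <- mean(perm >= obs)
  expect_lt(abs(p_perm - r$p), 0.02)
})
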