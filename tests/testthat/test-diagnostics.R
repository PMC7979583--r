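test_that("the inhibition transform is exact, signed and scale-invariant", {
  expect_equal(inhibition_percent(4000, 4000), 0)
  expect_equal(inhibition_percent(4000, 0), 100)
  expect_equal(inhibition_percent(4000, 1000), 75)
  expect_equal(inhibition_percent(4000, 5000), -25)  # measurement error
  c_scale <- 3.7
  expect_equal(inhibition_percent(4000 * c_scale, 1000 * c_scale), 75)
  expect_error(inhibition_percent(0, 1), "positive")
})

test_that("the concentration-effect curve is monotone with a ~2 ng/mL midpoint", {
  curve <- concentration_effect_curve(conc = 10^seq(-2, 3, length.out = 101))
  expect_true(all(diff(curve$inhibition) >= -1e-9))
  # inhibition vanishes at the low end and saturates above 50 ng/mL
  expect_lt(curve$inhibition[1], 2)
  expect_gt(curve$inhibition[curve$conc >= 50][1], 95)
  ic50 <- attr(curve, "ic50_ng_mL")
  expect_gt(ic50, 1)
  expect_lt(ic50, 3)
  # the midpoint is consistent: inhibition at the IC50 is 50%
  at_ic50 <- concentration_effect_curve(conc = ic50)
  expect_equal(at_ic50$inhibition, 50, tolerance = 1e-6)
  # the sex shift moves the target pools but barely the midpoint
  icf <- attr(concentration_effect_curve(sex = "female"), "ic50_ng_mL")
  expect_equal(icf, ic50, tolerance = 0.2)
  expect_error(concentration_effect_curve(conc = c(-1, 1)), "positive")
})

test_that("VPC bands are deterministic, ordered and collapse without variability", {
  dat <- small_dataset()
  v <- tmdd_variability()
  b1 <- vpc(dat, n_rep = 10, seed = 77)
  b2 <- vpc(dat, n_rep = 10, seed = 77)
  expect_identical(b1, b2)
  expect_true(all(b1$obs_p5 <= b1$obs_p50 & b1$obs_p50 <= b1$obs_p95))
  expect_true(all(b1$sim_p5 <= b1$sim_p50 & b1$sim_p50 <= b1$sim_p95))
  expect_true(all(b1$sim_p50_lo <= b1$sim_p50_hi))

  # near-zero variability in a homogeneous cohort: all simulated
  # percentiles collapse onto the population prediction
  twin <- subjects(1:3, egfr = 44)
  dat_twin <- generate_dataset(twin, sampling_design("ALBUM"), seed = 81,
                               sample_iiv = FALSE)
  v0 <- tmdd_variability(omega = diag(1e-12, 3), sigma2_pk = 1e-12,
                         sigma2_svap1 = 1e-12, sigma2_act = 1e-12)
  b0 <- vpc(dat_twin, variability = v0, n_rep = 5, seed = 78)
  expect_equal(b0$sim_p5, b0$sim_p95, tolerance = 1e-4)
  expect_equal(b0$sim_p50_lo, b0$sim_p50_hi, tolerance = 1e-4)

  # a single replicate is its own band
  bb <- vpc(dat, n_rep = 1, seed = 79)
  expect_equal(bb$sim_p50, bb$sim_p50_lo)
  expect_equal(bb$sim_p50, bb$sim_p50_hi)
})

test_that("outlier flagging is strict at the cutoff and catches injected spikes", {
  cohort <- sample_covariates(population_spec("ALBUM", n = 3), seed = 91)
  dat <- generate_dataset(cohort, sampling_design("ALBUM"), seed = 92)
  etas <- attr(dat, "etas")
  fit <- structure(list(
    params = tmdd_params(), variability = tmdd_variability(),
    etas = tibble::tibble(id = 1:3, eta_cl = etas[, 1],
                          eta_svap1 = etas[, 2], eta_sl = etas[, 3])),
    class = "tmdd_fit")
  flagged <- flag_outliers(fit, dat)
  expect_true(all(c("CWRES", "OUTLIER") %in% names(flagged)))

  # inject a spike: +10 residual SDs on one activity record
  sub1 <- qetmdd:::prep_subjects(dat)[[1]]
  f <- qetmdd:::subject_ipred(sub1, tmdd_params(), etas[1, ])
  k_act <- which(sub1$cmt == 4)[1]
  row_global <- sub1$rows[k_act]
  sdv <- qetmdd:::residual_sd(4L, "phase2", tmdd_variability())
  dat2 <- dat
  dat2$DV[row_global] <- f[k_act] + 10 * sdv
  flagged2 <- flag_outliers(fit, dat2)
  hit <- flagged2[abs(flagged2$CWRES - 10) < 1e-6, ]
  expect_equal(nrow(hit), 1)
  expect_true(hit$OUTLIER)

  # strictness: a residual just inside the cutoff is not flagged, just
  # outside is
  dat3 <- dat
  dat3$DV[row_global] <- f[k_act] + 2.999 * sdv
  expect_false(flag_outliers(fit, dat3)[
    abs(flag_outliers(fit, dat3)$CWRES - 2.999) < 1e-6, ]$OUTLIER)
  dat3$DV[row_global] <- f[k_act] + 3.001 * sdv
  expect_true(flag_outliers(fit, dat3)[
    abs(flag_outliers(fit, dat3)$CWRES - 3.001) < 1e-6, ]$OUTLIER)
})

test_that("population summary reports ordered percentiles", {
  cohort <- sample_covariates(population_spec("ALBUM", n = 8), seed = 95)
  pop <- simulate_population(cohort, dose_mg = 10, weeks = 52, seed = 96)
  sm <- population_summary(pop)
  expect_true(all(sm$p5 <= sm$p50 & sm$p50 <= sm$p95))
  expect_true("avg_inhibition_24h" %in% sm$metric)
  # omega = 0 and identical covariates: all subjects identical
  twin <- subjects(1:2, egfr = 44)
  v0 <- tmdd_variability(omega = matrix(0, 3, 3))
  pop0 <- simulate_population(twin, dose_mg = 10, weeks = 52,
                              variability = v0, seed = 97)
  expect_equal(pop0$auc24_52w[1], pop0$auc24_52w[2])
  expect_equal(pop0$avg_inhibition_24h[1], pop0$avg_inhibition_24h[2])
})
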