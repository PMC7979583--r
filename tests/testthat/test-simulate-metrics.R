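test_that("zero-dose simulation stays at baseline", {
  prof <- simulate_profile(build_regimen(data.frame()), grid = 0:48,
                           horizon = 48)
  expect_true(all(prof$conc_drug == 0))
  ip <- apply_covariates(typical_subject(), tmdd_params())
  expect_equal(prof$activity, rep(ip$activity0, nrow(prof)))
  expect_equal(prof$inhibition, rep(0, nrow(prof)))
})

test_that("superposition holds in the linear limit", {
  ip <- linear_iparams()
  grid <- seq(0, 96, by = 2)
  p1 <- simulate_profile(build_regimen(data.frame(time = 0, dose_mg = 20)),
                         iparams = ip, grid = grid, horizon = 96)
  p2 <- simulate_profile(build_regimen(data.frame(time = 0, dose_mg = 40)),
                         iparams = ip, grid = grid, horizon = 96)
  nz <- p1$conc_drug > 0
  expect_equal(p2$conc_drug[nz] / p1$conc_drug[nz],
               rep(2, sum(nz)), tolerance = 1e-3)
})

test_that("single linear-limit dose matches the matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  ip <- linear_iparams()
  grid <- c(1, 2, 6, 12, 24, 48)
  prof <- simulate_profile(build_regimen(data.frame(time = 0, dose_mg = 40)),
                           iparams = ip, grid = grid, horizon = 48)
  oracle <- oracle_linear_profile(ip, ip$f1_rel * mg_to_nmol(40), grid)
  conc_oracle <- nM_to_ng_per_mL(oracle[, 3] / ip$v2)
  expect_equal(prof$conc_drug[match(grid, prof$time)], conc_oracle,
               tolerance = 1e-3)
})

test_that("steady-state metrics are internally consistent", {
  prof <- simulate_qd(10, weeks = 52)
  met <- secondary_params(prof)
  expect_equal(met$t_half_weeks, met$tss_weeks / 5)
  expect_gte(met$tmax_52w, 0)
  expect_lte(met$tmax_52w, 24)
  expect_gt(met$auc24_52w, 0)
  # the final-interval average concentration is below Cmax
  expect_lt(met$auc24_52w / 24, met$cmax_52w)
  expect_error(secondary_params(simulate_qd(10, weeks = 2)), "52 weeks")
})

test_that("a flat profile reaches steady state at the first examined trough", {
  n_days <- 52 * 7
  reg <- qd_regimen(1, weeks = 52)
  prof <- tibble::tibble(
    time = sort(unique(c((0:n_days) * 24,
                         seq((n_days - 1) * 24, n_days * 24, 0.1)))),
    conc_drug = 5, conc_svap1 = 5.52, activity = 3000, inhibition = 20)
  met <- secondary_params(prof, regimen = reg)
  expect_equal(met$tss_weeks, 24 / 168)
  expect_equal(met$t_half_weeks, 24 / 168 / 5)
})

test_that("average inhibition integrates the inhibition trace", {
  # activity pinned at 10% of baseline: average inhibition is 90%
  prof <- tibble::tibble(time = seq(0, 24, 0.5), conc_drug = 1,
                         conc_svap1 = 5.52, activity = 100,
                         inhibition = 90)
  expect_equal(average_inhibition_24h(prof, window = c(0, 24)), 90)
  expect_error(average_inhibition_24h(prof, window = c(10, 10)), "positive")
  # zero dose: identically zero
  prof0 <- simulate_profile(build_regimen(data.frame()), grid = 0:24)
  expect_equal(average_inhibition_24h(prof0, window = c(0, 24)), 0)
})

test_that("dose-normalised exposure is flat for linear PK and the reference maps to itself", {
  met <- tibble::tibble(dose_mg = c(40, 10), auc24_52w = c(2000, 500))
  out <- dose_normalized_auc(met)
  expect_equal(out$auc_norm[1], 2000)      # reference dose: AUC itself
  expect_equal(out$auc_norm[2], 2000)      # proportional PK: ratio 1
  expect_error(dose_normalized_auc(tibble::tibble(dose_mg = 0,
                                                  auc24_52w = 1)),
               "positive")
})

test_that("with binding, dose-normalised AUC decreases and Tss shortens with dose", {
  doses <- c(0.1, 1, 10, 40)
  mets <- dplyr::bind_rows(lapply(doses, function(d) {
    cbind(dose_mg = d, secondary_params(simulate_qd(d, weeks = 52)))
  }))
  dn <- dose_normalized_auc(mets)
  expect_true(all(diff(dn$auc_norm) < 0))
  expect_true(all(diff(dn$tss_weeks) <= 0))
})
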