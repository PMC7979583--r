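p_truth <- tmdd_params()
v_truth <- tmdd_variability()

# noise-free dataset at given etas (residual variances zero at generation)
noisefree_dataset <- function(cohort, seed = 1) {
  v0 <- tmdd_variability(sigma2_pk = 0, sigma2_svap1 = 0, sigma2_act = 0)
  generate_dataset(cohort, sampling_design("ALBUM"), variability = v0,
                   seed = seed, sample_iiv = FALSE)
}

test_that("individual deviance matches the closed form and a density oracle", {
  dat <- small_dataset()
  d1 <- dat[dat$ID == 1, ]
  ip <- apply_covariates(
    subjects(1, sex = ifelse(d1$SEX[1] == 1, "female", "male"),
             egfr = d1$EGFR[1]), p_truth)

  # single zero-residual observation with unit variance: exactly log(2*pi)
  one <- d1[d1$EVID == 1, ][1:2, ]
  obs <- d1[d1$CMT == 3 & d1$EVID == 0, ][1, ]
  obs$DV <- log(ip$svap1c)  # prediction is exact for the target conc
  v1 <- tmdd_variability(sigma2_svap1 = 1)
  val <- individual_neg2ll(rbind(one, obs), ip, v1)
  expect_equal(val, log(2 * pi), tolerance = 1e-10)

  # doubling sigma changes the deviance by the analytic amount
  obs$DV <- log(ip$svap1c) + 0.5
  v2 <- tmdd_variability(sigma2_svap1 = 4)
  a <- individual_neg2ll(rbind(one, obs), ip, v1)
  b <- individual_neg2ll(rbind(one, obs), ip, v2)
  expect_equal(b - a, log(4) + 0.25 / 4 - 0.25, tolerance = 1e-10)

  # five observations against a normal-density oracle
  d5 <- d1[d1$EVID == 1 | (d1$EVID == 0 & d1$LLOQFLAG == 0), ]
  keep_obs <- which(d5$EVID == 0)[1:5]
  d5 <- d5[c(which(d5$EVID == 1), keep_obs), ]
  val5 <- individual_neg2ll(d5, ip, v_truth)
  sub <- qetmdd:::prep_subjects(d5)[[1]]
  f <- qetmdd:::subject_ipred(sub, p_truth, c(0, 0, 0), rtol = 1e-8,
                              atol = 1e-10)
  sdv <- qetmdd:::residual_sd(sub$cmt, sub$phase, v_truth)
  oracle <- -2 * sum(dnorm(sub$y, f, sdv, log = TRUE))
  expect_equal(val5, oracle, tolerance = 1e-6)

  expect_error(individual_neg2ll(dat, ip, v_truth), "one subject")
})

test_that("MAP etas recover the generating random effects from noise-free data", {
  cohort0 <- subjects(1)
  dat0 <- noisefree_dataset(cohort0)
  m0 <- map_etas(dat0[dat0$ID == 1, ], p_truth, v_truth)
  expect_lt(sqrt(sum(m0$eta^2)), 1e-3)

  # rich phase-1 sampling so the data dominate the prior: trough-heavy
  # drug sampling plus regular activity sampling over 4 weeks
  rich <- sampling_design(schedule = rbind(
    data.frame(time = seq(24, 672, by = 12), type = "drug"),
    data.frame(time = seq(0, 672, by = 48), type = "activity"),
    data.frame(time = seq(0, 672, by = 96), type = "svap1")),
    regimen_label = "ALBUM")
  cohort1 <- subjects(1, eta_cl = 0.3, study_phase = "phase1")
  v0 <- tmdd_variability(sigma2_pk = 0, sigma2_svap1 = 0, sigma2_act = 0)
  dat1 <- generate_dataset(cohort1, rich, variability = v0, seed = 2,
                           sample_iiv = FALSE)
  m1 <- map_etas(dat1, p_truth, v_truth)
  expect_equal(unname(m1$eta["eta_cl"]), 0.3, tolerance = 0.04)
  expect_lt(abs(m1$eta["eta_sl"]), 5e-2)

  # no observations: prior mode
  doses_only <- dat0[dat0$EVID == 1, ]
  m_empty <- map_etas(doses_only, p_truth, v_truth)
  expect_equal(unname(m_empty$eta), c(0, 0, 0))

  sing <- tmdd_variability(omega = matrix(0, 3, 3))
  expect_error(map_etas(dat0, p_truth, sing), "invertible")
})

test_that("population fit recovers the generating parameters on noise-free, eta-free data", {
  cohort <- subjects(1:3, egfr = c(30, 44, 65))
  dat <- noisefree_dataset(cohort)
  v_small <- tmdd_variability(omega = diag(1e-4, 3))
  p0 <- tmdd_params(cl = 17.6 * 1.3, svap1c = 5.52 * 1.2)
  fit <- fit_population(dat, params = p0, variability = v_small,
                        free = c("cl", "svap1c"), estimate_omega = FALSE,
                        control = list(outer_maxit = 10, cycles = 1))
  expect_equal(fit$params$cl, 17.6, tolerance = 1e-2)
  expect_equal(fit$params$svap1c, 5.52, tolerance = 1e-2)
})

test_that("the objective prefers the generating model and is invariant to relabeling", {
  dat <- small_dataset()
  at <- function(p, d) {
    fit_population(d, params = p, variability = v_truth,
                   free = "cl", estimate_omega = FALSE,
                   control = list(outer_maxit = 0, cycles = 1))$ofv
  }
  ofv_truth <- at(p_truth, dat)
  ofv_off <- at(tmdd_params(cl = 17.6 * 1.5), dat)
  expect_lt(ofv_truth, ofv_off)

  # relabel subjects and shuffle rows: same objective
  dat2 <- dat
  dat2$ID <- dat2$ID + 100
  set.seed(8)
  dat2 <- dat2[sample(nrow(dat2)), ]
  dat2 <- dat2[order(dat2$ID, dat2$TIME, dat2$EVID), ]
  expect_equal(at(p_truth, dat2), ofv_truth, tolerance = 1e-4)

  expect_error(fit_population(dat[dat$ID == 1, ], params = p_truth,
                              variability = v_truth),
               "at least 2")
  # all-placebo data with PK parameters free is non-identifiable
  placebo <- dat[dat$CMT != 2, ]
  expect_error(fit_population(placebo, params = p_truth,
                              variability = v_truth, free = "cl"),
               "identifiable")
})

test_that("eta shrinkage grows as the sampling design is thinned", {
  cohort <- sample_covariates(population_spec("ALBUM", n = 15), seed = 31)
  dat <- generate_dataset(cohort, sampling_design("ALBUM"), seed = 32)
  densities <- list(
    rich = function(d) d,
    medium = function(d) d[d$EVID == 1 | d$TIME %in% (168 * c(2, 4)), ],
    sparse = function(d) d[d$EVID == 1 |
                             (d$TIME == 168 * 2 & d$CMT == 4), ])
  sd_by_density <- vapply(densities, function(thin) {
    d <- thin(dat)
    etas <- t(vapply(split(d, d$ID), function(di) {
      qetmdd:::gn_map(qetmdd:::prep_subjects(di)[[1]], p_truth, v_truth,
                      broyden = TRUE, max_iter = 30, tol = 1e-4)$eta
    }, numeric(3)))
    mean(apply(etas, 2, sd) / sqrt(diag(v_truth$omega)))
  }, numeric(1))
  # smaller relative spread of the MAP etas = more shrinkage
  expect_true(sd_by_density["rich"] > sd_by_density["medium"])
  expect_true(sd_by_density["medium"] > sd_by_density["sparse"])
})
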