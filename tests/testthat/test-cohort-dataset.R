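test_that("covariate sampling reproduces the DKD study distributions", {
  spec <- population_spec("ALBUM", n = 10000)
  cohort <- sample_covariates(spec, seed = 5)
  expect_equal(mean(cohort$sex == "male"), 0.775, tolerance = 0.015)
  expect_equal(median(cohort$egfr), 44, tolerance = 0.02)
  expect_true(all(cohort$egfr >= 22.1 & cohort$egfr <= 71.5))
  # reproducible under seed
  again <- sample_covariates(spec, seed = 5)
  expect_identical(cohort, again)
  expect_equal(nrow(sample_covariates(population_spec("ALBUM", n = 0))), 0)
  expect_error(population_spec("ALBUM", egfr_bounds = c(5, 2)), "ordered")
  expect_error(population_spec("ALBUM", male_fraction = 1.2), "0, 1")
})

test_that("eta draws recover the full omega block", {
  e0 <- sample_etas(10, omega = matrix(0, 3, 3), seed = 1)
  expect_true(all(e0 == 0))
  etas <- sample_etas(1e5, default_omega(), seed = 6)
  emp <- cov(etas)
  expect_equal(emp[1, 1], 0.128, tolerance = 0.03)
  expect_equal(emp[2, 2], 0.0735, tolerance = 0.03)
  expect_equal(emp[3, 3], 0.0574, tolerance = 0.03)
  expect_equal(emp[1, 3], -0.0301, tolerance = 0.05)
  expect_equal(emp[1, 2], 0.0213, tolerance = 0.05)
  bad <- matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3, 3)
  expect_error(sample_etas(10, bad), "semi-definite")
})

test_that("datasets carry the right bookkeeping", {
  dat <- small_dataset()
  # rows per subject: doses plus samples
  n_dose <- nrow(build_regimen("ALBUM"))
  n_obs <- nrow(sampling_design("ALBUM"))
  expect_equal(nrow(dat), 10 * (n_dose + n_obs))
  expect_true(all(dat$MDV[dat$EVID == 1] == 1))
  expect_true(all(dat$AMT[dat$EVID == 0] == 0))
  # time-sorted within subject
  by_id <- split(dat$TIME, dat$ID)
  expect_true(all(vapply(by_id, function(x) !is.unsorted(x), logical(1))))
  # seed determinism, byte for byte
  cohort <- sample_covariates(population_spec("ALBUM", n = 10), seed = 401)
  again <- generate_dataset(cohort, sampling_design("ALBUM"), seed = 402)
  expect_identical(as.data.frame(dat), as.data.frame(again))
})

test_that("zero residual variance reproduces the noiseless predictions", {
  cohort <- sample_covariates(population_spec("ALBUM", n = 2), seed = 11)
  v0 <- tmdd_variability(sigma2_pk = 0, sigma2_svap1 = 0, sigma2_act = 0)
  dat <- generate_dataset(cohort, sampling_design("ALBUM"),
                          variability = v0, seed = 12, sample_iiv = FALSE)
  d1 <- dat[dat$ID == 1 & dat$EVID == 0, ]
  ip <- apply_covariates(cohort[1, ], tmdd_params())
  sol <- qetmdd:::tmdd_integrate(ip, build_regimen("ALBUM"),
                                 times = unique(d1$TIME))
  pred <- predict_observations(sol, ip)
  idx <- match(d1$TIME, sol[, "time"])
  expected <- ifelse(d1$CMT == 2, pred$log_drug[idx],
                     ifelse(d1$CMT == 3, pred$log_svap1[idx],
                            pred$log_activity[idx]))
  expect_equal(d1$DV, expected, tolerance = 1e-12)
})

test_that("below-LLOQ drug observations are flagged, not dropped", {
  cohort <- subjects(1)
  des <- sampling_design(schedule = data.frame(
    time = c(24, 24 * 100), type = "drug"), regimen_label = "0001-single-1")
  dat <- generate_dataset(cohort, des, seed = 13, sample_iiv = FALSE)
  obs <- dat[dat$EVID == 0, ]
  expect_equal(nrow(obs), 2)
  # 100 days after a single 1 mg dose the concentration is below 0.1 ng/mL
  expect_equal(obs$LLOQFLAG, c(0L, 1L))
  expect_true(all(is.finite(obs$DV)))
})

test_that("NONMEM-style CSV round-trips exactly and tolerates reordering", {
  dat <- small_dataset()
  tmp <- tempfile(fileext = ".csv")
  write_nonmem_csv(dat, tmp, comment = "seed 402")
  back <- read_nonmem_csv(tmp)
  expect_equal(as.data.frame(back), as.data.frame(dat)[names(back)],
               ignore_attr = TRUE)
  # shuffled column order still reads
  lines <- readLines(tmp)
  hdr <- strsplit(lines[2], ",")[[1]]
  perm <- rev(seq_along(hdr))
  body <- vapply(strsplit(lines[-(1:2)], ","), function(x) {
    paste(x[perm], collapse = ",")
  }, character(1))
  tmp2 <- tempfile(fileext = ".csv")
  writeLines(c(paste(hdr[perm], collapse = ","), body), tmp2)
  back2 <- read_nonmem_csv(tmp2)
  expect_equal(as.data.frame(back2), as.data.frame(back),
               ignore_attr = TRUE)
  expect_error(read_nonmem_csv({
    t3 <- tempfile(); writeLines("ID,TIME\n1,0", t3); t3
  }), "lacks columns")
})
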