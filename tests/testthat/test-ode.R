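ip_typ <- apply_covariates(typical_subject(), tmdd_params())

test_that("right-hand side handles the structural edge cases", {
  # all-zero state: nothing moves
  d0 <- tmdd_rhs(0, c(A1 = 0, At = 0, A2 = 0, A3 = 0, A4 = 0), ip_typ)[[1]]
  expect_equal(d0, rep(0, 5))
  # drug only in the depot: flux goes to the transit compartment first
  d1 <- tmdd_rhs(0, c(A1 = 100, At = 0, A2 = 0, A3 = 0, A4 = 0), ip_typ)[[1]]
  expect_equal(d1[2], ip_typ$ka * 100)
  expect_equal(d1[3], 0)
  # no elimination: total drug is conserved by the flux balance
  ip_nocl <- ip_typ
  ip_nocl$cl <- 0
  set.seed(1)
  for (i in 1:5) {
    s <- runif(5, 0, 5000)
    d <- tmdd_rhs(0, s, ip_nocl)[[1]]
    expect_equal(sum(d), 0, tolerance = 1e-10)
  }
  expect_error(tmdd_rhs(0, c(NA, 0, 0, 0, 0), ip_typ), "finite")
})

test_that("compiled and R right-hand sides integrate to the same trajectory", {
  reg <- build_regimen(data.frame(time = c(0, 24), dose_mg = c(40, 40)))
  times <- seq(0, 72, by = 4)
  a <- qetmdd:::tmdd_integrate(ip_typ, reg, times, use_compiled = TRUE)
  b <- qetmdd:::tmdd_integrate(ip_typ, reg, times, use_compiled = FALSE)
  expect_equal(a[, "A2"], b[, "A2"], tolerance = 1e-6)
  expect_equal(a[, "A4"], b[, "A4"], tolerance = 1e-6)
})

test_that("with no elimination the dosed amount is conserved along the solution", {
  ip <- ip_typ
  ip$cl <- 0
  reg <- build_regimen(data.frame(time = c(0, 24, 48), dose_mg = 10))
  out <- qetmdd:::tmdd_integrate(ip, reg, times = seq(0, 96, by = 2))
  total <- rowSums(out[, c("A1", "At", "A2", "A3", "A4")])
  dosed <- vapply(out[, "time"], function(t) {
    sum(ip$f1_rel * mg_to_nmol(reg$dose_mg)[reg$time + ip$lag <= t])
  }, numeric(1))
  expect_equal(total, dosed, tolerance = 1e-6)
  # and solver outputs stay non-negative
  expect_true(all(out[, -1] > -1e-9))
})

test_that("the linear-PK limit matches the matrix-exponential solution", {
  skip_if_not_installed("Matrix")
  ip <- linear_iparams()
  reg <- build_regimen(data.frame(time = 0, dose_mg = 40))
  times <- c(0.5, 1, 2, 4, 8, 12, 24, 48, 96)
  out <- qetmdd:::tmdd_integrate(ip, reg, times)
  oracle <- oracle_linear_profile(ip, ip$f1_rel * mg_to_nmol(40), times)
  idx <- match(times, out[, "time"])
  for (j in 1:5) {
    expect_equal(out[idx, j + 1], oracle[, j], tolerance = 1e-3,
                 ignore_attr = TRUE)
  }
})

test_that("observation equations expose the soluble-bound complex share", {
  # saturation: at huge central amounts the measured log concentration
  # approaches log total
  st <- c(A1 = 0, At = 0, A2 = 1e9, A3 = 0, A4 = 0)
  pred <- predict_observations(st, ip_typ)
  expect_equal(pred$log_drug, log(1e9 / ip_typ$v2), tolerance = 1e-4)
  # weight of the bound complex in the measured signal: sVAP-1c / tVAP-1c
  expect_equal(ip_typ$svap1c / ip_typ$tvap1c, 5.52 / 17.28, tolerance = 1e-3)
  expect_equal(ip_typ$svap1c / ip_typ$tvap1c, 0.3194, tolerance = 1e-3)
  # zero drug: drug prediction is flagged -Inf (log of zero concentration)
  pred0 <- predict_observations(c(A1 = 0, At = 0, A2 = 0, A3 = 0, A4 = 0),
                                ip_typ)
  expect_identical(pred0$log_drug, -Inf)
  expect_error(predict_observations(c(A1 = 0, At = 0, A2 = -1, A3 = 0,
                                      A4 = 0), ip_typ), "Negative")
})

test_that("drug-free activity equals the baseline power law times the free-target factor", {
  pred0 <- predict_observations(c(A1 = 0, At = 0, A2 = 0, A3 = 0, A4 = 0),
                                ip_typ)
  phit0 <- free_fraction_target(ip_typ$tvap1c, 0, ip_typ$kd)
  expect_equal(phit0, 1)
  expect_equal(exp(pred0$log_activity), ip_typ$sl * ip_typ$svap1c^ip_typ$pow)
  expect_equal(exp(pred0$log_activity), 3641, tolerance = 1e-3)
})
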