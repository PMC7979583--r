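# Small covariate-selection problems: a 16-subject cohort with a wide eGFR
# spread, drug observations only, and only the clearance parameter free, so
# every candidate fit is quick.
sw_cohort <- function(seed) {
  set.seed(seed)
  subjects(1:16, egfr = runif(16, 25, 110), study_phase = "phase1",
           weight = exp(rnorm(16, log(85), 0.2)))
}
sw_design <- sampling_design(schedule = data.frame(
  time = 168 * c(2, 4, 8, 12), type = "drug"), regimen_label = "ALBUM")

# base model without renal covariates (what the screen should rediscover)
sw_base_params <- tmdd_params(emax_egfr_cl = 0, pow_egfr_f1 = 0)
sw_ctl <- list(outer_maxit = 4, cycles = 1)

sw_fit_base <- function(dat) {
  fit_population(dat, params = sw_base_params,
                 variability = tmdd_variability(), free = "cl",
                 estimate_omega = FALSE, control = sw_ctl)
}

test_that("an empty candidate list returns the base fit untouched", {
  dat <- generate_dataset(sw_cohort(51), sw_design, params = sw_base_params,
                          seed = 52)
  base <- sw_fit_base(dat)
  out <- stepwise_covariates(dat, base, list())
  expect_identical(out$selected, list())
  expect_identical(out$fit, base)
  expect_equal(nrow(out$trail), 0)
})

test_that("a strong simulated eGFR-clearance effect is discovered and retained", {
  gen <- tmdd_params(emax_egfr_cl = 0, pow_egfr_f1 = 0, extra_terms = list(
    covariate_term("cl", "egfr", "power", theta = 1.2, ref = 64)))
  dat <- generate_dataset(sw_cohort(53), sw_design, params = gen, seed = 54)
  base <- sw_fit_base(dat)
  cands <- list(covariate_term("cl", "egfr", "power", ref = 64),
                covariate_term("cl", "weight", "power", ref = 85))
  out <- stepwise_covariates(dat, base, cands, refit_base = FALSE,
                             control = sw_ctl)
  labels <- vapply(out$selected, function(t) {
    paste(t$covariate, t$param)
  }, character(1))
  expect_true("egfr cl" %in% labels)
  expect_false("weight cl" %in% labels)
  est <- out$fit$params$extra_terms[[1]]$theta
  expect_equal(est, 1.2, tolerance = 0.25)
  expect_true(all(c("screen", "forward") %in% out$trail$stage))
})

test_that("null data rarely admits a covariate at the 6.63/10.8 gates", {
  hits <- 0L
  for (seed in 1:3) {
    dat <- generate_dataset(sw_cohort(60 + seed), sw_design,
                            params = sw_base_params, seed = 80 + seed)
    base <- sw_fit_base(dat)
    out <- stepwise_covariates(
      dat, base, list(covariate_term("cl", "weight", "power", ref = 85)),
      refit_base = FALSE, control = sw_ctl)
    hits <- hits + length(out$selected)
  }
  expect_lte(hits, 1L)
})

test_that("candidates on unsupported parameters are rejected", {
  dat <- generate_dataset(sw_cohort(55), sw_design, params = sw_base_params,
                          seed = 56)
  base <- sw_fit_base(dat)
  expect_error(stepwise_covariates(dat, base, list(
    list(param = "ka", covariate = "egfr", form = "power", theta = 0))),
    "unsupported")
  expect_error(covariate_term("ka", "egfr"), "supported")
  expect_error(covariate_term("cl", "height"), "Unknown covariate")
  expect_error(covariate_term("cl", "weight", "categorical-shift"),
               "only defined for sex")
})
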