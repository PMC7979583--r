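#' Simulate an individual concentration-time profile
#'
#' Integrates the TMDD system for one subject under a dosing regimen and
#' evaluates the observation equations on an output grid.  Each dose enters
#' the depot as `f1_rel * mg_to_nmol(dose_mg)` at its nominal time plus the
#' absorption lag.  Inhibition is expressed against the subject's own
#' drug-free baseline activity (`activity0`), so a zero-dose regimen gives
#' 0% inhibition throughout.
#'
#' Doses outside the range studied in the clinic (0.1-200 mg) trigger a
#' warning: the binding parameters were characterised inside that range and
#' target turnover, neglected by the model, may matter beyond it.
#'
#' @param regimen A [build_regimen()] table (possibly empty).
#' @param subject A one-row subject tibble (default the typical DKD
#'   subject); ignored when `iparams` is given.
#' @param params Population parameters ([tmdd_params()]).
#' @param grid Output times (h).  Default: hourly to the horizon.
#' @param horizon Simulation end (h); default covers the regimen plus 24 h.
#' @param iparams Optionally, a precomputed one-row [apply_covariates()]
#'   result (bypasses `subject`/`params`).
#' @param rtol,atol Solver tolerances (relative; absolute, nmol).
#' @return A tibble of class `tmdd_profile` with columns `time` (h),
#'   `conc_drug` (total measured drug, ng/mL), `conc_svap1` (nM),
#'   `activity` (nM) and `inhibition` (% of drug-free baseline).
#' @examples
#' prof <- simulate_profile(qd_regimen(40, weeks = 1),
#'                          grid = seq(0, 192, by = 1))
#' head(prof)
#' @export
simulate_profile <- function(regimen, subject = typical_subject(),
                             params = tmdd_params(), grid = NULL,
                             horizon = NULL, iparams = NULL,
                             rtol = 1e-8, atol = 1e-10) {
  if (is.null(iparams)) iparams <- apply_covariates(subject, params)
  stopifnot(nrow(iparams) == 1L)
  if (nrow(regimen) &&
      (max(regimen$dose_mg) > 200 || min(regimen$dose_mg) < 0.1)) {
    warn("Doses outside 0.1-200 mg are beyond the range the model was built on; interpret with caution.")
  }
  if (is.null(horizon)) {
    horizon <- if (nrow(regimen)) max(regimen$time) + 24 else 24
  }
  if (nrow(regimen) && max(regimen$time) > horizon) {
    abort("The regimen extends beyond the simulation horizon.")
  }
  if (is.null(grid)) grid <- seq(0, horizon, by = 1)
  if (max(grid) > horizon + 1e-9) abort("`grid` must lie within the horizon.")
  out <- tmdd_integrate(iparams, regimen, times = grid, rtol = rtol,
                        atol = atol)
  pred <- predict_observations(out, iparams)
  activity <- exp(pred$log_activity)
  prof <- tibble(
    time = out[, "time"],
    conc_drug = nM_to_ng_per_mL(exp(pmax(pred$log_drug, -745))),
    conc_svap1 = exp(pred$log_svap1),
    activity = activity,
    inhibition = if (iparams$activity0 > 0) {
      100 * (1 - activity / iparams$activity0)
    } else {
      rep(0, length(activity))
    }
  )
  prof$conc_drug[pred$log_drug == -Inf] <- 0
  class(prof) <- c("tmdd_profile", class(prof))
  attr(prof, "iparams") <- iparams
  attr(prof, "regimen") <- regimen
  prof
}

#' Simulate once-daily dosing with a metrics-ready output grid
#'
#' Convenience wrapper around [simulate_profile()] for the steady-state
#' simulations: once-daily dosing for `weeks` weeks, with an output grid
#' holding every daily pre-dose trough plus the final dosing interval
#' sampled at 0.1 h, as required by [secondary_params()].
#'
#' @inheritParams simulate_profile
#' @param dose_mg Daily dose (mg).
#' @param weeks Duration (weeks); 52 ensures steady state at all doses.
#' @return A `tmdd_profile` tibble (see [simulate_profile()]).
#' @examples
#' \donttest{
#' prof <- simulate_qd(10, weeks = 52)
#' secondary_params(prof)
#' }
#' @export
simulate_qd <- function(dose_mg, weeks = 52, subject = typical_subject(),
                        params = tmdd_params(), iparams = NULL,
                        rtol = 1e-8, atol = 1e-10) {
  n_days <- round(weeks * 7)
  grid <- sort(unique(c((0:n_days) * 24,
                        seq((n_days - 1) * 24, n_days * 24, by = 0.1))))
  simulate_profile(qd_regimen(dose_mg, weeks), subject = subject,
                   params = params, grid = grid, horizon = n_days * 24,
                   iparams = iparams, rtol = rtol, atol = atol)
}
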