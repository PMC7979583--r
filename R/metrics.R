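#' Secondary steady-state PK metrics from a once-daily profile
#'
#' From a simulated once-daily profile spanning the full dosing period
#' (conventionally 52 weeks, long enough for steady state at every dose):
#' * `auc24_52w`: area under the total drug concentration over the final
#'   24 h dosing interval, trapezoid rule on the dense grid (ng h/mL);
#' * `cmax_52w`, `tmax_52w`: maximum concentration in the final interval
#'   and its time measured from the final dose (h);
#' * `tss_weeks`: time to steady state, the first daily pre-dose trough
#'   reaching 97% of the final-week trough (weeks);
#' * `t_half_weeks`: apparent terminal half-life, defined as `tss / 5`.
#'
#' Troughs are the concentrations sampled immediately before each daily
#' dose (at t = 24k h, before the lag-shifted dose of that day enters the
#' depot).
#'
#' @param profile A `tmdd_profile` from [simulate_qd()] (daily troughs plus
#'   a final interval sampled at no coarser than 0.1 h must be present).
#' @param regimen The regimen used; defaults to the one stored on the
#'   profile.
#' @return A one-row tibble with the five metrics.
#' @examples
#' \donttest{
#' secondary_params(simulate_qd(10, weeks = 52))
#' }
#' @export
secondary_params <- function(profile, regimen = attr(profile, "regimen")) {
  if (is.null(regimen) || !nrow(regimen)) {
    abort("`secondary_params()` needs the dosing regimen.")
  }
  t_last <- max(regimen$time)
  t_end <- t_last + 24
  if (max(profile$time) < t_end - 1e-9) {
    abort("Profile does not cover the final dosing interval.")
  }
  n_days <- round(t_end / 24)
  if (n_days < 52 * 7) {
    abort("Profile must span at least 52 weeks of daily dosing.")
  }

  fin <- profile[profile$time >= t_last - 1e-9 &
                   profile$time <= t_end + 1e-9, ]
  if (max(diff(fin$time)) > 0.1 + 1e-6) {
    abort("Final dosing interval must be sampled at a 0.1 h step or finer.")
  }
  auc <- trapz(fin$time, fin$conc_drug)
  imax <- which.max(fin$conc_drug)
  cmax <- fin$conc_drug[imax]
  tmax <- fin$time[imax] - t_last

  trough_t <- (1:n_days) * 24
  idx <- match(trough_t, round(profile$time, 6))
  if (anyNA(idx)) abort("Profile must contain every daily trough time.")
  troughs <- profile$conc_drug[idx]
  trough_ss <- troughs[n_days]
  k <- which(troughs >= 0.97 * trough_ss)[1]
  tss_weeks <- trough_t[k] / 168

  tibble(auc24_52w = auc, cmax_52w = cmax, tmax_52w = tmax,
         tss_weeks = tss_weeks, t_half_weeks = tss_weeks / 5)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Time-averaged target inhibition over a window
#'
#' Trapezoid time-average of the profile's inhibition (percent of the
#' subject's drug-free baseline activity) over a window, conventionally the
#' final 24 h dosing interval of a 52-week simulation.
#'
#' @param profile A `tmdd_profile`.
#' @param window Length-2 numeric, `c(start, end)` in h.  Default: the
#'   final 24 h of the profile.
#' @return Average inhibition (%), a scalar.
#' @export
average_inhibition_24h <- function(profile,
                                   window = max(profile$time) - c(24, 0)) {
  stopifnot(length(window) == 2L)
  if (diff(window) <= 0) abort("`window` must have positive length.")
  sel <- profile$time >= window[1] - 1e-9 & profile$time <= window[2] + 1e-9
  if (sum(sel) < 2L) abort("`window` contains too few profile points.")
  trapz(profile$time[sel], profile$inhibition[sel]) /
    (max(profile$time[sel]) - min(profile$time[sel]))
}

#' Dose-normalised steady-state exposure
#'
#' Expresses each subject's steady-state AUC relative to a reference dose:
#' `reference * auc / dose`.  With linear PK the normalised exposure is
#' flat in dose; target-mediated elimination makes it fall as the dose
#' rises and the target pool saturates.
#'
#' @param metrics A tibble with columns `dose_mg` and `auc24_52w` (e.g.
#'   stacked [secondary_params()] rows or [simulate_population()] output).
#' @param reference Reference dose (mg), default 40.
#' @return The input with an added `auc_norm` column.
#' @export
dose_normalized_auc <- function(metrics, reference = 40) {
  stopifnot(all(c("dose_mg", "auc24_52w") %in% names(metrics)))
  if (any(metrics$dose_mg <= 0)) abort("Doses must be positive.")
  mutate(metrics, auc_norm = reference * .data$auc24_52w / .data$dose_mg)
}
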