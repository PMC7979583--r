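#' Describe a virtual study population
#'
#' Covariate distributions for cohort sampling: sex is Bernoulli with the
#' given male fraction; baseline eGFR is truncated normal.  The `"ALBUM"`
#' preset emulates the phase-2 DKD study: 77.5% male, eGFR mean 44 and SD
#' 11.1 mL/min/1.73m2 truncated to the observed range \[22.1, 71.5\].  The
#' mean and SD are reconstructed from the printed median and 5th/95th
#' percentiles under normality (SD = (63.4 - 26.9) / (2 x 1.645)); body
#' weight is a pass-through covariate sampled log-normally around the
#' study median.
#'
#' @param preset `"ALBUM"` or `NULL` for fully custom values.
#' @param n Number of subjects.
#' @param male_fraction Proportion male, in \[0, 1\].
#' @param egfr_mean,egfr_sd Mean and SD of baseline eGFR.
#' @param egfr_bounds Truncation bounds (positive, ordered).
#' @param phase `"phase1"` or `"phase2"`.
#' @return A list of class `population_spec`.
#' @examples
#' population_spec("ALBUM", n = 100)
#' @export
population_spec <- function(preset = "ALBUM", n = 1000,
                            male_fraction = NULL, egfr_mean = NULL,
                            egfr_sd = NULL, egfr_bounds = NULL,
                            phase = NULL) {
  if (!is.null(preset) && preset == "ALBUM") {
    male_fraction <- male_fraction %||% 0.775
    egfr_mean <- egfr_mean %||% 44
    egfr_sd <- egfr_sd %||% 11.1
    egfr_bounds <- egfr_bounds %||% c(22.1, 71.5)
    phase <- phase %||% "phase2"
  } else if (!is.null(preset)) {
    abort("Unknown population preset; available: \"ALBUM\".")
  }
  if (male_fraction < 0 || male_fraction > 1) {
    abort("`male_fraction` must lie in [0, 1].")
  }
  if (egfr_sd <= 0) abort("`egfr_sd` must be positive.")
  if (length(egfr_bounds) != 2L || any(egfr_bounds <= 0) ||
      egfr_bounds[1] >= egfr_bounds[2]) {
    abort("`egfr_bounds` must be positive and ordered.")
  }
  structure(list(n = n, male_fraction = male_fraction,
                 egfr_mean = egfr_mean, egfr_sd = egfr_sd,
                 egfr_bounds = egfr_bounds, phase = phase),
            class = "population_spec")
}

#' Sample subject covariates
#'
#' Draws a cohort from a [population_spec()]: sex ~ Bernoulli(male
#' fraction), eGFR ~ truncated normal (inverse-CDF sampling, so draws are
#' reproducible under a seed without rejection), body weight log-normal
#' (pass-through, no model effect).  Random effects are left at zero; use
#' [sample_etas()] to add inter-individual variability.
#'
#' @param spec A [population_spec()].
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A subject tibble with `spec$n` rows (empty for `n = 0`).
#' @examples
#' sample_covariates(population_spec("ALBUM", n = 5), seed = 1)
#' @export
sample_covariates <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n
  if (n <= 0) return(subjects(id = integer()))
  sex <- ifelse(runif(n) < spec$male_fraction, "male", "female")
  lo <- pnorm(spec$egfr_bounds[1], spec$egfr_mean, spec$egfr_sd)
  hi <- pnorm(spec$egfr_bounds[2], spec$egfr_mean, spec$egfr_sd)
  egfr <- qnorm(lo + runif(n) * (hi - lo), spec$egfr_mean, spec$egfr_sd)
  weight <- exp(rnorm(n, log(91.7), 0.199))
  subjects(id = seq_len(n), sex = sex, egfr = egfr,
           study_phase = spec$phase, weight = weight)
}

#' Sample individual random effects
#'
#' Multivariate-normal draws with mean zero and the full covariance block
#' `omega`, ordered (CL, sVAP-1c, SL).
#'
#' @param n Number of subjects.
#' @param omega 3x3 covariance matrix (positive semi-definite).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return An `n x 3` matrix with columns `eta_cl`, `eta_svap1`, `eta_sl`.
#' @examples
#' sample_etas(3, default_omega(), seed = 1)
#' @export
sample_etas <- function(n, omega = default_omega(), seed = NULL) {
  omega <- as.matrix(omega)
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1)) {
    abort("`omega` must be positive semi-definite.")
  }
  if (!is.null(seed)) set.seed(seed)
  if (all(omega == 0)) {
    etas <- matrix(0, n, 3)
  } else {
    etas <- MASS::mvrnorm(n, mu = c(0, 0, 0), Sigma = omega)
    if (n == 1L) etas <- matrix(etas, nrow = 1)
  }
  colnames(etas) <- c("eta_cl", "eta_svap1", "eta_sl")
  etas
}

#' Sampling-design presets
#'
#' A sampling design pairs a regimen label with a schedule of observation
#' times and types.  Presets:
#' * `"ALBUM"` (also used for VIDI): 12 weeks of 40 mg daily dosing; drug
#'   concentration measured at weeks 2, 4, 8, 12, 16, 24 and 36; soluble
#'   target concentration and plasma activity at baseline and weeks 2, 4,
#'   6, 8, 12, 16, 24 and 36;
#' * `"phase1-rich"`: the 27-day loading-dose regimen with dense day-1 and
#'   day-14 drug/activity sampling (0.5, 1, 2, 4, 8, 12 h post dose) plus
#'   daily troughs in week 1.
#'
#' @param preset Preset name, or `NULL` with an explicit `schedule`.
#' @param schedule Data frame with columns `time` (h) and `type` (one of
#'   `"drug"`, `"svap1"`, `"activity"`).
#' @param regimen_label Regimen preset name resolved by [build_regimen()].
#' @return A tibble of class `sampling_design` with columns `time`, `type`,
#'   `cmt`; the regimen label is stored as an attribute.
#' @examples
#' sampling_design("ALBUM")
#' @export
sampling_design <- function(preset = NULL, schedule = NULL,
                            regimen_label = NULL) {
  if (!is.null(preset)) {
    if (preset == "ALBUM") {
      wk <- function(w) w * 168
      schedule <- rbind(
        data.frame(time = wk(c(2, 4, 8, 12, 16, 24, 36)), type = "drug"),
        data.frame(time = wk(c(0, 2, 4, 6, 8, 12, 16, 24, 36)),
                   type = "svap1"),
        data.frame(time = wk(c(0, 2, 4, 6, 8, 12, 16, 24, 36)),
                   type = "activity"))
      regimen_label <- regimen_label %||% "ALBUM"
    } else if (preset == "phase1-rich") {
      post <- c(0.5, 1, 2, 4, 8, 12)
      days <- c(0, 13)
      tt <- c(outer(post, days * 24, `+`), (1:7) * 24)
      schedule <- rbind(
        data.frame(time = tt, type = "drug"),
        data.frame(time = c(0, tt), type = "activity"))
      regimen_label <- regimen_label %||% "0002-part2"
    } else {
      abort("Unknown design preset; available: \"ALBUM\", \"phase1-rich\".")
    }
  }
  if (is.null(schedule) || is.null(regimen_label)) {
    abort("Provide a preset, or both `schedule` and `regimen_label`.")
  }
  if (!all(schedule$type %in% c("drug", "svap1", "activity"))) {
    abort("Observation types must be drug, svap1 or activity.")
  }
  if (any(schedule$time < 0)) abort("Observation times must be >= 0.")
  out <- as_tibble(schedule[order(schedule$time), ])
  out$cmt <- c(drug = CMT_DRUG, svap1 = CMT_SVAP1,
               activity = CMT_ACT)[out$type]
  class(out) <- c("sampling_design", class(out))
  attr(out, "regimen_label") <- regimen_label
  out
}
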