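#' Build a table of virtual subjects
#'
#' Subjects carry the covariates of the final model (sex, baseline eGFR,
#' study phase), a pass-through body weight column (no effect in the final
#' model), and the three individual random effects on the log scale.
#'
#' @param id Subject identifiers.
#' @param sex `"male"` or `"female"` (recycled).
#' @param egfr Baseline eGFR (mL/min/1.73m2, positive).
#' @param study_phase `"phase1"` or `"phase2"` (recycled).
#' @param weight Body weight (kg); covariate column only, no model effect.
#' @param eta_cl,eta_svap1,eta_sl Individual random effects (log scale).
#' @return A tibble with one row per subject.
#' @examples
#' subjects(1:2, sex = c("male", "female"), egfr = 44)
#' @export
subjects <- function(id, sex = "male", egfr = 44, study_phase = "phase2",
                     weight = 91.7, eta_cl = 0, eta_svap1 = 0, eta_sl = 0) {
  out <- tibble(id = id, sex = sex, egfr = egfr, study_phase = study_phase,
                weight = weight, eta_cl = eta_cl, eta_svap1 = eta_svap1,
                eta_sl = eta_sl)
  if (!all(out$sex %in% c("male", "female"))) {
    abort("`sex` must be \"male\" or \"female\".")
  }
  if (!all(out$study_phase %in% c("phase1", "phase2"))) {
    abort("`study_phase` must be \"phase1\" or \"phase2\".")
  }
  if (any(!is.finite(out$egfr)) || any(out$egfr <= 0)) {
    abort("`egfr` must be positive and finite.")
  }
  if (any(!is.finite(out$eta_cl)) || any(!is.finite(out$eta_svap1)) ||
      any(!is.finite(out$eta_sl))) {
    abort("Random effects must be finite.")
  }
  out
}

#' The typical DKD subject used for reference simulations
#'
#' A male subject with baseline eGFR 44 mL/min/1.73m2 (the DKD-study
#' median) and all random effects at zero.
#'
#' @param egfr Baseline eGFR; default 44.
#' @param sex Sex; default `"male"`.
#' @return A one-row subject tibble.
#' @export
typical_subject <- function(egfr = 44, sex = "male") {
  subjects(id = 1L, sex = sex, egfr = egfr)
}

#' An additional covariate term for model exploration
#'
#' Describes one candidate covariate-parameter relationship of the kind
#' screened during stepwise covariate selection.  Terms act multiplicatively
#' on the individual value of `param` before the random effect is applied:
#' * `"power"`: `(cov / ref) ^ theta` (continuous covariates),
#' * `"categorical-shift"`: `1 + theta * [female]` (sex),
#' * `"sigmoid-emax"`: `1 + emax * cov^hill / (ec50^hill + cov^hill)` with
#'   the hill coefficient fixed at 10.
#'
#' @param param One of `"cl"`, `"v2"`, `"svap1c"`, `"sl"`.
#' @param covariate One of `"egfr"`, `"weight"`, `"sex"`.
#' @param form `"power"`, `"categorical-shift"` or `"sigmoid-emax"`.
#' @param theta Coefficient (power exponent or categorical shift); start 0.
#' @param emax,ec50 Sigmoid-emax coefficients (only for that form).
#' @param ref Reference value normalising continuous covariates.
#' @return A list describing the term, to be placed in the `extra_terms`
#'   field of [tmdd_params()].
#' @export
covariate_term <- function(param, covariate, form = "power", theta = 0,
                           emax = 0, ec50 = 60, ref = 64) {
  if (!param %in% c("cl", "v2", "svap1c", "sl")) {
    abort("Covariate terms are supported on cl, v2, svap1c and sl only.")
  }
  if (!covariate %in% c("egfr", "weight", "sex")) {
    abort("Unknown covariate.")
  }
  if (!form %in% c("power", "categorical-shift", "sigmoid-emax")) {
    abort("Unknown covariate form.")
  }
  if (form == "categorical-shift" && covariate != "sex") {
    abort("categorical-shift is only defined for sex.")
  }
  list(param = param, covariate = covariate, form = form, theta = theta,
       emax = emax, ec50 = ec50, ref = ref)
}

term_multiplier <- function(term, subject_row) {
  cov <- switch(term$covariate,
                egfr = subject_row$egfr,
                weight = subject_row$weight,
                sex = as.numeric(subject_row$sex == "female"))
  switch(term$form,
         "power" = (cov / term$ref)^term$theta,
         "categorical-shift" = 1 + term$theta * cov,
         "sigmoid-emax" = 1 + term$emax * cov^10 / (term$ec50^10 + cov^10))
}

#' Apply covariates and random effects to the population parameters
#'
#' Maps the population fixed effects to individual parameters for each
#' subject:
#' * clearance: `cl * (1 + emax * egfr^h / (ec50^h + egfr^h)) * exp(eta_cl)`
#'   with hill coefficient `h = 10`, so subjects above the EC50 clear the
#'   drug roughly 2.3-fold faster than subjects below it;
#' * relative bioavailability: `f1_rel = (egfr / egfr_ref_f1) ^ pow_egfr_f1`,
#'   multiplying every administered dose;
#' * soluble target: `svap1c * (1 + sex_vap1 * [female]) * exp(eta_svap1)`;
#'   all membrane-bound pools scale along through their fixed factors, so
#'   the sex effect and the random effect move every target pool together;
#' * activity slope: `sl * exp(eta_sl)`.
#'
#' @param subjects A subject tibble (see [subjects()]).
#' @param params A [tmdd_params()] object.
#' @return A tibble with one row per subject holding the individual
#'   parameters, including `f1_rel`, the derived total central target
#'   `tvap1c = svap1c_i * (1 + f_mvap1c)`, the peripheral target pools, and
#'   the subject's drug-free baseline activity `activity0` (nM).
#' @examples
#' apply_covariates(typical_subject(), tmdd_params())
#' @export
apply_covariates <- function(subjects, params) {
  stopifnot(inherits(params, "tmdd_params"))
  if (any(subjects$egfr <= 0)) abort("`egfr` must be positive.")
  n <- nrow(subjects)
  hill <- params$hill_egfr_cl
  egfr_h <- (subjects$egfr / params$ec50_egfr_cl)^hill
  cl_i <- params$cl * (1 + params$emax_egfr_cl * egfr_h / (1 + egfr_h)) *
    exp(subjects$eta_cl)
  f1_rel <- (subjects$egfr / params$egfr_ref_f1)^params$pow_egfr_f1
  female <- subjects$sex == "female"
  svap1c_i <- params$svap1c * (1 + params$sex_vap1 * female) *
    exp(subjects$eta_svap1)
  sl_i <- params$sl * exp(subjects$eta_sl)
  v2_i <- rep_len(params$v2, n)

  for (term in params$extra_terms) {
    mult <- vapply(seq_len(n), function(i) {
      term_multiplier(term, subjects[i, ])
    }, numeric(1))
    switch(term$param,
           cl = { cl_i <- cl_i * mult },
           v2 = { v2_i <- v2_i * mult },
           svap1c = { svap1c_i <- svap1c_i * mult },
           sl = { sl_i <- sl_i * mult })
  }

  tibble(
    id = subjects$id,
    sex = subjects$sex, egfr = subjects$egfr,
    study_phase = subjects$study_phase,
    ka = params$ka, lag = params$lag,
    cl = cl_i, v2 = v2_i, q = params$q, v3 = params$v3_factor * v2_i,
    q2 = params$q2, v4 = params$v4, kd = params$kd,
    f1_rel = f1_rel,
    svap1c = svap1c_i,
    mvap1c = params$f_mvap1c * svap1c_i,
    tvap1c = svap1c_i * (1 + params$f_mvap1c),
    mvap1p1 = params$f_mvap1p1 * svap1c_i,
    mvap1p2 = params$f_mvap1p2 * params$f_mvap1p1 * svap1c_i,
    sl = sl_i, pow = params$pow,
    activity0 = sl_i * svap1c_i^params$pow
  )
}
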