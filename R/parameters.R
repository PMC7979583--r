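#' Fixed-effect parameters of the quasi-equilibrium TMDD model
#'
#' Constructs the set of structural (fixed-effect) parameters of the
#' population PK-PD model.  Defaults are the published point estimates for
#' ASP8232: a three-compartment disposition model with first-order absorption
#' through one transit compartment and a lag time, quasi-equilibrium binding
#' of drug to soluble target in the central compartment and membrane-bound
#' target in all compartments (shared dissociation constant `kd`), a power
#' model linking free soluble target to plasma enzymatic activity, and
#' covariate effects of renal function (eGFR) on clearance and relative
#' bioavailability and of sex on the target concentrations.
#'
#' All clearances and volumes are apparent (scaled by bioavailability).
#' Target pools are parameterised as multiples of the soluble central
#' concentration `svap1c`: membrane-bound central = `f_mvap1c * svap1c`,
#' first peripheral = `f_mvap1p1 * svap1c`, second peripheral =
#' `f_mvap1p2` times the first peripheral pool.
#'
#' @param ka First-order absorption rate constant (1/h), also used for the
#'   transit-to-central step.
#' @param lag Absorption lag time (h); shifts every dose's entry into the
#'   depot.
#' @param cl Apparent clearance CL/F1 (L/h) of unbound drug.
#' @param v2 Apparent central volume V2/F1 (L).
#' @param q First inter-compartmental clearance Q/F1 (L/h).
#' @param v3_factor Ratio V3/V2 (fixed at 1 in the final model).
#' @param q2 Second inter-compartmental clearance Q2/F1 (L/h).
#' @param v4 Apparent second peripheral volume V4/F1 (L).
#' @param kd Equilibrium dissociation constant of the drug-target complex
#'   (nM), shared across all binding sites.
#' @param svap1c Soluble target concentration in the central compartment (nM).
#' @param f_mvap1c,f_mvap1p1,f_mvap1p2 Dimensionless target-pool multipliers
#'   (see Details); `f_mvap1p2` is fixed at 1 in the final model.
#' @param sl Slope of the activity power model (1/h).
#' @param pow Power of the activity model, in (0, 2).
#' @param emax_egfr_cl Maximum fractional increase of CL at high eGFR.
#' @param ec50_egfr_cl eGFR at half-maximal CL effect (mL/min/1.73m2).
#' @param hill_egfr_cl Hill coefficient of the eGFR-CL relationship, fixed
#'   at 10 (an effectively on/off switch around `ec50_egfr_cl`).
#' @param pow_egfr_f1 Power of eGFR on relative bioavailability (negative:
#'   bioavailability rises as renal function declines).
#' @param sex_vap1 Fractional increase of all target concentrations in
#'   females.
#' @param egfr_ref_f1 Reference eGFR normalising the bioavailability power
#'   term.  Default 44 mL/min/1.73m2, the DKD-study median, so the typical
#'   DKD subject has a relative bioavailability of exactly 1; see the
#'   methods vignette for the rationale.
#' @param extra_terms Optional list of additional covariate terms (used by
#'   [stepwise_covariates()]); see [covariate_term()].
#'
#' @return An object of class `tmdd_params` (a named list).
#' @seealso [tmdd_variability()], [apply_covariates()], [read_tmdd_config()]
#' @examples
#' theta <- tmdd_params()
#' theta$cl
#' @export
tmdd_params <- function(ka = 3.12, lag = 0.31, cl = 17.6, v2 = 210,
                        q = 37.6, v3_factor = 1, q2 = 80.5, v4 = 26.7,
                        kd = 0.929, svap1c = 5.52, f_mvap1c = 2.13,
                        f_mvap1p1 = 52, f_mvap1p2 = 1, sl = 851,
                        pow = 0.851, emax_egfr_cl = 1.3, ec50_egfr_cl = 77,
                        hill_egfr_cl = 10, pow_egfr_f1 = -0.257,
                        sex_vap1 = 0.125, egfr_ref_f1 = 44,
                        extra_terms = list()) {
  p <- list(ka = ka, lag = lag, cl = cl, v2 = v2, q = q,
            v3_factor = v3_factor, q2 = q2, v4 = v4, kd = kd,
            svap1c = svap1c, f_mvap1c = f_mvap1c, f_mvap1p1 = f_mvap1p1,
            f_mvap1p2 = f_mvap1p2, sl = sl, pow = pow,
            emax_egfr_cl = emax_egfr_cl, ec50_egfr_cl = ec50_egfr_cl,
            hill_egfr_cl = hill_egfr_cl, pow_egfr_f1 = pow_egfr_f1,
            sex_vap1 = sex_vap1, egfr_ref_f1 = egfr_ref_f1,
            extra_terms = extra_terms)
  validate_tmdd_params(p)
  structure(p, class = "tmdd_params")
}

validate_tmdd_params <- function(p) {
  pos <- c("ka", "cl", "v2", "q", "v3_factor", "q2", "v4", "kd", "svap1c",
           "sl", "ec50_egfr_cl", "egfr_ref_f1")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0) {
      abort(sprintf("Parameter `%s` must be a single positive number.", nm))
    }
  }
  if (p$lag < 0) abort("`lag` must be non-negative.")
  if (p$pow <= 0 || p$pow >= 2) abort("`pow` must lie in (0, 2).")
  if (p$f_mvap1c < 0 || p$f_mvap1p1 < 0 || p$f_mvap1p2 < 0) {
    abort("Target-pool factors must be non-negative.")
  }
  invisible(p)
}

#' @export
print.tmdd_params <- function(x, ...) {
  cat("<tmdd_params> quasi-equilibrium TMDD fixed effects\n")
  flat <- unlist(x[setdiff(names(x), "extra_terms")])
  print(round(flat, 4))
  if (length(x$extra_terms)) {
    cat("extra covariate terms:", length(x$extra_terms), "\n")
  }
  invisible(x)
}

#' Random-effect and residual-error parameters
#'
#' Bundles the stochastic model: a full 3x3 covariance block `omega` for the
#' log-normal inter-individual random effects on clearance, soluble target
#' concentration and activity slope (in that order), the additive log-scale
#' residual variances per observation type, and the residual-SD multiplier
#' applied to drug-concentration and activity observations from phase-2
#' studies.  Defaults are the published estimates.
#'
#' @param omega 3x3 symmetric positive semi-definite covariance matrix of
#'   the random effects, ordered (CL, sVAP-1c, SL).
#' @param sigma2_pk Residual variance of log drug concentration.
#' @param sigma2_svap1 Residual variance of log soluble-target concentration.
#' @param sigma2_act Residual variance of log activity.
#' @param phase2_factor Multiplier on the residual SD (not variance) of drug
#'   and activity observations from phase-2 studies.
#' @return An object of class `tmdd_variability`.
#' @examples
#' tmdd_variability()
#' @export
tmdd_variability <- function(omega = default_omega(),
                             sigma2_pk = 0.115,
                             sigma2_svap1 = 0.0351,
                             sigma2_act = 0.0696,
                             phase2_factor = 1.88) {
  omega <- as.matrix(omega)
  if (!isTRUE(all.equal(dim(omega), c(3L, 3L))) ||
      !isTRUE(all.equal(omega, t(omega), tolerance = 1e-8))) {
    abort("`omega` must be a symmetric 3x3 matrix.")
  }
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1)) {
    abort("`omega` must be positive semi-definite.")
  }
  if (any(c(sigma2_pk, sigma2_svap1, sigma2_act) < 0)) {
    abort("Residual variances must be non-negative.")
  }
  if (phase2_factor <= 0) abort("`phase2_factor` must be positive.")
  dimnames(omega) <- list(c("cl", "svap1c", "sl"), c("cl", "svap1c", "sl"))
  structure(list(omega = omega, sigma2_pk = sigma2_pk,
                 sigma2_svap1 = sigma2_svap1, sigma2_act = sigma2_act,
                 phase2_factor = phase2_factor),
            class = "tmdd_variability")
}

#' The published full omega block
#'
#' Covariance matrix of the random effects on (CL, sVAP-1c, SL): variances
#' 0.128, 0.0735 and 0.0574 with all three covariances estimated.
#'
#' @return A 3x3 covariance matrix.
#' @export
default_omega <- function() {
  matrix(c(0.128,  0.0213, -0.0301,
           0.0213, 0.0735, -0.0222,
          -0.0301, -0.0222, 0.0574), nrow = 3, byrow = TRUE)
}

#' @export
print.tmdd_variability <- function(x, ...) {
  cat("<tmdd_variability>\nomega (CL, sVAP-1c, SL):\n")
  print(round(x$omega, 4))
  cat(sprintf("sigma2: pk %.4g, svap1 %.4g, activity %.4g; phase-2 SD factor %.3g\n",
              x$sigma2_pk, x$sigma2_svap1, x$sigma2_act, x$phase2_factor))
  invisible(x)
}

# Residual SD for a vector of observation types (CMT codes) given the
# study phase ("phase1"/"phase2").  The phase-2 factor applies to drug and
# activity observations only.
residual_sd <- function(type, phase, variability) {
  base <- c(sqrt(variability$sigma2_pk), sqrt(variability$sigma2_svap1),
            sqrt(variability$sigma2_act))[match(type, c(CMT_DRUG, CMT_SVAP1,
                                                        CMT_ACT))]
  fac <- ifelse(phase == "phase2" & type %in% c(CMT_DRUG, CMT_ACT),
                variability$phase2_factor, 1)
  base * fac
}

#' Read or write a model configuration file
#'
#' The full parameter set (fixed effects, omega block, residual variances)
#' round-trips through a YAML document.  A packaged configuration with the
#' published estimates ships as
#' `system.file("extdata", "asp8232_params.yaml", package = "qetmdd")`.
#'
#' @param path Path to a YAML file.
#' @return `read_tmdd_config()` returns `list(params, variability)`.
#' @examples
#' cfg <- read_tmdd_config(system.file("extdata", "asp8232_params.yaml",
#'                                     package = "qetmdd"))
#' cfg$params$kd
#' @export
read_tmdd_config <- function(path) {
  doc <- yaml::read_yaml(path)
  theta <- doc$params
  om <- matrix(unlist(doc$variability$omega), nrow = 3, byrow = TRUE)
  list(params = do.call(tmdd_params, theta),
       variability = tmdd_variability(
         omega = om,
         sigma2_pk = doc$variability$sigma2_pk,
         sigma2_svap1 = doc$variability$sigma2_svap1,
         sigma2_act = doc$variability$sigma2_act,
         phase2_factor = doc$variability$phase2_factor))
}

#' @rdname read_tmdd_config
#' @param params A [tmdd_params()] object.
#' @param variability A [tmdd_variability()] object.
#' @export
write_tmdd_config <- function(params, variability, path) {
  stopifnot(inherits(params, "tmdd_params"),
            inherits(variability, "tmdd_variability"))
  doc <- list(
    params = params[setdiff(names(params), "extra_terms")],
    variability = list(
      omega = apply(unname(variability$omega), 1, as.list),
      sigma2_pk = variability$sigma2_pk,
      sigma2_svap1 = variability$sigma2_svap1,
      sigma2_act = variability$sigma2_act,
      phase2_factor = variability$phase2_factor))
  yaml::write_yaml(doc, path)
  invisible(path)
}
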