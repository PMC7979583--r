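#' @title Nonlinear mixed-effects estimation for the TMDD model
#' @name estimation
#' @description
#' The estimation layer fits the population model to NONMEM-style datasets:
#' per-subject MAP (empirical-Bayes) random effects, and population fixed
#' effects by maximising a Laplace approximation of the marginal likelihood
#' (second-order expansion around the MAP etas, with a Gauss-Newton
#' approximation to the inner Hessian -- the same curvature approximation
#' classical FOCE-type estimators use).  Omega and the residual variances
#' are updated by EM-type closed-form steps between cycles of the outer
#' optimisation.
NULL

# ---- internal data preparation ---------------------------------------------

# Split a NONMEM-style dataset into per-subject structures used by the
# likelihood machinery.  `mask` is an optional logical vector over rows of
# `data` marking observations to exclude (outliers); below-LLOQ drug rows
# are excluded unless use_lloq = TRUE.
prep_subjects <- function(data, use_lloq = FALSE, mask = NULL) {
  if (is.null(mask)) mask <- rep(FALSE, nrow(data))
  data$..drop <- mask
  split_rows <- split(seq_len(nrow(data)), data$ID)
  lapply(split_rows, function(ix) {
    d <- data[ix, ]
    doses <- d[d$EVID == 1L, ]
    obs <- d[d$EVID == 0L & d$MDV == 0L & !d$..drop, ]
    if (!use_lloq) obs <- obs[obs$LLOQFLAG == 0L, ]
    times <- sort(unique(obs$TIME))
    list(id = d$ID[1],
         doses = data.frame(time = doses$TIME, dose_mg = doses$AMT),
         times = times,
         oidx = match(obs$TIME, times),
         cmt = obs$CMT,
         y = obs$DV,
         rows = ix[d$EVID == 0L & d$MDV == 0L & !d$..drop &
                     (use_lloq | d$LLOQFLAG == 0L)],
         sex = ifelse(d$SEX[1] == 1L, "female", "male"),
         egfr = d$EGFR[1],
         weight = if ("WT" %in% names(d)) d$WT[1] else NA_real_,
         phase = ifelse(d$PHASE[1] == 2L, "phase2", "phase1"))
  })
}

# Individual parameters as a plain list (fast path used inside likelihood
# loops; mirrors apply_covariates() and is tested against it).
iparams_fast <- function(params, sex, egfr, phase, eta, weight = NA_real_) {
  egfr_h <- (egfr / params$ec50_egfr_cl)^params$hill_egfr_cl
  cl <- params$cl * (1 + params$emax_egfr_cl * egfr_h / (1 + egfr_h)) *
    exp(eta[1])
  svap1c <- params$svap1c * (1 + params$sex_vap1 * (sex == "female")) *
    exp(eta[2])
  sl <- params$sl * exp(eta[3])
  v2 <- params$v2
  if (length(params$extra_terms)) {
    srow <- list(egfr = egfr, weight = weight, sex = sex)
    for (term in params$extra_terms) {
      mult <- term_multiplier(term, srow)
      if (term$param == "cl") cl <- cl * mult
      else if (term$param == "v2") v2 <- v2 * mult
      else if (term$param == "svap1c") svap1c <- svap1c * mult
      else if (term$param == "sl") sl <- sl * mult
    }
  }
  list(ka = params$ka, lag = params$lag, cl = cl, v2 = v2, q = params$q,
       v3 = params$v3_factor * v2, q2 = params$q2, v4 = params$v4,
       kd = params$kd, f1_rel = (egfr / params$egfr_ref_f1)^params$pow_egfr_f1,
       svap1c = svap1c, tvap1c = svap1c * (1 + params$f_mvap1c),
       mvap1p1 = params$f_mvap1p1 * svap1c,
       mvap1p2 = params$f_mvap1p2 * params$f_mvap1p1 * svap1c,
       sl = sl, pow = params$pow, activity0 = sl * svap1c^params$pow)
}

# Build a fast predictor closure for one subject under fixed population
# parameters: eta -> vector of log-scale predictions at the subject's
# observation rows.  The event table and solver grid are precomputed (the
# lag and relative bioavailability do not depend on the random effects),
# and predictions are assembled without tibble overhead; this is the inner
# loop of the whole estimation layer.
make_predictor <- function(sub, params, rtol = 1e-6, atol = 1e-8) {
  ip0 <- iparams_fast(params, sub$sex, sub$egfr, sub$phase, c(0, 0, 0),
                      weight = sub$weight)
  solve_times <- sort(unique(c(0, sub$times)))
  evt <- NULL
  if (nrow(sub$doses)) {
    o <- order(sub$doses$time)
    evt <- data.frame(var = "A1", time = sub$doses$time[o] + ip0$lag,
                      value = ip0$f1_rel * mg_to_nmol(sub$doses$dose_mg[o]),
                      method = "add")
    # doses after the last observation cannot influence the likelihood
    evt <- evt[evt$time <= max(solve_times), , drop = FALSE]
    if (!nrow(evt)) evt <- NULL else
      solve_times <- sort(unique(c(solve_times, evt$time)))
  }
  obs_row <- match(sub$times, solve_times)[sub$oidx]
  is_drug <- sub$cmt == CMT_DRUG
  is_sv <- sub$cmt == CMT_SVAP1
  is_act <- sub$cmt == CMT_ACT
  y0 <- c(A1 = 0, At = 0, A2 = 0, A3 = 0, A4 = 0)
  function(eta) {
    ip <- iparams_fast(params, sub$sex, sub$egfr, sub$phase, eta,
                       weight = sub$weight)
    if (length(solve_times) < 2L) {
      out <- matrix(c(solve_times, y0), nrow = 1,
                    dimnames = list(NULL, c("time", names(y0))))
    } else {
      out <- deSolve::ode(y = y0, times = solve_times,
                          func = "qetmdd_derivs",
                          parms = solver_parms(ip), dllname = "qetmdd",
                          initfunc = "qetmdd_initmod", method = "lsoda",
                          rtol = rtol, atol = atol,
                          events = if (!is.null(evt)) list(data = evt))
      if (attr(out, "istate")[1] < 0) {
        abort(sprintf("ODE solver failed for subject %s.", format(sub$id)))
      }
    }
    ipred <- numeric(length(sub$cmt))
    if (any(is_drug)) {
      c2 <- pmax(out[obs_row[is_drug], "A2"], 0) / ip$v2
      phic <- phi_free(c2, ip$tvap1c, ip$kd)
      sv_share <- if (ip$tvap1c > 0) ip$svap1c / ip$tvap1c else 0
      conc <- phic * c2 + (1 - phic) * c2 * sv_share
      # floor far below any observable level: keeps the objective finite
      # (and steeply penalised) when a trial parameter set predicts no
      # drug at a sampling time
      ipred[is_drug] <- log(pmax(conc, 1e-30))
    }
    if (any(is_sv)) ipred[is_sv] <- log(ip$svap1c)
    if (any(is_act)) {
      c2a <- pmax(out[obs_row[is_act], "A2"], 0) / ip$v2
      phit <- phi_free(ip$tvap1c, c2a, ip$kd)
      ipred[is_act] <- log(ip$sl) + ip$pow * log(phit * ip$svap1c)
    }
    ipred
  }
}

# Log-scale individual predictions at a subject's observation rows.
subject_ipred <- function(sub, params, eta, rtol = 1e-6, atol = 1e-8) {
  if (!length(sub$times)) return(numeric(0))
  make_predictor(sub, params, rtol, atol)(eta)
}

check_sigma_positive <- function(variability) {
  if (min(variability$sigma2_pk, variability$sigma2_svap1,
          variability$sigma2_act) <= 0) {
    abort("Estimation requires strictly positive residual variances.")
  }
  invisible(TRUE)
}

# ---- individual likelihood --------------------------------------------------

#' Individual -2 log-likelihood of one subject's observations
#'
#' Additive normal residual error on the log scale: the contribution of a
#' subject is `sum((dv - ipred)^2 / sd^2 + log(sd^2) + log(2 pi))` over the
#' kept observations, with the residual SD taken per observation type and
#' multiplied by the phase-2 factor for drug and activity records of
#' phase-2 subjects.  Below-LLOQ drug records are skipped by default.
#'
#' @param data Rows of one subject from a NONMEM-style dataset.
#' @param iparams Individual parameters: one row of [apply_covariates()]
#'   output (random effects already applied).
#' @param variability A [tmdd_variability()] supplying the residual model.
#' @param use_lloq Include below-LLOQ drug observations (default `FALSE`).
#' @return The scalar -2 log-likelihood.
#' @export
individual_neg2ll <- function(data, iparams, variability,
                              use_lloq = FALSE) {
  if (length(unique(data$ID)) > 1L) {
    abort("`individual_neg2ll()` expects one subject's rows.")
  }
  check_sigma_positive(variability)
  sub <- prep_subjects(data, use_lloq = use_lloq)[[1]]
  ip <- as.list(iparams)
  if (length(sub$times)) {
    sol <- tmdd_integrate(ip, sub$doses, times = sub$times)
    pred <- predict_observations(sol, ip)
    idx <- match(sub$times, sol[, "time"])[sub$oidx]
    ipred <- ifelse(sub$cmt == CMT_DRUG, pred$log_drug[idx],
                    ifelse(sub$cmt == CMT_SVAP1, pred$log_svap1[idx],
                           pred$log_activity[idx]))
  } else {
    return(0)
  }
  if (any(!is.finite(sub$y))) abort("Observations must be finite log values.")
  sd <- residual_sd(sub$cmt, sub$phase, variability)
  sum((sub$y - ipred)^2 / sd^2 + log(sd^2) + log(2 * pi))
}

# ---- MAP estimation of random effects --------------------------------------

# Damped Gauss-Newton minimisation of
#   g(eta) = 0.5 * sum(r^2 / sd^2) + 0.5 * eta' Omega^-1 eta
# returning the mode, the Gauss-Newton Hessian (J' W J + Omega^-1), the
# residuals and the prediction Jacobian.  The Jacobian columns for eta_cl
# and eta_svap1 come from forward differences (one ODE solve each); the
# eta_sl column is exact (activity predictions shift one-for-one with
# eta_sl, nothing else depends on it).  With `broyden = TRUE` the exact
# Jacobian is computed on the first iteration and every `refresh`-th
# thereafter, with rank-one secant updates in between -- the line-search
# solves then carry almost the whole cost of an iteration, which matters
# in the population fit where this routine runs warm-started thousands of
# times.
gn_map <- function(sub, params, variability, eta0 = c(0, 0, 0),
                   max_iter = 30, tol = 1e-6, rtol = 1e-6, atol = 1e-8,
                   broyden = FALSE, refresh = 4L) {
  P <- solve(variability$omega)
  sd <- residual_sd(sub$cmt, sub$phase, variability)
  w <- 1 / sd^2
  if (!length(sub$y)) {
    return(list(eta = c(0, 0, 0), H = P, r = numeric(0),
                J = matrix(0, 0, 3), g = 0, neg2ll = 0, converged = TRUE,
                sd = sd))
  }
  pred <- make_predictor(sub, params, rtol, atol)
  eta <- eta0
  f <- pred(eta)
  r <- sub$y - f
  gval <- 0.5 * sum(r^2 * w) + 0.5 * drop(eta %*% P %*% eta)
  h <- 1e-4
  J <- matrix(0, length(r), 3)
  J[, 3] <- as.numeric(sub$cmt == CMT_ACT)
  eta_at_J <- rep(NA_real_, 3)
  exact_J <- function(eta, f) {
    for (k in 1:2) {
      ek <- eta; ek[k] <- ek[k] + h
      J[, k] <<- (pred(ek) - f) / h
    }
    eta_at_J <<- eta
  }
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    if (!broyden || iter == 1L || (iter - 1L) %% refresh == 0L) {
      exact_J(eta, f)
    }
    H <- crossprod(J, J * w) + P
    grad <- -crossprod(J, r * w) + P %*% eta
    delta <- tryCatch(drop(solve(H, -grad)), error = function(e) NULL)
    if (is.null(delta) || any(!is.finite(delta))) break
    if (max(abs(delta)) > 5) delta <- delta * 5 / max(abs(delta))
    step <- 1
    accepted <- FALSE
    while (step >= 1 / 64) {
      eta_new <- eta + step * delta
      f_new <- pred(eta_new)
      r_new <- sub$y - f_new
      g_new <- 0.5 * sum(r_new^2 * w) +
        0.5 * drop(eta_new %*% P %*% eta_new)
      if (is.finite(g_new) && g_new <= gval + 1e-12) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    d_eta <- eta_new - eta
    if (broyden && sum(d_eta^2) > 0) {
      # rank-one secant update of the two ODE-dependent columns
      resid_vec <- as.numeric((f_new - f) - J %*% d_eta)
      upd <- outer(resid_vec, d_eta) / sum(d_eta^2)
      J[, 1:2] <- J[, 1:2] + upd[, 1:2]
    }
    moved <- max(abs(d_eta))
    eta <- eta_new; f <- f_new; r <- r_new; gval <- g_new
    if (moved < tol) { converged <- TRUE; break }
  }
  # refresh the curvature for the Laplace term only if the secant-updated
  # Jacobian is anchored too far from the final point
  if (broyden && (anyNA(eta_at_J) || max(abs(eta - eta_at_J)) > 0.02)) {
    exact_J(eta, f)
  }
  H <- crossprod(J, J * w) + P
  neg2ll <- sum(r^2 * w + log(sd^2) + log(2 * pi))
  list(eta = eta, H = H, r = r, J = J, g = gval, neg2ll = neg2ll,
       converged = converged, sd = sd)
}

#' MAP (empirical-Bayes) estimate of one subject's random effects
#'
#' Minimises the penalised individual deviance
#' `individual_neg2ll + eta' Omega^-1 eta` by damped Gauss-Newton, with
#' multistart from the prior mode and +/- 0.5 on each axis to guard
#' against local minima of the nonlinear binding model.  A subject with no
#' usable observations returns the prior mode (zero).
#'
#' @param data Rows of one subject from a NONMEM-style dataset.
#' @param params Population fixed effects.
#' @param variability Random-effect/residual model; `omega` must be
#'   invertible.
#' @param multistart Use the 7-point multistart (default) or start only
#'   from zero.
#' @return A list with `eta` (named length-3 vector), `converged`, and the
#'   penalised objective `g`.
#' @export
map_etas <- function(data, params, variability, multistart = TRUE) {
  if (rcond(variability$omega) < 1e-12) {
    abort("`omega` must be invertible for MAP estimation.")
  }
  check_sigma_positive(variability)
  sub <- prep_subjects(data)[[1]]
  starts <- list(c(0, 0, 0))
  if (multistart) {
    for (k in 1:3) for (s in c(-0.5, 0.5)) {
      e <- c(0, 0, 0); e[k] <- s; starts <- c(starts, list(e))
    }
  }
  best <- NULL
  for (e0 in starts) {
    fit <- gn_map(sub, params, variability, eta0 = e0, broyden = TRUE,
                  max_iter = 40, tol = 1e-5)
    if (is.null(best) || fit$g < best$g) best <- fit
  }
  list(eta = setNames(best$eta, c("eta_cl", "eta_svap1", "eta_sl")),
       converged = best$converged, g = best$g)
}

# ---- outer parameter transforms --------------------------------------------

LOG_SCALE_PARS <- c("ka", "cl", "v2", "q", "q2", "v4", "kd", "svap1c", "sl",
                    "pow", "ec50_egfr_cl", "f_mvap1c", "f_mvap1p1")
ID_SCALE_PARS <- c("lag", "emax_egfr_cl", "pow_egfr_f1", "sex_vap1",
                   "v3_factor", "f_mvap1p2", "hill_egfr_cl", "egfr_ref_f1")

# Map between a named free-parameter vector (optimiser scale) and the
# params object.  Names may be plain fields or "term<i>.<coef>" for extra
# covariate terms (coef in theta/emax/ec50).
theta_pack <- function(params, free) {
  vapply(free, function(nm) {
    if (grepl("^term[0-9]+\\.", nm)) {
      i <- as.integer(sub("^term([0-9]+)\\..*$", "\\1", nm))
      coef <- sub("^term[0-9]+\\.", "", nm)
      val <- params$extra_terms[[i]][[coef]]
      if (coef == "ec50") log(val) else val
    } else if (nm %in% LOG_SCALE_PARS) {
      log(params[[nm]])
    } else if (nm %in% ID_SCALE_PARS) {
      params[[nm]]
    } else {
      abort(paste0("Unknown free parameter: ", nm))
    }
  }, numeric(1))
}

theta_unpack <- function(params, x) {
  for (nm in names(x)) {
    if (grepl("^term[0-9]+\\.", nm)) {
      i <- as.integer(sub("^term([0-9]+)\\..*$", "\\1", nm))
      coef <- sub("^term[0-9]+\\.", "", nm)
      params$extra_terms[[i]][[coef]] <-
        if (coef == "ec50") exp(x[[nm]]) else x[[nm]]
    } else if (nm %in% LOG_SCALE_PARS) {
      params[[nm]] <- exp(x[[nm]])
    } else {
      params[[nm]] <- x[[nm]]
    }
  }
  params
}

# ---- population fit ---------------------------------------------------------

#' Fit the population model by Laplace-approximate marginal likelihood
#'
#' Maximises the Laplace approximation of the marginal likelihood over the
#' free fixed effects, alternating with EM-type closed-form updates of the
#' random-effect covariance (and optionally the residual variances).  The
#' objective function value reported is
#' `OFV = sum_i [ neg2ll_i(eta*) + eta*' Omega^-1 eta* + log|Omega| +
#' log|H_i| ]`, the standard -2 log Laplace marginal likelihood (additive
#' constants included, so OFV differences are likelihood-ratio statistics).
#'
#' Within each outer objective evaluation the per-subject MAP problems are
#' re-solved warm-started from the previous evaluation; the outer gradient
#' uses the envelope property (at the inner mode, the derivative of the
#' profiled objective with respect to the fixed effects equals the partial
#' derivative at fixed etas), which saves re-solving the inner problems
#' during finite differencing.
#'
#' @param data NONMEM-style dataset (two or more subjects).
#' @param params Initial fixed effects ([tmdd_params()]).
#' @param variability Initial random-effect/residual model.
#' @param free Character vector naming the fixed effects to estimate
#'   (positive parameters are optimised on the log scale).  Covariate-term
#'   coefficients are addressed as `"term1.theta"` etc.
#' @param estimate_omega Update omega by EM between cycles (default TRUE).
#' @param estimate_sigma Update the residual variances likewise (default
#'   FALSE).
#' @param exclude_rows Integer row indices of `data` to mask (flagged
#'   outliers); masked rows are kept in the data but ignored by the fit.
#' @param control List: `cycles` (outer cycles, default 2 when omega is
#'   estimated), `outer_maxit` (BFGS iterations per cycle, default 15),
#'   `rtol`/`atol` (ODE tolerances of the estimation path), `inner_maxit`,
#'   `verbose`.
#' @return An object of class `tmdd_fit`: estimated `params`,
#'   `variability`, `ofv`, per-subject MAP `etas`, eta `shrinkage` (%),
#'   `convergence` diagnostics and the OFV `trail` across cycles.
#'   [tidy()] and [glance()] methods are available.
#' @export
fit_population <- function(data, params = tmdd_params(),
                           variability = tmdd_variability(),
                           free = c("cl", "svap1c", "sl", "pow"),
                           estimate_omega = TRUE, estimate_sigma = FALSE,
                           exclude_rows = NULL, control = list()) {
  ctl <- modifyList(list(cycles = if (estimate_omega) 2L else 1L,
                         outer_maxit = 15L, inner_maxit = 30L,
                         rtol = 1e-6, atol = 1e-8, verbose = FALSE),
                    control)
  check_sigma_positive(variability)
  mask <- rep(FALSE, nrow(data))
  if (!is.null(exclude_rows)) mask[exclude_rows] <- TRUE
  subs <- prep_subjects(data, mask = mask)
  if (length(subs) < 2L) abort("Need at least 2 subjects to fit.")
  n_drug <- sum(vapply(subs, function(s) sum(s$cmt == CMT_DRUG), numeric(1)))
  pk_pars <- c("cl", "v2", "q", "q2", "v4", "ka", "kd")
  if (n_drug == 0L && any(free %in% pk_pars)) {
    abort("Non-identifiable: no drug observations but PK parameters free.")
  }

  st <- new.env(parent = emptyenv())
  st$eta <- matrix(0, length(subs), 3)
  st$fits <- vector("list", length(subs))

  inner_pass <- function(cur_params, cur_var, warm = TRUE, maxit = NULL,
                         exact = FALSE) {
    maxit <- maxit %||% ctl$inner_maxit
    total <- 0
    ldO <- determinant(cur_var$omega, logarithm = TRUE)$modulus
    P <- solve(cur_var$omega)
    for (i in seq_along(subs)) {
      e0 <- if (warm) st$eta[i, ] else c(0, 0, 0)
      fit <- gn_map(subs[[i]], cur_params, cur_var, eta0 = e0,
                    max_iter = maxit, tol = 1e-4, rtol = ctl$rtol,
                    atol = ctl$atol, broyden = !exact)
      st$eta[i, ] <- fit$eta
      st$fits[[i]] <- fit
      ld <- determinant(fit$H, logarithm = TRUE)
      total <- total + fit$neg2ll + drop(fit$eta %*% P %*% fit$eta) +
        as.numeric(ldO) + as.numeric(ld$modulus)
    }
    total
  }

  # neg2ll + eta penalty at fixed etas (default: the stored MAP etas); no
  # inner re-convergence
  frozen_ofv <- function(cur_params, P, etas = st$eta) {
    total <- 0
    for (i in seq_along(subs)) {
      sub <- subs[[i]]
      if (!length(sub$y)) next
      eta <- etas[i, ]
      f <- subject_ipred(sub, cur_params, eta, ctl$rtol, ctl$atol)
      total <- total + sum((sub$y - f)^2 / st$fits[[i]]$sd^2) +
        drop(eta %*% P %*% eta)
    }
    total
  }

  cur_params <- params
  cur_var <- variability
  trail <- numeric(0)
  conv_codes <- integer(0)

  # One frozen-eta Gauss-Newton step over the free fixed effects: the
  # prediction sensitivities to theta are finite-differenced at the stored
  # MAP etas (one solve per subject per free parameter), giving a
  # least-squares step on the optimiser scale; by the envelope property the
  # frozen gradient equals the gradient of the eta-profiled objective, so
  # iterating step + inner re-convergence climbs the Laplace objective
  # (the small theta-dependence of the log-determinant term is neglected,
  # the same curvature shortcut classical FOCE-type estimators take).
  gn_theta_step <- function(x) {
    h <- 1e-4
    K <- length(x)
    Hm <- matrix(0, K, K)
    gv <- numeric(K)
    f_pert <- vector("list", K)
    for (k in seq_len(K)) {
      xp <- x; xp[k] <- xp[k] + h
      pp <- theta_unpack(cur_params, setNames(xp, free))
      f_pert[[k]] <- lapply(seq_along(subs), function(i) {
        if (!length(subs[[i]]$y)) return(numeric(0))
        subject_ipred(subs[[i]], pp, st$eta[i, ], ctl$rtol, ctl$atol)
      })
    }
    P <- solve(cur_var$omega)
    Hte_l <- vector("list", length(subs))
    Hee_inv_l <- vector("list", length(subs))
    g_eta_l <- vector("list", length(subs))
    for (i in seq_along(subs)) {
      fit <- st$fits[[i]]
      if (!length(fit$r)) next
      f_base <- subs[[i]]$y - fit$r
      Jt <- vapply(seq_len(K), function(k) (f_pert[[k]][[i]] - f_base) / h,
                   numeric(length(f_base)))
      Jt <- matrix(Jt, ncol = K)
      w <- 1 / fit$sd^2
      # profile the subject's random effects out of the step (Schur
      # complement on the joint Gauss-Newton system), so the direction
      # anticipates how the MAP etas re-adjust to a theta change
      Hte <- crossprod(Jt, fit$J * w)
      Hee_inv <- solve(fit$H)
      g_eta <- -crossprod(fit$J, fit$r * w) + P %*% fit$eta
      Hte_l[[i]] <- Hte; Hee_inv_l[[i]] <- Hee_inv; g_eta_l[[i]] <- g_eta
      Hm <- Hm + crossprod(Jt, Jt * w) - Hte %*% Hee_inv %*% t(Hte)
      gv <- gv + crossprod(Jt, fit$r * w) + Hte %*% Hee_inv %*% g_eta
    }
    delta <- tryCatch(drop(solve(Hm, gv)), error = function(e) NULL)
    if (is.null(delta) || any(!is.finite(delta))) return(NULL)
    if (max(abs(delta)) > 0.5) delta <- delta * 0.5 / max(abs(delta))
    # linearised eta response per unit step along delta
    eta_resp <- matrix(0, length(subs), 3)
    for (i in seq_along(subs)) {
      if (is.null(Hte_l[[i]])) next
      eta_resp[i, ] <- -drop(Hee_inv_l[[i]] %*%
                               (g_eta_l[[i]] + t(Hte_l[[i]]) %*% delta))
    }
    list(delta = delta, eta_resp = eta_resp)
  }

  for (cycle in seq_len(ctl$cycles)) {
    ofv <- inner_pass(cur_params, cur_var, warm = TRUE)
    x <- theta_pack(cur_params, free)
    P <- solve(cur_var$omega)
    code <- 0L
    for (it in seq_len(ctl$outer_maxit)) {
      gs <- gn_theta_step(x)
      if (is.null(gs)) { code <- 1L; break }
      base <- frozen_ofv(cur_params, P)
      step <- 1
      x_new <- x
      improved <- FALSE
      while (step >= 1 / 16) {
        x_try <- x + step * gs$delta
        p_try <- theta_unpack(cur_params, setNames(x_try, free))
        val <- frozen_ofv(p_try, P, st$eta + step * gs$eta_resp)
        if (is.finite(val) && val < base + 1e-9) {
          x_new <- x_try
          st$eta <- st$eta + step * gs$eta_resp
          improved <- TRUE
          break
        }
        step <- step / 2
      }
      if (!improved) break
      p_new <- theta_unpack(cur_params, setNames(x_new, free))
      ofv_new <- inner_pass(p_new, cur_var, warm = TRUE)
      if (ctl$verbose) {
        cat(sprintf("cycle %d it %d OFV %.4f (step %.3g)\n",
                    cycle, it, ofv_new, step))
      }
      moved <- max(abs(x_new - x))
      x <- x_new
      cur_params <- p_new
      done <- abs(ofv - ofv_new) < 0.01 && moved < 0.01
      ofv <- ofv_new
      if (done) break
    }
    conv_codes <- c(conv_codes, code)
    trail <- c(trail, ofv)

    if (estimate_omega || estimate_sigma) {
      om_new <- matrix(0, 3, 3)
      for (i in seq_along(subs)) {
        fit <- st$fits[[i]]
        om_new <- om_new + tcrossprod(fit$eta) + solve(fit$H)
      }
      om_new <- om_new / length(subs)
      sig <- list(pk = cur_var$sigma2_pk, sv = cur_var$sigma2_svap1,
                  act = cur_var$sigma2_act)
      if (estimate_sigma) {
        num <- c(0, 0, 0); den <- c(0, 0, 0)
        for (i in seq_along(subs)) {
          fit <- st$fits[[i]]; sub <- subs[[i]]
          if (!length(sub$y)) next
          corr <- rowSums((fit$J %*% solve(fit$H)) * fit$J)
          fac2 <- (fit$sd / sqrt(c(cur_var$sigma2_pk, cur_var$sigma2_svap1,
                                   cur_var$sigma2_act)[match(sub$cmt,
                                     c(CMT_DRUG, CMT_SVAP1, CMT_ACT))]))^2
          contr <- (fit$r^2 + corr) / fac2
          for (j in seq_along(sub$cmt)) {
            k <- match(sub$cmt[j], c(CMT_DRUG, CMT_SVAP1, CMT_ACT))
            num[k] <- num[k] + contr[j]
            den[k] <- den[k] + 1
          }
        }
        sig <- list(pk = if (den[1]) num[1] / den[1] else sig$pk,
                    sv = if (den[2]) num[2] / den[2] else sig$sv,
                    act = if (den[3]) num[3] / den[3] else sig$act)
      }
      if (estimate_omega) {
        cur_var <- tmdd_variability(omega = (om_new + t(om_new)) / 2,
                                    sigma2_pk = sig$pk,
                                    sigma2_svap1 = sig$sv,
                                    sigma2_act = sig$act,
                                    phase2_factor = cur_var$phase2_factor)
      } else if (estimate_sigma) {
        cur_var <- tmdd_variability(omega = cur_var$omega,
                                    sigma2_pk = sig$pk,
                                    sigma2_svap1 = sig$sv,
                                    sigma2_act = sig$act,
                                    phase2_factor = cur_var$phase2_factor)
      }
    }
  }

  ofv <- inner_pass(cur_params, cur_var, warm = TRUE, exact = TRUE)
  eta_sd <- apply(st$eta, 2, sd)
  shrink <- 100 * (1 - eta_sd / sqrt(diag(cur_var$omega)))
  etas <- tibble(id = vapply(subs, `[[`, numeric(1), "id"),
                 eta_cl = st$eta[, 1], eta_svap1 = st$eta[, 2],
                 eta_sl = st$eta[, 3])
  structure(list(
    params = cur_params, variability = cur_var, free = free, ofv = ofv,
    etas = etas,
    shrinkage = setNames(shrink, c("eta_cl", "eta_svap1", "eta_sl")),
    convergence = list(codes = conv_codes,
                       ok = all(conv_codes == 0) && is.finite(ofv)),
    trail = trail, n_subjects = length(subs),
    n_obs = sum(vapply(subs, function(s) length(s$y), numeric(1)))),
    class = "tmdd_fit")
}

#' @export
print.tmdd_fit <- function(x, ...) {
  cat(sprintf("<tmdd_fit> %d subjects, %d observations, OFV %.3f\n",
              x$n_subjects, x$n_obs, x$ofv))
  est <- vapply(x$free, function(nm) {
    if (grepl("^term", nm)) {
      i <- as.integer(sub("^term([0-9]+)\\..*$", "\\1", nm))
      coef <- sub("^term[0-9]+\\.", "", nm)
      x$params$extra_terms[[i]][[coef]]
    } else x$params[[nm]]
  }, numeric(1))
  print(round(est, 4))
  cat("eta shrinkage (%):",
      paste(sprintf("%.1f", x$shrinkage), collapse = ", "), "\n")
  invisible(x)
}
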