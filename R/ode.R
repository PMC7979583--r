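#' Right-hand side of the TMDD ODE system
#'
#' The state holds drug *amounts* (nmol): `A1` depot, `At` transit, `A2`
#' central (total drug, free plus target-bound), `A3` and `A4` the two
#' peripheral compartments (total).  Absorption passes through one transit
#' compartment at the same first-order rate `ka` as the depot.  All
#' distribution and elimination fluxes act on the free drug only, so each
#' rate constant is weighted by the quasi-equilibrium free fraction
#' evaluated at the current total concentration in its source compartment
#' against that compartment's target pool:
#' \deqn{dA_2/dt = k_a A_t - \phi_c (k_{20}+k_{23}+k_{24}) A_2
#'   + \phi_{p1} k_{32} A_3 + \phi_{p2} k_{42} A_4.}
#' Rate constants are derived, never stored: `k20 = cl/v2`, `k23 = q/v2`,
#' `k32 = q/v3`, `k24 = q2/v2`, `k42 = q2/v4`.
#'
#' This R implementation mirrors the compiled right-hand side used by the
#' solver and exists for inspection and testing.
#'
#' @param t Time (h); unused (the system is autonomous between doses).
#' @param state Named numeric vector `c(A1, At, A2, A3, A4)`, nmol.
#' @param parms One row of [apply_covariates()] output (or a named list
#'   with the same fields).
#' @return List with the derivative vector, as expected by
#'   [deSolve::ode()].
#' @export
tmdd_rhs <- function(t, state, parms) {
  if (any(!is.finite(state))) abort("Non-finite state passed to tmdd_rhs().")
  p <- as.list(parms)
  k20 <- p$cl / p$v2
  k23 <- p$q / p$v2
  k32 <- p$q / p$v3
  k24 <- p$q2 / p$v2
  k42 <- p$q2 / p$v4
  phic <- phi_free(state[[3]] / p$v2, p$tvap1c, p$kd)
  phip1 <- phi_free(state[[4]] / p$v3, p$mvap1p1, p$kd)
  phip2 <- phi_free(state[[5]] / p$v4, p$mvap1p2, p$kd)
  dA1 <- -p$ka * state[[1]]
  dAt <- p$ka * state[[1]] - p$ka * state[[2]]
  dA2 <- p$ka * state[[2]] - phic * (k20 + k23 + k24) * state[[3]] +
    phip1 * k32 * state[[4]] + phip2 * k42 * state[[5]]
  dA3 <- phic * k23 * state[[3]] - phip1 * k32 * state[[4]]
  dA4 <- phic * k24 * state[[3]] - phip2 * k42 * state[[5]]
  list(c(dA1, dAt, dA2, dA3, dA4))
}

# Pack one individual-parameter row into the parameter vector consumed by
# the compiled right-hand side (order fixed by src/qetmdd_init.c).
solver_parms <- function(ip) {
  c(ka = ip$ka, k20 = ip$cl / ip$v2, k23 = ip$q / ip$v2, k32 = ip$q / ip$v3,
    k24 = ip$q2 / ip$v2, k42 = ip$q2 / ip$v4, v2 = ip$v2, v3 = ip$v3,
    v4 = ip$v4, kd = ip$kd, tvap1c = ip$tvap1c, mvap1p1 = ip$mvap1p1,
    mvap1p2 = ip$mvap1p2)
}

# Integrate the system for one individual.  `dose_events` is a data frame
# with columns time (h, nominal) and dose_mg; doses enter the depot as
# f1_rel * mg_to_nmol(dose) at time + lag.  Output at `times` (the solver
# grid is augmented with the event times internally).  Stiff-capable
# adaptive integration (lsoda) at tight tolerances: the free-fraction
# nonlinearity produces sharp gradients near KD at low concentrations.
tmdd_integrate <- function(ip, dose_events, times, rtol = 1e-8,
                           atol = 1e-10, use_compiled = TRUE) {
  y0 <- c(A1 = 0, At = 0, A2 = 0, A3 = 0, A4 = 0)
  times <- sort(unique(c(0, times)))
  events <- NULL
  if (nrow(dose_events)) {
    evt <- data.frame(var = "A1",
                      time = dose_events$time + ip$lag,
                      value = ip$f1_rel * mg_to_nmol(dose_events$dose_mg),
                      method = "add")
    evt <- evt[order(evt$time), , drop = FALSE]
    # doses after the last requested output cannot influence it
    evt <- evt[evt$time <= max(times), , drop = FALSE]
    if (nrow(evt)) events <- list(data = evt)
  }
  solve_times <- if (is.null(events)) times else
    sort(unique(c(times, events$data$time)))
  if (length(solve_times) < 2L) {
    # nothing to integrate: the state at t = 0 is the (empty) initial state
    out <- matrix(c(solve_times, y0), nrow = 1,
                  dimnames = list(NULL, c("time", names(y0))))
    attr(out, "istate") <- 2L
    return(out)
  }
  if (use_compiled) {
    out <- deSolve::ode(y = y0, times = solve_times, func = "qetmdd_derivs",
                        parms = solver_parms(ip), dllname = "qetmdd",
                        initfunc = "qetmdd_initmod", method = "lsoda",
                        rtol = rtol, atol = atol, events = events)
  } else {
    out <- deSolve::ode(y = y0, times = solve_times, func = tmdd_rhs,
                        parms = ip, method = "lsoda", rtol = rtol,
                        atol = atol, events = events)
  }
  if (attr(out, "istate")[1] < 0) {
    abort(sprintf("ODE solver failed near t = %.3g h.",
                  out[nrow(out), "time"]))
  }
  out[out[, "time"] %in% times, , drop = FALSE]
}

#' Observation equations of the model
#'
#' Maps drug amounts to the three log-scale individual predictions:
#' * total measured drug concentration: free drug plus the share of complex
#'   bound to *soluble* target (the assays measure plasma, so drug bound to
#'   membrane target is not seen):
#'   `log(phi_c * C2 + (1 - phi_c) * C2 * svap1c / tvap1c)` with
#'   `C2 = A2/v2`;
#' * total soluble target concentration: `log(svap1c_i)`, constant under
#'   the no-turnover assumption;
#' * plasma activity: `log(sl * (phi_t * svap1c_i) ^ pow)`, driven by the
#'   free soluble target concentration `phi_t * svap1c_i`.
#'
#' At `A2 = 0` the drug prediction is `-Inf` (log of zero concentration);
#' callers must treat it as below any quantifiable level.
#'
#' @param state Matrix of solver output (columns `A1, At, A2, A3, A4`) or a
#'   single named state vector.
#' @param iparams One row of [apply_covariates()] output.
#' @return A tibble with columns `log_drug`, `log_svap1`, `log_activity`
#'   (natural logs of nM concentrations).
#' @export
predict_observations <- function(state, iparams) {
  if (is.null(dim(state))) state <- matrix(state, nrow = 1,
                                           dimnames = list(NULL, names(state)))
  a2 <- unname(state[, "A2"])
  if (any(a2 < -1e-9)) abort("Negative central amount.")
  a2 <- pmax(a2, 0)
  c2 <- a2 / iparams$v2
  phic <- phi_free(c2, iparams$tvap1c, iparams$kd)
  phit <- phi_free(iparams$tvap1c, c2, iparams$kd)
  sv_share <- if (iparams$tvap1c > 0) iparams$svap1c / iparams$tvap1c else 0
  conc_meas <- phic * c2 + (1 - phic) * c2 * sv_share
  tibble(
    log_drug = ifelse(conc_meas > 0, log(conc_meas), -Inf),
    log_svap1 = rep_len(log(iparams$svap1c), length(c2)),
    log_activity = log(iparams$sl) +
      iparams$pow * log(phit * iparams$svap1c)
  )
}
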