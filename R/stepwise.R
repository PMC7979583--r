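#' Stepwise covariate selection
#'
#' Screens candidate covariate-parameter relationships against a base fit,
#' then builds the covariate model by forward inclusion and backward
#' elimination using likelihood-ratio gates on the Laplace objective
#' function value: a candidate enters if it drops the OFV by at least 6.63
#' points (chi-square, 1 df, p < 0.01) and survives backward deletion only
#' if its removal raises the OFV by at least 10.8 points (p < 0.001).
#' Candidates are screened univariately, ranked by their OFV drop, and
#' added one at a time in rank order until no remaining candidate clears
#' the forward gate.
#'
#' Each candidate fit estimates the candidate's coefficient(s) together
#' with the base fit's free parameters (pass `refit_base = FALSE` to hold
#' the base fixed effects at their fitted values and estimate only the
#' covariate coefficients -- faster, at the cost of ignoring
#' base-covariate correlation).
#'
#' @param data NONMEM-style dataset.
#' @param base_fit A converged [fit_population()] result.
#' @param candidates List of [covariate_term()] descriptions.
#' @param forward,backward OFV-drop thresholds for inclusion/retention.
#' @param refit_base Re-estimate the base free parameters in every
#'   candidate fit (default `TRUE`).
#' @param control Passed to [fit_population()].
#' @return A list with `selected` (the retained terms), `fit` (the final
#'   model fit) and `trail` (a tibble auditing every step: stage, candidate,
#'   OFV, delta-OFV, decision).
#' @export
stepwise_covariates <- function(data, base_fit, candidates,
                                forward = 6.63, backward = 10.8,
                                refit_base = TRUE, control = list()) {
  if (!inherits(base_fit, "tmdd_fit")) abort("`base_fit` must be a tmdd_fit.")
  if (!isTRUE(base_fit$convergence$ok)) {
    warn("Base fit did not report clean convergence.")
  }
  if (!length(candidates)) {
    return(list(selected = list(), fit = base_fit,
                trail = tibble(stage = character(), candidate = character(),
                               ofv = numeric(), delta_ofv = numeric(),
                               decision = character())))
  }
  for (cand in candidates) {
    if (!cand$param %in% c("cl", "v2", "svap1c", "sl")) {
      abort(paste0("Candidate on unsupported parameter: ", cand$param))
    }
  }
  cand_label <- function(cand) {
    paste0(cand$covariate, "->", cand$param, " (", cand$form, ")")
  }
  term_free <- function(i, form) {
    if (form == "sigmoid-emax") paste0("term", i, c(".emax", ".ec50"))
    else paste0("term", i, ".theta")
  }
  base_free <- if (refit_base) base_fit$free else character(0)

  fit_with <- function(terms) {
    p <- base_fit$params
    p$extra_terms <- terms
    free <- c(base_free,
              unlist(lapply(seq_along(terms),
                            function(i) term_free(i, terms[[i]]$form))))
    if (!length(free)) return(base_fit)
    fit_population(data, params = p, variability = base_fit$variability,
                   free = free, estimate_omega = FALSE,
                   estimate_sigma = FALSE, control = control)
  }

  trail <- list()
  note <- function(stage, cand, ofv, dofv, decision) {
    trail[[length(trail) + 1]] <<- tibble(
      stage = stage, candidate = cand, ofv = ofv, delta_ofv = dofv,
      decision = decision)
  }

  # univariate screen
  screen <- vapply(candidates, function(cand) {
    f <- fit_with(list(cand))
    f$ofv
  }, numeric(1))
  drops <- base_fit$ofv - screen
  for (i in seq_along(candidates)) {
    note("screen", cand_label(candidates[[i]]), screen[i], drops[i],
         ifelse(drops[i] >= forward, "candidate", "not significant"))
  }
  order_idx <- order(-drops)

  # forward inclusion
  current <- list()
  current_fit <- base_fit
  for (i in order_idx) {
    if (drops[i] < forward) next
    trial <- c(current, list(candidates[[i]]))
    f <- fit_with(trial)
    dofv <- current_fit$ofv - f$ofv
    if (dofv >= forward) {
      current <- trial
      current_fit <- f
      note("forward", cand_label(candidates[[i]]), f$ofv, dofv, "included")
    } else {
      note("forward", cand_label(candidates[[i]]), f$ofv, dofv, "rejected")
    }
  }

  # backward elimination
  repeat {
    if (!length(current)) break
    worst <- NULL
    for (j in seq_along(current)) {
      reduced <- current[-j]
      f <- if (length(reduced)) fit_with(reduced) else
        (if (refit_base) base_fit else base_fit)
      rise <- f$ofv - current_fit$ofv
      note("backward", cand_label(current[[j]]), f$ofv, rise,
           ifelse(rise >= backward, "retained", "dropped"))
      if (rise < backward && (is.null(worst) || rise < worst$rise)) {
        worst <- list(j = j, rise = rise, fit = f)
      }
    }
    if (is.null(worst)) break
    current <- current[-worst$j]
    current_fit <- worst$fit
  }

  list(selected = current, fit = current_fit, trail = bind_rows(trail))
}
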