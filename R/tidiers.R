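#' Tidy a fitted TMDD population model
#'
#' @param x A [fit_population()] result.
#' @param ... Unused.
#' @return A tibble with one row per estimated quantity: the free fixed
#'   effects, the omega block entries and the residual variances, with
#'   columns `term`, `type` and `estimate`.
#' @export
tidy.tmdd_fit <- function(x, ...) {
  fe <- tibble(
    term = x$free, type = "fixed",
    estimate = vapply(x$free, function(nm) {
      if (grepl("^term", nm)) {
        i <- as.integer(sub("^term([0-9]+)\\..*$", "\\1", nm))
        coef <- sub("^term[0-9]+\\.", "", nm)
        x$params$extra_terms[[i]][[coef]]
      } else x$params[[nm]]
    }, numeric(1)))
  om <- x$variability$omega
  nm <- outer(rownames(om), colnames(om), paste, sep = ",")
  keep <- lower.tri(om, diag = TRUE)
  ov <- tibble(term = paste0("omega[", nm[keep], "]"), type = "omega",
               estimate = om[keep])
  sg <- tibble(term = c("sigma2_pk", "sigma2_svap1", "sigma2_act"),
               type = "sigma",
               estimate = c(x$variability$sigma2_pk,
                            x$variability$sigma2_svap1,
                            x$variability$sigma2_act))
  bind_rows(fe, ov, sg)
}

#' Glance at a fitted TMDD population model
#'
#' @param x A [fit_population()] result.
#' @param ... Unused.
#' @return A one-row tibble: `ofv`, `n_subjects`, `n_obs`, the three eta
#'   shrinkages (%), and a `converged` flag.
#' @export
glance.tmdd_fit <- function(x, ...) {
  tibble(ofv = x$ofv, n_subjects = x$n_subjects, n_obs = x$n_obs,
         shrink_cl = unname(x$shrinkage["eta_cl"]),
         shrink_svap1 = unname(x$shrinkage["eta_svap1"]),
         shrink_sl = unname(x$shrinkage["eta_sl"]),
         converged = x$convergence$ok)
}
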