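#' Quasi-equilibrium free fractions of drug and target
#'
#' Under the quasi-equilibrium assumption, binding of drug to target is an
#' instantaneous 1:1 equilibrium governed by the dissociation constant
#' `kd`.  Given total drug and total target concentrations (free plus
#' bound), the free concentration of either species is the positive root of
#' the mass-balance quadratic
#' \deqn{C_{free}^2 + (T + K_D - C) C_{free} - K_D C = 0,}
#' and the free *fraction* is that root divided by the total.  The same
#' expression with the roles of drug and target swapped gives the target's
#' free fraction.
#'
#' The closed form is evaluated in a cancellation-safe arrangement and the
#' indeterminate 0/0 limit at zero total concentration is taken explicitly:
#' as total drug goes to 0 the drug free fraction tends to
#' `kd / (kd + c_target)`, and symmetrically for the target.
#'
#' @param c_drug Total drug concentration (nM, non-negative; vectorised).
#' @param c_target Total target concentration (nM, non-negative; vectorised).
#' @param kd Dissociation constant (nM, positive).
#' @return Free fraction in (0, 1].
#' @examples
#' free_fraction_drug(2, 2, 1)       # 0.5
#' free_fraction_target(17.28, 0, 0.929)  # 1: no drug, all target free
#' @export
free_fraction_drug <- function(c_drug, c_target, kd) {
  check_binding_args(c_drug, c_target, kd)
  phi_free(c_drug, c_target, kd)
}

#' @rdname free_fraction_drug
#' @export
free_fraction_target <- function(c_target, c_drug, kd) {
  check_binding_args(c_drug, c_target, kd)
  phi_free(c_target, c_drug, kd)
}

check_binding_args <- function(c_drug, c_target, kd) {
  if (any(kd <= 0)) abort("`kd` must be positive.")
  if (any(c_drug < 0) || any(c_target < 0)) {
    abort("Total concentrations must be non-negative.")
  }
  invisible(TRUE)
}

# Free fraction of species A (total conc `C`) against binding partner B
# (total conc `T`).  Vectorised; mirrors phi_free() in src/qetmdd_init.c.
# For C <= T + kd the conjugate form 2 kd / (sqrt(b^2 + 4 kd C) - b) avoids
# the catastrophic cancellation of the textbook root.
phi_free <- function(C, T, kd) {
  n <- max(length(C), length(T), length(kd))
  C <- rep_len(C, n); T <- rep_len(T, n); kd <- rep_len(kd, n)
  out <- numeric(n)
  zeroT <- T <= 0
  zeroC <- !zeroT & C <= 0
  rest <- !zeroT & !zeroC
  out[zeroT] <- 1
  out[zeroC] <- kd[zeroC] / (kd[zeroC] + T[zeroC])
  if (any(rest)) {
    b <- C[rest] - T[rest] - kd[rest]
    s <- sqrt(b^2 + 4 * kd[rest] * C[rest])
    out[rest] <- ifelse(b > 0, (b + s) / (2 * C[rest]),
                        2 * kd[rest] / (s - b))
  }
  out
}
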