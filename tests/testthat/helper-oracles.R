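# Independent oracles used across the suite.

# Brute-force free fraction of species A (total `ca`) against partner B
# (total `cb`): numeric root of the scalar mass balance
#   free * (1 + cb / (kd + free)) = ca,
# solved for log(free) so the residual is a log-ratio (no catastrophic
# cancellation near the root); entirely independent of the closed form
# under test.
oracle_free_fraction <- function(ca, cb, kd) {
  if (ca <= 0) return(kd / (kd + cb))
  g <- function(u) u + log1p(cb / (kd + exp(u))) - log(ca)
  u <- uniroot(g, lower = log(ca) - 80, upper = log(ca),
               tol = 1e-13)$root
  exp(u) / ca
}

# Linear three-compartment + transit system matrix (all targets zero, so
# every free fraction is 1); states (A1, At, A2, A3, A4).
linear_system_matrix <- function(ip) {
  k20 <- ip$cl / ip$v2; k23 <- ip$q / ip$v2; k32 <- ip$q / ip$v3
  k24 <- ip$q2 / ip$v2; k42 <- ip$q2 / ip$v4
  matrix(c(
    -ip$ka,      0,            0,                  0,     0,
     ip$ka, -ip$ka,            0,                  0,     0,
         0,  ip$ka, -(k20 + k23 + k24),          k32,   k42,
         0,      0,          k23,                -k32,     0,
         0,      0,          k24,                   0,  -k42),
    nrow = 5, byrow = TRUE)
}

# Matrix-exponential solution of the linear system after a single oral
# dose (amount entering the depot at time `lag`), evaluated at `times`.
oracle_linear_profile <- function(ip, dose_nmol, times) {
  A <- linear_system_matrix(ip)
  y0 <- c(dose_nmol, 0, 0, 0, 0)
  t(vapply(times, function(t) {
    if (t <= ip$lag) return(numeric(5))
    as.numeric(Matrix::expm(A * (t - ip$lag)) %*% y0)
  }, numeric(5)))
}

# A typical-subject individual-parameter row with all target pools removed
# (the linear-PK limit).
linear_iparams <- function(params = tmdd_params()) {
  ip <- apply_covariates(typical_subject(), params)
  ip$svap1c <- 0
  ip$mvap1c <- 0
  ip$tvap1c <- 0
  ip$mvap1p1 <- 0
  ip$mvap1p2 <- 0
  ip$activity0 <- 0
  ip
}

# Small shared fixture: a 10-subject phase-2 dataset on the 12-week design.
small_dataset <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      cohort <- sample_covariates(population_spec("ALBUM", n = 10), seed = 401)
      memo <<- generate_dataset(cohort, sampling_design("ALBUM"), seed = 402)
    }
    memo
  }
})
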