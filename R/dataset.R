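#' Generate a NONMEM-style longitudinal dataset
#'
#' Builds the longitudinal observation table every downstream stage
#' (estimation, VPC, covariate selection) consumes, emulating a clinical
#' study: each subject of the cohort receives the design's dosing regimen,
#' is simulated noiselessly at the scheduled observation times, and then
#' additive normal residual error is applied on the log scale per
#' observation type.  For phase-2 subjects the residual SD of drug and
#' activity observations is multiplied by the phase-2 factor.  Drug
#' observations whose simulated concentration falls below the assay lower
#' limit of quantification are retained but flagged (`LLOQFLAG = 1`);
#' estimation ignores flagged rows by default.
#'
#' @param cohort Subject tibble; etas are drawn from `variability$omega`
#'   when `sample_iiv` is `TRUE` (the default), otherwise the cohort's own
#'   eta columns are used.
#' @param design A [sampling_design()].
#' @param params Population fixed effects.
#' @param variability Random-effect/residual model ([tmdd_variability()]).
#' @param seed Integer seed (etas and residuals).
#' @param sample_iiv Draw fresh etas (default `TRUE`).
#' @param lloq Drug-assay lower limit of quantification, ng/mL.
#' @param horizon Simulation horizon (h); defaults to covering both the
#'   regimen and the sampling schedule.  Scheduled times beyond an
#'   explicitly supplied horizon are an error.
#' @return A tibble with columns `ID, TIME, AMT, EVID, CMT, DV, MDV,
#'   LLOQFLAG, SEX, EGFR, PHASE, WT`: dose rows (`EVID = 1`, `MDV = 1`, `AMT`
#'   in mg, `CMT = 1`) and observation rows (`EVID = 0`, `MDV = 0`, `DV` =
#'   log concentration in nM or log activity in nM, `CMT` 2 = drug, 3 =
#'   soluble target, 4 = activity).  `SEX` is 0 = male, 1 = female;
#'   `PHASE` is 1 or 2.  The generating etas are attached as attribute
#'   `"etas"`.
#' @examples
#' cohort <- sample_covariates(population_spec("ALBUM", n = 2), seed = 1)
#' dat <- generate_dataset(cohort, sampling_design("ALBUM"), seed = 2)
#' head(dat)
#' @export
generate_dataset <- function(cohort, design, params = tmdd_params(),
                             variability = tmdd_variability(), seed = NULL,
                             sample_iiv = TRUE, lloq = 0.1,
                             horizon = NULL) {
  stopifnot(inherits(design, "sampling_design"))
  regimen <- build_regimen(attr(design, "regimen_label"))
  t_need <- max(c(design$time, regimen$time + 24))
  if (is.null(horizon)) {
    horizon <- t_need
  } else if (max(design$time) > horizon) {
    abort("Sampling times extend beyond the simulation horizon.")
  }
  if (!is.null(seed)) set.seed(seed)
  if (sample_iiv) {
    etas <- sample_etas(nrow(cohort), variability$omega)
    cohort$eta_cl <- etas[, "eta_cl"]
    cohort$eta_svap1 <- etas[, "eta_svap1"]
    cohort$eta_sl <- etas[, "eta_sl"]
  } else {
    etas <- as.matrix(cohort[, c("eta_cl", "eta_svap1", "eta_sl")])
  }
  ip_all <- apply_covariates(cohort, params)
  obs_times <- sort(unique(design$time))

  per_subject <- lapply(seq_len(nrow(cohort)), function(i) {
    ip <- ip_all[i, ]
    sol <- tmdd_integrate(ip, regimen, times = obs_times)
    pred <- predict_observations(sol, ip)
    idx <- match(design$time, sol[, "time"])
    ipred <- ifelse(design$cmt == CMT_DRUG, pred$log_drug[idx],
                    ifelse(design$cmt == CMT_SVAP1, pred$log_svap1[idx],
                           pred$log_activity[idx]))
    sdv <- residual_sd(design$cmt, cohort$study_phase[i], variability)
    dv <- ipred + rnorm(nrow(design), 0, sdv)
    obs <- tibble(
      ID = cohort$id[i], TIME = design$time, AMT = 0, EVID = 0L,
      CMT = design$cmt, DV = dv, MDV = 0L,
      LLOQFLAG = as.integer(design$cmt == CMT_DRUG &
                              nM_to_ng_per_mL(exp(dv)) < lloq))
    dose <- tibble(
      ID = cohort$id[i], TIME = regimen$time, AMT = regimen$dose_mg,
      EVID = 1L, CMT = CMT_DOSE, DV = NA_real_, MDV = 1L, LLOQFLAG = 0L)
    out <- bind_rows(dose, obs)
    out <- out[order(out$TIME, out$EVID), ]
    out$SEX <- as.integer(cohort$sex[i] == "female")
    out$EGFR <- cohort$egfr[i]
    out$PHASE <- ifelse(cohort$study_phase[i] == "phase2", 2L, 1L)
    out$WT <- cohort$weight[i]
    out
  })
  out <- bind_rows(per_subject)
  attr(out, "etas") <- etas
  out
}

NM_COLS <- c("ID", "TIME", "AMT", "EVID", "CMT", "DV", "MDV", "LLOQFLAG",
             "SEX", "EGFR", "PHASE", "WT")

#' Read and write NONMEM-style CSV files
#'
#' The writer emits the fixed column order `ID, TIME, AMT, EVID, CMT, DV,
#' MDV, LLOQFLAG, SEX, EGFR, PHASE, WT` (body weight is a pass-through
#' covariate with no effect in the final model), with numeric values at full (17
#' significant digit) precision so a write/read round trip reproduces the
#' table exactly.  An optional commented header records package version and
#' seed provenance.  The reader tolerates arbitrary column order and
#' ignores `#` comment lines.
#'
#' @param data A dataset as produced by [generate_dataset()].
#' @param path File path.
#' @param comment Optional character vector of provenance lines to embed
#'   (each written prefixed with `# `).
#' @return `read_nonmem_csv()` returns a tibble with the standard columns.
#' @export
write_nonmem_csv <- function(data, path, comment = NULL) {
  missing <- setdiff(NM_COLS, names(data))
  if (length(missing)) {
    abort(paste0("Dataset lacks columns: ", paste(missing, collapse = ", ")))
  }
  df <- as.data.frame(data)[, NM_COLS]
  for (nm in NM_COLS) {
    if (is.double(df[[nm]])) {
      df[[nm]] <- ifelse(is.na(df[[nm]]), "",
                         formatC(df[[nm]], digits = 17, format = "g"))
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) {
    writeLines(paste0("# ", comment), con)
  }
  utils::write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_nonmem_csv
#' @export
read_nonmem_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#",
                        na.strings = c("NA", "", "."))
  if (!"WT" %in% names(df)) df$WT <- NA_real_
  missing <- setdiff(NM_COLS, names(df))
  if (length(missing)) {
    abort(paste0("File lacks columns: ", paste(missing, collapse = ", ")))
  }
  out <- as_tibble(df[, NM_COLS])
  for (nm in c("EVID", "MDV", "LLOQFLAG", "SEX", "PHASE", "CMT")) {
    out[[nm]] <- as.integer(out[[nm]])
  }
  for (nm in c("TIME", "AMT", "DV", "EGFR", "WT")) {
    out[[nm]] <- as.numeric(out[[nm]])
  }
  out[order(out$ID, out$TIME, out$EVID), ]
}
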