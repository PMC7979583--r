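#' Convert an oral dose in mg to nmol
#'
#' Doses are administered in mg but the model tracks molar amounts, using the
#' molecular weight of the free base (444 g/mol).
#'
#' @param dose_mg Dose in mg (scalar or vector, non-negative).
#' @return Amount in nmol.
#' @examples
#' mg_to_nmol(40)
#' @export
mg_to_nmol <- function(dose_mg) {
  stopifnot(is.numeric(dose_mg))
  if (any(dose_mg < 0, na.rm = TRUE)) {
    abort("`dose_mg` must be non-negative.")
  }
  dose_mg * 1e6 / MW_DRUG
}

#' Convert between molar and mass concentration units
#'
#' Plasma concentrations are modelled in nM and reported in ng/mL; the two
#' are related through the molecular weight of the free base (444 g/mol).
#'
#' @param conc Concentration (non-negative scalar or vector).
#' @return The converted concentration.
#' @examples
#' nM_to_ng_per_mL(4.5045)
#' ng_per_mL_to_nM(2)
#' @export
nM_to_ng_per_mL <- function(conc) {
  stopifnot(is.numeric(conc))
  if (any(conc < 0, na.rm = TRUE)) {
    abort("`conc` must be non-negative.")
  }
  conc * MW_DRUG / 1000
}

#' @rdname nM_to_ng_per_mL
#' @export
ng_per_mL_to_nM <- function(conc) {
  stopifnot(is.numeric(conc))
  if (any(conc < 0, na.rm = TRUE)) {
    abort("`conc` must be non-negative.")
  }
  conc * 1000 / MW_DRUG
}
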