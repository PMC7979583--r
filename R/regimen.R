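#' Build a dosing regimen
#'
#' A regimen is an ordered table of oral dose events, `(time, dose_mg)`,
#' with `time` the nominal administration time in hours.  Either pass a
#' data frame of explicit events, or the name of a packaged preset covering
#' the clinical study arms:
#'
#' * `"ALBUM"`, `"VIDI"`: 40 mg once daily for 12 weeks (84 doses);
#' * `"0002-part2"`: 250 mg loading dose on day 1, then 150 mg daily on
#'   days 2-28;
#' * `"0001-single-<dose>"`: a single dose, e.g. `"0001-single-10"` for the
#'   10 mg arm (arms 0.1, 1, 3, 10, 30, 100 mg);
#' * `"0001-multiple-low"`: 0.2 mg on day 1, 1 mg loading dose on day 8,
#'   then 0.2 mg daily on days 9-21;
#' * `"0001-multiple-mid"`: 200 mg on day 1, 600 mg loading dose on day 2,
#'   then 200 mg daily on days 3-14.
#'
#' @param spec A preset name, or a data frame with columns `time` and
#'   `dose_mg` (times non-decreasing, doses positive).  An empty data frame
#'   gives an empty regimen (baseline-only simulation).
#' @param label Optional free-text label; defaults to the preset name.
#' @return A tibble of class `tmdd_regimen` with columns `time`, `dose_mg`.
#' @examples
#' build_regimen("ALBUM")
#' build_regimen(data.frame(time = 0, dose_mg = 40))
#' @export
build_regimen <- function(spec, label = NULL) {
  if (is.character(spec)) {
    events <- regimen_preset(spec)
    label <- label %||% spec
  } else if (is.data.frame(spec)) {
    if (nrow(spec) && !all(c("time", "dose_mg") %in% names(spec))) {
      abort("A custom regimen needs `time` and `dose_mg` columns.")
    }
    events <- if (nrow(spec)) spec[, c("time", "dose_mg")] else
      data.frame(time = numeric(), dose_mg = numeric())
    label <- label %||% "custom"
  } else {
    abort("`spec` must be a preset name or a data frame.")
  }
  if (nrow(events)) {
    if (is.unsorted(events$time)) abort("Dose times must be non-decreasing.")
    if (any(events$dose_mg <= 0)) abort("Doses must be positive.")
  }
  out <- as_tibble(events)
  class(out) <- c("tmdd_regimen", class(out))
  attr(out, "label") <- label
  out
}

regimen_preset <- function(name) {
  if (name %in% c("ALBUM", "VIDI")) {
    return(data.frame(time = (0:83) * 24, dose_mg = 40))
  }
  if (name == "0002-part2") {
    return(data.frame(time = (0:27) * 24, dose_mg = c(250, rep(150, 27))))
  }
  if (grepl("^0001-single-", name)) {
    dose <- suppressWarnings(as.numeric(sub("^0001-single-", "", name)))
    if (is.na(dose) || !dose %in% c(0.1, 1, 3, 10, 30, 100)) {
      abort(paste0("Unknown single-dose arm: ", name,
                   ". Doses 0.1, 1, 3, 10, 30, 100 mg are available."))
    }
    return(data.frame(time = 0, dose_mg = dose))
  }
  if (name == "0001-multiple-low") {
    return(data.frame(time = c(0, 7 * 24, (8:20) * 24),
                      dose_mg = c(0.2, 1, rep(0.2, 13))))
  }
  if (name == "0001-multiple-mid") {
    return(data.frame(time = c(0, 24, (2:13) * 24),
                      dose_mg = c(200, 600, rep(200, 12))))
  }
  abort(paste0(
    "Unknown regimen preset \"", name, "\". Available presets: ALBUM, VIDI, ",
    "0002-part2, 0001-single-<dose>, 0001-multiple-low, 0001-multiple-mid."))
}

#' Once-daily dosing regimen
#'
#' @param dose_mg Daily dose (mg).
#' @param weeks Number of weeks of daily dosing.
#' @return A `tmdd_regimen` with `7 * weeks` daily doses starting at t = 0.
#' @examples
#' qd_regimen(40, weeks = 52)
#' @export
qd_regimen <- function(dose_mg, weeks = 52) {
  n <- round(weeks * 7)
  build_regimen(data.frame(time = (seq_len(n) - 1) * 24, dose_mg = dose_mg),
                label = sprintf("%g mg QD x %g weeks", dose_mg, weeks))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
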