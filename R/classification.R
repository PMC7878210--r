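# Cutoff-based interpretation of pressure indices and reclassification
# analysis after hydrostatic correction.

#' Diagnostic cutoffs for the pressure indices
#'
#' Conventional treat thresholds: FFR 0.80 under hyperemia, resting Pd/Pa
#' 0.92. An index at or below its cutoff is interpreted as positive
#' (hemodynamically significant); the boundary convention is configurable
#' via [interpret_index()].
#'
#' @param ffr_cutoff FFR cutoff, in (0, 1).
#' @param pdpa_cutoff resting Pd/Pa cutoff, in (0, 1).
#' @return An object of class `"cutoffs"`.
#' @export
cutoffs <- function(ffr_cutoff = 0.80, pdpa_cutoff = 0.92) {
  for (v in c(ffr_cutoff, pdpa_cutoff))
    if (!is.finite(v) || v <= 0 || v >= 1)
      stop("cutoffs must lie in (0, 1)")
  structure(list(ffr_cutoff = ffr_cutoff, pdpa_cutoff = pdpa_cutoff),
            class = "cutoffs")
}

#' Dichotomous interpretation of a pressure index
#'
#' `"positive"` (hemodynamically significant stenosis) if the index is at or
#' below the cutoff, `"negative"` otherwise. The boundary value counts as
#' positive by default, matching the clinical reading of "FFR <= 0.80";
#' set `boundary_positive = FALSE` for a strict-inequality convention.
#'
#' @param index index value(s), dimensionless.
#' @param cutoff cutoff value in (0, 1).
#' @param boundary_positive logical; does `index == cutoff` count positive?
#' @return character vector of `"positive"` / `"negative"`.
#' @export
interpret_index <- function(index, cutoff, boundary_positive = TRUE) {
  pos <- if (boundary_positive) index <= cutoff else index < cutoff
  ifelse(pos, "positive", "negative")
}

#' Did correction change the interpretation?
#'
#' TRUE when the measured and corrected index values fall on opposite sides
#' of the cutoff, i.e. hydrostatic correction flips a positive result to
#' negative or vice versa.
#'
#' @param measured measured index value(s).
#' @param corrected corrected index value(s).
#' @inheritParams interpret_index
#' @return logical vector.
#' @export
is_reclassified <- function(measured, corrected, cutoff,
                            boundary_positive = TRUE) {
  interpret_index(measured, cutoff, boundary_positive) !=
    interpret_index(corrected, cutoff, boundary_positive)
}

#' Reclassification report for a corrected cohort
#'
#' Counts and percentage rates of lesions whose dichotomous FFR and resting
#' Pd/Pa interpretations change after hydrostatic correction. Percentages
#' are rounded to the nearest integer.
#'
#' @param lesions data frame carrying measured and corrected indices
#'   (columns `ffr_measured`, `ffr_corrected`, `pdpa_measured`,
#'   `pdpa_corrected`), e.g. from [correct_lesions()].
#' @param cut a [cutoffs()] object.
#' @param boundary_positive boundary convention, see [interpret_index()].
#' @return An object of class `"cohort_report"`: list with `n_lesions`,
#'   `n_reclassified_ffr`, `n_reclassified_pdpa`, `rate_ffr`, `rate_pdpa`
#'   (integer percent), `cutoffs`, and `per_lesion` (data frame of flags).
#' @export
reclassification_report <- function(lesions, cut = cutoffs(),
                                    boundary_positive = TRUE) {
  stopifnot(inherits(cut, "cutoffs"))
  need <- c("ffr_measured", "ffr_corrected", "pdpa_measured", "pdpa_corrected")
  if (!is.data.frame(lesions) || !all(need %in% names(lesions)))
    stop("`lesions` must be a data frame with columns ",
         paste(need, collapse = ", "), " (see correct_lesions())")
  if (nrow(lesions) == 0)
    stop("empty cohort: no lesions to report on")
  flag_ffr <- is_reclassified(lesions$ffr_measured, lesions$ffr_corrected,
                              cut$ffr_cutoff, boundary_positive)
  flag_pdpa <- is_reclassified(lesions$pdpa_measured, lesions$pdpa_corrected,
                               cut$pdpa_cutoff, boundary_positive)
  per_lesion <- data.frame(
    lesion_id = if ("lesion_id" %in% names(lesions)) lesions$lesion_id
                else seq_len(nrow(lesions)),
    segment = if ("segment" %in% names(lesions)) lesions$segment else NA,
    ffr_measured = lesions$ffr_measured,
    ffr_corrected = lesions$ffr_corrected,
    ffr_reclassified = flag_ffr,
    pdpa_measured = lesions$pdpa_measured,
    pdpa_corrected = lesions$pdpa_corrected,
    pdpa_reclassified = flag_pdpa,
    stringsAsFactors = FALSE)
  n <- nrow(lesions)
  structure(list(n_lesions = n,
                 n_reclassified_ffr = sum(flag_ffr),
                 n_reclassified_pdpa = sum(flag_pdpa),
                 rate_ffr = round_half_out(100 * sum(flag_ffr) / n, 0),
                 rate_pdpa = round_half_out(100 * sum(flag_pdpa) / n, 0),
                 cutoffs = cut,
                 per_lesion = per_lesion),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Reclassification after hydrostatic correction (n = %d lesions)\n",
              x$n_lesions))
  cat(sprintf("  FFR   (cutoff %.2f): %d reclassified (%d%%)\n",
              x$cutoffs$ffr_cutoff, x$n_reclassified_ffr, x$rate_ffr))
  cat(sprintf("  Pd/Pa (cutoff %.2f): %d reclassified (%d%%)\n",
              x$cutoffs$pdpa_cutoff, x$n_reclassified_pdpa, x$rate_pdpa))
  invisible(x)
}
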