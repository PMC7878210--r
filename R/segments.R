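# Syntax-nomenclature segment model, per-segment height aggregation and the
# per-segment correction table (hydrostatic pressure, corrected FFR / Pd/Pa
# at a reference aortic pressure, and the index shift delta).

#' Epicardial coronary segments (Syntax nomenclature)
#'
#' The ten epicardial segments in which intracoronary pressure is routinely
#' measured: proximal/mid/distal LAD, proximal/distal CX, proximal/mid/distal
#' RCA, and the posterolateral (PL) and posterior descending (PD) branches.
#' The left main stem and branches under 2 mm are excluded. A mapping to
#' Syntax segment numbers ships in
#' `system.file("extdata", "segment_syntax_map.csv", package = "hydroffr")`.
#'
#' @format character vector of 10 segment labels.
#' @export
syntax_segments <- c("LAD_prox", "LAD_mid", "LAD_dist",
                     "CX_prox", "CX_dist",
                     "RCA_prox", "RCA_mid", "RCA_dist",
                     "PL", "PD")

#' Reference per-segment height statistics
#'
#' Mean and SD (mm) of the orifice-to-sensor height difference for each of
#' the ten segments, from 305 lateral-view measurements in a supine cohort:
#' every LAD segment lies above its orifice (negative heights, highest at
#' the apex), the CX runs downward (positive), the RCA heights are small
#' proximally and positive distally; PL and PD here originate from the RCA
#' (right-dominant circulation).
#'
#' @param circulation `"right_dominant"` (default) or `"left_dominant"`.
#'   The PL/PD origin is metadata only: the height statistics were observed
#'   in a right-dominant cohort and no left-dominant reference values are
#'   available, so the left-dominant table carries the same numbers with
#'   the origin recorded as CX.
#' @return data frame with columns `segment`, `height_mean_mm`,
#'   `height_sd_mm`, `origin`.
#' @export
reference_heights <- function(circulation = c("right_dominant", "left_dominant")) {
  circulation <- match.arg(circulation)
  df <- data.frame(
    segment = syntax_segments,
    height_mean_mm = c(-13.69, -46.13, -56.80, 14.98, 28.04,
                       -6.39, -6.86, 17.95, 29.65, 17.53),
    height_sd_mm = c(5.4, 6.1, 7.7, 8.3, 6.3, 2.9, 7.0, 6.6, 6.1, 6.6),
    stringsAsFactors = FALSE)
  branch_origin <- if (circulation == "right_dominant") "RCA" else "CX"
  df$origin <- ifelse(df$segment %in% c("PL", "PD"), branch_origin,
                      sub("_.*$", "", df$segment))
  df
}

check_segments <- function(segment) {
  bad <- setdiff(unique(as.character(segment)), syntax_segments)
  if (length(bad))
    stop("unknown segment label(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(syntax_segments, collapse = ", "), ")")
  invisible(TRUE)
}

#' Summarize measured heights per coronary segment
#'
#' Arithmetic mean and sample SD (n - 1 denominator) of the height
#' measurements in each segment, plus the derived correction quantities:
#' mean hydrostatic pressure, corrected FFR and Pd/Pa cells at the reference
#' aortic pressure, and the index shift delta. The SD of the hydrostatic
#' pressure is reported as `factor * height_sd`, an approximation labelled
#' as such (see the methods vignette). Segments with a single measurement
#' get `NA` SDs.
#'
#' @param heights data frame with columns `segment` and `height_mm`, one
#'   row per measurement.
#' @param factor mmHg per mm (number or [conversion_factor()]).
#' @param pa_ref reference aortic pressure, mmHg.
#' @param ffr0 reference measured FFR for the corrected-FFR column.
#' @param pdpa0 reference measured resting Pd/Pa.
#' @return data frame of class `"segment_summary"` with one row per segment
#'   present: `segment`, `n`, `height_mean_mm`, `height_sd_mm`,
#'   `p_h_mean_mmhg`, `p_h_sd_mmhg`, `ffr_at_ref`, `pdpa_at_ref`, `delta`
#'   (unrounded; see [write_correction_table()] for 3-dp display).
#' @export
summarize_heights <- function(heights, factor = 0.077, pa_ref = 100,
                              ffr0 = 0.80, pdpa0 = 0.92) {
  if (!is.data.frame(heights) || !all(c("segment", "height_mm") %in% names(heights)))
    stop("`heights` must be a data frame with columns segment, height_mm")
  if (nrow(heights) == 0) {
    out <- derive_segment_columns(
      data.frame(segment = character(0), n = integer(0),
                 height_mean_mm = numeric(0), height_sd_mm = numeric(0)),
      factor, pa_ref, ffr0, pdpa0)
    class(out) <- c("segment_summary", "data.frame")
    return(out)
  }
  check_segments(heights$segment)
  present <- syntax_segments[syntax_segments %in% heights$segment]
  vals <- lapply(present, function(s) heights$height_mm[heights$segment == s])
  out <- derive_segment_columns(
    data.frame(segment = present,
               n = vapply(vals, length, integer(1)),
               height_mean_mm = vapply(vals, mean, numeric(1)),
               height_sd_mm = vapply(vals, function(x)
                 if (length(x) > 1) stats::sd(x) else NA_real_, numeric(1)),
               stringsAsFactors = FALSE),
    factor, pa_ref, ffr0, pdpa0)
  class(out) <- c("segment_summary", "data.frame")
  out
}

derive_segment_columns <- function(df, factor, pa_ref, ffr0, pdpa0) {
  if (!is.finite(pa_ref) || pa_ref <= 0) stop("`pa_ref` must be positive (mmHg)")
  f <- as_factor_mmhg_per_mm(factor)
  df$p_h_mean_mmhg <- f * df$height_mean_mm
  df$p_h_sd_mmhg <- f * df$height_sd_mm  # scaled-SD approximation
  # the tabulated index shift is defined on the displayed (3 dp) pressure,
  # so the delta column is consistent with the printed pressure column
  df$delta <- round_half_out(df$p_h_mean_mmhg, 3) / pa_ref
  df$ffr_at_ref <- ffr0 - df$delta
  df$pdpa_at_ref <- pdpa0 - df$delta
  df[, c("segment", "n", "height_mean_mm", "height_sd_mm",
         "p_h_mean_mmhg", "p_h_sd_mmhg", "ffr_at_ref", "pdpa_at_ref", "delta")]
}

#' Build the per-segment correction table
#'
#' One row per segment plus a zero-height reference row: for each segment's
#' mean height, the mean hydrostatic pressure, the value a measured FFR of
#' `ffr0` (Pd/Pa of `pdpa0`) corrects to at `pa_ref` mmHg aortic pressure,
#' and the index shift `delta = p_h / pa_ref`. Values are kept unrounded;
#' the conventional display is 3 decimals (see [write_correction_table()]).
#'
#' @param heights per-segment statistics: a data frame with columns
#'   `segment`, `height_mean_mm` and optionally `height_sd_mm`, `n` — e.g.
#'   [reference_heights()] or a [summarize_heights()] result.
#' @inheritParams summarize_heights
#' @return data frame of class `"correction_table"`; first row is the
#'   zero-height reference (`segment = "none"`).
#' @examples
#' tab <- build_correction_table(reference_heights())
#' round_half_out(tab$delta, 3)
#' @export
build_correction_table <- function(heights, pa_ref = 100, ffr0 = 0.80,
                                   pdpa0 = 0.92, factor = 0.077) {
  if (!is.data.frame(heights) ||
      !all(c("segment", "height_mean_mm") %in% names(heights)))
    stop("`heights` must have columns segment, height_mean_mm")
  check_segments(heights$segment)
  df <- data.frame(segment = as.character(heights$segment),
                   n = if ("n" %in% names(heights)) heights$n else NA_integer_,
                   height_mean_mm = heights$height_mean_mm,
                   height_sd_mm = if ("height_sd_mm" %in% names(heights))
                     heights$height_sd_mm else NA_real_,
                   stringsAsFactors = FALSE)
  zero <- data.frame(segment = "none", n = NA_integer_,
                     height_mean_mm = 0, height_sd_mm = 0,
                     stringsAsFactors = FALSE)
  out <- derive_segment_columns(rbind(zero, df), factor, pa_ref, ffr0, pdpa0)
  attr(out, "pa_ref") <- pa_ref
  attr(out, "ffr0") <- ffr0
  attr(out, "pdpa0") <- pdpa0
  attr(out, "factor") <- as_factor_mmhg_per_mm(factor)
  class(out) <- c("correction_table", "data.frame")
  out
}

#' Look up a segment's mean correction
#'
#' Returns the segment's mean hydrostatic pressure and index shift from a
#' correction table, for empirical segment-based correction when no
#' per-lesion height is available.
#'
#' @param segment a segment label (or `"none"` for the reference row).
#' @param table a `"correction_table"` from [build_correction_table()].
#' @return list with `p_h_mean_mmhg` and `delta`.
#' @export
segment_correction_lookup <- function(segment, table) {
  stopifnot(inherits(table, "correction_table"))
  i <- match(segment, table$segment)
  if (is.na(i))
    stop("segment not present in correction table: ", segment)
  list(p_h_mean_mmhg = table$p_h_mean_mmhg[i], delta = table$delta[i])
}

#' Write a correction table to CSV or JSON
#'
#' CSV header: `segment,height_mean_mm,height_sd_mm,p_h_mean_mmhg,`
#' `ffr_at_ref,pdpa_at_ref,delta`. Derived cells are rounded
#' half-away-from-zero to `digits` decimals for display.
#'
#' @param table a `"correction_table"`.
#' @param path output file path.
#' @param format `"csv"` or `"json"` (default from the file extension).
#' @param digits display decimals for the derived columns.
#' @return `path`, invisibly.
#' @export
write_correction_table <- function(table, path,
                                   format = c("auto", "csv", "json"),
                                   digits = 3) {
  stopifnot(inherits(table, "correction_table"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  out <- data.frame(segment = table$segment,
                    height_mean_mm = table$height_mean_mm,
                    height_sd_mm = table$height_sd_mm,
                    p_h_mean_mmhg = round_half_out(table$p_h_mean_mmhg, digits),
                    ffr_at_ref = round_half_out(table$ffr_at_ref, digits),
                    pdpa_at_ref = round_half_out(table$pdpa_at_ref, digits),
                    delta = round_half_out(table$delta, digits))
  if (format == "csv") {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}
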