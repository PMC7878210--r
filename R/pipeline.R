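# End-to-end orchestration: read lesion records, resolve heights (tabulated
# or computed from centerlines), apply the hydrostatic correction, classify,
# summarize per segment, and write artifacts. Plus the 2D-vs-3D
# height-method comparison.

LESION_COLUMNS <- c("lesion_id", "segment", "pa_mmhg", "pd_rest_mmhg",
                    "pd_hyper_mmhg", "height_mm")

#' Read a lesions CSV
#'
#' Expected header: `lesion_id,segment,pa_mmhg,pd_rest_mmhg,pd_hyper_mmhg,`
#' `height_mm` with an optional `centerline_path` column (paths relative to
#' the CSV's directory). `height_mm` may be blank for lesions that carry a
#' centerline. UTF-8, comma separator, `.` decimal point.
#'
#' @param path CSV file path.
#' @return data frame of lesion records; attribute `"base_dir"` holds the
#'   directory against which centerline paths resolve.
#' @export
read_lesions <- function(path) {
  if (!file.exists(path)) stop("lesions file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(LESION_COLUMNS, names(df))
  if (length(missing_cols))
    stop("lesions CSV ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0)
    stop("lesions CSV is empty: ", path)
  for (col in c("pa_mmhg", "pd_rest_mmhg", "pd_hyper_mmhg", "height_mm")) {
    v <- df[[col]]
    if (!is.numeric(v) && !all(is.na(v))) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v) & v != "")
      if (length(bad))
        stop("non-numeric value in column '", col, "', row ", bad[1],
             " of ", path)
      df[[col]] <- suppressWarnings(as.numeric(v))
    }
  }
  check_segments(df$segment)
  attr(df, "base_dir") <- dirname(path)
  df
}

#' Pipeline configuration
#'
#' @param factor conversion factor, mmHg per mm (number or
#'   [conversion_factor()]).
#' @param cut a [cutoffs()] object.
#' @param pa_reference reference aortic pressure for the segment table, mmHg.
#' @param ffr0,pdpa0 reference measured index values for the segment table.
#' @param height_method how to obtain each lesion's height: `"from_column"`
#'   (use `height_mm`, falling back to the centerline when blank) or one of
#'   `"direct3d"`, `"triangle"`, `"lateral2d"` (compute from the lesion's
#'   centerline).
#' @param outdir output directory for artifacts, or `NULL` to skip writing.
#' @param seed integer seed applied before any stochastic step (only the
#'   optional 2D noise draws); `NULL` leaves the RNG alone.
#' @param noise_sd_mm SD of 2D measurement noise for the `"lateral2d"`
#'   method and for [compare_height_methods()].
#' @param verbose emit an INFO log line with factor, cutoffs and seed.
#' @return An object of class `"run_config"`.
#' @export
pipeline_config <- function(factor = 0.077, cut = cutoffs(),
                            pa_reference = 100, ffr0 = 0.80, pdpa0 = 0.92,
                            height_method = c("from_column", "direct3d",
                                              "triangle", "lateral2d"),
                            outdir = NULL, seed = NULL, noise_sd_mm = 0,
                            verbose = TRUE) {
  structure(list(factor = as_factor_mmhg_per_mm(factor), cut = cut,
                 pa_reference = pa_reference, ffr0 = ffr0, pdpa0 = pdpa0,
                 height_method = match.arg(height_method),
                 outdir = outdir, seed = seed, noise_sd_mm = noise_sd_mm,
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Read a pipeline configuration file (JSON or YAML)
#'
#' Recognized keys mirror the [pipeline_config()] arguments, with
#' `factor_mmhg_per_mm`, `ffr_cutoff`, `pdpa_cutoff`, `pa_reference_mmhg`
#' accepted as the on-disk spellings.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return An object of class `"run_config"`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  pipeline_config(
    factor = cfg$factor_mmhg_per_mm %||% cfg$factor %||% 0.077,
    cut = cutoffs(ffr_cutoff = cfg$ffr_cutoff %||% 0.80,
                  pdpa_cutoff = cfg$pdpa_cutoff %||% 0.92),
    pa_reference = cfg$pa_reference_mmhg %||% cfg$pa_reference %||% 100,
    ffr0 = cfg$ffr0 %||% 0.80,
    pdpa0 = cfg$pdpa0 %||% 0.92,
    height_method = cfg$height_method %||% "from_column",
    outdir = cfg$outdir,
    seed = cfg$seed,
    noise_sd_mm = cfg$noise_sd_mm %||% 0,
    verbose = cfg$verbose %||% TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

height_from_centerline <- function(cl, method, noise_sd_mm = 0) {
  switch(method,
         direct3d = height_direct(cl)$height_mm,
         triangle = {
           d <- derive_triangle_inputs(cl, lateral_view())
           height_triangle(d$inputs, d$distal_is_anterior)$height_mm
         },
         lateral2d = height_2d_lateral(project_centerline(cl, lateral_view()),
                                       noise_sd_mm = noise_sd_mm)$height_mm,
         stop("unknown height method: ", method))
}

resolve_heights <- function(lesions, method, base_dir = ".",
                            centerlines = NULL, noise_sd_mm = 0) {
  height <- rep(NA_real_, nrow(lesions))
  skipped <- character(0)
  for (i in seq_len(nrow(lesions))) {
    cl <- NULL
    if (!is.null(centerlines))
      cl <- centerlines[[lesions$lesion_id[i]]]
    if (is.null(cl) && "centerline_path" %in% names(lesions) &&
        !is.na(lesions$centerline_path[i]) &&
        nzchar(lesions$centerline_path[i])) {
      p <- lesions$centerline_path[i]
      if (!file.exists(p)) p <- file.path(base_dir, lesions$centerline_path[i])
      if (file.exists(p)) cl <- read_centerline(p)
    }
    h_col <- lesions$height_mm[i]
    if (method == "from_column" && !is.na(h_col)) {
      height[i] <- h_col
    } else if (!is.null(cl)) {
      height[i] <- height_from_centerline(
        cl, if (method == "from_column") "direct3d" else method, noise_sd_mm)
    } else if (!is.na(h_col)) {
      height[i] <- h_col  # no centerline: fall back to the tabulated height
    } else {
      skipped <- c(skipped, as.character(lesions$lesion_id[i]))
    }
  }
  list(height_mm = height, skipped = skipped)
}

#' Apply the hydrostatic correction to a lesion table
#'
#' Computes the measured indices (`ffr = pd_hyper / pa`,
#' `pdpa = pd_rest / pa`), the per-lesion hydrostatic pressure
#' `p_h = factor * height`, and the corrected pressures and indices
#' (`pd - p_h`, `index - p_h / pa`). A lesion with measured FFR above its
#' measured resting Pd/Pa triggers a warning (physiologically unexpected),
#' not an error.
#'
#' @param lesions lesion data frame with columns `pa_mmhg`, `pd_rest_mmhg`,
#'   `pd_hyper_mmhg`, `height_mm` (see [read_lesions()]).
#' @param factor conversion factor, mmHg per mm.
#' @return the input data frame with columns `p_h_mmhg`, `ffr_measured`,
#'   `pdpa_measured`, `pd_hyper_corr_mmhg`, `pd_rest_corr_mmhg`,
#'   `ffr_corrected`, `pdpa_corrected` appended.
#' @export
correct_lesions <- function(lesions, factor = 0.077) {
  need <- c("pa_mmhg", "pd_rest_mmhg", "pd_hyper_mmhg", "height_mm")
  if (!is.data.frame(lesions) || !all(need %in% names(lesions)))
    stop("`lesions` must have columns ", paste(need, collapse = ", "))
  if (any(!is.finite(lesions$pa_mmhg)) || any(lesions$pa_mmhg <= 0))
    stop("`pa_mmhg` must be positive")
  f <- as_factor_mmhg_per_mm(factor)
  out <- lesions
  out$p_h_mmhg <- f * lesions$height_mm
  out$ffr_measured <- lesions$pd_hyper_mmhg / lesions$pa_mmhg
  out$pdpa_measured <- lesions$pd_rest_mmhg / lesions$pa_mmhg
  out$pd_hyper_corr_mmhg <- correct_distal_pressure(lesions$pd_hyper_mmhg,
                                                    out$p_h_mmhg)
  out$pd_rest_corr_mmhg <- correct_distal_pressure(lesions$pd_rest_mmhg,
                                                   out$p_h_mmhg)
  out$ffr_corrected <- out$pd_hyper_corr_mmhg / lesions$pa_mmhg
  out$pdpa_corrected <- out$pd_rest_corr_mmhg / lesions$pa_mmhg
  odd <- which(out$ffr_measured > out$pdpa_measured + 1e-12)
  if (length(odd))
    warning("measured FFR exceeds resting Pd/Pa for lesion(s): ",
            paste(utils::head(out$lesion_id[odd], 5), collapse = ", "))
  out
}

#' Run the full correction pipeline
#'
#' Reads (or accepts) a lesion table, resolves each lesion's height
#' (tabulated value or computed from its 3D centerline by the configured
#' method), applies the hydrostatic correction, builds the per-segment
#' correction table from the cohort's heights, and produces the
#' reclassification report. With `cfg$outdir` set, writes
#' `lesions_corrected.csv`, `segment_table.csv`, `report.json` and
#' `run_log.txt`. Deterministic given inputs and seed.
#'
#' @param lesions a lesions CSV path, or a data frame as from
#'   [read_lesions()] / [generate_cohort()].
#' @param cfg a [pipeline_config()].
#' @param centerlines optional named list of `"centerline"` objects keyed
#'   by `lesion_id` (takes precedence over `centerline_path`).
#' @return list of class `"pipeline_result"`: `lesions` (corrected table
#'   with reclassification flags), `report` (a `"cohort_report"`),
#'   `segment_table` (a `"correction_table"`), `skipped` (lesion ids with
#'   no usable height), `config`.
#' @export
run_pipeline <- function(lesions, cfg = pipeline_config(),
                         centerlines = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  base_dir <- "."
  if (is.character(lesions)) {
    lesions <- read_lesions(lesions)
    base_dir <- attr(lesions, "base_dir")
  }
  if (!is.data.frame(lesions) || nrow(lesions) == 0)
    stop("no lesion records supplied")
  check_segments(lesions$segment)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (cfg$verbose)
    message(sprintf(
      "INFO hydroffr: factor=%.3f mmHg/mm, cutoffs FFR<=%.2f Pd/Pa<=%.2f, method=%s, seed=%s",
      cfg$factor, cfg$cut$ffr_cutoff, cfg$cut$pdpa_cutoff, cfg$height_method,
      if (is.null(cfg$seed)) "none" else cfg$seed))
  res <- resolve_heights(lesions, cfg$height_method, base_dir, centerlines,
                         cfg$noise_sd_mm)
  lesions$height_mm <- res$height_mm
  if (length(res$skipped)) {
    warning("skipping lesion(s) with neither height nor centerline: ",
            paste(res$skipped, collapse = ", "))
    lesions <- lesions[!(lesions$lesion_id %in% res$skipped), , drop = FALSE]
  }
  if (nrow(lesions) == 0)
    stop("no lesion left with a usable height")
  corrected <- correct_lesions(lesions, cfg$factor)
  corrected$ffr_reclassified <- is_reclassified(
    corrected$ffr_measured, corrected$ffr_corrected, cfg$cut$ffr_cutoff)
  corrected$pdpa_reclassified <- is_reclassified(
    corrected$pdpa_measured, corrected$pdpa_corrected, cfg$cut$pdpa_cutoff)
  report <- reclassification_report(corrected, cfg$cut)
  seg_summary <- summarize_heights(
    corrected[, c("segment", "height_mm")], factor = cfg$factor,
    pa_ref = cfg$pa_reference, ffr0 = cfg$ffr0, pdpa0 = cfg$pdpa0)
  seg_table <- build_correction_table(
    seg_summary, pa_ref = cfg$pa_reference, ffr0 = cfg$ffr0,
    pdpa0 = cfg$pdpa0, factor = cfg$factor)
  out <- list(lesions = corrected, report = report,
              segment_table = seg_table, skipped = res$skipped, config = cfg)
  class(out) <- "pipeline_result"
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    num <- vapply(corrected, is.numeric, logical(1))
    disp <- corrected
    disp[num] <- lapply(disp[num], function(x) round_half_out(x, 6))
    utils::write.csv(disp, file.path(cfg$outdir, "lesions_corrected.csv"),
                     row.names = FALSE, quote = FALSE)
    write_correction_table(seg_table,
                           file.path(cfg$outdir, "segment_table.csv"))
    jsonlite::write_json(
      list(n_lesions = report$n_lesions,
           n_reclassified_ffr = report$n_reclassified_ffr,
           n_reclassified_pdpa = report$n_reclassified_pdpa,
           rate_ffr_pct = report$rate_ffr,
           rate_pdpa_pct = report$rate_pdpa,
           ffr_cutoff = cfg$cut$ffr_cutoff,
           pdpa_cutoff = cfg$cut$pdpa_cutoff,
           skipped = res$skipped),
      file.path(cfg$outdir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(sprintf(
      "factor_mmhg_per_mm=%.6f\nffr_cutoff=%.2f\npdpa_cutoff=%.2f\nheight_method=%s\nseed=%s\nn_lesions=%d\nn_skipped=%d",
      cfg$factor, cfg$cut$ffr_cutoff, cfg$cut$pdpa_cutoff,
      cfg$height_method, if (is.null(cfg$seed)) "none" else cfg$seed,
      report$n_lesions, length(res$skipped)),
      file.path(cfg$outdir, "run_log.txt"))
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result: %d lesions corrected, %d skipped>\n",
              nrow(x$lesions), length(x$skipped)))
  print(x$report)
  invisible(x)
}

#' Compare the triangle and 2D-lateral height methods
#'
#' For each centerline, extracts the height via the foreshortening-corrected
#' chord triangle and via the 2D lateral projection (with optional Gaussian
#' measurement noise on the 2D reading), and reports their Pearson
#' correlation. With zero noise both methods equal the direct coordinate
#' difference, so r = 1.
#'
#' @param centerlines list of `"centerline"` objects (>= 3).
#' @param noise_sd_mm SD of the 2D measurement noise, mm.
#' @return list of class `"correlation_result"`: `n`, `pearson_r`,
#'   `p_value`, `heights` (data frame with both methods).
#' @export
compare_height_methods <- function(centerlines, noise_sd_mm = 0) {
  if (length(centerlines) < 3)
    stop("need at least 3 centerlines to correlate height methods")
  h3 <- vapply(centerlines, function(cl) {
    d <- derive_triangle_inputs(cl, lateral_view())
    height_triangle(d$inputs, d$distal_is_anterior)$height_mm
  }, numeric(1))
  h2 <- vapply(centerlines, function(cl) {
    height_2d_lateral(project_centerline(cl, lateral_view()),
                      noise_sd_mm = noise_sd_mm)$height_mm
  }, numeric(1))
  if (stats::sd(h3) == 0 || stats::sd(h2) == 0)
    stop("height variance is zero; correlation undefined")
  ct <- stats::cor.test(h3, h2, method = "pearson")
  structure(list(n = length(centerlines),
                 pearson_r = unname(ct$estimate),
                 p_value = ct$p.value,
                 heights = data.frame(triangle_mm = h3, lateral2d_mm = h2)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<height-method correlation: n = %d, r = %.4f, p = %.3g>\n",
              x$n, x$pearson_r, x$p_value))
  invisible(x)
}
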