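# Synthetic cohort generator: per-segment heights with the reference
# distributions, smooth 3D centerline templates, and rest/hyperemia
# pressure recordings carrying the hydrostatic offset forward. Ground truth
# is retained so every pipeline stage can be validated by recovery.

# Per-segment centerline template parameters (mm). Drifts set the endpoint
# excursions in x (rightward negative / leftward positive) and z (cranial
# positive); amplitudes add smooth in-plane bowing so the arc exceeds the
# chord and oblique views foreshorten nontrivially. Signs follow the usual
# supine course: LAD anterior toward the apex, CX posterior-downward, RCA
# rightward then caudal into PL/PD.
CENTERLINE_TEMPLATES <- list(
  LAD_prox = list(x_drift = 15, z_drift = 25, x_amp = 6, z_amp = 8),
  LAD_mid  = list(x_drift = 30, z_drift = 10, x_amp = 10, z_amp = 12),
  LAD_dist = list(x_drift = 45, z_drift = -15, x_amp = 12, z_amp = 15),
  CX_prox  = list(x_drift = 25, z_drift = -10, x_amp = 8, z_amp = 6),
  CX_dist  = list(x_drift = 35, z_drift = -25, x_amp = 10, z_amp = 8),
  RCA_prox = list(x_drift = -15, z_drift = -10, x_amp = 5, z_amp = 4),
  RCA_mid  = list(x_drift = -25, z_drift = -25, x_amp = 8, z_amp = 6),
  RCA_dist = list(x_drift = -20, z_drift = -45, x_amp = 10, z_amp = 8),
  PL       = list(x_drift = -10, z_drift = -55, x_amp = 8, z_amp = 6),
  PD       = list(x_drift = 10, z_drift = -60, x_amp = 8, z_amp = 6))

#' Specification of a synthetic lesion cohort
#'
#' Defines the study conditions emulated by [generate_cohort()]: 41 lesions
#' distributed 3/18/6 over the proximal/mid/distal LAD, 1/5 over the
#' proximal/distal CX and 2/6 over the mid/distal RCA; true FFR drawn from
#' a truncated normal (mean 0.83, sd 0.04, bounds 0.70-0.90, the study's
#' inclusion window), true resting Pd/Pa from a truncated normal (mean
#' 0.90, sd 0.04) constrained above the lesion's FFR and at most 1; aortic
#' pressure normal (mean 100, sd 10) floored at 60 mmHg; per-segment
#' heights from [reference_heights()].
#'
#' @param n_lesions total number of lesions.
#' @param segment_mix named integer vector of lesions per segment; must sum
#'   to `n_lesions`.
#' @param ffr_mean,ffr_sd,ffr_bounds truncated-normal parameters of the
#'   true FFR.
#' @param pdpa_mean,pdpa_sd,pdpa_upper truncated-normal parameters of the
#'   true resting Pd/Pa (lower bound is the lesion's FFR).
#' @param pa_mean,pa_sd,pa_floor aortic-pressure distribution, mmHg.
#' @param noise_sd_mmhg SD of additive beat-mean pressure noise, mmHg.
#' @param factor hydrostatic conversion factor, mmHg per mm.
#' @param seed integer seed recorded in the manifest; `NULL` leaves the RNG
#'   state untouched.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_lesions = 41,
                        segment_mix = c(LAD_prox = 3, LAD_mid = 18,
                                        LAD_dist = 6, CX_prox = 1,
                                        CX_dist = 5, RCA_mid = 2,
                                        RCA_dist = 6),
                        ffr_mean = 0.83, ffr_sd = 0.04,
                        ffr_bounds = c(0.70, 0.90),
                        pdpa_mean = 0.90, pdpa_sd = 0.04, pdpa_upper = 1.0,
                        pa_mean = 100, pa_sd = 10, pa_floor = 60,
                        noise_sd_mmhg = 0, factor = 0.077, seed = NULL) {
  if (n_lesions < 0) stop("`n_lesions` must be >= 0")
  if (n_lesions == 0) segment_mix <- segment_mix[0]
  check_segments(names(segment_mix))
  if (sum(segment_mix) != n_lesions)
    stop("`segment_mix` must sum to `n_lesions` (",
         sum(segment_mix), " != ", n_lesions, ")")
  stopifnot(all(is.finite(c(ffr_mean, ffr_sd, ffr_bounds, pdpa_mean, pdpa_sd,
                            pdpa_upper, pa_mean, pa_sd, pa_floor,
                            noise_sd_mmhg))))
  structure(list(n_lesions = n_lesions, segment_mix = segment_mix,
                 ffr_mean = ffr_mean, ffr_sd = ffr_sd, ffr_bounds = ffr_bounds,
                 pdpa_mean = pdpa_mean, pdpa_sd = pdpa_sd,
                 pdpa_upper = pdpa_upper,
                 pa_mean = pa_mean, pa_sd = pa_sd, pa_floor = pa_floor,
                 noise_sd_mmhg = noise_sd_mmhg,
                 factor = as_factor_mmhg_per_mm(factor),
                 seed = seed),
            class = "cohort_spec")
}

# rejection-sampled truncated normal; errors out rather than looping forever
rtruncnorm1 <- function(mean, sd, lower = -Inf, upper = Inf,
                        max_tries = 10000) {
  if (sd == 0) {
    if (mean < lower || mean > upper)
      stop("generation error: degenerate truncated normal outside its bounds")
    return(mean)
  }
  for (i in seq_len(max_tries)) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
  stop("generation error: truncated-normal constraint unsatisfiable ",
       sprintf("(mean %.3f, sd %.3f, bounds [%.3f, %.3f])",
               mean, sd, lower, upper))
}

#' Draw a height for a segment
#'
#' Samples from the segment's normal height distribution
#' (mean/SD from `model`), using the current RNG state.
#'
#' @param segment a segment label.
#' @param model data frame with columns `segment`, `height_mean_mm`,
#'   `height_sd_mm`; default [reference_heights()].
#' @param n number of draws.
#' @return numeric vector of signed heights, mm.
#' @export
sample_height <- function(segment, model = reference_heights(), n = 1) {
  i <- match(segment, model$segment)
  if (is.na(i)) stop("unknown segment label: ", segment)
  stats::rnorm(n, model$height_mean_mm[i], model$height_sd_mm[i])
}

#' Generate a smooth synthetic centerline for a segment
#'
#' Builds a smooth parametric 3D path from the orifice whose
#' orifice-minus-sensor height equals `target_height_mm` exactly (the
#' vertical coordinate follows a smoothstep ramp), with per-segment lateral
#' (x) and craniocaudal (z) drifts and bows so that the path is curved
#' (arc > chord) and foreshortens nontrivially in oblique views. `jitter`
#' randomly rescales the x/z excursions (uniform +/- fraction), leaving the
#' height untouched.
#'
#' @param segment a segment label (template must exist).
#' @param target_height_mm desired signed height, mm.
#' @param n_points number of polyline points.
#' @param jitter fractional random variation of the template amplitudes
#'   (uses the current RNG state); 0 for a deterministic template.
#' @return a `"centerline"`.
#' @export
generate_centerline <- function(segment, target_height_mm, n_points = 50,
                                jitter = 0) {
  tmpl <- CENTERLINE_TEMPLATES[[segment]]
  if (is.null(tmpl)) stop("no centerline template for segment: ", segment)
  scl <- if (jitter > 0) 1 + stats::runif(4, -jitter, jitter) else rep(1, 4)
  t <- seq(0, 1, length.out = n_points)
  ramp <- 3 * t^2 - 2 * t^3  # smoothstep: 0 -> 1, zero end slopes
  bow <- sin(pi * t)
  x <- tmpl$x_drift * scl[1] * t + tmpl$x_amp * scl[2] * bow
  y <- -target_height_mm * ramp  # y_first - y_last = target by construction
  z <- tmpl$z_drift * scl[3] * t + tmpl$z_amp * scl[4] * bow
  centerline(cbind(x = x, y = y, z = z), label = segment)
}

#' Generate one synthetic lesion
#'
#' Forward model at beat-mean granularity: draws the lesion's true FFR,
#' true resting Pd/Pa, aortic pressure and height; computes the hydrostatic
#' pressure `p_h = factor * height`; and records the distal pressures the
#' wire would measure, `pd = (index_true + p_h/pa) * pa + eps` with
#' `eps ~ N(0, noise_sd_mmhg)`, for both phases. Ground truth is returned
#' alongside the measurements.
#'
#' @param spec a [cohort_spec()].
#' @param segment segment label for this lesion.
#' @param lesion_id identifier string.
#' @param model height model, see [sample_height()].
#' @return list with `lesion` (one-row data frame of measurable quantities),
#'   `truth` (one-row data frame of generating values) and `centerline`.
#' @export
generate_lesion <- function(spec, segment, lesion_id = "L001",
                            model = reference_heights()) {
  stopifnot(inherits(spec, "cohort_spec"))
  ffr_true <- rtruncnorm1(spec$ffr_mean, spec$ffr_sd,
                          spec$ffr_bounds[1], spec$ffr_bounds[2])
  pdpa_true <- rtruncnorm1(spec$pdpa_mean, spec$pdpa_sd,
                           lower = ffr_true, upper = spec$pdpa_upper)
  pa <- max(stats::rnorm(1, spec$pa_mean, spec$pa_sd), spec$pa_floor)
  height <- sample_height(segment, model)
  cl <- generate_centerline(segment, height, jitter = 0.2)
  p_h <- spec$factor * height
  eps <- stats::rnorm(2, 0, spec$noise_sd_mmhg)
  pd_hyper <- (ffr_true + p_h / pa) * pa + eps[1]
  pd_rest <- (pdpa_true + p_h / pa) * pa + eps[2]
  list(lesion = data.frame(lesion_id = lesion_id, segment = segment,
                           pa_mmhg = pa, pd_rest_mmhg = pd_rest,
                           pd_hyper_mmhg = pd_hyper, height_mm = height,
                           stringsAsFactors = FALSE),
       truth = data.frame(lesion_id = lesion_id, segment = segment,
                          ffr_true = ffr_true, pdpa_true = pdpa_true,
                          pa_mmhg = pa, height_mm = height, p_h_mmhg = p_h,
                          stringsAsFactors = FALSE),
       centerline = cl)
}

#' Generate a synthetic lesion cohort
#'
#' Draws `spec$n_lesions` lesions with the configured segment mix,
#' deterministic given `spec$seed`. Optionally writes the cohort to disk:
#' `lesions.csv` (with `centerline_path` column), `centerlines/<id>.csv`
#' and `truth.json` (ground-truth manifest including the seed).
#'
#' @param spec a [cohort_spec()].
#' @param outdir output directory, or `NULL` (default) to skip writing.
#' @param model height model, see [sample_height()].
#' @return list with `lesions` (data frame), `truth` (data frame),
#'   `centerlines` (named list of `"centerline"`), `spec`.
#' @examples
#' coh <- generate_cohort(cohort_spec(seed = 7))
#' table(coh$lesions$segment)
#' @export
generate_cohort <- function(spec = cohort_spec(), outdir = NULL,
                            model = reference_heights()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  segments <- rep(names(spec$segment_mix), times = spec$segment_mix)
  ids <- sprintf("L%03d", seq_along(segments))
  lesions <- list(); truth <- list(); centerlines <- list()
  for (i in seq_along(segments)) {
    g <- generate_lesion(spec, segments[i], ids[i], model)
    lesions[[i]] <- g$lesion
    truth[[i]] <- g$truth
    centerlines[[ids[i]]] <- g$centerline
  }
  empty_lesions <- data.frame(lesion_id = character(0), segment = character(0),
                              pa_mmhg = numeric(0), pd_rest_mmhg = numeric(0),
                              pd_hyper_mmhg = numeric(0), height_mm = numeric(0),
                              stringsAsFactors = FALSE)
  lesions <- if (length(lesions)) do.call(rbind, lesions) else empty_lesions
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(lesion_id = character(0))
  out <- list(lesions = lesions, truth = truth, centerlines = centerlines,
              spec = spec)
  if (!is.null(outdir)) {
    dir.create(file.path(outdir, "centerlines"), recursive = TRUE,
               showWarnings = FALSE)
    paths <- character(nrow(lesions))
    for (i in seq_along(centerlines)) {
      paths[i] <- file.path("centerlines", paste0(names(centerlines)[i], ".csv"))
      write_centerline(centerlines[[i]], file.path(outdir, paths[i]))
    }
    lesions_out <- lesions
    lesions_out$centerline_path <- paths
    utils::write.csv(lesions_out, file.path(outdir, "lesions.csv"),
                     row.names = FALSE, quote = FALSE)
    manifest <- list(seed = spec$seed, n_lesions = spec$n_lesions,
                     segment_mix = as.list(spec$segment_mix),
                     noise_sd_mmhg = spec$noise_sd_mmhg,
                     factor_mmhg_per_mm = spec$factor,
                     truth = truth)
    jsonlite::write_json(manifest, file.path(outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$outdir <- outdir
  }
  out
}
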