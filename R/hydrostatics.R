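# Hydrostatic pressure from height, corrected distal pressure, corrected
# indices, and the delta between measured and corrected index.
#
# Convention (the one that reproduces every per-segment correction-table
# cell): p_h = factor * (y_orifice - y_sensor) and pd_corrected = pd - p_h.
# A sensor above the orifice (negative height) gives negative p_h, so the
# corrected distal pressure and index are HIGHER than measured.

#' Round half away from zero
#'
#' Display rounding used throughout the package (0.0005 rounds to 0.001,
#' -0.0005 to -0.001), unlike [round()]'s round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_out <- function(x, digits = 3) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Blood-column to mercury-column conversion factor
#'
#' How many mmHg one mm of blood column exerts: the ratio of the specific
#' gravity of blood (default 1.05 g/cm^3) to that of mercury (13.55 g/cm^3),
#' rounded half-away-from-zero to `decimals` places. The defaults give the
#' conventional 0.077 mmHg per mm. The blood density is hematocrit
#' dependent; pass `rho_blood` to explore that sensitivity.
#'
#' @param rho_blood blood density, g/cm^3 (> 0).
#' @param rho_mercury mercury density, g/cm^3 (> 0).
#' @param decimals decimal places for the rounded factor; use >= 6 for the
#'   effectively unrounded value.
#' @return An object of class `"conversion_factor"`: list with
#'   `mmhg_per_mm`, `provenance`, `rho_blood`, `rho_mercury`, `decimals`.
#' @examples
#' conversion_factor()$mmhg_per_mm           # 0.077
#' conversion_factor(decimals = 6)$mmhg_per_mm
#' @export
conversion_factor <- function(rho_blood = 1.05, rho_mercury = 13.55,
                              decimals = 3) {
  if (!is.finite(rho_blood) || rho_blood <= 0 ||
      !is.finite(rho_mercury) || rho_mercury <= 0)
    stop("densities must be positive (g/cm^3)")
  f <- round_half_out(rho_blood / rho_mercury, decimals)
  if (f <= 0 || f > 1)
    stop("conversion factor out of range (0, 1]: check densities")
  prov <- if (identical(c(rho_blood, rho_mercury, decimals), c(1.05, 13.55, 3)))
    "paper_default" else "computed"
  structure(list(mmhg_per_mm = f, provenance = prov,
                 rho_blood = rho_blood, rho_mercury = rho_mercury,
                 decimals = decimals),
            class = "conversion_factor")
}

#' @export
print.conversion_factor <- function(x, ...) {
  cat(sprintf("<conversion factor: %g mmHg per mm blood column (%s)>\n",
              x$mmhg_per_mm, x$provenance))
  invisible(x)
}

as_factor_mmhg_per_mm <- function(f) {
  v <- if (inherits(f, "conversion_factor")) f$mmhg_per_mm else as.numeric(f)
  if (!all(is.finite(v)) || any(v <= 0) || any(v > 1))
    stop("conversion factor must be in (0, 1] mmHg per mm")
  v
}

#' Hydrostatic pressure of a blood column
#'
#' `p_h = factor * height`, sign preserving: a sensor above the orifice
#' (negative height) gives a negative hydrostatic pressure.
#'
#' @param height signed orifice-minus-sensor height(s), mm; a numeric
#'   vector or a `"height_measurement"`.
#' @param factor mmHg per mm: a number or a [conversion_factor()] object;
#'   default 0.077.
#' @return hydrostatic pressure(s), mmHg, signed.
#' @examples
#' hydrostatic_pressure(-56.80)  # distal LAD: about -4.374 mmHg
#' @export
hydrostatic_pressure <- function(height, factor = 0.077) {
  as_factor_mmhg_per_mm(factor) * as_height_mm(height)
}

#' Correct a distal pressure for hydrostatic offset
#'
#' `pd_corrected = pd - p_h`. Subtracting the (signed) hydrostatic pressure
#' removes the blood-column artifact: a sensor above the orifice reads low,
#' and its corrected pressure is higher than measured.
#'
#' @param pd measured distal pressure(s), mmHg.
#' @param p_h signed hydrostatic pressure(s), mmHg.
#' @return corrected distal pressure(s), mmHg.
#' @export
correct_distal_pressure <- function(pd, p_h) {
  pd - p_h
}

#' Correct a pressure-derived index (FFR or resting Pd/Pa)
#'
#' Since the index is Pd/Pa, subtracting `p_h` from Pd shifts the index by
#' `-p_h / Pa`: `index_corrected = index_measured - p_h / pa`. The shift
#' (delta, reported as measured minus corrected, = `p_h / pa`) is inversely
#' proportional to the aortic pressure.
#'
#' @param index_measured measured index (dimensionless ratio), vectorized.
#' @param pa aortic pressure(s), mmHg, > 0.
#' @param p_h signed hydrostatic pressure(s), mmHg.
#' @return data frame with columns `p_h`, `index_measured`,
#'   `index_corrected`, `delta` (= measured - corrected = `p_h / pa`).
#' @examples
#' correct_index(0.80, 100, hydrostatic_pressure(-56.80))  # distal LAD
#' @export
correct_index <- function(index_measured, pa, p_h) {
  if (!all(is.finite(pa)) || any(pa <= 0))
    stop("`pa` must be positive (mmHg)")
  delta <- p_h / pa
  out <- data.frame(p_h = p_h,
                    index_measured = index_measured,
                    index_corrected = index_measured - delta,
                    delta = delta + 0 * index_measured)
  out
}

#' Index shift caused by a hydrostatic pressure
#'
#' `delta = p_h / pa`, the amount by which the measured index exceeds the
#' corrected one. For fixed height, `delta * pa` is constant: the effect is
#' inversely proportional to the actual aortic pressure.
#'
#' @inheritParams correct_index
#' @return signed index shift(s).
#' @export
delta_index <- function(p_h, pa) {
  if (!all(is.finite(pa)) || any(pa <= 0))
    stop("`pa` must be positive (mmHg)")
  p_h / pa
}

#' Forward model: index measured in the presence of a hydrostatic offset
#'
#' The exact inverse of [correct_index()]:
#' `index_measured = index_true + p_h / pa`. With a sensor above the orifice
#' (p_h < 0, as in the mid/distal LAD) the measured FFR reads LOW; with a
#' sensor below (distal CX) it reads high.
#'
#' @param index_true true (artifact-free) index, vectorized.
#' @inheritParams correct_index
#' @return measured index value(s).
#' @export
simulate_measured <- function(index_true, pa, p_h) {
  if (!all(is.finite(pa)) || any(pa <= 0))
    stop("`pa` must be positive (mmHg)")
  index_true + p_h / pa
}
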