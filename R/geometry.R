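# 3D centerline geometry: arc/chord metrics, angiographic projection,
# foreshortening, and the orifice-to-sensor height extraction procedures.
#
# Patient coordinate frame (supine):
#   x: patient right (-) -> left (+)
#   y: posterior (-) -> anterior (+)   -- the vertical axis in supine position
#   z: caudal (-) -> cranial (+)
# Heights are signed as d = y_orifice - y_sensor, so a sensor lying anterior
# to (above) the orifice gives a negative height, as in the LAD.

VALID_HEIGHT_METHODS <- c("direct3d", "triangle", "lateral2d")

#' Construct a 3D coronary centerline
#'
#' A centerline is an ordered polyline in patient coordinates (mm), running
#' from the coronary orifice (the catheter tip, where pressures are
#' equalized) to the pressure-wire sensor position. The frame is fixed as
#' x: right to left, y: posterior to anterior (the vertical axis with the
#' patient supine), z: caudal to cranial.
#'
#' @param points numeric matrix or data frame with three columns (`x`, `y`,
#'   `z`, in mm) and at least two rows; row 1 is the orifice, the last row
#'   the sensor position. An unnamed three-column matrix is accepted.
#' @param label optional free-text label.
#' @return An object of class `"centerline"`: a list with elements `points`
#'   (n x 3 numeric matrix) and `label`.
#' @examples
#' cl <- centerline(rbind(c(0, 0, 0), c(10, 20, 5), c(15, 40, 12)))
#' arc_length(cl)
#' chord_length(cl)
#' height_direct(cl)
#' @export
centerline <- function(points, label = "") {
  if (is.data.frame(points)) {
    cols <- if (all(c("x", "y", "z") %in% names(points))) c("x", "y", "z") else seq_len(3)
    points <- as.matrix(points[, cols])
  }
  if (!is.matrix(points) || ncol(points) != 3 || !is.numeric(points))
    stop("`points` must be a numeric matrix with 3 columns (x, y, z in mm)")
  if (nrow(points) < 2)
    stop("a centerline needs at least 2 points (orifice and sensor)")
  if (!all(is.finite(points)))
    stop("centerline coordinates must be finite")
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y", "z")
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] - points[-nrow(points), , drop = FALSE])^2))
  if (any(seg == 0))
    stop("consecutive centerline points must not coincide")
  structure(list(points = points, label = as.character(label)[1]),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  n <- nrow(x$points)
  cat(sprintf("<centerline%s: %d points, arc %.2f mm, chord %.2f mm, height %.2f mm>\n",
              if (nzchar(x$label)) paste0(" ", x$label) else "",
              n, arc_length(x), chord_length(x), height_direct(x)$height_mm))
  invisible(x)
}

as_centerline <- function(x) {
  if (inherits(x, "centerline")) x else centerline(x)
}

#' Read / write centerline files
#'
#' The on-disk format is a CSV with header
#' `point_index,x_mm,y_mm,z_mm` (0-based indices, row 0 = orifice), or a
#' JSON array of `[x, y, z]` triples.
#'
#' @param path file path (`.csv` or `.json`).
#' @param label label for the returned centerline (defaults to the file name).
#' @return `read_centerline()` returns a `"centerline"`;
#'   `write_centerline()` returns `path` invisibly.
#' @export
read_centerline <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("centerline file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    m <- jsonlite::fromJSON(path)
    if (is.list(m)) m <- do.call(rbind, m)
    return(centerline(matrix(as.numeric(m), ncol = 3), label = label))
  }
  df <- utils::read.csv(path)
  need <- c("point_index", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop("centerline CSV must have header: ", paste(need, collapse = ","))
  df <- df[order(df$point_index), , drop = FALSE]
  centerline(cbind(x = df$x_mm, y = df$y_mm, z = df$z_mm), label = label)
}

#' @rdname read_centerline
#' @param cl a `"centerline"`.
#' @export
write_centerline <- function(cl, path) {
  cl <- as_centerline(cl)
  df <- data.frame(point_index = seq_len(nrow(cl$points)) - 1L,
                   x_mm = cl$points[, "x"],
                   y_mm = cl$points[, "y"],
                   z_mm = cl$points[, "z"])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Arc length, chord length and arc-chord ratio of a centerline
#'
#' `arc_length()` is the summed Euclidean length of the polyline (the
#' analyzed segment length), `chord_length()` the straight-line distance
#' between orifice and sensor, and `arc_chord_ratio()` their ratio, a
#' standard tortuosity measure (1 for a straight vessel).
#'
#' @param cl a `"centerline"` (or coercible matrix).
#' @return length in mm, or a dimensionless ratio >= 1.
#' @export
arc_length <- function(cl) {
  p <- as_centerline(cl)$points
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' @rdname arc_length
#' @export
chord_length <- function(cl) {
  p <- as_centerline(cl)$points
  sqrt(sum((p[nrow(p), ] - p[1, ])^2))
}

#' @rdname arc_length
#' @export
arc_chord_ratio <- function(cl) {
  ch <- chord_length(cl)
  if (ch < 1e-6)
    stop("degenerate geometry: orifice and sensor coincide (chord < 1e-6 mm)")
  arc_length(cl) / ch
}

#' Angiographic view angles
#'
#' A C-arm view is parameterized by the rotation angle (LAO positive, RAO
#' negative) and the angulation (cranial positive, caudal negative), both in
#' degrees. The lateral view is (LAO 90, 0): the X-ray beam runs along the
#' patient's right-left axis, so anterior-posterior heights project without
#' foreshortening.
#'
#' @param lao_deg rotation in degrees, in (-180, 180].
#' @param cran_deg angulation in degrees, in (-180, 180].
#' @return An object of class `"view_angles"`.
#' @export
view_angles <- function(lao_deg, cran_deg) {
  for (a in c(lao_deg, cran_deg))
    if (!is.finite(a) || a <= -180 || a > 180)
      stop("view angles must be finite and in (-180, 180] degrees")
  structure(list(lao_deg = lao_deg, cran_deg = cran_deg), class = "view_angles")
}

#' @rdname view_angles
#' @export
lateral_view <- function() view_angles(90, 0)

#' X-ray beam direction for a view
#'
#' Unit vector of the beam in patient coordinates:
#' `u = (sin(lao) cos(cran), cos(lao) cos(cran), sin(cran))`, so that
#' (0, 0) is the standard posterior-anterior beam (along +y) and (90, 0)
#' the lateral beam along the patient's x axis.
#'
#' @param view a `"view_angles"`.
#' @return numeric length-3 unit vector.
#' @export
beam_direction <- function(view) {
  stopifnot(inherits(view, "view_angles"))
  lao <- view$lao_deg * pi / 180
  cran <- view$cran_deg * pi / 180
  c(sin(lao) * cos(cran), cos(lao) * cos(cran), sin(cran))
}

# screen basis orthogonal to the beam; for the lateral view the horizontal
# screen axis is exactly +y (anterior) and the vertical axis +z (cranial)
screen_basis <- function(view) {
  u <- beam_direction(view)
  w <- c(0, 0, 1) - sum(c(0, 0, 1) * u) * u
  if (sqrt(sum(w^2)) < 1e-9)  # beam along z: fall back to anterior-up screen
    w <- c(0, 1, 0) - sum(c(0, 1, 0) * u) * u
  w <- w / sqrt(sum(w^2))
  h <- c(w[2] * u[3] - w[3] * u[2],
         w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  list(u = u, h = h, w = w)
}

#' Orthographic projection of a centerline into a view
#'
#' Projects each point onto the screen plane orthogonal to the beam. Screen
#' coordinates are in mm; for the lateral view (LAO 90, 0) the horizontal
#' coordinate equals the patient y coordinate exactly (heights appear
#' without foreshortening, measured horizontally with the sternum to the
#' screen left) and the vertical coordinate equals z.
#'
#' @param cl a `"centerline"`.
#' @param view a `"view_angles"`; defaults to the lateral view.
#' @return An object of class `"projected_path"`: list with `points`
#'   (n x 2 matrix, columns `h`, `v`), `view`, `label`.
#' @export
project_centerline <- function(cl, view = lateral_view()) {
  cl <- as_centerline(cl)
  b <- screen_basis(view)
  pts <- cbind(h = as.numeric(cl$points %*% b$h),
               v = as.numeric(cl$points %*% b$w))
  structure(list(points = pts, view = view, label = cl$label),
            class = "projected_path")
}

#' @export
print.projected_path <- function(x, ...) {
  cat(sprintf("<projected_path: %d points, view (LAO %g, cran %g)>\n",
              nrow(x$points), x$view$lao_deg, x$view$cran_deg))
  invisible(x)
}

#' Foreshortening of a centerline chord in a view
#'
#' Apparent shortening of the orifice-sensor chord under projection:
#' `F = 1 - projected chord length / true chord length`, in \[0, 1\].
#' F is 0 when the chord lies in the screen plane and 1 when it is parallel
#' to the beam.
#'
#' @inheritParams project_centerline
#' @return foreshortening fraction in \[0, 1\].
#' @export
foreshortening <- function(cl, view = lateral_view()) {
  cl <- as_centerline(cl)
  p <- cl$points
  d <- p[nrow(p), ] - p[1, ]
  len <- sqrt(sum(d^2))
  if (len < 1e-6)
    stop("degenerate geometry: orifice and sensor coincide (chord < 1e-6 mm)")
  u <- beam_direction(view)
  proj <- sqrt(max(sum(d^2) - sum(d * u)^2, 0))
  min(max(1 - proj / len, 0), 1)
}

#' Height measurement record
#'
#' A signed orifice-minus-sensor height difference in mm, tagged with the
#' extraction method. The sign convention is `d = y_orifice - y_sensor`:
#' negative when the sensor lies anterior to (in supine position, above)
#' the orifice, as in the LAD; positive when it lies posterior/below, as in
#' the CX.
#'
#' @param height_mm signed height difference in mm.
#' @param method one of `"direct3d"`, `"triangle"`, `"lateral2d"`.
#' @return An object of class `"height_measurement"`.
#' @export
height_measurement <- function(height_mm, method) {
  if (!is.numeric(height_mm) || length(height_mm) != 1 || !is.finite(height_mm))
    stop("`height_mm` must be a finite number")
  method <- match.arg(method, VALID_HEIGHT_METHODS)
  structure(list(height_mm = as.numeric(height_mm), method = method),
            class = "height_measurement")
}

#' @export
print.height_measurement <- function(x, ...) {
  cat(sprintf("<height %+.3f mm [%s]>\n", x$height_mm, x$method))
  invisible(x)
}

as_height_mm <- function(d) {
  if (inherits(d, "height_measurement")) d$height_mm else as.numeric(d)
}

#' Height difference by direct coordinate difference
#'
#' The ground-truth height: the difference between the vertical (y)
#' coordinates of the orifice and the sensor, `y_first - y_last`.
#'
#' @param cl a `"centerline"`.
#' @return a `"height_measurement"` with method `"direct3d"`.
#' @export
height_direct <- function(cl) {
  p <- as_centerline(cl)$points
  height_measurement(p[1, "y"] - p[nrow(p), "y"], "direct3d")
}

#' Triangle-method inputs
#'
#' The quantities read off a projected view for the chord-triangle height
#' construction: the in-view chord length, the foreshortening fraction of
#' the view, and the angle `alpha` at the distal vertex between the
#' foreshortening-corrected chord and the vertical (height) axis.
#'
#' @param chord_view_mm chord length measured in the view, mm, > 0.
#' @param foreshortening fraction in \[0, 1).
#' @param alpha_deg angle in degrees, in \[0, 180\].
#' @return An object of class `"triangle_inputs"`.
#' @export
triangle_inputs <- function(chord_view_mm, foreshortening, alpha_deg) {
  if (!is.finite(chord_view_mm) || chord_view_mm <= 0)
    stop("`chord_view_mm` must be a positive length in mm")
  if (!is.finite(foreshortening) || foreshortening < 0 || foreshortening > 1)
    stop("`foreshortening` must be a fraction in [0, 1)")
  if (foreshortening >= 1)
    stop("degenerate geometry: chord fully foreshortened (F = 1)")
  if (!is.finite(alpha_deg) || alpha_deg < 0 || alpha_deg > 180)
    stop("`alpha_deg` must be in [0, 180] degrees")
  structure(list(chord_view_mm = chord_view_mm,
                 foreshortening = foreshortening,
                 alpha_deg = alpha_deg),
            class = "triangle_inputs")
}

#' Derive triangle-method inputs from a centerline and view
#'
#' Measures the projected chord length and foreshortening in the given view
#' and the 3D angle `alpha` between the orifice-sensor chord and the
#' vertical axis oriented toward the distal side (so `alpha` is in
#' \[0, 90\] and the `distal_is_anterior` flag carries the sign). With these
#' inputs [height_triangle()] reproduces [height_direct()] exactly.
#'
#' @inheritParams project_centerline
#' @return list with elements `inputs` (a `"triangle_inputs"`) and
#'   `distal_is_anterior` (logical).
#' @export
derive_triangle_inputs <- function(cl, view = lateral_view()) {
  cl <- as_centerline(cl)
  p <- cl$points
  d <- p[nrow(p), ] - p[1, ]
  len <- sqrt(sum(d^2))
  if (len < 1e-6)
    stop("degenerate geometry: orifice and sensor coincide (chord < 1e-6 mm)")
  f <- foreshortening(cl, view)
  if (f >= 1 - 1e-12)
    stop("degenerate geometry: chord is parallel to the beam in this view")
  distal_is_anterior <- d["y"] > 0
  axis_y <- if (distal_is_anterior) 1 else -1
  cosa <- min(max(axis_y * d["y"] / len, -1), 1)
  list(inputs = triangle_inputs(chord_view_mm = len * (1 - f),
                                foreshortening = f,
                                alpha_deg = acos(cosa) * 180 / pi),
       distal_is_anterior = unname(distal_is_anterior))
}

#' Height difference by the chord-triangle construction
#'
#' The in-view chord is first corrected for foreshortening,
#' `c = chord_view / (1 - F)`, then used as the hypotenuse of a right
#' triangle whose vertical leg is the height: `b = c * cos(alpha)`. The sign
#' is set by the distal sensor's side: height is `-b` when the distal end is
#' anterior (sensor above the orifice), `+b` otherwise.
#'
#' @param t a `"triangle_inputs"`.
#' @param distal_is_anterior logical; is the sensor anterior to the orifice?
#' @return a `"height_measurement"` with method `"triangle"`.
#' @export
height_triangle <- function(t, distal_is_anterior) {
  stopifnot(inherits(t, "triangle_inputs"), is.logical(distal_is_anterior))
  c_true <- t$chord_view_mm / (1 - t$foreshortening)
  b <- c_true * cos(t$alpha_deg * pi / 180)
  height_measurement(if (distal_is_anterior) -b else b, "triangle")
}

#' Height difference from a 2D lateral projection
#'
#' In the lateral view heights project without foreshortening and, with the
#' patient supine and the sternum to the screen left, are measured
#' horizontally: height = horizontal(first) - horizontal(last). Optional
#' Gaussian noise emulates manual 2D quantitation error.
#'
#' @param p a `"projected_path"` produced in the lateral view.
#' @param noise_sd_mm standard deviation (mm) of additive measurement noise;
#'   default 0 (exact).
#' @return a `"height_measurement"` with method `"lateral2d"`.
#' @export
height_2d_lateral <- function(p, noise_sd_mm = 0) {
  stopifnot(inherits(p, "projected_path"))
  if (abs(p$view$lao_deg - 90) > 1e-9 || abs(p$view$cran_deg) > 1e-9)
    stop("height_2d_lateral() requires a lateral (LAO 90, 0) projection")
  h <- p$points[1, "h"] - p$points[nrow(p$points), "h"]
  if (noise_sd_mm > 0) h <- h + stats::rnorm(1, 0, noise_sd_mm)
  height_measurement(unname(h), "lateral2d")
}
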