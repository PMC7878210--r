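# Shared fixtures, built in code at test time.

# planar quarter circle of radius r in the y-z plane, sampled at `step` deg
quarter_circle <- function(r = 50, step = 1) {
  th <- seq(0, 90, by = step) * pi / 180
  centerline(cbind(x = 0, y = r * sin(th), z = r - r * cos(th)))
}

semi_circle <- function(r = 50, step = 1) {
  th <- seq(0, 180, by = step) * pi / 180
  centerline(cbind(x = 0, y = r * sin(th), z = r - r * cos(th)))
}

# random smooth centerline with a nondegenerate, not-fully-foreshortened
# chord in the lateral view; uses the current RNG state
random_centerline <- function(n_points = 25) {
  repeat {
    drift <- stats::runif(3, -60, 60)
    amp <- stats::runif(3, 0, 15)
    phase <- stats::runif(3, 0, 2 * pi)
    t <- seq(0, 1, length.out = n_points)
    pts <- vapply(1:3, function(k) {
      drift[k] * t + amp[k] * (sin(2 * pi * t + phase[k]) - sin(phase[k]))
    }, numeric(n_points))
    cl <- try(centerline(pts), silent = TRUE)
    if (inherits(cl, "try-error")) next
    if (chord_length(cl) < 1 ||
        sqrt(sum((cl$points[nrow(cl$points), c("y", "z")] -
                  cl$points[1, c("y", "z")])^2)) < 0.5) next
    return(cl)
  }
}

# printed per-segment reference cells (height mean/sd; derived cells at the
# reference conditions Pa 100 mmHg, measured FFR 0.80, measured Pd/Pa 0.92)
reference_table_cells <- function() {
  data.frame(
    segment = c("none", syntax_segments),
    p_h = c(0, -1.054, -3.552, -4.374, 1.153, 2.159,
            -0.492, -0.528, 1.382, 2.283, 1.350),
    ffr = c(0.8, 0.811, 0.836, 0.844, 0.788, 0.778,
            0.805, 0.805, 0.786, 0.777, 0.787),
    pdpa = c(0.92, 0.931, 0.956, 0.964, 0.908, 0.898,
             0.925, 0.925, 0.906, 0.897, 0.907),
    delta = c(0, -0.011, -0.036, -0.044, 0.012, 0.022,
              -0.005, -0.005, 0.014, 0.023, 0.014),
    stringsAsFactors = FALSE)
}
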