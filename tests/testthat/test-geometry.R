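# Centerline metrics, projection, foreshortening and height extraction.

test_that("arc length, chord length and arc-chord ratio match closed forms", {
  straight <- centerline(rbind(c(0, 0, 0), c(0, 0, 30), c(0, 0, 60)))
  expect_equal(arc_length(straight), 60)
  expect_equal(chord_length(straight), 60)
  expect_equal(arc_chord_ratio(straight), 1.0)

  pythag <- centerline(rbind(c(0, 0, 0), c(30, 40, 0)))
  expect_equal(arc_length(pythag), 50)
  expect_equal(chord_length(pythag), 50)

  qc <- quarter_circle(r = 50, step = 1)
  expect_equal(arc_length(qc), 50 * pi / 2, tolerance = 0.01 / (50 * pi / 2))
  expect_equal(chord_length(qc), 50 * sqrt(2), tolerance = 1e-9)
  expect_equal(arc_chord_ratio(qc), (50 * pi / 2) / (50 * sqrt(2)),
               tolerance = 1e-4)
  expect_equal(arc_chord_ratio(semi_circle()), pi / 2, tolerance = 1e-4)
})

test_that("degenerate and invalid centerlines are rejected", {
  expect_error(centerline(matrix(c(0, 0, 0), 1, 3)), "at least 2")
  expect_error(centerline(rbind(c(0, 0, 0), c(0, 0, 0))), "coincide")
  expect_error(centerline(rbind(c(0, 0, 0), c(NA, 1, 1))), "finite")
  loop <- centerline(rbind(c(0, 0, 0), c(10, 10, 0), c(0, 0, 1e-9)))
  expect_error(arc_chord_ratio(loop), "degenerate")
  expect_error(foreshortening(loop), "degenerate")
})

test_that("lateral projection preserves the y and z axes exactly", {
  expect_equal(beam_direction(lateral_view()), c(1, 0, 0), tolerance = 1e-12)
  expect_equal(beam_direction(view_angles(0, 0)), c(0, 1, 0),
               tolerance = 1e-12)
  set.seed(11)
  for (i in 1:20) {
    cl <- random_centerline()
    pp <- project_centerline(cl, lateral_view())
    expect_equal(pp$points[, "h"], unname(cl$points[, "y"]), tolerance = 1e-12)
    expect_equal(pp$points[, "v"], unname(cl$points[, "z"]), tolerance = 1e-12)
  }
  along_x <- centerline(rbind(c(0, 0, 0), c(50, 0, 0)))
  pp <- project_centerline(along_x, lateral_view())
  expect_equal(sqrt(sum((pp$points[2, ] - pp$points[1, ])^2)), 0,
               tolerance = 1e-12)
})

test_that("foreshortening is the fractional chord shortening of the view", {
  cl <- centerline(rbind(c(0, 0, 0), c(30, 40, 0)))
  expect_equal(foreshortening(cl, lateral_view()), 0.2, tolerance = 1e-12)
  pp <- project_centerline(cl, lateral_view())
  expect_equal(sqrt(sum((pp$points[2, ] - pp$points[1, ])^2)), 40,
               tolerance = 1e-12)

  in_plane <- centerline(rbind(c(0, 0, 0), c(0, 30, 40)))
  expect_equal(foreshortening(in_plane, lateral_view()), 0, tolerance = 1e-12)
  along_beam <- centerline(rbind(c(0, 0, 0), c(50, 0, 0)))
  expect_equal(foreshortening(along_beam, lateral_view()), 1, tolerance = 1e-12)
})

test_that("foreshortening stays in [0,1] and grows as the beam approaches the chord", {
  # chord at 45 degrees between x and y in the x-y plane
  cl <- centerline(rbind(c(0, 0, 0), c(30, 30, 0)))
  laos <- c(90, 75, 60, 45)  # beam rotates from x-axis toward the chord
  f <- vapply(laos, function(a) foreshortening(cl, view_angles(a, 0)),
              numeric(1))
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(diff(f) > 0))
  set.seed(12)
  for (i in 1:50) {
    cl <- random_centerline()
    v <- view_angles(stats::runif(1, -179, 180), stats::runif(1, -89, 89))
    f1 <- foreshortening(cl, v)
    expect_true(f1 >= 0 && f1 <= 1)
  }
})

test_that("direct height is the signed orifice-minus-sensor y difference", {
  cl <- centerline(rbind(c(0, 0, 0), c(10, 56.8, 20)))
  h <- height_direct(cl)
  expect_equal(h$height_mm, -56.8)
  expect_identical(h$method, "direct3d")
  expect_equal(height_direct(centerline(rbind(c(0, 0, 0), c(5, 0, 9))))$height_mm, 0)
  expect_equal(height_direct(centerline(rbind(c(0, 0, 0),
                                              c(0, -28.04, -40))))$height_mm,
               28.04)
})

test_that("triangle construction reproduces stated cases and rejects bad input", {
  # oracle: chord (30,40,0) seen laterally -> chord_view 40, F 0.2, cos a 0.8
  t <- triangle_inputs(chord_view_mm = 40, foreshortening = 0.2,
                       alpha_deg = acos(0.8) * 180 / pi)
  expect_equal(height_triangle(t, distal_is_anterior = TRUE)$height_mm, -40,
               tolerance = 1e-9)
  expect_equal(height_triangle(triangle_inputs(10, 0, 90), TRUE)$height_mm, 0,
               tolerance = 1e-12)
  expect_equal(height_triangle(triangle_inputs(50, 0, 0), TRUE)$height_mm, -50)
  expect_equal(height_triangle(triangle_inputs(50, 0, 0), FALSE)$height_mm, 50)
  expect_error(triangle_inputs(40, 1, 30), "foreshortened")
  expect_error(triangle_inputs(40, 0.2, 200), "180")
  expect_error(triangle_inputs(-5, 0.2, 30), "positive")
})

test_that("triangle method equals the direct coordinate difference (seeded oracle)", {
  set.seed(101)
  for (i in 1:1000) {
    cl <- random_centerline(n_points = 10)
    d <- derive_triangle_inputs(cl, lateral_view())
    expect_lt(abs(height_triangle(d$inputs, d$distal_is_anterior)$height_mm -
                    height_direct(cl)$height_mm), 1e-9)
  }
})

test_that("triangle-direct equivalence also holds for oblique derivation views", {
  set.seed(102)
  views <- list(view_angles(30, 20), view_angles(-45, -15), view_angles(10, 40))
  for (i in 1:100) {
    cl <- random_centerline(n_points = 10)
    for (v in views) {
      if (foreshortening(cl, v) > 0.999) next
      d <- derive_triangle_inputs(cl, v)
      expect_lt(abs(height_triangle(d$inputs, d$distal_is_anterior)$height_mm -
                      height_direct(cl)$height_mm), 1e-9)
    }
  }
})

test_that("2D lateral height equals the direct height and requires the lateral view", {
  set.seed(13)
  for (i in 1:50) {
    cl <- random_centerline()
    h <- height_2d_lateral(project_centerline(cl, lateral_view()))
    expect_lt(abs(h$height_mm - height_direct(cl)$height_mm), 1e-9)
    expect_identical(h$method, "lateral2d")
  }
  flat <- centerline(rbind(c(0, 0, 0), c(10, 0, 30)))
  expect_equal(height_2d_lateral(project_centerline(flat))$height_mm, 0)
  pp <- project_centerline(random_centerline(), view_angles(30, 0))
  expect_error(height_2d_lateral(pp), "lateral")
})

test_that("centerline CSV and JSON round-trip through the file formats", {
  set.seed(14)
  cl <- random_centerline()
  csv <- tempfile(fileext = ".csv")
  write_centerline(cl, csv)
  expect_equal(read_centerline(csv)$points, cl$points, tolerance = 1e-9)
  js <- tempfile(fileext = ".json")
  jsonlite::write_json(unname(split(cl$points, row(cl$points)[, 1])), js,
                       digits = NA)
  expect_equal(read_centerline(js)$points, cl$points, tolerance = 1e-9)
  expect_error(read_centerline(tempfile()), "not found")
})
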