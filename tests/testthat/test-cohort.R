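# Synthetic cohort generator: distributions, centerline templates, forward
# model, determinism, and ground-truth recovery.

test_that("height sampling recovers its generating distribution", {
  set.seed(51)
  x <- sample_height("LAD_dist", n = 10000)
  expect_lt(abs(mean(x) - (-56.80)), 3 * 7.7 / sqrt(10000))
  expect_lt(abs(stats::sd(x) - 7.7), 0.3)
  degen <- reference_heights()
  degen$height_sd_mm <- 0
  expect_equal(sample_height("PL", degen, n = 5), rep(29.65, 5))
  set.seed(52)
  expect_gt(mean(sample_height("CX_dist", n = 10000) > 0), 0.999)
  expect_error(sample_height("LM"), "unknown segment")
})

test_that("generated centerlines hit the target height exactly and are curved", {
  set.seed(53)
  for (seg in syntax_segments) {
    target <- sample_height(seg)
    cl <- generate_centerline(seg, target, jitter = 0.2)
    expect_lt(abs(height_direct(cl)$height_mm - target), 1e-6)
    expect_gt(arc_chord_ratio(cl), 1)
    h2 <- height_2d_lateral(project_centerline(cl, lateral_view()))
    expect_lt(abs(h2$height_mm - target), 1e-6)
    expect_gt(foreshortening(cl, lateral_view()), 0)  # oblique 3D course
  }
  expect_error(generate_centerline("LM", 10), "template")
})

test_that("template signs follow the anatomy: LAD above the orifice, CX below", {
  set.seed(54)
  for (seg in c("LAD_prox", "LAD_mid", "LAD_dist"))
    expect_lt(height_direct(generate_centerline(seg, sample_height(seg),
                                                jitter = 0.2))$height_mm, 0)
  for (seg in c("CX_prox", "CX_dist"))
    expect_gt(height_direct(generate_centerline(seg, sample_height(seg),
                                                jitter = 0.2))$height_mm, 0)
})

test_that("noise-free lesions are exactly invertible; LAD FFR reads low", {
  set.seed(55)
  spec <- cohort_spec(noise_sd_mmhg = 0)
  for (i in 1:20) {
    g <- generate_lesion(spec, "LAD_dist")
    ffr_meas <- g$lesion$pd_hyper_mmhg / g$lesion$pa_mmhg
    rec <- correct_index(ffr_meas, g$lesion$pa_mmhg, g$truth$p_h_mmhg)
    expect_equal(rec$index_corrected, g$truth$ffr_true, tolerance = 1e-12)
    expect_lt(ffr_meas, g$truth$ffr_true)  # sensor above orifice: reads low
    expect_gt(g$truth$pdpa_true, g$truth$ffr_true)
    expect_true(g$truth$ffr_true >= 0.70 && g$truth$ffr_true <= 0.90)
  }
})

test_that("the default cohort carries the study segment mix and is seed-stable", {
  coh <- generate_cohort(cohort_spec(seed = 56))
  expect_equal(nrow(coh$lesions), 41)
  mix <- table(coh$lesions$segment)
  expect_equal(as.integer(mix[c("LAD_prox", "LAD_mid", "LAD_dist", "CX_prox",
                                "CX_dist", "RCA_mid", "RCA_dist")]),
               c(3L, 18L, 6L, 1L, 5L, 2L, 6L))
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  generate_cohort(cohort_spec(seed = 56), outdir = d1)
  generate_cohort(cohort_spec(seed = 56), outdir = d2)
  expect_identical(readLines(file.path(d1, "lesions.csv")),
                   readLines(file.path(d2, "lesions.csv")))
  expect_identical(readLines(file.path(d1, "centerlines", "L001.csv")),
                   readLines(file.path(d2, "centerlines", "L001.csv")))
  tr <- jsonlite::fromJSON(file.path(d1, "truth.json"))
  expect_equal(tr$seed, 56)
  expect_equal(nrow(tr$truth), 41)
})

test_that("an empty cohort is valid and writes empty files", {
  coh <- generate_cohort(cohort_spec(n_lesions = 0, seed = 1),
                         outdir = file.path(tempdir(), "coh0"))
  expect_equal(nrow(coh$lesions), 0)
  lf <- utils::read.csv(file.path(tempdir(), "coh0", "lesions.csv"))
  expect_equal(nrow(lf), 0)
})

test_that("cohort spec validates its segment mix", {
  expect_error(cohort_spec(n_lesions = 40), "sum")
  expect_error(cohort_spec(segment_mix = c(FOO = 41)), "unknown segment")
})

test_that("sample means of a seeded cohort sit near the generating values", {
  set.seed(58)
  spec <- cohort_spec(noise_sd_mmhg = 0)
  coh <- generate_cohort(spec)
  ffr_meas <- coh$lesions$pd_hyper_mmhg / coh$lesions$pa_mmhg
  # measured FFR = truth + p_h/pa; compare against the realized expectation
  expect_lt(abs(mean(ffr_meas) -
                  mean(coh$truth$ffr_true + coh$truth$p_h_mmhg / coh$truth$pa_mmhg)),
            1e-12)
  expect_lt(abs(mean(coh$truth$ffr_true) - 0.83), 3 * 0.04 / sqrt(41))
})

test_that("full-pipeline recovery: exact when noise-free, bounded at 1 mmHg noise", {
  coh0 <- generate_cohort(cohort_spec(seed = 59, noise_sd_mmhg = 0))
  cor0 <- correct_lesions(coh0$lesions)
  expect_equal(cor0$ffr_corrected, coh0$truth$ffr_true, tolerance = 1e-12)
  expect_equal(cor0$pdpa_corrected, coh0$truth$pdpa_true, tolerance = 1e-12)

  coh1 <- generate_cohort(cohort_spec(seed = 60, noise_sd_mmhg = 1))
  # independent rest/hyperemia noise can invert near-equal index pairs
  cor1 <- suppressWarnings(correct_lesions(coh1$lesions))
  mae <- mean(abs(c(cor1$ffr_corrected - coh1$truth$ffr_true,
                    cor1$pdpa_corrected - coh1$truth$pdpa_true)))
  expect_lt(mae, 0.015)
})
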