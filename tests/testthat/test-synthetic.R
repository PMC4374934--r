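geom <- retina_geometry()
contour <- retina_contour(geom)

test_that("zero-mass population gives an empty map; negatives are rejected", {
  cm <- generate_population(geom, population_spec("OHSt", target_total = 0))
  expect_identical(nrow(cm), 0L)
  expect_error(population_spec("OHSt", target_total = -5), ">= 0")
})

test_that("generators are bit-identical under a fixed seed", {
  s <- population_spec("Brn3a", target_total = 2000, seed = 77)
  a <- generate_population(geom, s, contour)
  b <- generate_population(geom, s, contour)
  expect_identical(a$x_mm, b$x_mm)
  expect_identical(a$y_mm, b$y_mm)
  i1 <- generate_iop_series(seed = 5)
  i2 <- generate_iop_series(seed = 5)
  expect_identical(i1, i2)
})

test_that("realized control OHSt count falls within 3 sigma of the 38,479 target", {
  cm <- generate_population(geom, population_spec("OHSt", seed = 123), contour)
  expect_lt(abs(nrow(cm) - 38479), 3 * sqrt(38479))
})

test_that("uniform profile reproduces the histogram oracle and target density", {
  s <- population_spec("OHSt", target_total = 10000, profile = "uniform",
                       seed = 42)
  cm <- generate_population(geom, s, contour)
  A <- polygon_area(contour)
  # oracle: direct per-bin count / bin area over a coarse grid well inside
  edges <- seq(-1.2, 1.2, by = 0.4)
  dens <- numeric(0)
  for (i in seq_len(length(edges) - 1)) {
    for (j in seq_len(length(edges) - 1)) {
      cnt <- sum(cm$x_mm >= edges[i] & cm$x_mm < edges[i + 1] &
                   cm$y_mm >= edges[j] & cm$y_mm < edges[j + 1])
      dens <- c(dens, cnt / 0.16)
    }
  }
  expect_lt(abs(mean(dens) - 10000 / A) / (10000 / A), 0.1)
})

test_that("radial profile is denser centrally; melanopsin peaks dorso-temporally", {
  cm <- generate_population(geom, population_spec("OHSt", seed = 3), contour)
  r <- sqrt(cm$x_mm^2 + cm$y_mm^2)
  inner <- sum(r < 1.1) / (pi * 1.1^2)
  outer_d <- sum(r >= 1.1 & r < 2.2) / (pi * (2.2^2 - 1.1^2))
  expect_gt(inner / outer_d, 1.2)

  mel <- generate_population(geom, population_spec("melanopsin",
                                                   target_total = 4000,
                                                   seed = 8), contour)
  az <- point_azimuth(mel$x_mm, mel$y_mm)
  dt <- sum(az >= 0 & az < 90)     # dorso-temporal quadrant
  vn <- sum(az >= 180 & az < 270)  # opposite quadrant
  expect_gt(dt / vn, 1.3)
})

test_that("mean realized count over replicates is within 2% of target", {
  s0 <- population_spec("OHSt", target_total = 10000, profile = "uniform")
  counts <- vapply(1:200, function(k) {
    s <- population_spec("OHSt", target_total = 10000, profile = "uniform",
                         seed = 1000 + k)
    nrow(generate_population(geom, s, contour))
  }, 1L)
  expect_lt(abs(mean(counts) - 10000) / 10000, 0.02)
})

test_that("lesion identity, total ablation, and subset property", {
  cm <- generate_population(geom, population_spec("Brn3a", target_total = 3000,
                                                  seed = 21), contour)
  same <- apply_lesion(cm, lesion_spec(), seed = 1)
  expect_identical(same$x_mm, cm$x_mm)

  gone <- apply_lesion(cm, lesion_spec(data.frame(
    start_deg = 0, span_deg = 360, loss_fraction = 1)), seed = 1)
  expect_identical(nrow(gone), 0L)

  les <- lesion_spec(data.frame(start_deg = 120, span_deg = 75,
                                loss_fraction = 0.7),
                     diffuse_fraction = 0.2)
  cut <- apply_lesion(cm, les, seed = 2)
  expect_true(all(paste(cut$x_mm, cut$y_mm) %in% paste(cm$x_mm, cm$y_mm)))
})

test_that("single ablated wedge removes the binomial fraction", {
  s <- population_spec("OHSt", target_total = 38000, profile = "uniform",
                       seed = 6)
  cm <- generate_population(geom, s, contour)
  les <- lesion_spec(data.frame(start_deg = 10, span_deg = 90,
                                loss_fraction = 1))
  cut <- apply_lesion(cm, les, seed = 7)
  # oracle: exact wedge membership of the original pattern
  az <- point_azimuth(cm$x_mm, cm$y_mm)
  in_w <- ((az - 10) %% 360) < 90
  expect_identical(nrow(cut), sum(!in_w))
  frac <- nrow(cut) / nrow(cm)
  expect_lt(abs(frac - 0.75), 3 * sqrt(0.75 * 0.25 / 38000) + sd(in_w) / sqrt(38000) * 3)
})

test_that("overlapping wedges combine losses multiplicatively", {
  n <- 40000
  cm <- generate_population(geom, population_spec(
    "OHSt", target_total = n, profile = "uniform", seed = 31), contour)
  les <- lesion_spec(data.frame(start_deg = c(0, 0), span_deg = c(60, 60),
                                loss_fraction = c(0.5, 0.5)))
  cut <- apply_lesion(cm, les, seed = 32)
  az <- point_azimuth(cm$x_mm, cm$y_mm)
  in_w <- az < 60
  surv_in <- sum(points_in_wedge <- paste(cut$x_mm, cut$y_mm) %in%
                   paste(cm$x_mm[in_w], cm$y_mm[in_w]))
  # survival probability inside the double wedge is (1-0.5)^2 = 0.25
  p_hat <- surv_in / sum(in_w)
  expect_lt(abs(p_hat - 0.25), 3 * sqrt(0.25 * 0.75 / sum(in_w)))
})

test_that("lesion fractions outside [0,1] are rejected", {
  expect_error(lesion_spec(data.frame(start_deg = 0, span_deg = 90,
                                      loss_fraction = 1.2)))
  expect_error(lesion_spec(diffuse_fraction = -0.1))
  expect_error(lesion_spec(data.frame(start_deg = 0, span_deg = 0,
                                      loss_fraction = 0.5)), "span")
})

test_that("SC profile generator: constant baseline, patches, unusable drops", {
  sp <- sc_profile_spec(baseline_area_fn = function(b) rep(0.8, length(b)))
  ss <- generate_sc_profile(sp)
  expect_true(all(ss$area_mm2 == 0.8))
  expect_equal(diff(ss$bregma_mm)[1], -0.030)
  expect_true(min(ss$bregma_mm) >= -4.72 && max(ss$bregma_mm) <= -3.08)

  # a full-loss patch over half the range halves the integral
  rng <- sp$bregma_range
  half <- mean(rng)
  sp2 <- sc_profile_spec(baseline_area_fn = function(b) rep(0.8, length(b)),
                         patches = data.frame(bregma_start = rng[1],
                                              bregma_end = half,
                                              area_loss_fraction = 1))
  ss2 <- generate_sc_profile(sp2)
  trap <- function(s) {
    o <- order(s$bregma_mm)
    x <- s$bregma_mm[o]; y <- s$area_mm2[o]
    sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  }
  expect_lt(trap(ss2) / trap(ss), 0.53)
  expect_gt(trap(ss2) / trap(ss), 0.47)

  sp3 <- sc_profile_spec(unusable_sections = c(5, 6, 7))
  expect_identical(nrow(generate_sc_profile(sp3)),
                   nrow(generate_sc_profile(sc_profile_spec())) - 3L)
})

test_that("IOP series peaks at the designed time and respects bounds", {
  s <- generate_iop_series(peak_mmHg = 30, peak_time_h = 24, noise_sd = 0)
  expect_equal(s$time_h[which.max(s$iop_mmhg)], 24)
  expect_equal(max(s$iop_mmhg), 30)
  expect_equal(s$iop_mmhg[s$time_h == 0], 15)
  # normotensive series stays clearly under the inclusion threshold
  low <- generate_iop_series(peak_mmHg = 20, seed = 9)
  expect_true(all(low$iop_mmhg < 25))
  expect_error(generate_iop_series(peak_mmHg = -3), "non-negative")
})

test_that("IOP course is already elevated at 1 h and basal by day 7", {
  s <- generate_iop_series(peak_mmHg = 30, baseline_mmHg = 15, noise_sd = 0)
  expect_gt(s$iop_mmhg[s$time_h == 1], 20)
  expect_lt(s$iop_mmhg[s$time_h == 168], 16)
})
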