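# centred quintic used as a closed-form generator throughout
quintic_coef <- c(0.8, 0.12, -0.4, 0.06, 0.25, -0.1)
quintic_fn <- function(b, centre = -3.9) {
  x <- b - centre
  oracle_polyval(quintic_coef, x)
}

test_that("section series validates monotone bregma and non-negative areas", {
  expect_error(section_series(c(-3.1, -3.1, -3.2), c(1, 1, 1)), "monotone")
  expect_error(section_series(c(-3.1, -3.2), c(1, -1)), ">= 0")
})

test_that("noiseless quintic data are recovered exactly", {
  sp <- sc_profile_spec(baseline_area_fn = quintic_fn)
  ss <- generate_sc_profile(sp)
  fit <- fit_area_profile(ss)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  centre <- mean(range(ss$bregma_mm))
  # compare by evaluation (coefficient bases differ by the recentring)
  probe <- seq(min(ss$bregma_mm), max(ss$bregma_mm), length.out = 31)
  got <- rgcmap:::polyval(fit$coef_centred, probe - centre)
  expect_equal(got, quintic_fn(probe), tolerance = 1e-8)
  got_raw <- rgcmap:::polyval(fit$coef_raw, probe)
  expect_equal(got_raw, quintic_fn(probe), tolerance = 1e-6)
})

test_that("constant series is a degenerate perfect fit", {
  ss <- section_series(seq(-3.08, -4.7, by = -0.03),
                       rep(0.8, length(seq(-3.08, -4.7, by = -0.03))))
  fit <- fit_area_profile(ss)
  expect_identical(fit$r_squared, 1)
  expect_false(fit$low_r2)
  vol <- integrate_volume(fit, c(-4.72, -3.08))
  expect_equal(vol$volume_mm3, 0.8 * 1.64, tolerance = 1e-9)
})

test_that("dropping interior sections of exact data leaves the fit unchanged", {
  sp <- sc_profile_spec(baseline_area_fn = quintic_fn)
  full <- generate_sc_profile(sp)
  sp2 <- sc_profile_spec(baseline_area_fn = quintic_fn,
                         unusable_sections = c(10, 20, 30))
  holey <- generate_sc_profile(sp2)
  f1 <- fit_area_profile(full)
  f2 <- fit_area_profile(holey)
  probe <- seq(-4.6, -3.2, length.out = 20)
  expect_equal(rgcmap:::polyval(f1$coef_raw, probe),
               rgcmap:::polyval(f2$coef_raw, probe), tolerance = 1e-8)
})

test_that("too few usable sections and low r^2 are handled as specified", {
  ss <- section_series(seq(-3.08, -3.2, by = -0.03), rep(1, 5))
  expect_error(fit_area_profile(ss), "at least 7")
  set.seed(5)
  noisy <- section_series(seq(-3.08, -4.7, by = -0.03),
                          stats::runif(55, 0, 2))
  expect_warning(fit <- fit_area_profile(noisy), "0.78")
  expect_true(fit$low_r2)
  expect_true(fit$r_squared >= 0 && fit$r_squared <= 1)
})

test_that("closed-form integration matches the antiderivative and Simpson", {
  sp <- sc_profile_spec(baseline_area_fn = quintic_fn)
  ss <- generate_sc_profile(sp)
  fit <- fit_area_profile(ss)
  rng <- range(ss$bregma_mm)
  vol <- integrate_volume(fit, rng)
  centre <- mean(rng)
  exact <- oracle_poly_integral(quintic_coef, rng[1] + 3.9, rng[2] + 3.9)
  expect_equal(vol$volume_mm3, exact, tolerance = 1e-8)
  simpson <- oracle_simpson(function(b) pmax(0, quintic_fn(b)),
                            rng[1], rng[2])
  expect_equal(vol$volume_mm3, simpson, tolerance = 1e-6)
})

test_that("negative excursions are clipped to zero before integrating", {
  # a line crossing zero: area profile positive on only part of the range
  lin <- section_series(seq(0, 1, by = 0.02) , pmax(0, seq(-0.5, 0.5, length.out = 51)))
  # fit the signed line directly (degree 1) to force a negative lobe
  ss <- section_series(seq(0, 1, by = 0.02),
                       pmax(0, seq(-0.5, 0.5, length.out = 51)))
  fit <- suppressWarnings(fit_area_profile(ss, degree = 1))
  vol <- integrate_volume(fit, c(0, 1))
  simpson <- oracle_simpson(
    function(x) pmax(0, rgcmap:::polyval(fit$coef_raw, x)), 0, 1)
  expect_equal(vol$volume_mm3, simpson, tolerance = 1e-6)
  expect_gte(vol$volume_mm3, 0)
})

test_that("integration is additive and invariant to bregma translation", {
  sp <- sc_profile_spec(baseline_area_fn = quintic_fn)
  ss <- generate_sc_profile(sp)
  fit <- fit_area_profile(ss)
  rng <- range(ss$bregma_mm)
  mid <- mean(rng) + 0.123
  whole <- integrate_volume(fit, rng)$volume_mm3
  part <- integrate_volume(fit, c(rng[1], mid))$volume_mm3 +
    integrate_volume(fit, c(mid, rng[2]))$volume_mm3
  expect_equal(whole, part, tolerance = 1e-12)

  shifted <- section_series(ss$bregma_mm + 2.5, ss$area_mm2)
  fit2 <- fit_area_profile(shifted)
  vol2 <- integrate_volume(fit2)$volume_mm3
  expect_equal(vol2, integrate_volume(fit)$volume_mm3, tolerance = 1e-8)

  expect_warning(integrate_volume(fit, c(rng[2], rng[1])), "reversed")
})

test_that("percent innervation: identity, ablation, and guards", {
  sp <- sc_profile_spec(baseline_area_fn = function(b) rep(0.8, length(b)))
  fit <- integrate_volume(fit_area_profile(generate_sc_profile(sp)))
  same <- percent_innervation(fit, fit)
  expect_equal(same$percent_innervated, 100)
  expect_equal(same$percent_deafferented, 0)

  zero <- fit; zero$volume_mm3 <- 0
  gone <- percent_innervation(zero, fit)
  expect_equal(gone$percent_deafferented, 100)
  expect_error(percent_innervation(fit, zero), "zero")
})

test_that("a half-loss patch reads out as ~50% deafferentation", {
  ctrl_spec <- sc_profile_spec()
  ctrl <- generate_sc_profile(ctrl_spec)
  rng <- ctrl_spec$bregma_range
  les <- generate_sc_profile(sc_profile_spec(
    patches = data.frame(bregma_start = rng[1], bregma_end = rng[2],
                         area_loss_fraction = 0.5)))
  f_ctrl <- integrate_volume(fit_area_profile(ctrl))
  f_les <- integrate_volume(fit_area_profile(les),
                            f_ctrl$integration_range_mm)
  out <- percent_innervation(f_les, f_ctrl)
  expect_lt(abs(out$percent_deafferented - 50), 1)
})

test_that("percent innervation is unbiased under 10% area noise", {
  ctrl_spec <- sc_profile_spec()
  rng <- ctrl_spec$bregma_range
  ratios <- vapply(1:100, function(k) {
    ctrl <- generate_sc_profile(sc_profile_spec(noise_cv = 0.1,
                                                seed = 2000 + k))
    les <- generate_sc_profile(sc_profile_spec(
      patches = data.frame(bregma_start = rng[1], bregma_end = rng[2],
                           area_loss_fraction = 0.4),
      noise_cv = 0.1, seed = 3000 + k))
    f_ctrl <- integrate_volume(fit_area_profile(ctrl))
    f_les <- integrate_volume(fit_area_profile(les),
                              f_ctrl$integration_range_mm)
    percent_innervation(f_les, f_ctrl)$percent_innervated
  }, 1.0)
  expect_lt(abs(mean(ratios) - 60), 2)
})
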