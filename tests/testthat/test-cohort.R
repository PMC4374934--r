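make_records <- function(animals, value = 100) {
  do.call(rbind, lapply(animals, function(a) {
    data.frame(animal_id = a, eye = c("RE", "LE"), timepoint = "2w",
               population = "OHSt", value = value)
  }))
}

test_that("cohort table enforces uniqueness and non-negative values", {
  r <- make_records(c("a1", "a2"))
  expect_s3_class(cohort_table(r), "cohort_table")
  expect_error(cohort_table(rbind(r, r[1, ])), "one value per")
  r$value[1] <- -2
  expect_error(cohort_table(r), "non-negative")
})

test_that("IOP inclusion rule: strict threshold, window, missing records", {
  peaks <- data.frame(animal_id = c("a1", "a2", "a3", "a4"),
                      peak_mmHg = c(26, 25.0, 31, NA),
                      peak_time_h = c(24, 24, 72, 24))
  cohort <- cohort_table(make_records(c("a1", "a2", "a3", "a4", "a5")),
                         iop_peaks = peaks)
  out <- filter_by_iop(cohort)
  kept <- unique(out$records$animal_id)
  expect_identical(kept, "a1")  # 26 > 25 within 48 h
  excl <- attr(out, "exclusions")
  expect_setequal(excl$animal_id, c("a2", "a3", "a4", "a5"))
  expect_match(excl$reason[excl$animal_id == "a2"], "not > 25")
  expect_match(excl$reason[excl$animal_id == "a3"], "48")
  expect_match(excl$reason[excl$animal_id == "a4"], "no IOP record")
})

test_that("filter pass-rate equals the designed fraction of a synthetic batch", {
  peaks <- c(rep(32, 9), rep(20, 3))  # designed: 9 of 12 hypertensive
  iop <- generate_iop_cohort(peaks, seed = 10)
  cohort <- cohort_table(make_records(sprintf("animal_%02d", 1:12)))
  out <- filter_by_iop(cohort, iop_series = iop)
  expect_identical(length(unique(out$records$animal_id)), 9L)
  expect_setequal(unique(out$records$animal_id), sprintf("animal_%02d", 1:9))
})

test_that("group summaries give mean and sample SD with singleton flag", {
  r <- data.frame(animal_id = c("a", "b", "c", "d"),
                  eye = c("RE", "RE", "RE", "LE"), timepoint = "2w",
                  population = "OHSt", value = c(2, 4, 6, 38479))
  s <- group_summary(cohort_table(r))
  re <- s[s$eye == "RE", ]
  le <- s[s$eye == "LE", ]
  expect_equal(re$mean, 4)
  expect_equal(re$sd, 2)
  expect_equal(le$mean, 38479)
  expect_equal(le$sd, 0)
  expect_true(le$singleton)
  expect_error(group_summary(cohort_table(r[0, ])), "empty")
})

test_that("percent loss and survival reproduce the published arithmetic", {
  expect_identical(percent_loss(38479, 19383)$percent_rounded, 50)
  expect_identical(percent_loss(38507, 14795)$percent_rounded, 62)
  expect_identical(survival_fraction(38507, 14795)$percent_rounded, 38)
  expect_identical(survival_fraction(37936, 15583)$percent_rounded, 41)
  expect_identical(survival_fraction(1059, 629)$percent_rounded, 59)
  expect_equal(percent_loss(5, 5)$percent, 0)
  expect_error(percent_loss(0, 10), "> 0")
})

test_that("loss and survival percentages are exact complements", {
  set.seed(3)
  for (k in 1:20) {
    ctrl <- stats::runif(1, 100, 50000)
    trt <- stats::runif(1, 0, ctrl)
    expect_equal(percent_loss(ctrl, trt)$percent +
                   survival_fraction(ctrl, trt)$percent, 100)
  }
})

test_that("GCL decomposition reproduces the control and treated subtraction", {
  expect_equal(gcl_decomposition(82094, 36623)$non_rgc, 45471)
  expect_equal(gcl_decomposition(61589, 14508)$non_rgc, 47081)
  expect_equal(gcl_decomposition(5, 5)$non_rgc, 0)
  expect_warning(out <- gcl_decomposition(100, 200), "exceeds")
  expect_true(out$flagged)
})

test_that("Mann-Whitney: exact enumeration cases", {
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(mann_whitney(c(1, 2, 3), c(10, 20, 30),
                            alternative = "less")$p_value, 1 / 20)
  expect_equal(mann_whitney(c(1, 2, 3), c(10, 20, 30))$p_value, 0.1)
  expect_warning(p <- mann_whitney(c(2, 2), c(2, 2, 2))$p_value, "tied")
  expect_equal(p, 1)
})

test_that("exact Mann-Whitney p equals the permutation oracle (with ties)", {
  set.seed(8)
  for (k in 1:12) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    a <- sample(1:6, na, replace = TRUE)  # replace => ties are common
    b <- sample(1:6, nb, replace = TRUE)
    for (alt in c("two.sided", "less", "greater")) {
      expect_equal(mann_whitney(a, b, alternative = alt)$p_value,
                   oracle_mw_p(a, b, alternative = alt),
                   tolerance = 1e-12,
                   info = sprintf("alt=%s a=%s b=%s", alt,
                                  paste(a, collapse = ","),
                                  paste(b, collapse = ",")))
    }
  }
})

test_that("large-sample Mann-Whitney approximation matches the reference", {
  set.seed(9)
  a <- stats::rnorm(15, 0); b <- stats::rnorm(14, 0.8)
  got <- mann_whitney(a, b, exact_limit = 16L)
  expect_false(got$exact)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("Kruskal-Wallis: identical groups, separation, and guards", {
  kw0 <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(kw0$p_value, 1)

  # fully separated ranks reach the enumeration maximum of H
  groups <- list(c(1, 2), c(3, 4), c(5, 6))
  kw <- kruskal_wallis(groups)
  h_all <- apply(utils::combn(6, 2), 2, function(i) {
    rest <- setdiff(1:6, i)
    g <- list(i, rest[1:2], rest[3:4])
    n <- 6; rs <- vapply(g, sum, 1.0)
    12 / (n * (n + 1)) * sum(rs^2 / 2) - 3 * (n + 1)
  })
  expect_equal(kw$statistic, max(h_all), tolerance = 1e-12)

  ref <- stats::kruskal.test(c(1, 5, 2, 8, 9, 3, 7, 7),
                             factor(c(1, 1, 2, 2, 3, 3, 3, 1)))
  got <- kruskal_wallis(split(c(1, 5, 2, 8, 9, 3, 7, 7),
                              c(1, 1, 2, 2, 3, 3, 3, 1)))
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)

  expect_error(kruskal_wallis(list(1:3, 4:6)), "at least 3")
  expect_error(kruskal_wallis(list(1:3, 4:6, numeric(0))), "empty")
})

test_that("correlation r^2: exact line, guards", {
  x <- c(1, 2, 3, 4)
  out <- correlation_r2(x, 2 * x)
  expect_equal(out$r_squared, 1)
  expect_equal(out$slope, 2)
  expect_equal(out$intercept, 0)
  expect_error(correlation_r2(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(correlation_r2(1:2, 1:2), "at least 3")
})

test_that("shared lesions couple populations with r^2 > 0.9", {
  geom <- retina_geometry()
  contour <- retina_contour(geom)
  ohst <- numeric(7); brn3a <- numeric(7)
  for (i in 1:7) {
    # per-animal lesion severity varies; both markers share the lesion
    f <- c(0.2, 0.9, 0.5, 1.0, 0.35, 0.7, 0.05)[i]
    les <- lesion_spec(data.frame(start_deg = 20 * i, span_deg = 120,
                                  loss_fraction = f),
                       diffuse_fraction = 0.3 * f)
    a <- generate_population(geom, population_spec(
      "OHSt", target_total = 8000, seed = 400 + i), contour)
    b <- generate_population(geom, population_spec(
      "Brn3a", target_total = 8000, seed = 500 + i), contour)
    ohst[i] <- nrow(apply_lesion(a, les, seed = 600 + i))
    brn3a[i] <- nrow(apply_lesion(b, les, seed = 700 + i))
  }
  expect_gt(correlation_r2(ohst, brn3a)$r_squared, 0.9)
})
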