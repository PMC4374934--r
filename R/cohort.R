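#' Assemble a cohort table
#'
#' Long-format cohort records: one value (cell count, volume, ...) per
#' animal x eye x timepoint x population. Treated eyes are the
#' laser-photocoagulated left eyes (`"LE"`); the untouched right eyes
#' (`"RE"`) are the within-animal controls.
#'
#' @param records Data.frame with columns `animal_id`, `eye`
#'   (`"LE"`/`"RE"`), `timepoint`, `population`, `value`.
#' @param iop_peaks Optional data.frame `animal_id`, `peak_mmHg`,
#'   `peak_time_h` (the treated-eye IOP peak within the first 48 h).
#' @return Object of class `cohort_table`.
#' @export
cohort_table <- function(records, iop_peaks = NULL) {
  req <- c("animal_id", "eye", "timepoint", "population", "value")
  if (!all(req %in% names(records))) {
    stop("records must have columns: ", paste(req, collapse = ", "))
  }
  if (any(records$value < 0, na.rm = TRUE)) stop("values must be non-negative")
  key <- do.call(paste, records[c("animal_id", "eye", "timepoint", "population")])
  if (anyDuplicated(key)) {
    stop("one value per (animal, eye, timepoint, population) is required")
  }
  structure(list(records = as.data.frame(records), iop_peaks = iop_peaks),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  r <- x$records
  cat(sprintf("<cohort_table> %d records, %d animals, populations: %s\n",
              nrow(r), length(unique(r$animal_id)),
              paste(unique(r$population), collapse = ", ")))
  invisible(x)
}

#' Extract the IOP peak within a time window
#'
#' @param series Data.frame `time_h`, `iop_mmhg` (one animal's treated eye).
#' @param window_h Window length from time 0 (default 48 h).
#' @return List `peak_mmHg`, `peak_time_h`.
#' @export
iop_peak <- function(series, window_h = 48) {
  w <- series[series$time_h <= window_h & series$time_h > 0, , drop = FALSE]
  if (nrow(w) == 0) return(list(peak_mmHg = NA_real_, peak_time_h = NA_real_))
  i <- which.max(w$iop_mmhg)
  list(peak_mmHg = w$iop_mmhg[i], peak_time_h = w$time_h[i])
}

#' Apply the ocular-hypertension inclusion filter
#'
#' Animals enter the study only if their treated eye reached a peak IOP
#' strictly greater than `threshold` mmHg within the first `window_h`
#' hours after photocoagulation. Animals without an IOP record are
#' excluded with an explicit reason.
#'
#' @param cohort A [cohort_table()] with `iop_peaks`, or with an
#'   `iop_series` data.frame passed separately.
#' @param threshold Inclusion threshold (mmHg), default 25 (strict `>`).
#' @param window_h Window (h), default 48.
#' @param iop_series Optional long IOP table (`animal_id`, `time_h`,
#'   `iop_mmhg`) used when `iop_peaks` is absent.
#' @return The filtered `cohort_table`; the exclusion log (data.frame
#'   `animal_id`, `reason`) is attached as attribute `"exclusions"`.
#' @export
filter_by_iop <- function(cohort, threshold = 25, window_h = 48,
                          iop_series = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  peaks <- cohort$iop_peaks
  if (is.null(peaks) && !is.null(iop_series)) {
    peaks <- do.call(rbind, lapply(split(iop_series, iop_series$animal_id),
      function(s) {
        p <- iop_peak(s, window_h)
        data.frame(animal_id = s$animal_id[1], peak_mmHg = p$peak_mmHg,
                   peak_time_h = p$peak_time_h)
      }))
  }
  animals <- unique(cohort$records$animal_id)
  excl <- data.frame(animal_id = character(0), reason = character(0))
  keep <- character(0)
  for (a in animals) {
    row <- if (is.null(peaks)) data.frame() else
      peaks[peaks$animal_id == a, , drop = FALSE]
    if (nrow(row) == 0 || is.na(row$peak_mmHg[1])) {
      excl <- rbind(excl, data.frame(animal_id = a, reason = "no IOP record"))
    } else if (!is.na(row$peak_time_h[1]) && row$peak_time_h[1] > window_h) {
      excl <- rbind(excl, data.frame(
        animal_id = a,
        reason = sprintf("peak outside the first %g h", window_h)))
    } else if (row$peak_mmHg[1] > threshold) {
      keep <- c(keep, a)
    } else {
      excl <- rbind(excl, data.frame(
        animal_id = a,
        reason = sprintf("peak %.1f mmHg not > %g mmHg", row$peak_mmHg[1],
                         threshold)))
    }
  }
  out <- cohort_table(cohort$records[cohort$records$animal_id %in% keep, ,
                                     drop = FALSE],
                      iop_peaks = if (is.null(peaks)) NULL else
                        peaks[peaks$animal_id %in% keep, , drop = FALSE])
  attr(out, "exclusions") <- excl
  out
}

#' Group mean and standard deviation
#'
#' Arithmetic mean with the sample (n-1) standard deviation per group,
#' the presentation used throughout (mean +/- SD). Singleton groups get
#' SD 0 with an `n = 1` flag.
#'
#' @param cohort A [cohort_table()] or plain data.frame of records.
#' @param grouping Character vector of grouping columns, default
#'   `c("eye", "timepoint", "population")`.
#' @return Data.frame with group keys, `n`, `mean`, `sd`, `singleton`.
#' @export
group_summary <- function(cohort,
                          grouping = c("eye", "timepoint", "population")) {
  r <- if (inherits(cohort, "cohort_table")) cohort$records else cohort
  if (nrow(r) == 0) stop("empty cohort")
  key <- interaction(r[grouping], drop = TRUE, lex.order = TRUE)
  parts <- split(r, key)
  out <- do.call(rbind, lapply(parts, function(g) {
    v <- g$value
    cbind(g[1, grouping, drop = FALSE],
          data.frame(n = length(v), mean = mean(v),
                     sd = if (length(v) > 1) stats::sd(v) else 0,
                     singleton = length(v) == 1L))
  }))
  rownames(out) <- NULL
  out
}

# round half away from zero, the convention of the published percentages
# (base round() is round-half-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of cells lost
#'
#' `100 * (1 - treated / control)` from group means, reported raw and
#' rounded half-up to the nearest integer (the published convention; e.g.
#' control 38,479 vs treated 19,383 gives 49.63 -> 50%).
#'
#' @param control_mean,treated_mean Group mean counts; control must be
#'   positive.
#' @return List `percent` (raw) and `percent_rounded`.
#' @export
percent_loss <- function(control_mean, treated_mean) {
  if (control_mean <= 0) stop("control mean must be > 0")
  p <- 100 * (1 - treated_mean / control_mean)
  list(percent = p, percent_rounded = round_half_up(p))
}

#' Percentage of cells surviving
#'
#' `100 * treated / control`, the complement of [percent_loss()]; e.g.
#' melanopsin RGCs at 2 weeks: 629 / 1,059 -> 59.4 -> 59%.
#'
#' @inheritParams percent_loss
#' @return List `percent` (raw) and `percent_rounded`.
#' @export
survival_fraction <- function(control_mean, treated_mean) {
  if (control_mean <= 0) stop("control mean must be > 0")
  p <- 100 * treated_mean / control_mean
  list(percent = p, percent_rounded = round_half_up(p))
}

#' Non-RGC nuclei in the ganglion cell layer
#'
#' The GCL holds RGCs plus displaced amacrine and non-neuronal cells;
#' subtracting the Brn3a+ RGC count from the DAPI+ nucleus count isolates
#' the non-RGC pool (e.g. 82,094 - 36,623 = 45,471 in controls). A
#' negative difference is flagged, not fatal, since both terms are noisy
#' group means.
#'
#' @param dapi_mean Mean total DAPI+ GCL nuclei.
#' @param brn3a_mean Mean Brn3a+ RGC count.
#' @return List `non_rgc` and logical `flagged` (TRUE when brn3a > dapi).
#' @export
gcl_decomposition <- function(dapi_mean, brn3a_mean) {
  flagged <- brn3a_mean > dapi_mean
  if (flagged) {
    warning("Brn3a count exceeds DAPI count; check population assignments")
  }
  list(non_rgc = dapi_mean - brn3a_mean, flagged = flagged)
}

#' Mann-Whitney U test (exact by enumeration for small groups)
#'
#' Two-group rank-sum comparison. For combined sample sizes up to
#' `exact_limit` (16 by default, covering the study's group sizes of 6-8
#' per arm) the p-value is exact: the observed (mid-)ranks are enumerated
#' over all ways to assign group membership, which handles ties without
#' approximation. Larger samples use the normal approximation with tie
#' correction. Data with every value identical give p = 1 with a warning.
#'
#' @param group_a,group_b Numeric vectors (each n >= 1).
#' @param alternative `"two.sided"` (default), `"less"`, or `"greater"`
#'   (U of `group_a` small / large).
#' @param exact_limit Maximal combined n for exact enumeration.
#' @return Object of class `rank_test_result`: `statistic` (U of group A),
#'   `p_value`, `test_name`, `n`, `exact`, `alpha`.
#' @export
mann_whitney <- function(group_a, group_b, alternative = "two.sided",
                         exact_limit = 16L) {
  alternative <- match.arg(alternative, c("two.sided", "less", "greater"))
  na <- length(group_a); nb <- length(group_b)
  if (na < 1 || nb < 1) stop("both groups need at least one observation")
  pooled <- c(group_a, group_b)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2

  if (length(unique(pooled)) == 1L) {
    warning("all observations tied; test uninformative")
    return(rank_test_result(u_obs, 1, "Mann-Whitney U", c(na, nb), TRUE))
  }

  n <- na + nb
  if (n <= exact_limit) {
    combos <- utils::combn(n, na)
    u_all <- colSums(matrix(rk[combos], nrow = na)) - na * (na + 1) / 2
    p <- switch(alternative,
      less = mean(u_all <= u_obs + 1e-9),
      greater = mean(u_all >= u_obs - 1e-9),
      two.sided = {
        mu <- na * nb / 2
        mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
      })
    rank_test_result(u_obs, p, "Mann-Whitney U", c(na, nb), TRUE)
  } else {
    mu <- na * nb / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(na * nb / 12 * (n + 1 - tie_term))
    z <- switch(alternative,
      less = (u_obs - mu + 0.5) / sigma,
      greater = (u_obs - mu - 0.5) / sigma,
      two.sided = (u_obs - mu - sign(u_obs - mu) * 0.5) / sigma)
    p <- switch(alternative,
      less = stats::pnorm(z),
      greater = stats::pnorm(z, lower.tail = FALSE),
      two.sided = 2 * stats::pnorm(-abs(z)))
    rank_test_result(u_obs, min(1, p), "Mann-Whitney U", c(na, nb), FALSE)
  }
}

rank_test_result <- function(statistic, p, name, n, exact) {
  structure(list(statistic = statistic, p_value = p, test_name = name,
                 n = n, exact = exact, alpha = 0.05,
                 significant = p < 0.05),
            class = "rank_test_result")
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s, n = %s)%s\n",
              x$test_name, x$statistic, x$p_value,
              if (x$exact) "exact" else "approximate",
              paste(x$n, collapse = "+"),
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Kruskal-Wallis H test
#'
#' Rank-based comparison of three or more groups: H statistic with tie
#' correction and a chi-square p-value on k - 1 degrees of freedom.
#' Fewer than three groups is an error (use [mann_whitney()] for two).
#'
#' @param groups List of numeric vectors, each non-empty.
#' @return A `rank_test_result` with the H statistic.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 3L) {
    stop("kruskal_wallis needs at least 3 groups")
  }
  if (any(vapply(groups, length, 1L) == 0L)) stop("empty group")
  pooled <- unlist(groups)
  n <- length(pooled)
  rk <- rank(pooled)
  idx <- rep(seq_along(groups), vapply(groups, length, 1L))
  r_sum <- tapply(rk, idx, sum)
  n_i <- vapply(groups, length, 1L)
  h <- 12 / (n * (n + 1)) * sum(r_sum^2 / n_i) - 3 * (n + 1)
  ties <- table(pooled)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr > 0) h <- h / corr
  p <- if (length(unique(pooled)) == 1L) 1 else
    stats::pchisq(h, df = length(groups) - 1L, lower.tail = FALSE)
  rank_test_result(h, p, "Kruskal-Wallis H", n_i, FALSE)
}

#' Squared Pearson correlation between paired counts
#'
#' Cross-population coupling of per-retina counts (e.g. Brn3a+ against
#' OHSt+ RGCs): squared Pearson correlation with the regression slope and
#' intercept. Zero variance in either vector is an explicit error.
#'
#' @param x_counts,y_counts Paired numeric vectors, n >= 3.
#' @return List `r_squared`, `slope`, `intercept`, `n`.
#' @export
correlation_r2 <- function(x_counts, y_counts) {
  if (length(x_counts) != length(y_counts)) stop("paired vectors required")
  if (length(x_counts) < 3) stop("need at least 3 pairs")
  if (stats::var(x_counts) == 0 || stats::var(y_counts) == 0) {
    stop("zero variance; correlation undefined")
  }
  r <- stats::cor(x_counts, y_counts)
  slope <- r * stats::sd(y_counts) / stats::sd(x_counts)
  list(r_squared = r^2, slope = slope,
       intercept = mean(y_counts) - slope * mean(x_counts),
       n = length(x_counts))
}
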