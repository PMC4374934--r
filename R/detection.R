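#' Detection parameters
#'
#' Tuning knobs of the automated cell detector. The defaults match the
#' synthetic renderer's point-spread function; on real material they
#' should be set from the observed soma size and magnification.
#'
#' @param psf_sigma_px Blob scale (pixels) used by the band-pass
#'   enhancement; the difference-of-Gaussians pair is
#'   (`psf_sigma_px`, `1.6 * psf_sigma_px`).
#' @param threshold `"otsu"` for automatic thresholding of the enhanced
#'   image, or a fixed numeric cut on enhanced intensity.
#' @param min_area_px,max_area_px Connected-component area band (pixels).
#' @param min_separation_px Detections closer than this are merged into
#'   the one with larger integrated intensity (lexicographic pixel order
#'   breaks exact ties).
#' @return Object of class `detection_params`.
#' @export
detection_params <- function(psf_sigma_px = 1.5, threshold = "otsu",
                             min_area_px = 3L, max_area_px = 400L,
                             min_separation_px = 2) {
  if (psf_sigma_px <= 0) stop("psf_sigma_px must be > 0")
  if (min_area_px > max_area_px) stop("min_area_px must be <= max_area_px")
  if (is.numeric(threshold) && threshold < 0) stop("threshold must be non-negative")
  structure(list(psf_sigma_px = psf_sigma_px, threshold = threshold,
                 min_area_px = as.integer(min_area_px),
                 max_area_px = as.integer(max_area_px),
                 min_separation_px = min_separation_px),
            class = "detection_params")
}

# separable Gaussian blur via banded matrix products (reflected edges are
# not needed at the accuracy required here; borders are renormalized).
gaussian_blur <- function(m, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  smooth_dim <- function(n) {
    B <- matrix(0, n, n)
    for (d in -half:half) {
      idx <- seq_len(n - abs(d))
      if (d >= 0) B[cbind(idx + d, idx)] <- k[d + half + 1L]
      else B[cbind(idx, idx - d)] <- k[-d + half + 1L]
    }
    # renormalize truncated rows at the borders
    B / rowSums(B)
  }
  smooth_dim(nrow(m)) %*% m %*% t(smooth_dim(ncol(m)))
}

#' Otsu threshold of an image
#'
#' Classic between-class-variance maximization on a 256-bin histogram.
#' @param values Numeric vector or matrix of intensities.
#' @param n_bins Histogram resolution.
#' @return Threshold on the intensity scale, or `NA` if degenerate
#'   (constant input).
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  v <- as.numeric(values)
  rng <- range(v)
  if (diff(rng) == 0) return(NA_real_)
  h <- as.numeric(tabulate(pmin(n_bins, floor((v - rng[1]) / diff(rng) * n_bins) + 1L),
                           nbins = n_bins))
  w <- cumsum(h)
  mu <- cumsum(h * seq_len(n_bins))
  n <- w[n_bins]
  mu_t <- mu[n_bins]
  between <- (mu_t * w - mu * n)^2 / (w * (n - w))
  between[!is.finite(between)] <- -Inf
  k <- which.max(between)
  rng[1] + k / n_bins * diff(rng)
}

#' Detect labelled cells on a montage
#'
#' A conventional, fully specified blob detector standing in for the
#' undisclosed commercial macro: difference-of-Gaussians band-pass at the
#' configured scale, automatic (Otsu) or fixed threshold on the enhanced
#' image, 8-connected components, an area band, intensity-weighted
#' sub-pixel centroids, and merging of peaks closer than the minimum
#' separation (brighter integrated intensity wins). Deterministic for a
#' fixed montage and parameter set.
#'
#' A blank (constant) or fully saturated montage yields an empty result
#' with a warning rather than an error.
#'
#' @param montage A [assemble_montage()] result (calibrated pixels).
#' @param params A [detection_params()].
#' @return A [cell_map()] in mm coordinates with per-detection
#'   `intensity` (integrated enhanced signal) and `area_px` columns.
#' @export
detect_cells <- function(montage, params = detection_params()) {
  stopifnot(inherits(montage, "montage"), inherits(params, "detection_params"))
  px <- montage$pixels
  empty <- function() cell_map(numeric(0), numeric(0), population = "detected",
                               extra = data.frame(intensity = numeric(0),
                                                  area_px = integer(0)))
  if (diff(range(px)) == 0) {
    warning("montage is blank or saturated; no cells detected")
    return(empty())
  }

  s1 <- params$psf_sigma_px
  enhanced <- gaussian_blur(px, s1) - gaussian_blur(px, 1.6 * s1)

  thr <- if (identical(params$threshold, "otsu")) {
    # Otsu on the positive response; background dominates the negative lobe
    otsu_threshold(enhanced[enhanced > 0])
  } else {
    params$threshold
  }
  if (is.na(thr)) {
    warning("degenerate enhanced image; no cells detected")
    return(empty())
  }

  binary <- enhanced > thr
  if (!any(binary)) {
    warning("nothing above threshold; no cells detected")
    return(empty())
  }
  labels <- .cc_label_cpp(binary)
  n_comp <- max(labels)
  idx <- which(labels > 0)
  lab <- labels[idx]
  wt <- pmax(0, enhanced[idx])
  rows <- ((idx - 1L) %% nrow(px)) + 1L
  cols <- ((idx - 1L) %/% nrow(px)) + 1L

  area <- tabulate(lab, nbins = n_comp)
  tot_w <- as.numeric(tapply(wt, lab, sum))
  # intensity-weighted centroids in continuous pixel coordinates
  cx <- as.numeric(tapply(wt * (cols - 0.5), lab, sum)) / tot_w
  cy <- as.numeric(tapply(wt * (rows - 0.5), lab, sum)) / tot_w
  # fall back to the geometric centroid where all weights are zero
  flat <- !is.finite(cx) | !is.finite(cy)
  if (any(flat)) {
    cx[flat] <- as.numeric(tapply(cols - 0.5, lab, mean))[flat]
    cy[flat] <- as.numeric(tapply(rows - 0.5, lab, mean))[flat]
  }

  keep <- area >= params$min_area_px & area <= params$max_area_px
  cx <- cx[keep]; cy <- cy[keep]
  inten <- tot_w[keep]; area <- area[keep]

  # merge peaks closer than min_separation: brighter integrated intensity
  # wins; exact ties resolved by (row, col) lexicographic pixel order
  if (length(cx) > 1 && params$min_separation_px > 0) {
    ord <- order(-inten, cy, cx)
    acc <- logical(length(cx))
    sel <- integer(0)
    for (i in ord) {
      if (length(sel) == 0 ||
          min((cx[sel] - cx[i])^2 + (cy[sel] - cy[i])^2) >=
            params$min_separation_px^2) {
        sel <- c(sel, i)
        acc[i] <- TRUE
      }
    }
    cx <- cx[acc]; cy <- cy[acc]; inten <- inten[acc]; area <- area[acc]
  }

  mm <- px_to_mm(montage$grid, cx, cy)
  cell_map(mm$x_mm, mm$y_mm, population = "detected",
           extra = data.frame(intensity = inten, area_px = area))
}

#' Match detections to ground truth
#'
#' Greedy nearest matching of detections to ground-truth positions within
#' a tolerance radius, for computing recall and precision against the
#' renderer's sidecar table.
#'
#' @param detected A [cell_map()] of detections.
#' @param truth Data.frame with `x_mm`, `y_mm` ground-truth positions.
#' @param match_radius_mm Maximal centre distance for a match.
#' @return List with `recall`, `precision`, `n_matched`, `n_detected`,
#'   `n_truth`, and the mean matched centroid error (mm).
#' @export
match_detections <- function(detected, truth, match_radius_mm) {
  nd <- nrow(detected); nt <- nrow(truth)
  if (nd == 0 || nt == 0) {
    return(list(recall = 0, precision = if (nd == 0) NA_real_ else 0,
                n_matched = 0L, n_detected = nd, n_truth = nt,
                mean_error_mm = NA_real_))
  }
  # bucket detections on a grid of the match radius, then collect all
  # candidate pairs and accept them greedily in order of distance
  r <- match_radius_mm
  x0 <- min(detected$x_mm, truth$x_mm)
  y0 <- min(detected$y_mm, truth$y_mm)
  bx <- floor((detected$x_mm - x0) / r)
  by <- floor((detected$y_mm - y0) / r)
  key <- paste(bx, by)
  buckets <- split(seq_len(nd), key)
  pair_d <- integer(0); pair_t <- integer(0); pair_dist <- numeric(0)
  tbx <- floor((truth$x_mm - x0) / r)
  tby <- floor((truth$y_mm - y0) / r)
  for (j in seq_len(nt)) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      b <- buckets[[paste(tbx[j] + dx, tby[j] + dy)]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    if (length(cand) == 0) next
    dist <- sqrt((detected$x_mm[cand] - truth$x_mm[j])^2 +
                   (detected$y_mm[cand] - truth$y_mm[j])^2)
    ok <- dist <= r
    pair_d <- c(pair_d, cand[ok])
    pair_t <- c(pair_t, rep.int(j, sum(ok)))
    pair_dist <- c(pair_dist, dist[ok])
  }
  matched_t <- logical(nt)
  matched_d <- logical(nd)
  errs <- numeric(0)
  for (k in order(pair_dist)) {
    i <- pair_d[k]; j <- pair_t[k]
    if (!matched_d[i] && !matched_t[j]) {
      matched_d[i] <- TRUE
      matched_t[j] <- TRUE
      errs <- c(errs, pair_dist[k])
    }
  }
  n_matched <- sum(matched_t)
  list(recall = n_matched / nt,
       precision = n_matched / nd,
       n_matched = as.integer(n_matched),
       n_detected = nd, n_truth = nt,
       mean_error_mm = if (length(errs)) mean(errs) else NA_real_)
}
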