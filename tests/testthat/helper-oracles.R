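# Independent oracles used across the suite. These deliberately take the
# naive route (full enumeration, O(n^2) scans, composite quadrature) so the
# package implementations are checked against a different computation path.

# exact per-point neighbour counts by full pairwise distance scan
oracle_neighbour_counts <- function(x, y, r) {
  n <- length(x)
  if (n == 0) return(integer(0))
  d <- as.matrix(stats::dist(cbind(x, y)))
  diag(d) <- Inf
  as.integer(rowSums(d <= r))
}

# exact Mann-Whitney p by enumerating group assignments and counting
# pairwise wins directly (no ranks involved)
oracle_mw_p <- function(a, b, alternative = "two.sided") {
  pooled <- c(a, b)
  na <- length(a)
  n <- length(pooled)
  u_of <- function(sel) {
    xa <- pooled[sel]
    xb <- pooled[-sel]
    sum(outer(xa, xb, ">")) + 0.5 * sum(outer(xa, xb, "=="))
  }
  u_obs <- u_of(seq_len(na))
  u_all <- apply(utils::combn(n, na), 2, u_of)
  mu <- na * (n - na) / 2
  switch(alternative,
    less = mean(u_all <= u_obs + 1e-9),
    greater = mean(u_all >= u_obs - 1e-9),
    two.sided = mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9))
}

# composite Simpson quadrature of f over [a, b]
oracle_simpson <- function(f, a, b, n_panels = 10000L) {
  x <- seq(a, b, length.out = 2L * n_panels + 1L)
  h <- (b - a) / (2 * n_panels)
  w <- rep(c(4, 2), n_panels)
  w <- c(1, w[-length(w)], 1)
  sum(w * f(x)) * h / 3
}

# polynomial evaluation for generator-side closed forms
oracle_polyval <- function(coef, x) {
  out <- 0
  for (k in rev(seq_along(coef))) out <- out * x + coef[k]
  out
}

# antiderivative value of an ascending-coefficient polynomial
oracle_poly_integral <- function(coef, a, b) {
  anti <- function(x) sum(coef * x^(seq_along(coef)) / seq_along(coef))
  anti(b) - anti(a)
}

# square test field with a uniform hard-core pattern, rendered and
# reassembled -- shared by detection tests
make_detection_fixture <- function(density_per_mm2 = 4000, seed = 11,
                                   w_mm = 0.45, h_mm = 0.34, ...) {
  box <- data.frame(x_mm = c(0, w_mm, w_mm, 0), y_mm = c(0, 0, h_mm, h_mm))
  spec <- population_spec("OHSt",
                          target_total = round(density_per_mm2 * w_mm * h_mm),
                          profile = "uniform", min_separation_mm = 0.008,
                          seed = seed)
  cells <- generate_population(retina_geometry(max(w_mm, h_mm)), spec,
                               contour = box)
  grid <- frame_grid(c(0, w_mm, 0, h_mm))
  ts <- render_tiles(cells, grid, seed = seed + 1L, ...)
  list(cells = cells, grid = grid, tile_set = ts,
       montage = assemble_montage(ts$tiles, grid))
}
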