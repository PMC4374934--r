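#' Microscope frame grid
#'
#' Lays out rectangular acquisition frames side-by-side with no gap or
#' overlap so that their union covers a bounding box (a wholemount is
#' photographed as a montage of such frames). Frame size defaults to
#' 0.45 x 0.34 mm, a 20x-field stand-in, at 1.25 um per pixel.
#'
#' @param bbox Numeric `c(xmin, xmax, ymin, ymax)` in mm, or a contour
#'   data.frame whose bounding box is used.
#' @param frame_w_mm,frame_h_mm Frame width/height (mm).
#' @param mm_per_pixel Pixel pitch (mm); frame dimensions must be whole
#'   pixel multiples of it.
#' @return Object of class `frame_grid`: rows/cols, frame pixel size,
#'   origin (top-left corner, mm), and pixel pitch.
#' @export
frame_grid <- function(bbox, frame_w_mm = 0.45, frame_h_mm = 0.34,
                       mm_per_pixel = 0.00125) {
  if (is.data.frame(bbox)) {
    bbox <- c(range(bbox$x_mm), range(bbox$y_mm))
  }
  stopifnot(length(bbox) == 4L, bbox[2] > bbox[1], bbox[4] > bbox[3])
  if (mm_per_pixel <= 0) stop("mm_per_pixel must be > 0")
  fw_px <- frame_w_mm / mm_per_pixel
  fh_px <- frame_h_mm / mm_per_pixel
  if (abs(fw_px - round(fw_px)) > 1e-6 || abs(fh_px - round(fh_px)) > 1e-6) {
    stop("frame dimensions must be whole multiples of mm_per_pixel")
  }
  n_cols <- ceiling((bbox[2] - bbox[1]) / frame_w_mm - 1e-9)
  n_rows <- ceiling((bbox[4] - bbox[3]) / frame_h_mm - 1e-9)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         frame_w_mm = frame_w_mm, frame_h_mm = frame_h_mm,
         frame_w_px = as.integer(round(fw_px)),
         frame_h_px = as.integer(round(fh_px)),
         mm_per_pixel = mm_per_pixel,
         origin_mm = c(x = bbox[1], y = bbox[3] + n_rows * frame_h_mm)),
    class = "frame_grid"
  )
}

# mm -> continuous pixel coordinates (0 at the top-left montage corner,
# x to the right, y downward); pixel (r, c) has centre (c - 0.5, r - 0.5).
mm_to_px <- function(grid, x_mm, y_mm) {
  list(px_x = (x_mm - grid$origin_mm[["x"]]) / grid$mm_per_pixel,
       px_y = (grid$origin_mm[["y"]] - y_mm) / grid$mm_per_pixel)
}

px_to_mm <- function(grid, px_x, px_y) {
  list(x_mm = grid$origin_mm[["x"]] + px_x * grid$mm_per_pixel,
       y_mm = grid$origin_mm[["y"]] - px_y * grid$mm_per_pixel)
}

#' Render synthetic fluorescence tiles from a cell pattern
#'
#' Projects each cell onto the frame grid as a Gaussian blob of the given
#' point-spread sigma, on a constant background, with optional Poisson
#' shot noise and Gaussian read noise, quantized to 16-bit counts. The
#' ground-truth positions are returned as a sidecar table so detection
#' performance can be scored exactly.
#'
#' @param cells A [cell_map()].
#' @param grid A [frame_grid()]; defaults to a grid covering the cell
#'   pattern's contour (or the cells' bounding box).
#' @param psf_sigma_px Blob sigma in pixels (> 0).
#' @param amplitude Peak signal above background (counts).
#' @param background Background level (counts).
#' @param shot_noise Apply Poisson noise to the expected photon counts.
#' @param read_noise_sd SD of additive Gaussian read noise (counts).
#' @param seed RNG seed.
#' @return Object of class `tile_set`: named list of integer tile
#'   matrices (`frame_<row>_<col>`), the grid, and the `truth` sidecar
#'   (`x_mm`, `y_mm`, `px_x`, `px_y`).
#' @export
render_tiles <- function(cells, grid = NULL, psf_sigma_px = 1.5,
                         amplitude = 3000, background = 500,
                         shot_noise = TRUE, read_noise_sd = 30,
                         seed = 1L) {
  if (psf_sigma_px <= 0) stop("psf_sigma_px must be > 0")
  if (is.null(grid)) {
    region <- attr(cells, "contour")
    if (is.null(region) && nrow(cells) > 0) region <- cells
    if (is.null(region)) stop("supply a frame_grid for an empty, contour-less pattern")
    grid <- frame_grid(region)
  }
  H <- grid$n_rows * grid$frame_h_px
  W <- grid$n_cols * grid$frame_w_px
  canvas <- matrix(background, nrow = H, ncol = W)

  p <- mm_to_px(grid, cells$x_mm, cells$y_mm)
  if (nrow(cells) > 0 &&
      (any(p$px_x < 0 | p$px_x > W) || any(p$px_y < 0 | p$px_y > H))) {
    stop("cells fall outside the tiled region")
  }
  half <- ceiling(4 * psf_sigma_px)
  for (k in seq_len(nrow(cells))) {
    cx <- p$px_x[k]; cy <- p$px_y[k]
    cols <- max(1L, floor(cx - half)):min(W, ceiling(cx + half))
    rows <- max(1L, floor(cy - half)):min(H, ceiling(cy + half))
    gx <- exp(-((cols - 0.5 - cx)^2) / (2 * psf_sigma_px^2))
    gy <- exp(-((rows - 0.5 - cy)^2) / (2 * psf_sigma_px^2))
    canvas[rows, cols] <- canvas[rows, cols] + amplitude * outer(gy, gx)
  }

  canvas <- with_local_seed(seed, {
    out <- canvas
    if (shot_noise) {
      out <- matrix(stats::rpois(length(out), lambda = out),
                    nrow = H, ncol = W)
    }
    if (read_noise_sd > 0) {
      out <- out + stats::rnorm(length(out), sd = read_noise_sd)
    }
    out
  })
  canvas <- matrix(as.integer(pmin(65535, pmax(0, round(canvas)))),
                   nrow = H, ncol = W)

  tiles <- split_canvas(canvas, grid)
  structure(
    list(tiles = tiles, grid = grid,
         truth = data.frame(x_mm = cells$x_mm, y_mm = cells$y_mm,
                            px_x = p$px_x, px_y = p$px_y)),
    class = "tile_set"
  )
}

split_canvas <- function(canvas, grid) {
  tiles <- list()
  for (r in seq_len(grid$n_rows)) {
    for (c in seq_len(grid$n_cols)) {
      rows <- ((r - 1L) * grid$frame_h_px + 1L):(r * grid$frame_h_px)
      cols <- ((c - 1L) * grid$frame_w_px + 1L):(c * grid$frame_w_px)
      tiles[[sprintf("frame_%d_%d", r, c)]] <- canvas[rows, cols, drop = FALSE]
    }
  }
  tiles
}

#' Assemble frames into a montage
#'
#' Lossless side-by-side concatenation of a complete frame grid: pixel
#' (r, c) of frame (i, j) maps to montage pixel
#' ((i-1)*frame_h + r, (j-1)*frame_w + c), and the inverse mapping is
#' exact. Missing frames are an error naming the gaps.
#'
#' @param tiles Named list of integer matrices (`frame_<row>_<col>`), as
#'   produced by [render_tiles()] or read from disk.
#' @param grid The [frame_grid()] the tiles belong to.
#' @return Object of class `montage`: the pixel matrix plus calibration
#'   (`mm_per_pixel`, `origin_mm`) and the grid.
#' @export
assemble_montage <- function(tiles, grid) {
  stopifnot(inherits(grid, "frame_grid"))
  expected <- as.vector(outer(seq_len(grid$n_rows), seq_len(grid$n_cols),
                              function(r, c) sprintf("frame_%d_%d", r, c)))
  missing <- setdiff(expected, names(tiles))
  if (length(missing) > 0) {
    stop("missing frames: ", paste(missing, collapse = ", "))
  }
  dims <- vapply(tiles[expected], dim, integer(2))
  if (any(dims[1, ] != grid$frame_h_px) || any(dims[2, ] != grid$frame_w_px)) {
    stop("all frames must be ", grid$frame_h_px, " x ", grid$frame_w_px, " pixels")
  }
  H <- grid$n_rows * grid$frame_h_px
  W <- grid$n_cols * grid$frame_w_px
  pixels <- matrix(0L, nrow = H, ncol = W)
  for (r in seq_len(grid$n_rows)) {
    for (c in seq_len(grid$n_cols)) {
      rows <- ((r - 1L) * grid$frame_h_px + 1L):(r * grid$frame_h_px)
      cols <- ((c - 1L) * grid$frame_w_px + 1L):(c * grid$frame_w_px)
      pixels[rows, cols] <- tiles[[sprintf("frame_%d_%d", r, c)]]
    }
  }
  structure(list(pixels = pixels, grid = grid,
                 mm_per_pixel = grid$mm_per_pixel,
                 origin_mm = grid$origin_mm),
            class = "montage")
}

#' Split a montage back into its frames
#'
#' Exact inverse of [assemble_montage()] (round-trips bit-identically).
#' @param montage A `montage`.
#' @return Named list of frame matrices.
#' @export
split_montage <- function(montage) {
  stopifnot(inherits(montage, "montage"))
  split_canvas(montage$pixels, montage$grid)
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %d x %d px (%d x %d frames of %d x %d), %.5f mm/px\n",
              nrow(x$pixels), ncol(x$pixels),
              x$grid$n_rows, x$grid$n_cols,
              x$grid$frame_h_px, x$grid$frame_w_px, x$mm_per_pixel))
  invisible(x)
}
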