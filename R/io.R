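# CSV dialect used everywhere: comma separator, '.' decimal, UTF-8,
# mandatory header. Readers validate the schema and name the offending
# column or line in errors.

read_checked_csv <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(what, " file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}

check_numeric_cols <- function(df, cols, path) {
  for (col in cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      stop("non-numeric values in column ", col, " of ", path,
           if (length(bad)) paste0(" (data line ", bad[1], ")") else "")
    }
  }
  df
}

#' Read / write cell coordinate tables
#'
#' Schema: `animal_id,eye,population,x_mm,y_mm` (retina-centred mm).
#'
#' @param path CSV path.
#' @param cells A [cell_map()] (writing).
#' @param animal_id,eye Provenance written alongside the coordinates;
#'   default to the tags carried by the `cell_map`.
#' @return `read_cells_csv`: a [cell_map()]; `write_cells_csv`: the path,
#'   invisibly.
#' @export
read_cells_csv <- function(path) {
  df <- read_checked_csv(path, c("animal_id", "eye", "population",
                                 "x_mm", "y_mm"), "cell table")
  check_numeric_cols(df, c("x_mm", "y_mm"), path)
  pop <- if (nrow(df) > 0) df$population[1] else "OHSt"
  cell_map(df$x_mm, df$y_mm, population = pop,
           animal_id = if (nrow(df) > 0) df$animal_id[1] else NA_character_,
           eye = if (nrow(df) > 0) df$eye[1] else NA_character_)
}

#' @rdname read_cells_csv
#' @export
write_cells_csv <- function(cells, path, animal_id = NULL, eye = NULL) {
  if (is.null(animal_id)) animal_id <- attr(cells, "animal_id")
  if (is.null(eye)) eye <- attr(cells, "eye")
  df <- data.frame(animal_id = if (is.na(animal_id)) "" else animal_id,
                   eye = if (is.na(eye)) "" else eye,
                   population = attr(cells, "population"),
                   x_mm = cells$x_mm, y_mm = cells$y_mm)
  if (nrow(cells) == 0) df <- df[0, , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a contour polygon
#'
#' Schema: `x_mm,y_mm`, vertices in order, closed implicitly.
#' @param path CSV path.
#' @param contour Polygon data.frame (writing).
#' @return The contour data.frame / the path.
#' @export
read_contour_csv <- function(path) {
  df <- read_checked_csv(path, c("x_mm", "y_mm"), "contour")
  check_numeric_cols(df, c("x_mm", "y_mm"), path)
  as_contour(df)
}

#' @rdname read_contour_csv
#' @export
write_contour_csv <- function(contour, path) {
  utils::write.csv(as_contour(contour)[c("x_mm", "y_mm")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write SC section-series tables
#'
#' Schema: `bregma_mm,area_mm2,usable` (usable as TRUE/FALSE).
#' @param path CSV path.
#' @param series A [section_series()] (writing).
#' @return A [section_series()] / the path.
#' @export
read_sections_csv <- function(path) {
  df <- read_checked_csv(path, c("bregma_mm", "area_mm2", "usable"),
                         "section series")
  check_numeric_cols(df, c("bregma_mm", "area_mm2"), path)
  section_series(df$bregma_mm, df$area_mm2, as.logical(df$usable))
}

#' @rdname read_sections_csv
#' @export
write_sections_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series)[c("bregma_mm", "area_mm2", "usable")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write IOP time-series tables
#'
#' Schema: `animal_id,eye,time_h,iop_mmhg`.
#' @param path CSV path.
#' @param iop Long IOP data.frame (writing).
#' @return Data.frame / the path.
#' @export
read_iop_csv <- function(path) {
  df <- read_checked_csv(path, c("animal_id", "eye", "time_h", "iop_mmhg"),
                         "IOP table")
  check_numeric_cols(df, c("time_h", "iop_mmhg"), path)
  df
}

#' @rdname read_iop_csv
#' @export
write_iop_csv <- function(iop, path) {
  utils::write.csv(iop[c("animal_id", "eye", "time_h", "iop_mmhg")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write 16-bit grayscale image tiles (plain PGM)
#'
#' Tiles are stored as plain-text PGM (P2, maxval 65535): a standard,
#' lossless single-channel 16-bit container that round-trips pixel values
#' exactly. Files are named `frame_<row>_<col>.pgm`; the grid geometry
#' and ground truth travel in a JSON sidecar (see [write_tile_set()]).
#'
#' @param m Integer matrix (writing); values in `[0, 65535]`.
#' @param path File path.
#' @return `read_pgm`: integer matrix; `write_pgm`: the path, invisibly.
#' @export
write_pgm <- function(m, path) {
  if (any(m < 0 | m > 65535)) stop("pixel values must lie in [0, 65535]")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), "65535"), con)
  # row-major pixel order, one image row per line
  writeLines(apply(m, 1, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (lines[1] != "P2") stop("not a plain (P2) PGM file: ", path)
  dims <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  vals <- as.integer(unlist(strsplit(trimws(lines[-(1:3)]), "\\s+")))
  if (length(vals) != dims[1] * dims[2]) {
    stop("pixel count mismatch in ", path)
  }
  matrix(vals, nrow = dims[2], ncol = dims[1], byrow = TRUE)
}

#' Write / read a full tile set with its JSON sidecar
#'
#' Writes every frame as `frame_<row>_<col>.pgm` plus `grid.json`
#' holding the grid geometry and the ground-truth cell positions.
#'
#' @param tile_set A [render_tiles()] result.
#' @param dir Output directory (created if needed).
#' @return `write_tile_set`: the directory; `read_tile_set`: a `tile_set`.
#' @export
write_tile_set <- function(tile_set, dir) {
  stopifnot(inherits(tile_set, "tile_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tile_set$tiles)) {
    write_pgm(tile_set$tiles[[nm]], file.path(dir, paste0(nm, ".pgm")))
  }
  g <- tile_set$grid
  sidecar <- list(
    grid = list(n_rows = g$n_rows, n_cols = g$n_cols,
                frame_w_mm = g$frame_w_mm, frame_h_mm = g$frame_h_mm,
                frame_w_px = g$frame_w_px, frame_h_px = g$frame_h_px,
                mm_per_pixel = g$mm_per_pixel,
                origin_x_mm = g$origin_mm[["x"]],
                origin_y_mm = g$origin_mm[["y"]]),
    truth = tile_set$truth
  )
  jsonlite::write_json(sidecar, file.path(dir, "grid.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_tile_set
#' @export
read_tile_set <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "grid.json"),
                                 simplifyVector = TRUE)
  g <- sidecar$grid
  grid <- structure(
    list(n_rows = g$n_rows, n_cols = g$n_cols,
         frame_w_mm = g$frame_w_mm, frame_h_mm = g$frame_h_mm,
         frame_w_px = g$frame_w_px, frame_h_px = g$frame_h_px,
         mm_per_pixel = g$mm_per_pixel,
         origin_mm = c(x = g$origin_x_mm, y = g$origin_y_mm)),
    class = "frame_grid")
  files <- list.files(dir, pattern = "^frame_\\d+_\\d+\\.pgm$")
  tiles <- lapply(files, function(f) read_pgm(file.path(dir, f)))
  names(tiles) <- sub("\\.pgm$", "", files)
  truth <- as.data.frame(sidecar$truth)
  structure(list(tiles = tiles, grid = grid, truth = truth),
            class = "tile_set")
}
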