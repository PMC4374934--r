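#' Labelled 2-D cell point pattern
#'
#' The central container of the pipeline: detected or ground-truth cell
#' positions of one population on one wholemount, in retina-centred mm
#' coordinates (optic disc at the origin), together with the retinal
#' contour they live in.
#'
#' @param x,y Numeric vectors of coordinates (mm).
#' @param population Population label, one of `"OHSt"`, `"Brn3a"`,
#'   `"melanopsin"`, `"DAPI_nonRGC"`, or another character tag.
#' @param contour Polygon data.frame (`x_mm`, `y_mm`) or `NULL`.
#' @param animal_id,eye Optional provenance tags carried into cohort tables.
#' @param extra Optional data.frame of per-cell columns (e.g. detection
#'   intensity and area), row-aligned with the coordinates.
#' @return Object of class `cell_map`: a data.frame with columns `x_mm`,
#'   `y_mm` (plus any extras) and attributes `population`, `contour`,
#'   `animal_id`, `eye`.
#' @export
cell_map <- function(x, y, population = "OHSt", contour = NULL,
                     animal_id = NA_character_, eye = NA_character_,
                     extra = NULL) {
  stopifnot(length(x) == length(y))
  df <- data.frame(x_mm = as.numeric(x), y_mm = as.numeric(y))
  if (!is.null(extra)) {
    stopifnot(nrow(extra) == nrow(df))
    df <- cbind(df, extra)
  }
  if (!is.null(contour)) contour <- as_contour(contour)
  structure(df,
            population = population,
            contour = contour,
            animal_id = animal_id,
            eye = eye,
            class = c("cell_map", "data.frame"))
}

#' @export
print.cell_map <- function(x, ...) {
  cat(sprintf("<cell_map> %d cells, population %s", nrow(x),
              attr(x, "population")))
  if (!is.na(attr(x, "animal_id"))) {
    cat(sprintf(" [animal %s, eye %s]", attr(x, "animal_id"), attr(x, "eye")))
  }
  cat("\n")
  if (nrow(x) > 0) {
    cat(sprintf("  x range: [%.3f, %.3f] mm, y range: [%.3f, %.3f] mm\n",
                min(x$x_mm), max(x$x_mm), min(x$y_mm), max(x$y_mm)))
  }
  invisible(x)
}

# preserve attributes when subsetting rows
#' @export
`[.cell_map` <- function(x, i, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "population") <- attr(x, "population")
    attr(out, "contour") <- attr(x, "contour")
    attr(out, "animal_id") <- attr(x, "animal_id")
    attr(out, "eye") <- attr(x, "eye")
    class(out) <- c("cell_map", "data.frame")
  }
  out
}

cm_contour <- function(cells, contour = NULL) {
  if (is.null(contour)) contour <- attr(cells, "contour")
  if (is.null(contour)) stop("no contour supplied and cell_map carries none")
  as_contour(contour)
}

#' Count cells inside a contour
#'
#' Number of cells strictly inside or exactly on the boundary of a simple
#' closed polygon (boundary points count as inside).
#'
#' @param cells A [cell_map()] (or data.frame with `x_mm`, `y_mm`).
#' @param contour Polygon; defaults to the contour carried by `cells`.
#' @return Integer count.
#' @export
#' @examples
#' cm <- cell_map(c(0, 3), c(0, 0), contour = retina_contour())
#' count_cells(cm)  # the cell at x = 3 mm lies outside the 2.2 mm disc
count_cells <- function(cells, contour = NULL) {
  contour <- cm_contour(cells, contour)
  if (!isTRUE(attr(contour, "simple")) && !is_simple_polygon(contour)) {
    stop("contour is self-intersecting; a simple closed polygon is required")
  }
  if (nrow(cells) == 0L) return(0L)
  sum(points_in_polygon(cells$x_mm, cells$y_mm, contour))
}
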