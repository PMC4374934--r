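#' Retinal wholemount geometry
#'
#' Describes the flattened wholemount as a disc centred on the optic disc
#' (the coordinate origin), with four radial relieving cuts whose azimuths
#' orient the preparation. Coordinates are retina-centred millimetres with
#' +x nasal and +y superior for a left eye viewed from the vitreal side.
#'
#' Azimuths follow the wholemount convention used throughout the package:
#' degrees measured from the temporal axis, increasing towards superior
#' (temporal = 0, superior = 90, nasal = 180, inferior = 270). The deepest
#' relieving cut marks the superior pole.
#'
#' @param radius_mm Retinal radius in mm. The mouse wholemount spans roughly
#'   4.4 mm tip to tip, so the default is 2.2.
#' @param cut_angles Azimuths (degrees) of the four radial cuts; the first is
#'   the deepest and marks the superior pole.
#' @param cut_depth_frac Depth of the relieving cuts as a fraction of the
#'   radius; the first cut is rendered half again as deep.
#' @return An object of class `retina_geometry`.
#' @export
#' @examples
#' geom <- retina_geometry()
#' contour <- retina_contour(geom)
#' polygon_area(contour)
retina_geometry <- function(radius_mm = 2.2,
                            cut_angles = c(90, 0, 180, 270),
                            cut_depth_frac = 0.12) {
  stopifnot(is.numeric(radius_mm), length(radius_mm) == 1L, radius_mm > 0)
  ca <- cut_angles %% 360
  if (anyDuplicated(ca)) {
    stop("cut_angles must be distinct modulo 360 degrees")
  }
  if (cut_depth_frac < 0 || cut_depth_frac >= 1) {
    stop("cut_depth_frac must lie in [0, 1)")
  }
  structure(
    list(
      radius_mm = radius_mm,
      optic_disc = c(x = 0, y = 0),
      orientation = "left eye, +x nasal, +y superior, vitreal side up",
      cut_angles = cut_angles,
      cut_depth_frac = cut_depth_frac
    ),
    class = "retina_geometry"
  )
}

#' @export
print.retina_geometry <- function(x, ...) {
  cat("Retinal wholemount geometry\n")
  cat(sprintf("  radius: %.3f mm (disc centred on the optic disc)\n", x$radius_mm))
  cat(sprintf("  orientation: %s\n", x$orientation))
  cat(sprintf("  radial cuts at azimuths: %s deg (first = deepest, superior)\n",
              paste(x$cut_angles, collapse = ", ")))
  invisible(x)
}

# Azimuth (deg, temporal = 0, increasing towards superior) -> math angle (rad)
# in the (+x nasal, +y superior) frame. Temporal sits at math angle 180 deg and
# azimuth increases towards +y, so math_deg = 180 - azimuth.
azimuth_to_math_rad <- function(azimuth_deg) {
  (180 - azimuth_deg) * pi / 180
}

# Math angle (rad) of points (x, y) -> azimuth in [0, 360).
math_rad_to_azimuth <- function(theta_rad) {
  (180 - theta_rad * 180 / pi) %% 360
}

#' Azimuth of points about the optic disc
#'
#' @param x,y Coordinates in mm relative to the optic disc.
#' @return Azimuth in degrees, `[0, 360)`, temporal = 0, superior = 90.
#' @export
point_azimuth <- function(x, y) {
  math_rad_to_azimuth(atan2(y, x))
}

#' Retinal contour polygon
#'
#' Samples the wholemount outline as a closed polygon: a circle of the
#' configured radius with triangular notches at the relieving cuts, the
#' superior cut being the deepest.
#'
#' @param geom A [retina_geometry()].
#' @param n_vertices Number of vertices used to sample the circular outline.
#' @return A data.frame with columns `x_mm`, `y_mm`; first vertex is not
#'   repeated (implicitly closed).
#' @export
retina_contour <- function(geom = retina_geometry(), n_vertices = 360L) {
  stopifnot(inherits(geom, "retina_geometry"), n_vertices >= 12L)
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  r <- rep(geom$radius_mm, n_vertices)
  depth <- geom$cut_depth_frac * geom$radius_mm *
    c(1.5, rep(1, length(geom$cut_angles) - 1L))
  half_width <- 2 * pi / 180  # angular half-width of each cut notch
  for (k in seq_along(geom$cut_angles)) {
    cut_math <- azimuth_to_math_rad(geom$cut_angles[k])
    d <- abs(((theta - cut_math + pi) %% (2 * pi)) - pi)
    inside <- d < half_width
    r[inside] <- geom$radius_mm - depth[k] * (1 - d[inside] / half_width)
  }
  out <- data.frame(x_mm = r * cos(theta), y_mm = r * sin(theta))
  # r(theta) is single-valued, so the polygon is simple by construction
  attr(out, "simple") <- TRUE
  out
}

#' Signed area of a simple polygon (shoelace)
#'
#' @param contour Data.frame with `x_mm`, `y_mm` (closed implicitly).
#' @return Absolute area in mm^2.
#' @export
polygon_area <- function(contour) {
  contour <- as_contour(contour)
  x <- contour$x_mm
  y <- contour$y_mm
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

as_contour <- function(contour) {
  if (is.matrix(contour)) {
    contour <- data.frame(x_mm = contour[, 1], y_mm = contour[, 2])
  }
  if (!all(c("x_mm", "y_mm") %in% names(contour))) {
    stop("contour must have columns x_mm and y_mm")
  }
  if (nrow(contour) < 3L) stop("contour needs at least 3 vertices")
  # drop an explicitly repeated closing vertex
  n <- nrow(contour)
  if (contour$x_mm[1] == contour$x_mm[n] && contour$y_mm[1] == contour$y_mm[n]) {
    contour <- contour[-n, , drop = FALSE]
  }
  contour
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

#' Test whether a polygon is simple (non self-intersecting)
#'
#' Quadratic-time check over non-adjacent edge pairs; intended for the
#' modest contour sizes used here.
#' @param contour Polygon data.frame (`x_mm`, `y_mm`).
#' @return Logical scalar.
#' @export
is_simple_polygon <- function(contour) {
  contour <- as_contour(contour)
  p <- cbind(contour$x_mm, contour$y_mm)
  n <- nrow(p)
  nxt <- c(seq_len(n)[-1L], 1L)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      # skip adjacent edges (share a vertex)
      if (j == i || nxt[i] == j || nxt[j] == i) next
      if (segments_intersect(p[i, ], p[nxt[i], ], p[j, ], p[nxt[j], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Point-in-polygon test (boundary counts as inside)
#'
#' Even-odd ray casting with an explicit on-boundary check, so points lying
#' exactly on a contour edge or vertex are classified inside. This is the
#' package-wide boundary convention for cell counting.
#'
#' @param x,y Point coordinates (vectors of equal length), mm.
#' @param contour Polygon data.frame with `x_mm`, `y_mm`.
#' @param tol Distance tolerance for the on-boundary test.
#' @return Logical vector.
#' @export
points_in_polygon <- function(x, y, contour, tol = 1e-12) {
  stopifnot(length(x) == length(y))
  contour <- as_contour(contour)
  .pip_cpp(as.numeric(x), as.numeric(y),
           as.numeric(contour$x_mm), as.numeric(contour$y_mm),
           as.numeric(tol))
}
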