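# Seed handling: every generator takes an explicit seed and restores the
# caller's RNG state, so fixed seed => bit-identical output without side
# effects on the session.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a child seed from a global seed
#'
#' Deterministic fan-out of one pipeline seed into per-stage seeds
#' (Lehmer step plus offset, kept below 2^31).
#' @param seed Integer master seed.
#' @param offset Integer stage offset.
#' @return Integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, offset = 0L) {
  s <- (as.numeric(seed) %% 2147483646) + 1
  as.integer((s * 48271 + as.numeric(offset) * 7919) %% 2147483647 + 1) - 1L
}

#' Population specification for the synthetic wholemount generator
#'
#' Declares which cell population to simulate and with what spatial
#' structure. Defaults encode the study conditions: a control OHSt-traced
#' RGC population of ~38,479 cells whose density falls off linearly from
#' centre to periphery (2:1), and melanopsin RGCs (~1,059 cells) enriched
#' in the dorso-temporal retina (2:1 peak:trough cosine modulation).
#'
#' @param label One of `"OHSt"`, `"Brn3a"`, `"melanopsin"`, `"DAPI_nonRGC"`.
#' @param target_total Expected total cell count; the realized count is
#'   Poisson with this mean. Defaults per label follow the control group
#'   means (OHSt 38479, Brn3a 37936, melanopsin 1059, non-RGC GCL nuclei
#'   45471).
#' @param profile Density profile: `"radial_linear"` (centre > periphery),
#'   `"uniform"`, or `"dorsotemporal"` (radial fall-off times an angular
#'   cosine bump centred on the dorso-temporal quadrant).
#' @param centre_edge_ratio Centre:edge density ratio for the radial
#'   fall-off (default 2).
#' @param peak_trough_ratio Peak:trough ratio of the angular modulation
#'   (dorsotemporal profile only, default 2).
#' @param peak_azimuth_deg Azimuth of the angular density peak (default 45,
#'   the centre of the dorso-temporal quadrant).
#' @param min_separation_mm Optional hard-core (soma-exclusion) distance;
#'   0 gives a pure inhomogeneous Poisson pattern. Mouse RGC somas are
#'   ~8-15 um wide, so 0.008 is a realistic choice when patterns feed the
#'   image renderer.
#' @param seed RNG seed.
#' @return Object of class `population_spec`.
#' @export
population_spec <- function(label = c("OHSt", "Brn3a", "melanopsin", "DAPI_nonRGC"),
                            target_total = NULL,
                            profile = NULL,
                            centre_edge_ratio = 2,
                            peak_trough_ratio = 2,
                            peak_azimuth_deg = 45,
                            min_separation_mm = 0,
                            seed = 1L) {
  label <- match.arg(label)
  if (is.null(target_total)) {
    target_total <- switch(label,
      OHSt = 38479, Brn3a = 37936, melanopsin = 1059, DAPI_nonRGC = 45471)
  }
  if (target_total < 0) stop("target_total must be >= 0")
  if (is.null(profile)) {
    profile <- if (label == "melanopsin") "dorsotemporal" else "radial_linear"
  }
  profile <- match.arg(profile, c("radial_linear", "uniform", "dorsotemporal"))
  if (centre_edge_ratio <= 0 || peak_trough_ratio <= 0) {
    stop("density ratios must be positive")
  }
  structure(
    list(label = label, target_total = target_total, profile = profile,
         centre_edge_ratio = centre_edge_ratio,
         peak_trough_ratio = peak_trough_ratio,
         peak_azimuth_deg = peak_azimuth_deg,
         min_separation_mm = min_separation_mm, seed = seed),
    class = "population_spec"
  )
}

# Unnormalized density of a population spec at polar position
# (r mm from optic disc, azimuth deg). Vectorized.
profile_density <- function(spec, r, azimuth_deg, radius_mm) {
  k <- spec$centre_edge_ratio
  radial <- switch(spec$profile,
    uniform = rep(1, length(r)),
    radial_linear = ,
    dorsotemporal = k - (k - 1) * pmin(r / radius_mm, 1)
  )
  if (spec$profile == "dorsotemporal") {
    m <- spec$peak_trough_ratio
    ang <- 1 + (m - 1) * (1 + cos((azimuth_deg - spec$peak_azimuth_deg) * pi / 180)) / 2
    radial * ang
  } else {
    radial
  }
}

#' Generate a synthetic wholemount cell population
#'
#' Simulates an inhomogeneous Poisson point pattern inside the retinal
#' contour: the realized count is Poisson with mean `spec$target_total`
#' and positions are drawn i.i.d. from the spec's density profile by
#' rejection sampling. With `min_separation_mm > 0` proposals violating
#' the hard-core distance are rejected (somas cannot overlap), giving a
#' simple sequential-inhibition pattern with the same target count.
#'
#' @param geom A [retina_geometry()].
#' @param spec A [population_spec()].
#' @param contour Optional precomputed contour polygon (defaults to
#'   [retina_contour()] of `geom`).
#' @return A [cell_map()] carrying the contour and population label.
#' @export
#' @examples
#' geom <- retina_geometry()
#' cm <- generate_population(geom, population_spec("melanopsin", seed = 7))
#' nrow(cm)  # ~1059
generate_population <- function(geom, spec, contour = NULL) {
  stopifnot(inherits(geom, "retina_geometry"), inherits(spec, "population_spec"))
  if (spec$target_total < 0) stop("target_total must be >= 0")
  if (is.null(contour)) contour <- retina_contour(geom)
  R <- geom$radius_mm

  # guard against profiles that go negative anywhere on the domain
  rg <- seq(0, R, length.out = 64)
  ag <- seq(0, 359, by = 5)
  dens_grid <- profile_density(spec, rep(rg, each = length(ag)),
                               rep(ag, length(rg)), R)
  if (any(dens_grid < 0)) stop("density profile is negative somewhere on the retina")
  dens_max <- max(dens_grid) * 1.0000001

  bbox_x <- range(contour$x_mm)
  bbox_y <- range(contour$y_mm)
  with_local_seed(spec$seed, {
    n <- stats::rpois(1L, spec$target_total)
    xs <- numeric(0); ys <- numeric(0)
    hard <- spec$min_separation_mm
    guard <- 0L
    while (length(xs) < n) {
      m <- max(2L * (n - length(xs)), 256L)
      px <- stats::runif(m, bbox_x[1], bbox_x[2])
      py <- stats::runif(m, bbox_y[1], bbox_y[2])
      u <- stats::runif(m)
      r <- sqrt(px^2 + py^2)
      az <- point_azimuth(px, py)
      ok <- u * dens_max <= profile_density(spec, r, az, R)
      ok[ok] <- points_in_polygon(px[ok], py[ok], contour)
      px <- px[ok]; py <- py[ok]
      if (hard > 0 && length(px) > 0) {
        keep <- logical(length(px))
        for (i in seq_along(px)) {
          if (length(xs) + sum(keep) >= n) break
          cand_x <- c(xs, px[keep]); cand_y <- c(ys, py[keep])
          if (length(cand_x) == 0 ||
              min((cand_x - px[i])^2 + (cand_y - py[i])^2) >= hard^2) {
            keep[i] <- TRUE
          }
        }
        px <- px[keep]; py <- py[keep]
      }
      take <- min(length(px), n - length(xs))
      xs <- c(xs, px[seq_len(take)])
      ys <- c(ys, py[seq_len(take)])
      guard <- guard + 1L
      if (guard > 10000L) stop("rejection sampling failed to converge; ",
                               "is min_separation_mm feasible at this density?")
    }
    cell_map(xs, ys, population = spec$label, contour = contour)
  })
}

#' Lesion specification: sectorial wedges plus diffuse loss
#'
#' Ocular hypertension produces pie-shaped sectors of RGC loss with the
#' apex at the optic disc and the base at the periphery, superimposed on
#' diffuse loss across the whole retina. A lesion is a set of angular
#' wedges, each removing cells with probability `loss_fraction`, plus an
#' independent diffuse removal probability applied everywhere.
#'
#' @param wedges Data.frame (or list coercible to one) with columns
#'   `start_deg`, `span_deg`, `loss_fraction`: each wedge starts at azimuth
#'   `start_deg` and extends `span_deg` degrees towards superior.
#' @param diffuse_fraction Probability in `[0, 1]` of removing each cell
#'   independently of the wedges.
#' @param diffuse_profile `"uniform"` (default) or `"eccentricity"`, in
#'   which case the diffuse removal probability scales linearly with
#'   distance from the optic disc (mean preserved).
#' @return Object of class `lesion_spec`.
#' @export
lesion_spec <- function(wedges = NULL, diffuse_fraction = 0,
                        diffuse_profile = c("uniform", "eccentricity")) {
  diffuse_profile <- match.arg(diffuse_profile)
  if (is.null(wedges)) {
    wedges <- data.frame(start_deg = numeric(0), span_deg = numeric(0),
                         loss_fraction = numeric(0))
  }
  wedges <- as.data.frame(wedges)
  req <- c("start_deg", "span_deg", "loss_fraction")
  if (!all(req %in% names(wedges))) {
    stop("wedges needs columns start_deg, span_deg, loss_fraction")
  }
  if (any(wedges$loss_fraction < 0 | wedges$loss_fraction > 1) ||
      diffuse_fraction < 0 || diffuse_fraction > 1) {
    stop("loss fractions must lie in [0, 1]")
  }
  if (any(wedges$span_deg <= 0 | wedges$span_deg > 360)) {
    stop("wedge spans must lie in (0, 360]")
  }
  structure(list(wedges = wedges, diffuse_fraction = diffuse_fraction,
                 diffuse_profile = diffuse_profile),
            class = "lesion_spec")
}

in_wedge <- function(azimuth_deg, start_deg, span_deg) {
  ((azimuth_deg - start_deg) %% 360) < span_deg |
    (span_deg >= 360)
}

#' Apply a sectorial/diffuse lesion to a cell pattern
#'
#' Each cell inside a wedge is removed with that wedge's loss fraction;
#' overlapping wedges combine as `1 - prod(1 - f_i)`. Every surviving cell
#' is additionally removed with the diffuse fraction. Removals are
#' independent Bernoulli draws; survivors keep their exact coordinates
#' (the lesion never adds or moves points).
#'
#' @param cells A [cell_map()].
#' @param lesion A [lesion_spec()].
#' @param seed RNG seed.
#' @return A [cell_map()] containing the surviving subset.
#' @export
apply_lesion <- function(cells, lesion, seed = 1L) {
  stopifnot(inherits(lesion, "lesion_spec"))
  n <- nrow(cells)
  if (n == 0L) return(cells)
  az <- point_azimuth(cells$x_mm, cells$y_mm)
  p_survive <- rep(1, n)
  for (i in seq_len(nrow(lesion$wedges))) {
    w <- lesion$wedges[i, ]
    hit <- in_wedge(az, w$start_deg, w$span_deg)
    p_survive[hit] <- p_survive[hit] * (1 - w$loss_fraction)
  }
  d <- lesion$diffuse_fraction
  if (d > 0) {
    if (lesion$diffuse_profile == "eccentricity") {
      r <- sqrt(cells$x_mm^2 + cells$y_mm^2)
      rmax <- max(r, .Machine$double.eps)
      # linear in r, scaled to keep the mean removal equal to d
      local_d <- pmin(1, d * 2 * r / rmax * (1 / (2 * mean(r) / rmax)))
      p_survive <- p_survive * (1 - local_d)
    } else {
      p_survive <- p_survive * (1 - d)
    }
  }
  with_local_seed(seed, {
    keep <- stats::runif(n) < p_survive
    cells[keep, , drop = FALSE]
  })
}

#' Superior colliculus area-profile specification
#'
#' The innervated area of the contralateral SC is measured on serial
#' 30-um coronal sections ordered by Bregma coordinate (anterior -3.08 mm
#' to posterior -4.72 mm). The generator draws per-section labelled areas
#' from a smooth baseline profile, attenuated inside deafferentation
#' patches, with optional multiplicative noise; sections lost to mounting
#' artefacts can be dropped.
#'
#' @param bregma_range Anterior/posterior limits (mm), default
#'   `c(-3.08, -4.72)`.
#' @param section_thickness_mm Section thickness, default 0.030.
#' @param baseline_area_fn Function of Bregma (mm) returning labelled area
#'   (mm^2); default a smooth positive dome peaking near the SC centre.
#' @param patches Data.frame with `bregma_start`, `bregma_end`,
#'   `area_loss_fraction` describing deafferentation patches.
#' @param unusable_sections Integer indices of sections dropped from the
#'   output (artefacts).
#' @param noise_cv Coefficient of variation of multiplicative Gaussian
#'   area noise (0 = noiseless).
#' @param seed RNG seed.
#' @return Object of class `sc_profile_spec`.
#' @export
sc_profile_spec <- function(bregma_range = c(-3.08, -4.72),
                            section_thickness_mm = 0.030,
                            baseline_area_fn = NULL,
                            patches = NULL,
                            unusable_sections = integer(0),
                            noise_cv = 0,
                            seed = 1L) {
  if (bregma_range[1] == bregma_range[2]) stop("bregma_range endpoints must differ")
  if (section_thickness_mm <= 0) stop("section_thickness_mm must be > 0")
  if (is.null(baseline_area_fn)) {
    mid <- mean(bregma_range)
    half <- abs(diff(bregma_range)) / 2
    baseline_area_fn <- function(b) 0.15 + 0.75 * pmax(0, 1 - ((b - mid) / half)^2)
  }
  if (is.null(patches)) {
    patches <- data.frame(bregma_start = numeric(0), bregma_end = numeric(0),
                          area_loss_fraction = numeric(0))
  }
  patches <- as.data.frame(patches)
  if (nrow(patches) > 0 &&
      any(patches$area_loss_fraction < 0 | patches$area_loss_fraction > 1)) {
    stop("area_loss_fraction must lie in [0, 1]")
  }
  structure(list(bregma_range = bregma_range,
                 section_thickness_mm = section_thickness_mm,
                 baseline_area_fn = baseline_area_fn,
                 patches = patches,
                 unusable_sections = as.integer(unusable_sections),
                 noise_cv = noise_cv, seed = seed),
            class = "sc_profile_spec")
}

#' Generate a synthetic SC labelled-area series
#'
#' @param spec An [sc_profile_spec()].
#' @return A [section_series()] with one record per usable section.
#' @export
generate_sc_profile <- function(spec) {
  stopifnot(inherits(spec, "sc_profile_spec"))
  step <- spec$section_thickness_mm * sign(spec$bregma_range[2] - spec$bregma_range[1])
  bregma <- seq(spec$bregma_range[1], spec$bregma_range[2], by = step)
  area <- spec$baseline_area_fn(bregma)
  if (any(area < 0)) stop("baseline_area_fn produced negative areas")
  for (i in seq_len(nrow(spec$patches))) {
    p <- spec$patches[i, ]
    lo <- min(p$bregma_start, p$bregma_end)
    hi <- max(p$bregma_start, p$bregma_end)
    hit <- bregma >= lo & bregma <= hi
    area[hit] <- area[hit] * (1 - p$area_loss_fraction)
  }
  if (spec$noise_cv > 0) {
    area <- with_local_seed(spec$seed, {
      pmax(0, area * (1 + stats::rnorm(length(area), sd = spec$noise_cv)))
    })
  }
  keep <- setdiff(seq_along(bregma), spec$unusable_sections)
  section_series(bregma[keep], area[keep],
                 section_thickness_mm = spec$section_thickness_mm)
}

#' Generate a synthetic intraocular-pressure time series
#'
#' Emulates the laser-photocoagulation pressure course: a rapid rise
#' already evident at 1 h, a maximum at `peak_time_h` (24 h by default),
#' sustained elevation over the first days and return to baseline by day
#' 7. The deterministic course is a saturating power-law rise to the peak
#' followed by exponential decay; Gaussian measurement noise is added on
#' top.
#'
#' @param peak_mmHg Peak pressure (mmHg) at `peak_time_h`.
#' @param peak_time_h Time of the peak (h); must be one of `times_h`.
#' @param baseline_mmHg Pre-laser baseline pressure.
#' @param times_h Sampling grid in hours (default 0 to day 7).
#' @param noise_sd SD of additive measurement noise (mmHg).
#' @param decay_tau_h Time constant of the post-peak decay.
#' @param seed RNG seed.
#' @return Data.frame with `time_h`, `iop_mmhg`.
#' @export
generate_iop_series <- function(peak_mmHg = 30, peak_time_h = 24,
                                baseline_mmHg = 15,
                                times_h = c(0, 1, 6, 12, 24, 48, 96, 168),
                                noise_sd = 1, decay_tau_h = 40, seed = 1L) {
  if (peak_mmHg < 0 || baseline_mmHg < 0) stop("pressures must be non-negative")
  if (!peak_time_h %in% times_h) stop("peak_time_h must lie on the sampling grid")
  delta <- peak_mmHg - baseline_mmHg
  f <- function(t) {
    ifelse(t <= 0, baseline_mmHg,
      ifelse(t <= peak_time_h,
        baseline_mmHg + delta * (t / peak_time_h)^0.3,
        baseline_mmHg + delta * exp(-(t - peak_time_h) / decay_tau_h)))
  }
  iop <- f(times_h)
  if (noise_sd > 0) {
    iop <- with_local_seed(seed, iop + stats::rnorm(length(times_h), sd = noise_sd))
  }
  data.frame(time_h = times_h, iop_mmhg = pmax(0, iop))
}

#' Generate a cohort of IOP series
#'
#' One series per animal with per-animal peak pressures, for exercising
#' the inclusion filter (peak > 25 mmHg within 48 h).
#'
#' @param peaks_mmHg Vector of per-animal peak pressures.
#' @param animal_ids Optional ids (default `animal_1 ...`).
#' @param seed RNG seed (fanned out per animal).
#' @param ... Passed to [generate_iop_series()].
#' @return Long data.frame `animal_id`, `eye`, `time_h`, `iop_mmhg`.
#' @export
generate_iop_cohort <- function(peaks_mmHg, animal_ids = NULL, seed = 1L, ...) {
  n <- length(peaks_mmHg)
  if (is.null(animal_ids)) animal_ids <- sprintf("animal_%02d", seq_len(n))
  out <- lapply(seq_len(n), function(i) {
    s <- generate_iop_series(peak_mmHg = peaks_mmHg[i],
                             seed = derive_seed(seed, i), ...)
    data.frame(animal_id = animal_ids[i], eye = "LE", s)
  })
  do.call(rbind, out)
}
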