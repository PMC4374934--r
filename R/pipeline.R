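#' Pipeline configuration
#'
#' Nested per-stage parameter blocks with a single global seed that fans
#' out deterministically to stage seeds. Unknown keys are rejected so
#' typos cannot silently fall back to defaults; a config round-trips
#' losslessly through its JSON serialization.
#'
#' @param seed Global RNG seed.
#' @param out_dir Output directory.
#' @param stages Character vector of stages to run, in order, from
#'   `c("cohort", "iop", "detect", "topography", "volumetry", "stats")`.
#' @param cohort Block: `n_animals`, `population`, `target_total`,
#'   `timepoint`, lesion fields `wedge_start_deg`, `wedge_span_deg`,
#'   `wedge_loss`, `diffuse_loss`.
#' @param iop Block: `peak_treated_mmHg`, `baseline_mmHg`, `threshold`.
#' @param detect Block: `field_w_mm`, `field_h_mm`, `density_per_mm2`,
#'   `min_separation_mm`.
#' @param topography Block: `bin_size_mm`, `scale_max`, `n_wedges`.
#' @param volumetry Block: `patch_loss`, `patch_frac`, `noise_cv`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("rgcmap_run_"),
                            stages = c("cohort", "iop", "detect",
                                       "topography", "volumetry", "stats"),
                            cohort = list(), iop = list(), detect = list(),
                            topography = list(), volumetry = list()) {
  known_stages <- c("cohort", "iop", "detect", "topography", "volumetry", "stats")
  if (!all(stages %in% known_stages)) {
    stop("unknown stage(s): ", paste(setdiff(stages, known_stages), collapse = ", "))
  }
  defaults <- list(
    cohort = list(n_animals = 7L, population = "OHSt", target_total = 38479,
                  timepoint = "2w", wedge_start_deg = 45, wedge_span_deg = 90,
                  wedge_loss = 1.0, diffuse_loss = 1 / 3),
    iop = list(peak_treated_mmHg = 32, baseline_mmHg = 15, threshold = 25),
    detect = list(field_w_mm = 0.45, field_h_mm = 0.34,
                  density_per_mm2 = 4000, min_separation_mm = 0.008),
    topography = list(bin_size_mm = 0.1, scale_max = 4800, n_wedges = 24L),
    volumetry = list(patch_loss = 0.5, patch_frac = 1.0, noise_cv = 0.05)
  )
  merge_block <- function(name, user) {
    unknown <- setdiff(names(user), names(defaults[[name]]))
    if (length(unknown) > 0) {
      stop("unknown key(s) in ", name, " block: ", paste(unknown, collapse = ", "))
    }
    utils::modifyList(defaults[[name]], user)
  }
  structure(
    list(seed = as.integer(seed), out_dir = out_dir, stages = stages,
         cohort = merge_block("cohort", cohort),
         iop = merge_block("iop", iop),
         detect = merge_block("detect", detect),
         topography = merge_block("topography", topography),
         volumetry = merge_block("volumetry", volumetry)),
    class = "pipeline_config"
  )
}

#' Save / load a pipeline configuration
#'
#' JSON serialization; loading re-validates every key, so the round trip
#' is lossless and unknown keys are still rejected.
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @return The path / the re-validated config.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(seed = raw$seed, out_dir = raw$out_dir, stages = raw$stages,
                  cohort = as.list(raw$cohort), iop = as.list(raw$iop),
                  detect = as.list(raw$detect),
                  topography = as.list(raw$topography),
                  volumetry = as.list(raw$volumetry))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Chains generation, the IOP inclusion filter, detection QC, topography,
#' SC volumetry and cohort statistics according to the configured stages.
#' Every artifact is written under `config$out_dir` and listed in a
#' manifest with parameters, seed and content hash, so identical
#' config + seed reproduce identical hashes. A stage failure halts the
#' run with a machine-readable error record in the manifest.
#'
#' The default configuration is the demonstration cohort: 7 animals with
#' control OHSt populations targeting 38,479 RGCs, treated eyes carrying
#' a 90-degree ablated sector plus 1/3 diffuse loss (designed total loss
#' 50%).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the report list (also written as `report.json`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed, stages = config$stages)
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fn) {
    if (!(name %in% config$stages)) return(NULL)
    res <- tryCatch(fn(), error = function(e) {
      rec <- list(stage = name, error = conditionMessage(e))
      jsonlite::write_json(rec, file.path(config$out_dir, "error.json"),
                           auto_unbox = TRUE)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    report[[name]] <<- res
    invisible(res)
  }

  run_stage("cohort", function() stage_cohort(config, state))
  run_stage("iop", function() stage_iop(config, state))
  run_stage("detect", function() stage_detect(config))
  run_stage("topography", function() stage_topography(config, state))
  run_stage("volumetry", function() stage_volumetry(config))
  run_stage("stats", function() stage_stats(config, state))

  report$manifest <- build_manifest(config)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}

stage_cohort <- function(config, state) {
  cc <- config$cohort
  geom <- retina_geometry()
  contour <- retina_contour(geom)
  lesion <- lesion_spec(
    wedges = data.frame(start_deg = cc$wedge_start_deg,
                        span_deg = cc$wedge_span_deg,
                        loss_fraction = cc$wedge_loss),
    diffuse_fraction = cc$diffuse_loss)
  records <- list()
  maps <- list()
  for (i in seq_len(cc$n_animals)) {
    id <- sprintf("animal_%02d", i)
    s_re <- derive_seed(config$seed, 100L + i)
    spec <- population_spec(cc$population, target_total = cc$target_total,
                            seed = s_re)
    re <- generate_population(geom, spec, contour = contour)
    le <- apply_lesion(re, lesion, seed = derive_seed(config$seed, 200L + i))
    write_cells_csv(re, file.path(config$out_dir, paste0(id, "_RE.csv")),
                    animal_id = id, eye = "RE")
    write_cells_csv(le, file.path(config$out_dir, paste0(id, "_LE.csv")),
                    animal_id = id, eye = "LE")
    records[[length(records) + 1L]] <- data.frame(
      animal_id = id, eye = c("RE", "LE"), timepoint = cc$timepoint,
      population = cc$population,
      value = c(count_cells(re, contour), count_cells(le, contour)))
    if (i == 1L) maps <- list(control = re, treated = le)
  }
  write_contour_csv(contour, file.path(config$out_dir, "contour.csv"))
  state$records <- do.call(rbind, records)
  state$maps <- maps
  state$contour <- contour
  wedge_frac <- cc$wedge_span_deg / 360 * cc$wedge_loss
  list(n_animals = cc$n_animals,
       designed_loss = 100 * (1 - (1 - wedge_frac) * (1 - cc$diffuse_loss)))
}

stage_iop <- function(config, state) {
  ic <- config$iop
  n <- config$cohort$n_animals
  peaks <- rep(ic$peak_treated_mmHg, n)
  iop <- generate_iop_cohort(peaks, animal_ids = sprintf("animal_%02d", seq_len(n)),
                             seed = derive_seed(config$seed, 300L),
                             baseline_mmHg = ic$baseline_mmHg)
  write_iop_csv(iop, file.path(config$out_dir, "iop.csv"))
  state$iop <- iop
  pk <- vapply(split(iop, iop$animal_id), function(s) iop_peak(s)$peak_mmHg, 1)
  list(n_series = n, min_peak = min(pk), max_peak = max(pk))
}

stage_detect <- function(config) {
  dc <- config$detect
  seed <- derive_seed(config$seed, 400L)
  area <- dc$field_w_mm * dc$field_h_mm
  # one acquisition frame at the target density, rendered and re-detected
  geom <- retina_geometry(radius_mm = max(dc$field_w_mm, dc$field_h_mm))
  n_target <- round(dc$density_per_mm2 * area)
  box <- data.frame(
    x_mm = c(0, dc$field_w_mm, dc$field_w_mm, 0),
    y_mm = c(0, 0, dc$field_h_mm, dc$field_h_mm))
  spec <- population_spec("OHSt", target_total = n_target, profile = "uniform",
                          min_separation_mm = dc$min_separation_mm, seed = seed)
  cells <- generate_population(geom, spec, contour = box)
  grid <- frame_grid(c(0, dc$field_w_mm, 0, dc$field_h_mm))
  ts <- render_tiles(cells, grid, seed = derive_seed(config$seed, 401L))
  write_tile_set(ts, file.path(config$out_dir, "tiles"))
  montage <- assemble_montage(ts$tiles, ts$grid)
  det <- detect_cells(montage)
  params <- detection_params()
  qc <- match_detections(det, ts$truth,
                         match_radius_mm = 2 * params$psf_sigma_px *
                           grid$mm_per_pixel)
  jsonlite::write_json(
    list(n_truth = qc$n_truth, n_detected = qc$n_detected,
         recall = qc$recall, precision = qc$precision,
         params = unclass(params)[c("psf_sigma_px", "min_area_px",
                                    "max_area_px", "min_separation_px")]),
    file.path(config$out_dir, "detection_qc.json"), auto_unbox = TRUE)
  qc[c("recall", "precision", "n_truth", "n_detected")]
}

stage_topography <- function(config, state) {
  tc <- config$topography
  if (is.null(state$maps)) stop("topography stage needs the cohort stage")
  iso <- isodensity(state$maps$treated, state$contour,
                    bin_size_mm = tc$bin_size_mm, scale_max = tc$scale_max)
  utils::write.csv(
    data.frame(row = as.vector(row(iso$density)),
               col = as.vector(col(iso$density)),
               count = as.vector(iso$count),
               density = as.vector(iso$density)),
    file.path(config$out_dir, "isodensity.csv"), row.names = FALSE)
  wp <- wedge_loss_profile(state$maps$treated, state$maps$control,
                           n_wedges = tc$n_wedges)
  utils::write.csv(wp$wedges, file.path(config$out_dir, "wedge_profile.csv"),
                   row.names = FALSE)
  list(isodensity_cells = iso$total_count,
       sector = if (is.null(wp$sector)) NULL else
         wp$sector[c("start_deg", "span_deg", "loss_fraction")])
}

stage_volumetry <- function(config) {
  vc <- config$volumetry
  ctrl_spec <- sc_profile_spec(noise_cv = vc$noise_cv,
                               seed = derive_seed(config$seed, 500L))
  ctrl <- generate_sc_profile(ctrl_spec)
  rng <- ctrl_spec$bregma_range
  patch_end <- rng[1] + vc$patch_frac * (rng[2] - rng[1])
  les_spec <- sc_profile_spec(
    patches = data.frame(bregma_start = rng[1], bregma_end = patch_end,
                         area_loss_fraction = vc$patch_loss),
    noise_cv = vc$noise_cv, seed = derive_seed(config$seed, 501L))
  les <- generate_sc_profile(les_spec)
  write_sections_csv(ctrl, file.path(config$out_dir, "sc_control.csv"))
  write_sections_csv(les, file.path(config$out_dir, "sc_treated.csv"))
  f_ctrl <- integrate_volume(fit_area_profile(ctrl))
  f_les <- integrate_volume(fit_area_profile(les),
                            range_mm = f_ctrl$integration_range_mm)
  pi <- percent_innervation(f_les, f_ctrl)
  c(pi, list(r2_control = f_ctrl$r_squared, r2_treated = f_les$r_squared))
}

stage_stats <- function(config, state) {
  if (is.null(state$records)) stop("stats stage needs the cohort stage")
  cohort <- cohort_table(state$records)
  if (!is.null(state$iop)) {
    cohort <- filter_by_iop(cohort, threshold = config$iop$threshold,
                            iop_series = state$iop)
  }
  summ <- group_summary(cohort)
  ctrl <- summ[summ$eye == "RE", ]
  trt <- summ[summ$eye == "LE", ]
  pl <- percent_loss(ctrl$mean[1], trt$mean[1])
  sf <- survival_fraction(ctrl$mean[1], trt$mean[1])
  mw <- mann_whitney(
    cohort$records$value[cohort$records$eye == "RE"],
    cohort$records$value[cohort$records$eye == "LE"])
  utils::write.csv(summ, file.path(config$out_dir, "group_summary.csv"),
                   row.names = FALSE)
  list(control_mean = ctrl$mean[1], control_sd = ctrl$sd[1],
       treated_mean = trt$mean[1], treated_sd = trt$sd[1],
       percent_loss = pl$percent, percent_loss_rounded = pl$percent_rounded,
       percent_survival = sf$percent,
       mann_whitney_p = mw$p_value, n_included = length(unique(cohort$records$animal_id)))
}

build_manifest <- function(config) {
  files <- sort(list.files(config$out_dir, recursive = TRUE))
  files <- setdiff(files, c("report.json"))
  hashes <- tools::md5sum(file.path(config$out_dir, files))
  list(seed = config$seed,
       files = data.frame(file = files, md5 = unname(hashes)))
}
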