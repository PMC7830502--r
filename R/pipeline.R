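#' Validate and complete a pipeline configuration
#'
#' Reads a YAML file (or takes a list) and applies the workflow defaults
#' wherever a field is omitted: VIF cutoff 5, correlation cutoff 0.75,
#' pseudo-absence ratio 10, train fraction 0.7, EOO buffer 0.1 degrees,
#' cell area 4 km2, threshold rules mtp/mtss/fixed_05, dispersal
#' scenarios full/none. Every applied default is recorded in
#' `config$defaults_applied`. Schema violations raise an error naming
#' the field and its constraint.
#'
#' @param config path to a YAML file, or a (possibly empty) list.
#' @return a completed config list of class `pipeline_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  defaults <- list(vif_max = 5, r_max = 0.75, pa_ratio = 10,
                   train_fraction = 0.7, buffer_deg = 0.1,
                   cell_area_km2 = 4, alpha = NULL,
                   threshold_rules = c("mtp", "mtss", "fixed_05"),
                   dispersal = c("full", "none"),
                   families = c("glm", "gam", "rf", "brt"),
                   replicates = 1,
                   allowed_landcover = 1L,
                   excluded_landcover = c(3L, 4L),
                   apply_landcover_mask = TRUE,
                   n_permutations = 10,
                   current_status = NA_character_,
                   trend = NA_character_,
                   species = "species",
                   seed = 1)
  applied <- setdiff(names(defaults), names(config))
  for (n in applied) config[[n]] <- defaults[[n]]
  with(config, {
    if (!is.numeric(vif_max) || vif_max <= 0)
      stop("config field 'vif_max' must be a positive number")
    if (!is.numeric(r_max) || r_max <= 0 || r_max > 1)
      stop("config field 'r_max' must be in (0, 1]")
    if (pa_ratio < 1) stop("config field 'pa_ratio' must be >= 1")
    if (train_fraction <= 0 || train_fraction >= 1)
      stop("config field 'train_fraction' must be in (0, 1)")
    if (buffer_deg < 0) stop("config field 'buffer_deg' must be >= 0")
    if (cell_area_km2 <= 0) stop("config field 'cell_area_km2' must be > 0")
    bad <- setdiff(threshold_rules, c("mtp", "mtss", "fixed_05"))
    if (length(bad)) stop("unknown threshold rule(s): ",
                          paste(bad, collapse = ", "))
    bad <- setdiff(dispersal, c("full", "none"))
    if (length(bad)) stop("unknown dispersal scenario(s): ",
                          paste(bad, collapse = ", "))
  })
  config$defaults_applied <- applied
  class(config) <- c("pipeline_config", "list")
  config
}

#' Run the full assessment pipeline for one species
#'
#' Orchestrates the whole workflow on in-memory objects: occurrence
#' cleaning, collinearity filtering, pseudo-absence sampling, ensemble
#' fitting, threshold binarization of the current and each future
#' suitability surface, land-cover and EOO masking, occupancy counting
#' under both dispersal scenarios, and risk categorization. Each stage
#' draws its seed deterministically from the master seed, so the run is
#' bit-reproducible and adding a stage does not reshuffle the others.
#'
#' @param occurrences an [occurrence_set] (raw; cleaning is applied).
#' @param current_stack a [predictor_stack] of current climate layers.
#' @param future_stacks named list of future `predictor_stack`s (one per
#'   climate scenario); several stacks for one scenario may be averaged
#'   beforehand with [average_stacks()].
#' @param landcover optional categorical [raster_grid]; when present,
#'   occurrence cleaning drops excluded classes and binary maps are
#'   masked to `config$allowed_landcover`.
#' @param config a [validate_config()] list (or raw list/path).
#' @param out_dir optional directory; when given, all artifacts
#'   (metrics CSV, assessment CSV, suitability and change rasters, EOO
#'   GeoJSON, run manifest JSON) are written under it.
#' @return list of class `pipeline_result` with `model`
#'   (the fitted [ensemble_sdm]), `selection` (collinearity report),
#'   `occurrences` (cleaned), `eoo`, `importance`, `aoo_table`
#'   (data.frame), `assessment` (a `risk_assessment`), `manifest`.
#' @export
run_pipeline <- function(occurrences, current_stack, future_stacks,
                         landcover = NULL, config = list(), out_dir = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config
  else validate_config(config)
  seed <- cfg$seed
  manifest <- list(seed = seed, defaults_applied = cfg$defaults_applied,
                   stages = character(0), warnings = character(0),
                   outputs = character(0))
  note <- function(stage) manifest$stages <<- c(manifest$stages, stage)
  grid <- grid_def(current_stack[[names(current_stack)[1]]])

  note("clean_occurrences")
  occ <- clean_occurrences(occurrences, grid, landcover = landcover,
                           excluded_classes = cfg$excluded_landcover)
  if (nrow(occ) < 3) stop("fewer than 3 occurrence records after cleaning")

  note("pseudo_absences")
  pa <- sample_pseudo_absences(current_stack, occ, ratio = cfg$pa_ratio,
                               seed = stage_seed(seed, "pseudo_absences"))
  table <- build_sample_table(current_stack, occ, pa)

  note("predictor_selection")
  selection <- select_predictors(table, vif_max = cfg$vif_max,
                                 r_max = cfg$r_max)

  note("ensemble_fit")
  model <- ensemble_sdm(table, variables = selection$retained,
                        families = cfg$families,
                        train_fraction = cfg$train_fraction,
                        replicates = cfg$replicates,
                        seed = stage_seed(seed, "ensemble_fit"))

  note("variable_importance")
  importance <- variable_importance(model, n_permutations = cfg$n_permutations,
                                    seed = stage_seed(seed, "importance"))

  note("eoo")
  eoo <- alpha_hull(occ, alpha = cfg$alpha, buffer_deg = cfg$buffer_deg)

  note("surfaces")
  current_surface <- predict(model, current_stack)
  future_surfaces <- lapply(future_stacks, function(s) predict(model, s))

  thr_value <- function(rule) switch(rule, mtp = model$thresholds$mtp,
                                     mtss = model$thresholds$mtss,
                                     fixed_05 = 0.5)
  mask_all <- function(surface, rule) {
    b <- binarize(surface, thr_value(rule))
    if (!is.null(landcover) && isTRUE(cfg$apply_landcover_mask))
      b <- mask_by_landcover(b, landcover, cfg$allowed_landcover)
    mask_by_polygon(b, eoo)
  }

  note("range_metrics")
  aoo_rows <- list()
  change_maps <- list()
  for (rule in cfg$threshold_rules) {
    cur_bin <- mask_all(current_surface, rule)
    cur_aoo <- compute_aoo(cur_bin, cfg$cell_area_km2, rule, "current")
    for (scn in names(future_surfaces)) {
      fut_bin <- mask_all(future_surfaces[[scn]], rule)
      change <- make_change_map(cur_bin, fut_bin)
      for (disp in cfg$dispersal) {
        ch <- apply_dispersal(change, disp)
        change_maps[[paste(scn, rule, disp, sep = "_")]] <- ch
        fut_aoo <- aoo_from_change(ch, cfg$cell_area_km2, rule)
        aoo_rows[[length(aoo_rows) + 1L]] <- data.frame(
          species = cfg$species, scenario = scn, threshold_rule = rule,
          dispersal = disp, threshold = thr_value(rule),
          cells_current = cur_aoo$cell_count,
          cells_future = fut_aoo$cell_count,
          area_current_km2 = cur_aoo$area_km2,
          area_future_km2 = fut_aoo$area_km2,
          change_pct = if (cur_aoo$cell_count > 0)
            aoo_change_percent(cur_aoo, fut_aoo) else NA_real_)
      }
    }
  }
  aoo_table <- do.call(rbind, aoo_rows)

  note("risk_assessment")
  ok <- !is.na(aoo_table$change_pct)
  if (!any(ok)) stop("current AOO is zero for every threshold rule")
  assessment <- assess(cfg$species, cfg$current_status,
                       aoo_table[ok, c("scenario", "threshold_rule",
                                       "dispersal", "change_pct")],
                       n_records = nrow(occ), trend = cfg$trend)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      write_model_metrics(model, file.path(out_dir, "model_metrics.csv")),
      write_assessment(assessment, file.path(out_dir, "assessment.csv")),
      write_eoo_geojson(eoo, file.path(out_dir, "eoo.geojson"),
                        species = cfg$species),
      write_raster(current_surface,
                   file.path(out_dir, "suitability_current.asc")),
      write_occurrences(occ, file.path(out_dir, "occurrences_clean.csv")))
    utils::write.csv(aoo_table, file.path(out_dir, "aoo.csv"),
                     row.names = FALSE)
    paths <- c(paths, file.path(out_dir, "aoo.csv"))
    for (scn in names(future_surfaces))
      paths <- c(paths, write_raster(
        future_surfaces[[scn]],
        file.path(out_dir, sprintf("suitability_%s.asc", scn))))
    for (nm in names(change_maps))
      paths <- c(paths, write_change_map(
        change_maps[[nm]], file.path(out_dir, sprintf("change_%s.asc", nm))))
    imp_df <- data.frame(variable = names(importance),
                         importance_pct = as.numeric(importance))
    utils::write.csv(imp_df, file.path(out_dir, "importance.csv"),
                     row.names = FALSE)
    paths <- c(paths, file.path(out_dir, "importance.csv"))
    manifest$outputs <- paths
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }

  structure(list(model = model, selection = selection, occurrences = occ,
                 eoo = eoo, importance = importance, aoo_table = aoo_table,
                 change_maps = change_maps, assessment = assessment,
                 current_surface = current_surface,
                 future_surfaces = future_surfaces,
                 config = cfg, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Habitat-suitability extinction-risk pipeline result\n\n")
  print(x$model)
  cat("\n")
  print(x$assessment)
  invisible(x)
}
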