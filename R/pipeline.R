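#' Assemble a run configuration
#'
#' Bundles everything one reproducible invocation needs: the synthetic
#' scene parameters (or a directory of persisted scene layers), the
#' hierarchy and factor-group definitions, and the decision-unit
#' parameters.
#'
#' @param scene a `landscape_config`, or the path of a directory written
#'   by [write_scene()].
#' @param hierarchies as [default_hierarchies()], or a YAML path for
#'   [load_hierarchies()].
#' @param groups named list of factor groups (default
#'   [default_factor_groups()]).
#' @param fine_m,coarse_m,developed_buffer_m decision-unit parameters in
#'   meters.
#' @param seed optional integer overriding the scene seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(scene = landscape_config(),
                       hierarchies = default_hierarchies(),
                       groups = default_factor_groups(),
                       fine_m = 250, coarse_m = 1000,
                       developed_buffer_m = 2000, seed = NULL) {
  if (is.character(hierarchies)) hierarchies <- load_hierarchies(hierarchies)
  if (!is.null(seed)) {
    if (!inherits(scene, "landscape_config"))
      stop("seed override requires a synthetic scene config", call. = FALSE)
    scene$seed <- as.integer(seed)
  }
  structure(list(scene = scene, hierarchies = hierarchies, groups = groups,
                 fine_m = fine_m, coarse_m = coarse_m,
                 developed_buffer_m = developed_buffer_m),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Reads a scene-parameter YAML (see the shipped
#' `extdata/demo_scene.yaml`) and turns it into a [run_config()]. Keys
#' under `landscape:` map to [landscape_config()] arguments; optional
#' `units:` keys map to the decision-unit parameters; an optional
#' `hierarchies:` path is loaded with [load_hierarchies()] relative to
#' the YAML file.
#'
#' @param path YAML file path.
#' @param seed optional seed override.
#' @return A `run_config`.
#' @export
load_run_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  lc_args <- y$landscape
  if (!is.null(lc_args$extent)) lc_args$extent <- as.numeric(lc_args$extent)
  scene <- do.call(landscape_config, lc_args)
  h <- if (!is.null(y$hierarchies))
    load_hierarchies(file.path(dirname(path), y$hierarchies))
  else default_hierarchies()
  u <- y$units
  run_config(scene = scene, hierarchies = h,
             fine_m = if (!is.null(u$fine_m)) u$fine_m else 250,
             coarse_m = if (!is.null(u$coarse_m)) u$coarse_m else 1000,
             developed_buffer_m = if (!is.null(u$developed_buffer_m))
               u$developed_buffer_m else 2000,
             seed = seed)
}

.pipeline_stages <- c("simulate", "suitability", "conflict", "sensitivity")

read_state <- function(outdir, what, needed_by) {
  p <- file.path(outdir, "state", paste0(what, ".rds"))
  if (!file.exists(p))
    stop(sprintf("stage '%s' needs the '%s' artifact (%s); run the earlier stages first",
                 needed_by, what, p), call. = FALSE)
  readRDS(p)
}

save_state <- function(obj, outdir, what) {
  d <- file.path(outdir, "state")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  saveRDS(obj, file.path(d, paste0(what, ".rds")))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order, persisting intermediate state
#' under `outdir/state/` and human-readable artifacts (ASCII grids,
#' GeoJSON, CSV, Markdown) under `outdir`. A later invocation with a
#' subset of stages resumes from the persisted intermediates; rerunning
#' with an identical config reproduces identical outputs. A run manifest
#' (`run_manifest.yaml`) records the config, seed, stage timings and
#' output checksums.
#'
#' @param config a [run_config()] (or a YAML path for
#'   [load_run_config()]).
#' @param outdir output directory.
#' @param stages subset of `c("simulate", "suitability", "conflict",
#'   "sensitivity")`.
#' @return Invisibly, a list with the final state (`scene`, `units`,
#'   `areas`, `sensitivity` as available) and the manifest path.
#' @export
run_pipeline <- function(config, outdir,
                         stages = .pipeline_stages) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, .pipeline_stages, several.ok = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  state <- list()

  if ("simulate" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    scene <- if (inherits(config$scene, "landscape_config"))
      generate_scene(config$scene) else read_scene(config$scene)
    write_scene(scene, file.path(outdir, "scene"))
    save_state(scene, outdir, "scene")
    state$scene <- scene
    timings$simulate <- proc.time()[["elapsed"]] - t0
  }

  if ("suitability" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    scene <- state$scene %||% read_state(outdir, "scene", "suitability")
    developed <- scene$vectors$settlements
    developed$geoms <- c(developed$geoms, scene$vectors$farms$geoms)
    developed$attrs <- data.frame(row.names = seq_along(developed$geoms))
    units <- build_decision_units(scene$extent, developed,
                                  scene$vectors$protected_areas,
                                  fine_m = config$fine_m,
                                  coarse_m = config$coarse_m,
                                  developed_buffer_m = config$developed_buffer_m,
                                  crs = scene$crs)
    save_state(units, outdir, "units_base")
    cache <- new.env(parent = emptyenv())
    for (goal in c("agriculture", "settlement", "wildlife"))
      units <- build_goal_suitability(goal, scene, units,
                                      config$hierarchies, cache)
    utils::write.csv(as.data.frame(units),
                     file.path(outdir, "suitability_units.csv"),
                     row.names = FALSE)
    save_state(units, outdir, "units")
    state$scene <- scene; state$units <- units
    timings$suitability <- proc.time()[["elapsed"]] - t0
  }

  if ("conflict" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    units <- state$units %||% read_state(outdir, "units", "conflict")
    units$pref_AG <- bin_preferences(units$suit_agriculture)
    units$pref_HS <- bin_preferences(units$suit_settlement)
    units$pref_WL <- bin_preferences(units$suit_wildlife)
    units$conflict <- classify_conflict(units$pref_WL, units$pref_AG,
                                        units$pref_HS)
    areas <- summarize_areas(units$conflict, units)
    utils::write.csv(data.frame(id = units$id, WL = units$pref_WL,
                                AG = units$pref_AG, HS = units$pref_HS,
                                conflict = as.character(units$conflict)),
                     file.path(outdir, "conflict_units.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(class = areas$class,
                                area_km2 = round(areas$area_km2),
                                share_pct = round(areas$share_pct, 1)),
                     file.path(outdir, "conflict_areas.csv"),
                     row.names = FALSE)
    save_state(list(units = units, areas = areas), outdir, "conflict")
    state$units <- units; state$areas <- areas
    timings$conflict <- proc.time()[["elapsed"]] - t0
  }

  if ("sensitivity" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    scene <- state$scene %||% read_state(outdir, "scene", "sensitivity")
    base_units <- read_state(outdir, "units_base", "sensitivity")
    rep <- run_sensitivity(scene, base_units, config$hierarchies,
                           config$groups)
    write_sensitivity_report(rep,
                             csv_path = file.path(outdir, "sensitivity.csv"),
                             md_path = file.path(outdir, "sensitivity.md"))
    save_state(rep, outdir, "sensitivity")
    state$sensitivity <- rep
    timings$sensitivity <- proc.time()[["elapsed"]] - t0
  }

  arts <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  arts <- arts[!grepl("run_manifest[.]yaml$|^state/|/state/", arts)]
  sums <- tools::md5sum(arts)
  cfg_echo <- list(
    scene = if (inherits(config$scene, "landscape_config"))
      unclass(config$scene) else config$scene,
    fine_m = config$fine_m, coarse_m = config$coarse_m,
    developed_buffer_m = config$developed_buffer_m)
  manifest <- list(
    seed = if (inherits(config$scene, "landscape_config"))
      config$scene$seed else NA,
    stages = stages, timings_s = lapply(timings, round, 2),
    config = cfg_echo,
    config_hash = unname(tools::md5sum(
      {tf <- tempfile(); yaml::write_yaml(cfg_echo, tf); tf})),
    outputs = as.list(stats::setNames(unname(sums),
                                      sub(paste0(outdir, "/?"), "", arts))))
  mp <- file.path(outdir, "run_manifest.yaml")
  yaml::write_yaml(manifest, mp)
  invisible(c(state, list(manifest = mp)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
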