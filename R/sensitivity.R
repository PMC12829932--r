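#' The five shipped map-removal factor groups
#'
#' Groups of criteria, shared across the agriculture and settlement goal
#' trees, that are removed one at a time in the sensitivity analysis:
#' existing land uses, terrain characteristics, road accessibility, water
#' proximity, and development constraints. Members are (goal, node-name)
#' pairs; removing a name removes every node or criterion with that name
#' from the named goal's tree. The wildlife surface is an external input
#' containing none of these factors, so removal never touches it.
#'
#' @return Named list of factor groups; each is a data.frame with columns
#'   `goal` and `name`.
#' @export
default_factor_groups <- function() {
  fg <- function(...) {
    m <- do.call(rbind, lapply(list(...), function(p)
      data.frame(goal = p[1], name = p[2], stringsAsFactors = FALSE)))
    m
  }
  list(
    existing_land_use = fg(c("agriculture", "existing_farms"),
                           c("agriculture", "distance_to_crop_farms"),
                           c("agriculture", "existing_livestock_location"),
                           c("settlement", "distance_to_settlement")),
    terrain_characteristics = fg(c("agriculture", "terrain_characteristics"),
                                 c("settlement", "terrain_characteristics")),
    road_accessibility = fg(c("agriculture", "transport_accessibility"),
                            c("settlement", "road_accessibility")),
    water_proximity = fg(c("agriculture", "water_proximity"),
                         c("agriculture", "water_accessibility")),
    development_constraints = fg(c("agriculture", "development_constraints"),
                                 c("settlement", "development_constraints")))
}

#' Load factor groups from a YAML config
#'
#' The YAML maps group names to lists of `goal: name` member pairs; the
#' shipped default lives at
#' `system.file("extdata", "factor_groups.yaml", package = "lucisr")`.
#'
#' @param path YAML path.
#' @return Named list of factor groups as in [default_factor_groups()].
#' @export
load_factor_groups <- function(path) {
  y <- yaml::read_yaml(path)
  lapply(y, function(members)
    do.call(rbind, lapply(members, function(m)
      data.frame(goal = m$goal, name = m$name, stringsAsFactors = FALSE))))
}

# Recursively drop children named in `drop`; renormalize survivors
# proportionally; prune nodes left childless.
prune_node <- function(node, drop) {
  if (is_criterion(node)) {
    if (node$name %in% drop) return(NULL)
    return(node)
  }
  kept <- list()
  for (ch in node$children) {
    if (!is_criterion(ch) && ch$name %in% drop) next
    if (is_criterion(ch) && ch$name %in% drop) next
    pr <- prune_node(ch, drop)
    if (!is.null(pr)) kept[[length(kept) + 1L]] <- pr
  }
  if (!length(kept)) return(NULL)
  tot <- sum(vapply(kept, `[[`, 0, "weight"))
  kept <- lapply(kept, function(ch) { ch$weight <- ch$weight / tot; ch })
  node$children <- kept
  node
}

#' Remove a factor group from a goal hierarchy
#'
#' Deletes every node or criterion of the group belonging to this goal,
#' renormalizes surviving sibling weights proportionally (so relative
#' importance is preserved; a single survivor gets weight 1), and prunes
#' any node left childless, redistributing its weight among its siblings
#' the same way.
#'
#' @param hierarchy root `lucis_node` of a goal tree.
#' @param group a factor group (data.frame with `goal`, `name`), or a
#'   character vector of names to drop from this tree.
#' @return The reduced hierarchy. Errors if removal would empty the goal.
#' @export
remove_factor_group <- function(hierarchy, group) {
  drop <- if (is.data.frame(group))
    group$name[group$goal == hierarchy$name] else as.character(group)
  if (!length(drop)) return(hierarchy)
  out <- prune_node(hierarchy, drop)
  if (is.null(out))
    stop("removing this factor group would empty goal '", hierarchy$name,
         "'", call. = FALSE)
  validate_hierarchy(out)
  out
}

#' Run the full conflict pipeline on a scene
#'
#' Suitability for the three goals, Jenks 1-3 preference binning,
#' conflict overlay, and area accounting.
#'
#' @param scene a `lucis_scene`.
#' @param units a `lucis_units`.
#' @param hierarchies as [default_hierarchies()].
#' @param cache optional criterion cache (reused across OAT scenarios).
#' @return A list: `units` (with criterion, suitability, preference and
#'   conflict columns), `areas` (an `area_summary`).
#' @export
run_conflict_pipeline <- function(scene, units,
                                  hierarchies = default_hierarchies(),
                                  cache = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  for (goal in c("agriculture", "settlement", "wildlife"))
    units <- build_goal_suitability(goal, scene, units, hierarchies, cache)
  units$pref_AG <- bin_preferences(units$suit_agriculture)
  units$pref_HS <- bin_preferences(units$suit_settlement)
  units$pref_WL <- bin_preferences(units$suit_wildlife)
  units$conflict <- classify_conflict(units$pref_WL, units$pref_AG,
                                      units$pref_HS)
  areas <- summarize_areas(units$conflict, units)
  list(units = units, areas = areas)
}

#' Run one map-removal scenario
#'
#' Removes the factor group from the agriculture and settlement trees
#' (the wildlife surface carries none of the factors), then re-runs the
#' whole pipeline — criteria, weighted aggregation, fresh Jenks binning,
#' conflict overlay, area accounting — on the reduced hierarchies. With
#' an empty group this reproduces the base result exactly.
#'
#' @param scene,units,hierarchies as in [run_conflict_pipeline()].
#' @param group a factor group (or `NULL` for the base run).
#' @param cache optional criterion cache shared across scenarios.
#' @return An `area_summary`.
#' @export
run_oat_scenario <- function(scene, units, hierarchies, group = NULL,
                             cache = NULL) {
  h <- hierarchies
  if (!is.null(group) && nrow(group) > 0) {
    h$agriculture <- remove_factor_group(h$agriculture, group)
    h$settlement <- remove_factor_group(h$settlement, group)
  }
  run_conflict_pipeline(scene, units, h, cache)$areas
}

#' Per-class change metrics between two area summaries
#'
#' The scenario-vs-base bookkeeping of a map-removal run: per conflict
#' class, the scenario area, the area change, and the percent change
#' relative to the base class area. A base area of zero with a nonzero
#' scenario area yields an undefined (`NA`) percent change.
#'
#' @param base,scenario `area_summary` objects over the same classes and
#'   total area.
#' @param scenario_name label for the output rows.
#' @return data.frame with columns `scenario`, `class`, `area_km2`,
#'   `change_km2`, `pct_change` (exact, unrounded; see
#'   [format_sensitivity_report()] for report rounding).
#' @export
change_metrics <- function(base, scenario, scenario_name = "scenario") {
  if (!identical(base$class, scenario$class))
    stop("base and scenario must cover the same classes", call. = FALSE)
  if (abs(attr(base, "total_area_km2") - attr(scenario, "total_area_km2")) >
      1e-6)
    stop("base and scenario must share the total area", call. = FALSE)
  change <- scenario$area_km2 - base$area_km2
  pct <- ifelse(base$area_km2 > 0, 100 * change / base$area_km2,
                ifelse(change == 0, 0, NA_real_))
  data.frame(scenario = scenario_name, class = base$class,
             area_km2 = scenario$area_km2, change_km2 = change,
             pct_change = pct, stringsAsFactors = FALSE)
}

#' One-at-a-time map-removal sensitivity analysis
#'
#' Runs the base pipeline and one scenario per factor group, reusing the
#' criterion evaluations (removal edits only the weight trees), and
#' assembles the per-scenario per-class change records.
#'
#' @param scene,units,hierarchies as in [run_conflict_pipeline()].
#' @param groups named list of factor groups (default
#'   [default_factor_groups()]).
#' @return A list of class `sensitivity_report`: `base` (the base
#'   `area_summary`) and `records` (data.frame of base + scenario rows;
#'   base rows have change 0).
#' @export
run_sensitivity <- function(scene, units,
                            hierarchies = default_hierarchies(),
                            groups = default_factor_groups()) {
  cache <- new.env(parent = emptyenv())
  base <- run_conflict_pipeline(scene, units, hierarchies, cache)$areas
  records <- change_metrics(base, base, "base")
  for (nm in names(groups)) {
    sc <- run_oat_scenario(scene, units, hierarchies, groups[[nm]], cache)
    records <- rbind(records, change_metrics(base, sc, nm))
  }
  structure(list(base = base, records = records),
            class = "sensitivity_report")
}

#' Round a sensitivity report for presentation
#'
#' Areas and changes to whole km^2, percent changes to one decimal — the
#' precision used in the report tables.
#'
#' @param report a `sensitivity_report` or its `records` data.frame.
#' @return data.frame with rounded columns.
#' @export
format_sensitivity_report <- function(report) {
  rec <- if (inherits(report, "sensitivity_report")) report$records
         else report
  rec$area_km2 <- round(rec$area_km2)
  rec$change_km2 <- round(rec$change_km2)
  rec$pct_change <- round(rec$pct_change, 1)
  rec
}

#' Write a sensitivity report as CSV and Markdown
#'
#' @param report a `sensitivity_report`.
#' @param csv_path output CSV path (columns scenario, intensity,
#'   area_km2, change_km2, pct_change), or `NULL` to skip.
#' @param md_path output Markdown path, or `NULL` to skip.
#' @return The formatted data.frame, invisibly.
#' @export
write_sensitivity_report <- function(report, csv_path = NULL,
                                     md_path = NULL) {
  fm <- format_sensitivity_report(report)
  out <- data.frame(scenario = fm$scenario, intensity = fm$class,
                    area_km2 = fm$area_km2, change_km2 = fm$change_km2,
                    pct_change = fm$pct_change)
  if (!is.null(csv_path))
    utils::write.csv(out, csv_path, row.names = FALSE)
  if (!is.null(md_path)) {
    lines <- c("| Removed factor | Intensity | Area (km2) | Change (km2) | Change (%) |",
               "|---|---|---:|---:|---:|",
               sprintf("| %s | %s | %.0f | %s | %s |", out$scenario,
                       out$intensity, out$area_km2,
                       ifelse(out$scenario == "base", "-",
                              as.character(out$change_km2)),
                       ifelse(out$scenario == "base", "-",
                              sprintf("%.1f", out$pct_change))))
    writeLines(lines, md_path)
  }
  invisible(out)
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("<sensitivity_report>\n")
  print(format_sensitivity_report(x))
  invisible(x)
}
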