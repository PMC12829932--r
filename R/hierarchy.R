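#' Define a suitability criterion
#'
#' A leaf of the suitability hierarchy: how one source layer is turned
#' into a 1-9 score on the decision units.
#'
#' Transforms:
#' \describe{
#'   \item{distance}{Euclidean distance surface to the source features,
#'     zonal mean, rescaled 1-9 (`invert = TRUE` scores proximity high).}
#'   \item{slope}{slope in degrees from the source DEM, zonal mean,
#'     rescaled (`invert = TRUE` favors flat land).}
#'   \item{reclass_table}{zonal majority class of a categorical raster
#'     mapped through `params$table` (class -> 1-9 score).}
#'   \item{identity}{zonal mean of a continuous raster, rescaled 1-9.}
#'   \item{buffer_exclusion}{score 1 where the unit centroid lies within
#'     `params$buffer_m` of the source features, 9 outside (regulatory
#'     buffers such as the 300-m cattle-post rule; with polygons and a
#'     nominal buffer it expresses in/out constraints like protected
#'     areas).}
#' }
#'
#' @param name unique criterion name within its goal tree.
#' @param source_layer name of a raster or vector layer in the scene.
#' @param transform one of `"distance"`, `"slope"`, `"reclass_table"`,
#'   `"identity"`, `"buffer_exclusion"`.
#' @param weight sibling weight in `(0, 1]`.
#' @param invert logical; reverse the 1-9 scale (cost-like criteria).
#' @param params transform parameters (`buffer_m`, `table`).
#' @return A list of class `lucis_criterion`.
#' @export
criterion <- function(name, source_layer, transform, weight,
                      invert = FALSE, params = list()) {
  transform <- match.arg(transform, c("distance", "slope", "reclass_table",
                                      "identity", "buffer_exclusion"))
  if (!is.numeric(weight) || weight <= 0 || weight > 1)
    stop("criterion weight must be in (0, 1]", call. = FALSE)
  if (transform == "buffer_exclusion") {
    if (is.null(params$buffer_m) || params$buffer_m <= 0)
      stop("buffer_exclusion requires params$buffer_m > 0", call. = FALSE)
  }
  if (transform == "reclass_table" && is.null(params$table))
    stop("reclass_table requires params$table", call. = FALSE)
  structure(list(name = name, source_layer = source_layer,
                 transform = transform, weight = as.numeric(weight),
                 invert = isTRUE(invert), params = params),
            class = "lucis_criterion")
}

#' Define an internal hierarchy node
#'
#' @param name node name.
#' @param level `"goal"`, `"objective"`, or `"sub_objective"`.
#' @param weight sibling weight in `(0, 1]`.
#' @param children list of `lucis_node` and/or `lucis_criterion`.
#' @return A list of class `lucis_node`.
#' @export
hier_node <- function(name, level, weight, children) {
  level <- match.arg(level, c("goal", "objective", "sub_objective"))
  if (!length(children)) stop("node must have children", call. = FALSE)
  structure(list(name = name, level = level, weight = as.numeric(weight),
                 children = children),
            class = "lucis_node")
}

is_criterion <- function(x) inherits(x, "lucis_criterion")

node_child_weights <- function(node)
  vapply(node$children, `[[`, 0, "weight")

#' Validate a hierarchy tree
#'
#' Sibling weights must sum to 1 within 0.01 at every internal node
#' (printed weight tables are rounded to two decimals), and the tree may
#' be at most three levels deep below the goal.
#'
#' @param node root `lucis_node`.
#' @param .depth internal recursion depth.
#' @return `node`, invisibly; errors naming the offending node.
#' @export
validate_hierarchy <- function(node, .depth = 0L) {
  if (is_criterion(node)) return(invisible(node))
  if (.depth > 3L)
    stop("hierarchy deeper than 3 levels below the goal at node ", node$name,
         call. = FALSE)
  w <- node_child_weights(node)
  if (abs(sum(w) - 1) > 0.01)
    stop(sprintf("children of node '%s' have weights summing to %.4f (not 1)",
                 node$name, sum(w)), call. = FALSE)
  for (ch in node$children) validate_hierarchy(ch, .depth + 1L)
  invisible(node)
}

#' Collect all criteria of a hierarchy
#'
#' @param node root `lucis_node` (or a criterion).
#' @return Named list of `lucis_criterion` (names = criterion names).
#' @export
collect_criteria <- function(node) {
  if (is_criterion(node)) return(stats::setNames(list(node), node$name))
  out <- list()
  for (ch in node$children) out <- c(out, collect_criteria(ch))
  out
}

# LULC class codes used by the synthetic scene:
# 1 grassland, 2 woodland, 3 shrubland, 4 bare, 5 cropland, 6 built
lulc_reclass_tables <- list(
  crop       = c(`1` = 6, `2` = 4, `3` = 3, `4` = 2, `5` = 9, `6` = 1),
  livestock  = c(`1` = 9, `2` = 5, `3` = 6, `4` = 3, `5` = 4, `6` = 1),
  settlement = c(`1` = 5, `2` = 3, `3` = 4, `4` = 6, `5` = 2, `6` = 9))

.terrain_node <- function(weight, goal_kind) {
  hier_node("terrain_characteristics", "sub_objective", weight, list(
    criterion(paste0("lulc_", goal_kind), "lulc", "reclass_table", 0.5,
              params = list(table = lulc_reclass_tables[[goal_kind]])),
    criterion("slope", "dem", "slope", 0.5, invert = TRUE)))
}

.dev_constraints <- function(weight)
  criterion("development_constraints", "protected_areas", "buffer_exclusion",
            weight, params = list(buffer_m = 1))

#' Default suitability hierarchies
#'
#' The shipped weight trees for the three goals. Agriculture splits into
#' crop farming (0.7) and livestock rearing (0.3); crop farming weighs
#' physical factors 0.60 (existing farms 0.30, soil condition 0.20,
#' terrain 0.20, development constraints 0.30) against economic factors
#' 0.40 (transport, water, market access and farm proximity at 0.25 each);
#' livestock weighs physical 0.40 (existing locations 0.40, terrain 0.30,
#' constraints 0.30), economic 0.30 (transport 0.33, water 0.34, the 300-m
#' cattle-post buffer 0.33) and wildlife condition 0.30 (lion 0.50,
#' leopard 0.20, hyaena 0.20, elephant 0.10, all inverted: predator
#' habitat depresses livestock suitability). Human settlement weighs
#' physical 0.50 (population density 0.40, terrain 0.30, constraints
#' 0.30) and economic 0.50 (road access 0.50, distance to settlement
#' 0.50). The wildlife goal is not a weight tree: it combines the
#' per-species habitat surfaces with a cell statistic (see
#' [build_goal_suitability()]).
#'
#' @return Named list with `agriculture` and `settlement` root nodes and
#'   a `wildlife` combination spec (`species`, `stat`).
#' @export
default_hierarchies <- function() {
  crop <- hier_node("crop_farming", "objective", 0.7, list(
    hier_node("physical", "sub_objective", 0.60, list(
      criterion("existing_farms", "farms", "distance", 0.30, invert = TRUE,
                params = list(max_dist_m = 5000)),
      hier_node("soil_condition", "sub_objective", 0.20, list(
        criterion("soil_ph", "soil_ph", "identity", 1 / 3),
        criterion("root_zone_depth", "root_zone_depth", "identity", 1 / 3),
        criterion("drainage", "drainage", "identity", 1 / 3))),
      .terrain_node(0.20, "crop"),
      .dev_constraints(0.30))),
    hier_node("economic", "sub_objective", 0.40, list(
      criterion("transport_accessibility", "roads", "distance", 0.25,
                invert = TRUE),
      criterion("water_proximity", "boreholes", "distance", 0.25,
                invert = TRUE),
      criterion("market_accessibility", "settlements", "distance", 0.25,
                invert = TRUE),
      criterion("distance_to_crop_farms", "farms", "distance", 0.25,
                invert = TRUE, params = list(max_dist_m = 5000))))))
  livestock <- hier_node("livestock", "objective", 0.3, list(
    hier_node("physical", "sub_objective", 0.40, list(
      criterion("existing_livestock_location", "cattle_posts", "distance",
                0.40, invert = TRUE, params = list(max_dist_m = 5000)),
      .terrain_node(0.30, "livestock"),
      .dev_constraints(0.30))),
    hier_node("economic", "sub_objective", 0.30, list(
      criterion("transport_accessibility", "roads", "distance", 0.33,
                invert = TRUE),
      criterion("water_accessibility", "boreholes", "distance", 0.34,
                invert = TRUE),
      criterion("livestock_buffer", "cattle_posts", "buffer_exclusion", 0.33,
                params = list(buffer_m = 300)))),
    hier_node("wildlife_condition", "sub_objective", 0.30, list(
      criterion("lion_habitat", "habitat_lion", "identity", 0.50,
                invert = TRUE),
      criterion("leopard_habitat", "habitat_leopard", "identity", 0.20,
                invert = TRUE),
      criterion("hyaena_habitat", "habitat_hyaena", "identity", 0.20,
                invert = TRUE),
      criterion("elephant_habitat", "habitat_elephant", "identity", 0.10,
                invert = TRUE)))))
  agriculture <- hier_node("agriculture", "goal", 1, list(crop, livestock))

  settlement <- hier_node("settlement", "goal", 1, list(
    hier_node("physical", "objective", 0.50, list(
      criterion("population_density", "population_density", "identity", 0.40),
      .terrain_node(0.30, "settlement"),
      .dev_constraints(0.30))),
    hier_node("economic", "objective", 0.50, list(
      criterion("road_accessibility", "roads", "distance", 0.50,
                invert = TRUE),
      criterion("distance_to_settlement", "settlements", "distance", 0.50,
                invert = TRUE)))))

  validate_hierarchy(agriculture)
  validate_hierarchy(settlement)
  list(agriculture = agriculture, settlement = settlement,
       wildlife = list(species = lucis_species, stat = "mean"))
}

# ---- YAML (de)serialization --------------------------------------------

node_to_list <- function(x) {
  if (is_criterion(x)) {
    out <- list(weight = x$weight, source = x$source_layer,
                transform = x$transform)
    if (x$invert) out$invert <- TRUE
    if (length(x$params)) {
      p <- x$params
      if (!is.null(p$table)) p$table <- as.list(p$table)
      out$params <- p
    }
    out
  } else {
    ch <- lapply(x$children, node_to_list)
    names(ch) <- vapply(x$children, `[[`, "", "name")
    list(weight = x$weight, children = ch)
  }
}

list_to_node <- function(name, x, level) {
  if (!is.null(x$children)) {
    next_level <- if (level == "goal") "objective" else "sub_objective"
    kids <- lapply(names(x$children), function(nm)
      list_to_node(nm, x$children[[nm]], next_level))
    hier_node(name, level, x$weight, kids)
  } else {
    params <- if (is.null(x$params)) list() else x$params
    if (!is.null(params$table))
      params$table <- unlist(params$table)
    criterion(name, x$source, x$transform, x$weight,
              invert = isTRUE(x$invert), params = params)
  }
}

#' Write hierarchies to a YAML config
#'
#' @param hierarchies as returned by [default_hierarchies()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_hierarchies <- function(hierarchies, path) {
  obj <- list(goals = list(
    agriculture = node_to_list(hierarchies$agriculture),
    settlement = node_to_list(hierarchies$settlement)),
    wildlife = hierarchies$wildlife)
  yaml::write_yaml(obj, path, precision = 12L)
  invisible(path)
}

#' Load hierarchies from a YAML config
#'
#' @param path YAML path as written by [write_hierarchies()]; the package
#'   ships its default at
#'   `system.file("extdata", "hierarchies_default.yaml", package = "lucisr")`.
#' @return Same structure as [default_hierarchies()].
#' @export
load_hierarchies <- function(path) {
  obj <- yaml::read_yaml(path)
  ag <- list_to_node("agriculture", obj$goals$agriculture, "goal")
  hs <- list_to_node("settlement", obj$goals$settlement, "goal")
  validate_hierarchy(ag); validate_hierarchy(hs)
  wl <- obj$wildlife
  wl$species <- as.character(wl$species)
  list(agriculture = ag, settlement = hs, wildlife = wl)
}
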