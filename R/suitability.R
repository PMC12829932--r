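criterion_cache_key <- function(spec) {
  p <- spec$params
  ptxt <- if (length(p)) paste(names(p), vapply(p, function(v)
    paste(format(v, digits = 15), collapse = ","), ""), collapse = ";") else ""
  paste(spec$transform, spec$source_layer, spec$invert, ptxt, sep = "|")
}

# Per-unit 1-9 scores for one criterion. `cache` (an environment) memoizes
# evaluations so criteria shared between goal trees are computed once per
# scene/units pair.
criterion_scores <- function(spec, scene, units, cache = NULL) {
  key <- criterion_cache_key(spec)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  src <- spec$source_layer
  template <- scene$rasters[[1]]
  scores <- switch(spec$transform,
    distance = {
      fs <- scene$vectors[[src]]
      if (is.null(fs)) stop("missing vector layer: ", src, call. = FALSE)
      d <- euclidean_distance_surface(fs, template)
      z <- zonal_aggregate(d, units, "mean", name = ".tmp")$.tmp
      # saturation radius: condition-type criteria ("optimize existing
      # use") score on 0..max_dist_m and flatten beyond, instead of a
      # landscape-wide gradient
      if (!is.null(spec$params$max_dist_m)) {
        md <- spec$params$max_dist_m
        s <- 1 + 8 * pmin(z, md) / md
        if (spec$invert) s <- 10 - s
        s
      } else {
        rescale_linear_1_9(z, invert = spec$invert)
      }
    },
    slope = {
      dem <- scene$rasters[[src]]
      if (is.null(dem)) stop("missing raster layer: ", src, call. = FALSE)
      s <- slope_from_dem(dem)
      z <- zonal_aggregate(s, units, "mean", name = ".tmp")$.tmp
      rescale_linear_1_9(z, invert = spec$invert)
    },
    identity = {
      r <- scene$rasters[[src]]
      if (is.null(r)) stop("missing raster layer: ", src, call. = FALSE)
      z <- zonal_aggregate(r, units, "mean", name = ".tmp")$.tmp
      rescale_linear_1_9(z, invert = spec$invert)
    },
    reclass_table = {
      r <- scene$rasters[[src]]
      if (is.null(r)) stop("missing raster layer: ", src, call. = FALSE)
      z <- zonal_aggregate(r, units, "majority", name = ".tmp")$.tmp
      tab <- spec$params$table
      cls <- as.character(z)
      unmapped <- setdiff(unique(cls[!is.na(z)]), names(tab))
      if (length(unmapped))
        stop("reclass table for '", spec$name, "' is missing classes: ",
             paste(unmapped, collapse = ", "), call. = FALSE)
      out <- unname(tab[cls])
      out[is.na(z)] <- NA_real_
      out
    },
    buffer_exclusion = {
      fs <- scene$vectors[[src]]
      if (is.null(fs)) stop("missing vector layer: ", src, call. = FALSE)
      ctr <- unit_centroids(units)
      d <- points_to_features_dist(fs, ctr[, 1], ctr[, 2])
      ifelse(d <= spec$params$buffer_m, 1, 9)
    })
  if (!is.null(cache)) cache[[key]] <- scores
  scores
}

#' Evaluate a single criterion onto decision units
#'
#' Applies the criterion's transform to its source layer, aggregates to
#' the units, and attaches the 1-9 score as a column named after the
#' criterion.
#'
#' @param spec a [criterion()].
#' @param scene a `lucis_scene` (or compatible layer list).
#' @param units a `lucis_units`.
#' @param cache optional environment memoizing shared criteria.
#' @return `units` with the new score column.
#' @export
evaluate_criterion <- function(spec, scene, units, cache = NULL) {
  units[[spec$name]] <- criterion_scores(spec, scene, units, cache)
  units
}

# Recursive WLC: returns the composite score vector of `node` given a
# data.frame of evaluated criterion columns.
node_composite <- function(node, crit_scores) {
  if (is_criterion(node)) {
    v <- crit_scores[[node$name]]
    if (is.null(v))
      stop("criterion '", node$name, "' has not been evaluated", call. = FALSE)
    return(v)
  }
  w <- node_child_weights(node)
  if (abs(sum(w) - 1) > 0.01)
    stop(sprintf("children of node '%s' have weights summing to %.4f (not 1)",
                 node$name, sum(w)), call. = FALSE)
  mats <- vapply(node$children, node_composite, crit_scores,
                 FUN.VALUE = numeric(nrow(crit_scores)))
  wlc_aggregate(mats, w / sum(w))
}

#' Aggregate evaluated criteria up a hierarchy
#'
#' Bottom-up weighted linear combination from criterion leaves through
#' sub-objectives and objectives to the goal; the goal-level composite is
#' rescaled to the 1-9 suitability scale (intermediate composites are
#' not).
#'
#' @param node root `lucis_node` of a goal tree.
#' @param units a `lucis_units` whose columns include every leaf
#'   criterion of the tree (see [evaluate_criterion()]).
#' @return `units` with a new `suit_<goal>` column in `[1, 9]`.
#' @export
evaluate_hierarchy <- function(node, units) {
  comp <- node_composite(node, units)
  units[[paste0("suit_", node$name)]] <- rescale_linear_1_9(comp)
  units
}

#' Build a goal suitability surface on the decision units
#'
#' For agriculture and settlement: evaluates every criterion of the goal's
#' weight tree and aggregates bottom-up. For wildlife: combines the
#' per-species habitat rasters with a cell statistic (mean by default),
#' takes zonal means, and rescales 1-9.
#'
#' @param goal `"agriculture"`, `"settlement"`, or `"wildlife"`.
#' @param scene a `lucis_scene`.
#' @param units a `lucis_units`.
#' @param hierarchies as returned by [default_hierarchies()] (the
#'   relevant entry is used).
#' @param cache optional criterion cache environment.
#' @return `units` with the criterion columns (for tree goals) and a
#'   `suit_<goal>` column in `[1, 9]`.
#' @export
build_goal_suitability <- function(goal, scene, units,
                                   hierarchies = default_hierarchies(),
                                   cache = NULL) {
  goal <- match.arg(goal, c("agriculture", "settlement", "wildlife"))
  if (goal == "wildlife") {
    wl <- hierarchies$wildlife
    comb <- combine_habitat(scene, species = wl$species, stat = wl$stat)
    z <- zonal_aggregate(comb, units, "mean", name = ".tmp")$.tmp
    units$suit_wildlife <- rescale_linear_1_9(z)
    return(units)
  }
  tree <- hierarchies[[goal]]
  validate_hierarchy(tree)
  for (spec in collect_criteria(tree))
    units <- evaluate_criterion(spec, scene, units, cache)
  evaluate_hierarchy(tree, units)
}
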