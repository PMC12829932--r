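#' Conflict classes, in severity order
#' @export
conflict_classes <- c("none", "low", "moderate", "high")

#' Bin a suitability surface into 1-3 preference levels
#'
#' Jenks natural-breaks classification with k = 3 on the per-unit
#' suitability scores: class 1 is the lowest-score (low preference) class
#' and class 3 the highest. By construction all three classes are
#' non-empty.
#'
#' @param scores numeric vector of per-unit suitability in `[1, 9]` with
#'   at least three distinct finite values.
#' @return Integer vector of levels 1-3 (`NA` preserved).
#' @export
bin_preferences <- function(scores) {
  jenks_breaks(scores, 3L)$assignments
}

#' Classify human-wildlife conflict from preference levels
#'
#' Applies the literal overlay criteria: high conflict where WL = 3 and
#' (AG = 3 or HS = 3); moderate where WL = 2 and (AG = 2 or HS = 2); low
#' where WL = 1 and (AG = 1 or HS = 1). Any triple matching no rule —
#' including mixed-level overlaps such as WL = 3 with AG = 2 — classifies
#' as `"none"`, as does any triple with a missing component (no wildlife
#' preference means no human-wildlife conflict).
#'
#' @param WL,AG,HS integer vectors of wildlife, agriculture and human
#'   settlement preference levels in `{1, 2, 3}` (`NA` allowed).
#' @return Factor with levels `none < low < moderate < high`.
#' @export
classify_conflict <- function(WL, AG, HS) {
  for (v in list(WL, AG, HS)) {
    bad <- !is.na(v) & !(v %in% 1:3)
    if (any(bad))
      stop("preference levels must be in {1, 2, 3} or NA", call. = FALSE)
  }
  n <- max(length(WL), length(AG), length(HS))
  WL <- rep_len(WL, n); AG <- rep_len(AG, n); HS <- rep_len(HS, n)
  out <- rep("none", n)
  ok <- !is.na(WL) & !is.na(AG) & !is.na(HS)
  out[ok & WL == 3 & (AG == 3 | HS == 3)] <- "high"
  out[ok & WL == 2 & (AG == 2 | HS == 2)] <- "moderate"
  out[ok & WL == 1 & (AG == 1 | HS == 1)] <- "low"
  factor(out, levels = conflict_classes, ordered = TRUE)
}

#' Area summary of a classified map
#'
#' Per-class areas and percentage shares of the study area. Constructs
#' the summary directly from per-class areas; see [summarize_areas()] for
#' the decision-unit entry point.
#'
#' @param areas_km2 named numeric vector of per-class areas (km^2); names
#'   are the classes.
#' @param total_area_km2 positive study area (km^2).
#' @return A data.frame of class `area_summary` with columns `class`,
#'   `area_km2`, `share_pct`, and attribute `total_area_km2`.
#' @export
area_summary <- function(areas_km2, total_area_km2) {
  if (!is.numeric(total_area_km2) || total_area_km2 <= 0)
    stop("total_area_km2 must be positive", call. = FALSE)
  df <- data.frame(class = names(areas_km2),
                   area_km2 = as.numeric(areas_km2),
                   share_pct = 100 * as.numeric(areas_km2) / total_area_km2,
                   stringsAsFactors = FALSE)
  structure(df, total_area_km2 = total_area_km2,
            class = c("area_summary", "data.frame"))
}

#' Summarize conflict areas over decision units
#'
#' True polygon areas of the (square) units are summed per conflict
#' class and expressed as shares of the study area.
#'
#' @param conflict factor of conflict classes, one per unit.
#' @param units a `lucis_units`.
#' @param total_area_km2 study area in km^2 (default: the summed unit
#'   area, i.e. the tiled extent).
#' @return An `area_summary` with one row per class in
#'   [conflict_classes] order.
#' @export
summarize_areas <- function(conflict, units,
                            total_area_km2 = units_area_km2(units)) {
  stopifnot(length(conflict) == nrow(units))
  a_unit <- (units$size_m / 1000)^2
  areas <- vapply(conflict_classes, function(cl)
    sum(a_unit[!is.na(conflict) & conflict == cl]), 0)
  area_summary(areas, total_area_km2)
}

#' @export
print.area_summary <- function(x, ...) {
  cat(sprintf("<area_summary> total %.0f km2\n", attr(x, "total_area_km2")))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-9s %6.0f km2  %5.1f%%  (%d%%)\n", x$class[i],
                x$area_km2[i], x$share_pct[i], round(x$share_pct[i])))
  invisible(x)
}
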