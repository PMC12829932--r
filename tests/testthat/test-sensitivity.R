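# printed base and scenario areas used for the change-metric arithmetic
base_printed <- area_summary(
  c(none = 4798, low = 697, moderate = 752, high = 596), 6842)

test_that("removing one of two siblings renormalizes the survivor to 1", {
  tree <- hier_node("g", "goal", 1, list(
    criterion("a", "z", "identity", 0.6),
    criterion("b", "z", "identity", 0.4)))
  out <- remove_factor_group(tree, "b")
  expect_length(out$children, 1)
  expect_equal(out$children[[1]]$weight, 1.0)
})

test_that("removing water proximity leaves equal thirds in crop economics", {
  h <- default_hierarchies()
  red <- remove_factor_group(h$agriculture, default_factor_groups()$water_proximity)
  econ <- red$children[[1]]$children[[2]]
  expect_equal(econ$name, "economic")
  expect_length(econ$children, 3)
  expect_equal(vapply(econ$children, `[[`, 0, "weight"), rep(1 / 3, 3))
  expect_false("water_proximity" %in%
                 names(collect_criteria(red)))
  # livestock economic also loses its water criterion: 0.33 and 0.33 remain
  lv_econ <- red$children[[2]]$children[[2]]
  expect_equal(vapply(lv_econ$children, `[[`, 0, "weight"), c(0.5, 0.5))
})

test_that("a group with no members in a goal leaves its tree unchanged", {
  h <- default_hierarchies()
  out <- remove_factor_group(h$settlement, default_factor_groups()$water_proximity)
  expect_equal(out, h$settlement)
})

test_that("removal that would empty a goal is rejected", {
  tree <- hier_node("g", "goal", 1, list(
    criterion("a", "z", "identity", 0.6),
    criterion("b", "z", "identity", 0.4)))
  expect_error(remove_factor_group(tree, c("a", "b")), "empty goal")
})

test_that("a node left childless is pruned and its weight redistributed", {
  tree <- hier_node("g", "goal", 1, list(
    hier_node("o1", "objective", 0.5, list(
      criterion("a", "z", "identity", 1))),
    hier_node("o2", "objective", 0.5, list(
      criterion("b", "z", "identity", 0.5),
      criterion("c", "z", "identity", 0.5)))))
  out <- remove_factor_group(tree, "a")
  expect_length(out$children, 1)
  expect_equal(out$children[[1]]$name, "o2")
  expect_equal(out$children[[1]]$weight, 1.0)
})

test_that("the five shipped factor groups name only existing criteria or nodes", {
  h <- default_hierarchies()
  node_names <- function(x) {
    if (is_crit <- inherits(x, "lucis_criterion")) return(x$name)
    c(x$name, unlist(lapply(x$children, node_names)))
  }
  available <- list(agriculture = node_names(h$agriculture),
                    settlement = node_names(h$settlement))
  groups <- default_factor_groups()
  expect_named(groups, c("existing_land_use", "terrain_characteristics",
                         "road_accessibility", "water_proximity",
                         "development_constraints"))
  for (g in groups)
    for (i in seq_len(nrow(g)))
      expect_true(g$name[i] %in% available[[g$goal[i]]],
                  label = paste(g$goal[i], g$name[i]))
})

test_that("change metrics reproduce the printed removal bookkeeping", {
  scen <- area_summary(c(none = 4933, low = 692, moderate = 895, high = 323),
                       6842)
  cm <- change_metrics(base_printed, scen, "existing_land_use")
  expect_equal(cm$change_km2, c(135, -5, 143, -273))
  expect_equal(round(cm$pct_change, 1), c(2.8, -0.7, 19.0, -45.8))
})

test_that("change metrics of a summary against itself are zero", {
  cm <- change_metrics(base_printed, base_printed, "base")
  expect_true(all(cm$change_km2 == 0))
  expect_true(all(cm$pct_change == 0))
})

test_that("zero base area yields an undefined percent change marker", {
  b <- area_summary(c(none = 10, high = 0), 10)
  s <- area_summary(c(none = 8, high = 2), 10)
  cm <- change_metrics(b, s)
  expect_true(is.na(cm$pct_change[cm$class == "high"]))
})

test_that("an empty-group scenario reproduces the base result exactly", {
  sc <- small_scene(); u <- small_units()
  cache <- new.env()
  base <- run_conflict_pipeline(sc, u, cache = cache)$areas
  again <- run_oat_scenario(sc, u, default_hierarchies(),
                            group = NULL, cache = cache)
  expect_identical(base$area_km2, again$area_km2)
})

test_that("OAT scenarios conserve total area exactly", {
  sc <- small_scene(); u <- small_units()
  rep <- run_sensitivity(sc, u)
  tot <- units_area_km2(u)
  for (scen in unique(rep$records$scenario)) {
    rows <- rep$records[rep$records$scenario == scen, ]
    expect_equal(sum(rows$area_km2), tot)
  }
  expect_true(all(rep$records$change_km2[rep$records$scenario == "base"] == 0))
})

test_that("removing existing land use pulls conflict off the farm corridor", {
  sc <- toy_corridor_scene()
  u <- build_decision_units(sc$extent, developed_features(sc),
                            sc$vectors$protected_areas)
  cache <- new.env()
  base <- run_conflict_pipeline(sc, u, cache = cache)$areas
  red <- run_oat_scenario(sc, u, default_hierarchies(),
                          default_factor_groups()$existing_land_use, cache)
  high_base <- base$area_km2[base$class == "high"]
  high_red <- red$area_km2[red$class == "high"]
  expect_lt(high_red, high_base)
})

test_that("sensitivity reports round areas to km2 and percents to 0.1", {
  rec <- data.frame(scenario = "x", class = "high", area_km2 = 123.456,
                    change_km2 = -7.89, pct_change = -4.5678)
  fm <- format_sensitivity_report(rec)
  expect_equal(fm$area_km2, 123)
  expect_equal(fm$change_km2, -8)
  expect_equal(fm$pct_change, -4.6)
})
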