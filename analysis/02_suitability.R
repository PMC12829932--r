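#!/usr/bin/env Rscript
# Stage 2 — land-suitability surfaces for the three competing uses.
#
# Builds the multi-resolution decision units (250 m near development,
# 1000 m inside protected land), evaluates every criterion of the weight
# hierarchies (soil condition, terrain, development constraints,
# accessibility, proximity-to-existing-use, predator habitat), and
# aggregates bottom-up by weighted linear combination into 1-9 suitability
# per goal. Scores per unit go to results/demo/suitability_units.csv.

suppressPackageStartupMessages(library(lucisr))

cfg <- load_run_config(system.file("extdata", "demo_scene.yaml",
                                   package = "lucisr"))
state <- run_pipeline(cfg, "results/demo", stages = "suitability")

u <- state$units
cat(sprintf("%d decision units (%d fine / %d coarse)\n", nrow(u),
            sum(u$resolution_class == "fine"),
            sum(u$resolution_class == "coarse")))
for (g in c("agriculture", "settlement", "wildlife")) {
  s <- u[[paste0("suit_", g)]]
  cat(sprintf("%-12s suitability: mean %.2f  [%.1f, %.1f]\n", g,
              mean(s), min(s), max(s)))
}
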