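#!/usr/bin/env Rscript
# Stage 3 — preference binning and conflict identification.
#
# Jenks natural breaks (k = 3) turn each suitability surface into 1-3
# preference levels; the literal overlay rules mark a unit high conflict
# where wildlife preference is 3 and agriculture or settlement preference
# is 3 (matched levels 2 and 1 give moderate and low; anything else is no
# conflict). Outputs: results/demo/conflict_units.csv and
# results/demo/conflict_areas.csv.

suppressPackageStartupMessages(library(lucisr))

cfg <- load_run_config(system.file("extdata", "demo_scene.yaml",
                                   package = "lucisr"))
state <- run_pipeline(cfg, "results/demo", stages = "conflict")

print(state$areas)
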