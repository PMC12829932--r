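# Demo synthetic landscape: a 50 x 50 km scene gridded at 250 m, with the
# default hierarchy weights. Intended as the worked example for the full
# suitability -> preference -> conflict -> sensitivity pipeline.
landscape:
  extent: [0.0, 0.0, 50000.0, 50000.0]
  cell_size_m: 250.0
  seed: 1
  n_roads: 3
  n_settlements: 8
  n_farms: 40
  n_boreholes: 25
  n_cattle_posts: 15
  protected_fraction: 0.35
  field_range_m: 2500.0
  farm_wildlife_overlap: 0.7
units:
  fine_m: 250.0
  coarse_m: 1000.0
  developed_buffer_m: 2000.0
hierarchies: hierarchies_default.yaml
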