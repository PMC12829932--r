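existing_land_use:
- goal: agriculture
  name: existing_farms
- goal: agriculture
  name: distance_to_crop_farms
- goal: agriculture
  name: existing_livestock_location
- goal: settlement
  name: distance_to_settlement
terrain_characteristics:
- goal: agriculture
  name: terrain_characteristics
- goal: settlement
  name: terrain_characteristics
road_accessibility:
- goal: agriculture
  name: transport_accessibility
- goal: settlement
  name: road_accessibility
water_proximity:
- goal: agriculture
  name: water_proximity
- goal: agriculture
  name: water_accessibility
development_constraints:
- goal: agriculture
  name: development_constraints
- goal: settlement
  name: development_constraints
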