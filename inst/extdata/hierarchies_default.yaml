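goals:
  agriculture:
    weight: 1.0
    children:
      crop_farming:
        weight: 0.7
        children:
          physical:
            weight: 0.6
            children:
              existing_farms:
                weight: 0.3
                source: farms
                transform: distance
                invert: yes
                params:
                  max_dist_m: 5000.0
              soil_condition:
                weight: 0.2
                children:
                  soil_ph:
                    weight: 0.333333333333
                    source: soil_ph
                    transform: identity
                  root_zone_depth:
                    weight: 0.333333333333
                    source: root_zone_depth
                    transform: identity
                  drainage:
                    weight: 0.333333333333
                    source: drainage
                    transform: identity
              terrain_characteristics:
                weight: 0.2
                children:
                  lulc_crop:
                    weight: 0.5
                    source: lulc
                    transform: reclass_table
                    params:
                      table:
                        '1': 6.0
                        '2': 4.0
                        '3': 3.0
                        '4': 2.0
                        '5': 9.0
                        '6': 1.0
                  slope:
                    weight: 0.5
                    source: dem
                    transform: slope
                    invert: yes
              development_constraints:
                weight: 0.3
                source: protected_areas
                transform: buffer_exclusion
                params:
                  buffer_m: 1.0
          economic:
            weight: 0.4
            children:
              transport_accessibility:
                weight: 0.25
                source: roads
                transform: distance
                invert: yes
              water_proximity:
                weight: 0.25
                source: boreholes
                transform: distance
                invert: yes
              market_accessibility:
                weight: 0.25
                source: settlements
                transform: distance
                invert: yes
              distance_to_crop_farms:
                weight: 0.25
                source: farms
                transform: distance
                invert: yes
                params:
                  max_dist_m: 5000.0
      livestock:
        weight: 0.3
        children:
          physical:
            weight: 0.4
            children:
              existing_livestock_location:
                weight: 0.4
                source: cattle_posts
                transform: distance
                invert: yes
                params:
                  max_dist_m: 5000.0
              terrain_characteristics:
                weight: 0.3
                children:
                  lulc_livestock:
                    weight: 0.5
                    source: lulc
                    transform: reclass_table
                    params:
                      table:
                        '1': 9.0
                        '2': 5.0
                        '3': 6.0
                        '4': 3.0
                        '5': 4.0
                        '6': 1.0
                  slope:
                    weight: 0.5
                    source: dem
                    transform: slope
                    invert: yes
              development_constraints:
                weight: 0.3
                source: protected_areas
                transform: buffer_exclusion
                params:
                  buffer_m: 1.0
          economic:
            weight: 0.3
            children:
              transport_accessibility:
                weight: 0.33
                source: roads
                transform: distance
                invert: yes
              water_accessibility:
                weight: 0.34
                source: boreholes
                transform: distance
                invert: yes
              livestock_buffer:
                weight: 0.33
                source: cattle_posts
                transform: buffer_exclusion
                params:
                  buffer_m: 300.0
          wildlife_condition:
            weight: 0.3
            children:
              lion_habitat:
                weight: 0.5
                source: habitat_lion
                transform: identity
                invert: yes
              leopard_habitat:
                weight: 0.2
                source: habitat_leopard
                transform: identity
                invert: yes
              hyaena_habitat:
                weight: 0.2
                source: habitat_hyaena
                transform: identity
                invert: yes
              elephant_habitat:
                weight: 0.1
                source: habitat_elephant
                transform: identity
                invert: yes
  settlement:
    weight: 1.0
    children:
      physical:
        weight: 0.5
        children:
          population_density:
            weight: 0.4
            source: population_density
            transform: identity
          terrain_characteristics:
            weight: 0.3
            children:
              lulc_settlement:
                weight: 0.5
                source: lulc
                transform: reclass_table
                params:
                  table:
                    '1': 5.0
                    '2': 3.0
                    '3': 4.0
                    '4': 6.0
                    '5': 2.0
                    '6': 9.0
              slope:
                weight: 0.5
                source: dem
                transform: slope
                invert: yes
          development_constraints:
            weight: 0.3
            source: protected_areas
            transform: buffer_exclusion
            params:
              buffer_m: 1.0
      economic:
        weight: 0.5
        children:
          road_accessibility:
            weight: 0.5
            source: roads
            transform: distance
            invert: yes
          distance_to_settlement:
            weight: 0.5
            source: settlements
            transform: distance
            invert: yes
wildlife:
  species:
  - lion
  - leopard
  - hyaena
  - elephant
  stat: mean
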