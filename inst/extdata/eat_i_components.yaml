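# Default EAT-Lancet dietary index (EAT-I) component specification.
# Ten main components, 80 points total. Targets and ranges are seeded
# from the EAT-Lancet reference diet for a 2500 kcal/d intake (g/d).
# Adequacy: points rise linearly from 0 at zero intake to max at the
#   target, then saturate.
# Moderation: max points at or below the target, falling linearly to 0
#   at `upper`.
# Optional: max points inside [lower, upper], falling linearly to 0 at
#   [lower_outer, upper_outer].
# `mapping` lists the intake variables (g/d) summed for the component.
# Edit freely; the scoring engine validates points and cut-off ordering.
components:
  - name: whole_grains
    kind: adequacy
    max_points: 10
    target: 232
    mapping: [whole_grains]
  - name: tubers_starchy_vegetables
    kind: moderation
    max_points: 10
    target: 50
    upper: 200
    mapping: [tubers]
  - name: vegetables
    kind: adequacy
    max_points: 10
    target: 300
    mapping: [vegetables]
  - name: fruits
    kind: adequacy
    max_points: 10
    target: 200
    mapping: [fruits]
  - name: dairy_foods
    kind: optional
    max_points: 5
    lower: 0
    upper: 500
    lower_outer: 0
    upper_outer: 1000
    mapping: [dairy]
  - name: red_processed_meats
    kind: moderation
    max_points: 5
    target: 28
    upper: 100
    mapping: [red_processed_meat]
  - name: poultry_eggs
    kind: optional
    max_points: 5
    subcomponents:
      - name: poultry
        kind: optional
        points: 2.5
        lower: 0
        upper: 58
        lower_outer: 0
        upper_outer: 116
        mapping: [poultry]
      - name: eggs
        kind: optional
        points: 2.5
        lower: 0
        upper: 25
        lower_outer: 0
        upper_outer: 50
        mapping: [eggs]
  - name: fish_plant_proteins
    kind: adequacy
    max_points: 5
    subcomponents:
      - name: fish
        kind: adequacy
        points: 2
        target: 28
        mapping: [fish]
      - name: legumes
        kind: adequacy
        points: 1.5
        target: 75
        mapping: [legumes]
      - name: nuts
        kind: adequacy
        points: 1.5
        target: 50
        mapping: [nuts]
  - name: added_fats
    kind: mixed
    max_points: 10
    subcomponents:
      - name: unsaturated_fats
        kind: adequacy
        points: 5
        target: 40
        mapping: [unsat_fats]
      - name: saturated_fats
        kind: moderation
        points: 5
        target: 11.8
        upper: 47
        mapping: [sat_fats]
  - name: free_sugars
    kind: moderation
    max_points: 10
    target: 31
    upper: 124
    mapping: [free_sugars]
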