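version: pnnsgs-config-1
components:
  fruit_veg:
    breaks:
    - 0.0
    - 3.5
    - 5.0
    - 7.5
    points:
    - 0.0
    - 0.5
    - 1.0
    - 2.0
    source: paper
  starch:
    breaks:
    - 0.0
    - 1.0
    - 3.0
    - 6.0
    points:
    - 0.0
    - 0.5
    - 1.0
    - 0.5
    source: reference
  wholegrain:
    breaks:
    - 0.0
    - 0.3333333
    - 0.6666667
    points:
    - 0.0
    - 0.5
    - 1.0
    source: paper
  dairy:
    breaks:
    - 0.0
    - 1.0
    - 2.5
    points:
    - 0.0
    - 0.5
    - 1.0
    upper:
      under: 3.5
      over: 4.5
    over_points: 0.0
    age_threshold: 55.0
    source: paper
  meat:
    zero_points: 0.0
    low_points: 0.5
    band:
    - 1.0
    - 2.0
    band_points: 1.0
    over_points: 0.5
    source: reference
  seafood:
    threshold: 2.0
    below: 0.0
    at_or_above: 1.0
    source: paper
  added_fat:
    threshold: 16.0
    at_or_below: 1.0
    above: 0.0
    source: paper
  veg_fat:
    ratio_threshold: 0.5
    favourable: 1.0
    unfavourable: 0.0
    source: paper
  sugar:
    high: 17.5
    low: 12.5
    points:
      above_high: -0.5
      mid: 0.0
      below_low: 1.0
    source: paper
  beverages:
    water_ml: 1000.0
    soda_ml: 250.0
    points:
      low_water_high_soda: 0.0
      high_water_high_soda: 0.5
      low_water_low_soda: 0.75
      high_water_low_soda: 1.0
    source: paper
  alcohol:
    threshold:
      F: 20.0
      M: 30.0
    abstainer: 1.0
    compliant: 0.8
    over: 0.0
    irregular_freq_per_week: 1.0
    source: paper
  salt:
    breaks:
    - 0.0
    - 6.0
    - 8.0
    - 10.0
    - 12.0
    points:
    - 1.5
    - 1.0
    - 0.5
    - 0.0
    - -0.5
    closure: right
    source: reference
  activity:
    breaks:
    - 0.0
    - 30.0
    - 60.0
    points:
    - 0.0
    - 1.0
    - 1.5
    source: paper
penalty_tolerance: 0.05
categories:
  pnns:
    low: 6.0
    high: 9.0
  mpnns:
    low: 5.5
    high: 8.5
pal:
  low: 1.55
  medium: 1.7
  high: 1.85
met_anchor:
  met_hours: 16.25
  minutes_per_day: 30.0
pa_points:
  low: 0.0
  medium: 1.0
  high: 1.5
met_table:
  walking_brisk: 6.5
  walking: 3.5
  cycling: 6.0
  swimming: 7.0
  running: 8.0
  gardening: 4.0
  tennis: 7.0
  gymnastics: 4.0
  dancing: 4.5
  hiking: 6.0
schofield:
  sex:
  - M
  - M
  - M
  - F
  - F
  - F
  age_min:
  - 18.0
  - 30.0
  - 60.0
  - 18.0
  - 30.0
  - 60.0
  age_max:
  - 30.0
  - 60.0
  - .na.real
  - 30.0
  - 60.0
  - .na.real
  slope:
  - 15.3
  - 11.6
  - 13.5
  - 14.7
  - 8.7
  - 10.5
  intercept:
  - 679.0
  - 879.0
  - 487.0
  - 496.0
  - 829.0
  - 596.0
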