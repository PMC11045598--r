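schema_version: 1
scenario:
  grid_rows: 120
  grid_cols: 120
  pixel_size: 30
  seed: 11
  epoch_years: [1985, 1990, 1995, 2000, 2010, 2015, 2020]
classes:
  codes: [1, 2, 3, 4, 5, 6]
  names: [forest, rangeland, cropland, barren, artificial, water]
  forest_code: 1
classifier:
  n_trees: 500
  seed: 1
  n_scenes: 10
  n_samples: 800
  train_fraction: 0.7
mlp:
  rms_target: 0.01
  max_iterations: 1000
projection:
  target_year: 2050
redd:
  emission_factor: 10
  effectiveness: 0.8
  displacement: 0.1
  horizon_years: 30
  reporting_period_years: 5
  belt_width_px: 8
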