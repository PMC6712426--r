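# Demo run configuration: a desk-scale end-to-end run (CSI simulation and
# quantification at the 2000/144 ms protocol, 1 mm phantoms, n = 12 cohort).
acquisition:
  tr: 2000
  te: 144
  bandwidth: 2000
  n_points: 2048
  field_ppm_hz: 127.728
  grid_shape: [9, 9]
  voxel_size: [15, 15, 15]
snr: 20
phase0_max: 30
half_width_ppm: 0.08
phantom:
  voxel_mm: 1.0
  image_shape: [96, 96, 96]
  icv_ml: 70.3
  noise_sd: 0
segmentation:
  tolerance: 20
  connectivity: 26
cohort:
  n_animals: 12
  sd_animal: 1.0
  sd_animal_region: 0.8
  sd_resid: 2.0
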