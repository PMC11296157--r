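{
  "n_specimens": 16,
  "split": [8, 3, 5],
  "n_chambers": [2, 3],
  "chamber_radius_vox": [3.5, 4.5],
  "wall_thickness_vox": [1.6, 2.0],
  "infill_fraction": [0.1, 0.5],
  "noise_sd": 300,
  "volume_shape": [16, 16, 16],
  "voxel_size_um": 1.75,
  "seed": 31
}
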