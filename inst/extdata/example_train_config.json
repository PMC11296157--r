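{
  "patch_size_vox": [8, 8, 8],
  "target_scale_vox": null,
  "stride_vox": 8,
  "batch_size": 8,
  "base_channels": 2,
  "learning_rate": 0.1,
  "class_weights": [1, 3, 6],
  "patience_epochs": 25,
  "max_epochs": 60,
  "n_replicates": 3,
  "seed": 7
}
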