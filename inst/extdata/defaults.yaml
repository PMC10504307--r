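# Pipeline defaults. The train/stitch/etdrs values carry the full-scale
# recipe (reconstruction weight 100, Adam 2e-4 / 1e-3, sliding-window stride
# 8 px, ETDRS 3 mm outer / 1 mm inner); the phantom and split sections are
# the scaled-down phantom study conditions.
seed: 1
phantom:
  n_subjects: 40
  image_size: 128
  px_per_mm: 24
  n_root_vessels: 6
  branch_prob: 0.25
split:
  n_train: 25
  n_val: 5
train:
  mode: synthesis
  epochs: 150
  patch_px: 64
  lambda: 100
  lr_g: 2.0e-4
  lr_d: 2.0e-4
  lr_segmentation: 1.0e-3
stitch:
  stride_px: 8
binarize:
  scales: [1.0, 1.5, 2.5]
  threshold: 0.5
  min_object_px: 10
etdrs:
  inner_diameter_mm: 1.0
  outer_diameter_mm: 3.0
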