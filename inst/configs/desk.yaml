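# Desk-scale phantom experiment: 64x64 phantoms, lightweight encoder,
# 20 epochs on CPU.
phantom:
  image_height: 64
  image_width: 64
  skin_band_fraction: 0.12
  gland_band_fraction: 0.35
  lesion_probability: 0.5
  malignant_fraction: 0.5
  lesion_radius_range: [5, 10]
  speckle_strength: 0.15
  contrast_lesion: -0.25
  classes: binary
model:
  desk_profile: true
  num_classes: 2
experiment:
  n_train: 200
  n_val: 50
  n_test: 50
  seed: 1
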