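# Ablation: fine decoder fed by category-selection features only.
phantom:
  image_height: 64
  image_width: 64
  classes: binary
model:
  desk_profile: true
  num_classes: 2
  fine:
    use_csm: true
    use_akgm: false
experiment:
  n_train: 200
  n_val: 50
  n_test: 50
  seed: 1
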