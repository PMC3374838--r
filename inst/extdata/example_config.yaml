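n_animals: 30
duration_s: 120.0
dt: 1.0
arena_mm:
- 25.0
- 25.0
dropout_prob: 0.33
min_spacing_mm: 1.0
mm_per_px: 0.01
n_substeps: 1
genotypes:
- wildtype
- dopamine_deficient
render: no
blob_sigma: 2.0
threshold: 0.05
min_area: 1
max_disp: 0.5
max_gap: 2
window: 5
min_track_s: 30.0
hist_bin_width: 0.006
curve_bin_width: 0.03
stat_field: speed_sd
seed: 1
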