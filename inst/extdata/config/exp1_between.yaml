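# Between-subject experiment (two arms, one session each), CI-scale
# profile: short blocks, 1,000 permutations, coarse predictor grid.
# Switch `profile: full` for the full-scale run (520-s blocks = 260
# 2-s epochs, 10,000 permutations, 10-mm grid).
profile: ci
design: between
cohort:
  n_subjects: 40
analysis:
  n_perm: 1000
  grid_spacing: 0.012
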