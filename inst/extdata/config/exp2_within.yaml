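# Within-subject replication (tACS and sham sessions per subject,
# order counterbalanced), CI-scale profile.
profile: ci
design: within
cohort:
  n_subjects: 19
analysis:
  n_perm: 1000
  grid_spacing: 0.012
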