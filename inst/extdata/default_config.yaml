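# Default pipeline configuration: the scanned task design (8 runs x 18
# trials), a 49-subject cohort, the 13 defensive-circuitry ROIs, and the
# documented generator defaults (100 voxels per ROI).
seed: 20260929
n_subjects: 49
alpha: 0.05
tau_variant: tau_a
roi_list:
  - amygdala_L
  - amygdala_R
  - hippocampus_L
  - hippocampus_R
  - insula_L
  - insula_R
  - acc_L
  - acc_R
  - vmpfc_L
  - vmpfc_R
  - vlpfc_L
  - vlpfc_R
  - midbrain
design:
  n_runs: 8
  trials_per_run: 18
  n_distal_per_run: 9
  n_imminent_per_run: 9
  n_per_level_per_run: 6
  p_both_shocked_on_help: 0.70
ratings: {}
neural:
  n_voxels: 100
decision: {}
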