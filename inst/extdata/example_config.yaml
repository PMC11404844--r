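# Canonical run configuration: defaults reproduce the study settings.
paths:
  trial_dir: fixtures
  trial_stem: trial_normal_seed0
  muscle_table: fixtures/muscle_params.tsv
solver:
  mesh: 100
  w_a: 1
  w_r: 1000
  w_v: 0.001
  T_R: 100
  tol_con: 1.0e-7
  a_min: 0.01
device:
  mode: spring        # none | motor | spring
  joint: ankle_pf     # ankle_pf | knee_ext | hip_flex | hip_abd
  b: 1000             # tanh engagement sharpness (1/s)
metabolics:
  basal: 0            # W/kg body mass; 0 = muscle-action rates only
  sigma: 250000.0     # specific tension (Pa)
  rho: 1059.7         # muscle density (kg/m^3)
output:
  dir: results
seed: 0
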