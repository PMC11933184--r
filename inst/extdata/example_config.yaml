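# Example pipeline configuration.  Every key is optional; omitted keys
# take the package defaults.  Parameter names follow param_registry().
seed: 1

parameters:
  T: 0.8          # cardiac period (s)
  pct_s: 0        # stenosis percentage diameter reduction

morris:
  r: 50           # trajectories
  p: 4            # grid levels
  oversample: 200 # candidate pool for spread-maximising selection

uq:
  n_samples: 110  # regression samples ('n' bare is a YAML boolean!)
  max_order: 2
  collocation_factor: 2

autoreg:
  pct: [20, 40, 50, 60]
  tolerance: 0.01
  max_iter: 50

cohort:
  n_patients: 41
  grafts_per_patient: 3
  class_mix: {patent: 0.5, questionable: 0.3, failed: 0.2}
  noise_sd_mlmin: 2
  jitter_sd_ms: 10
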