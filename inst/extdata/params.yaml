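# Example pipeline configuration. Omitted model parameters fall back to
# the documented defaults; the five structural parameters without a
# literature source (prevalence_albuminuria, p_fn_redetect,
# p_progress_symptomatic, p_fp_revert, p_recover) are logged as non-paper
# defaults when not set here.
cohort:
  source: simulate
  sim_params:
    n_patients: 157
model:
  discount_rate: 0.05
  horizon_years: 30
  wtp_threshold: 100000
analysis:
  comparator: DAY1
  psa_n: 1000
  seed: 1
  wtp_grid: {low: 0, high: 200000, step: 5000}
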