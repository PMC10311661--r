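# Demo configuration for `mitoscreen run` / run_discovery().
# Any value omitted here falls back to default_config(); every planted
# effect below is strong enough to be recovered at this small scale.
seed: 1
stages:
  simulate: true
  connect: true
  kinome: true
  amses: true
  slscreen: true
  synergy: true
cohort:
  n_patients: 150
  n_genes: 400
  n_signature_genes: 40
  anchor_gene: GSG2
  factor_loading: 1.0
  tumor_shift: 1.0
  hazard_beta: 0.5
  sl_partner_gene: BG001
  sl_interaction_beta: 1.2
  censor_rate: 0.2
  noise_sd: 0.5
kinome:
  n_kinases: 403
  n_mutant: 0
  n_hits: 17
  threshold: 10
connect:
  n_profiles: 21
  planted_id: CPD-PLANTED
  signal: 3
amses:
  tau: 0.25
  fdr_cut: 0.05
  elevation_fdr: 0.05
slscreen:
  n_decoys: 30
  split: median
  candidate_covariate: low-indicator
synergy:
  combo_alpha: 0.5
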