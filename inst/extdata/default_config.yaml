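# Default model configuration. Every tunable referenced in the documentation
# lives here; sglt_config() merges user overrides on top.
absorption:
  # Effective absorption surface constants (cm^-1). The absorption rate
  # constant is ka = intestinal permeability (cm/min) * 60 * surface constant,
  # calibrated once per drug so simulated tmax falls in the 1-2.5 h range.
  surface_per_cm:
    dapagliflozin: 183.0
    canagliflozin: 0.455
    empagliflozin: 17.5
    ipragliflozin: 344.0
  # first-order loss from gut lumen to feces, h^-1
  fecal_transit_per_h: 0.02
hepatic:
  # reference hepatic enzyme amount (umol) multiplying the specific
  # (per-umol-enzyme) clearances; calibrated once against healthy-subject
  # plasma clearance of dapagliflozin
  enzyme_reference_umol: 4.5
renal:
  # P-gp transporter amount (umol) and placement (kidney apical membrane,
  # secreting into tubule lumen, or gut)
  pgp_amount_umol: 0.01
  pgp_site: kidney
blood:
  plasma_ratio: 1.0
solver:
  rtol: 1.0e-6
  atol: 1.0e-8
  dt_out_h: 0.1
tubule:
  v_s1_l: 0.0075
  v_s2_l: 0.0075
  # fractional water reabsorption upstream of the S1/S2 boundary (proximal
  # tubule plus the unrepresented loop segment); S2 reabsorption is derived so
  # that urine flow matches urine_flow_l_day at the reference GFR
  f_reab_s1: 0.95
  urine_flow_l_day: 1.5
  # calibration targets for transporter amounts (threshold & transport maximum
  # at the reference GFR; both scale linearly with GFR)
  threshold_mmol_l: 10.0
  tm_mg_min_ref: 375.0
  gfr_ref_ml_min: 105.0
  # operational threshold definition: steady-state glucose spill (g/day, at
  # the reference GFR) marking the onset of overt glycosuria at the threshold
  # plasma glucose
  threshold_spill_g_day: 2.0
  # concentration driving transporter inhibition: unbound plasma
  # concentration, or the renal excretion flux diluted into tubular inflow
  luminal_model: plasma_unbound   # plasma_unbound | excretion_flux
  use_ki: true
  use_occupancy: true
glucose_plasma_mmol_l:
  t2dm: 8.0
  healthy: 5.5
population:
  # geometric SD of lognormal organ volume/flow variability
  organ_gsd: 1.16
  # coefficient of variation of GFR within a CKD stage
  gfr_cv: 0.15
  age_mean: 30
  age_sd: 5
  weight_mean_male: 73
  weight_mean_female: 60
  weight_sd: 10
  bmi_mean: 27
  bmi_sd: 4
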