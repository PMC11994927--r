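test_that("tubule geometry reproduces the daily urine volume and scales with GFR", {
  g <- tubule_geometry(105)
  expect_equal(g$urine_flow_l_h * 24, 1.5, tolerance = 1e-10)
  g2 <- tubule_geometry(52.5)
  expect_equal(g2$urine_flow_l_h / g$urine_flow_l_h, 0.5, tolerance = 1e-10)
  expect_equal(g$q_in_l_h, 6.3)
})

test_that("reabsorption flux follows Michaelis-Menten with competitive inhibition", {
  expect_equal(reabsorption_flux(400, 100, 400), 50)           # half saturation
  # d = ki doubles the apparent Km: flux(c = 2 km) = vmax/2
  expect_equal(reabsorption_flux(800, 100, 400, d_lumen = 2, ki = 2), 50)
  # direct arithmetic oracle
  expect_equal(reabsorption_flux(400, 100, 400, d_lumen = 0.1, ki = 1e-4),
               100 * 400 / (400 * 1001 + 400), tolerance = 1e-12)
  expect_error(reabsorption_flux(-1, 1, 1), class = "sgltsim_validation_error")
  expect_error(reabsorption_flux(1, 1, 1, d_lumen = 1, ki = 0),
               class = "sgltsim_validation_error")
})

test_that("occupancy kinetics: equilibrium, isotherm, and exponential decay", {
  # at d = kd the equilibrium occupancy is 0.5 (rate vanishes there)
  expect_equal(occupancy_rate(1.57e-3, 0.5, kd = 1.57e-3, koff = 6.3e-4), 0)
  # equilibrium occupancy = d/(d+kd): dapagliflozin SGLT2 at d = 0.1 umol/L
  d <- 0.1; kd <- 1.57e-3
  occ_eq <- d / (d + kd)
  expect_equal(occ_eq, 0.9845, tolerance = 1e-4)
  expect_equal(occupancy_rate(d, occ_eq, kd, 6.3e-4), 0, tolerance = 1e-12)
  # drug-free decay: integrating the rate reproduces occ0 * exp(-koff t)
  koff <- 0.3
  sol <- deSolve::lsoda(
    c(occ = 0.8), seq(0, 10, 0.5),
    function(t, y, p) list(occupancy_rate(0, y[[1]], kd = 1, koff = koff)),
    parms = NULL, rtol = 1e-10, atol = 1e-12)
  expect_equal(sol[, "occ"], 0.8 * exp(-koff * sol[, "time"]),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(occupancy_rate(0.1, 1.2, 1, 1),
               class = "sgltsim_validation_error")
})

test_that("filtered glucose load arithmetic", {
  expect_equal(filtered_glucose_load(105, 8, 24),
               0.105 * 60 * 8 * 24 * 180.16 / 1000, tolerance = 1e-12)
  expect_equal(filtered_glucose_load(105, 8, 24), 217.9, tolerance = 1e-3)
  expect_equal(filtered_glucose_load(0, 8, 24), 0)
})

test_that("transporter calibration hits both targets", {
  cal <- calibrate_transporter_amounts(sglt_glucose(), tubule_geometry(105))
  # Tm identity: the two maximal rates sum to the target exactly
  tm_umol_h <- 375 * 60 / 180.16 * 1000
  expect_equal(sum(cal$vmax_umol_h), tm_umol_h, tolerance = 1e-10)
  expect_true(cal$sglt2_share > 0.5)   # SGLT2-dominant capacity
  # threshold contract: drug-free steady spill at 10 mmol/L equals the
  # 2 g/day target within 2% (simulated over 24 h from an empty tubule)
  u <- simulate_uge(gfr_ml_min = 105, plasma_glucose_mmol_l = 10)
  expect_equal(glance(u)$uge_24h_g, 2, tolerance = 0.02)
})

test_that("calibration split is GFR-invariant and amounts scale linearly", {
  glu <- sglt_glucose()
  cal_ref <- calibrate_transporter_amounts(glu, tubule_geometry(105),
                                           target_tm_mg_min = 375)
  cal_low <- calibrate_transporter_amounts(glu, tubule_geometry(45),
                                           target_tm_mg_min = 375 * 45 / 105)
  expect_equal(cal_low$sglt2_share, cal_ref$sglt2_share, tolerance = 1e-9)
  expect_equal(cal_low$vmax_umol_h / cal_ref$vmax_umol_h,
               c(SGLT1 = 45 / 105, SGLT2 = 45 / 105), tolerance = 1e-9)
})

test_that("unattainable calibration targets raise a typed error", {
  expect_error(
    calibrate_transporter_amounts(sglt_glucose(), tubule_geometry(105),
                                  threshold_spill_g_day = 400),
    class = "sgltsim_calibration_error")
  # a tiny Tm cannot clear the threshold load at a small spill
  expect_error(
    calibrate_transporter_amounts(sglt_glucose(), tubule_geometry(105),
                                  target_tm_mg_min = 10),
    class = "sgltsim_calibration_error")
})

test_that("drug-free normoglycemic urine is essentially glucose-free", {
  u <- simulate_uge(gfr_ml_min = 105, plasma_glucose_mmol_l = 5.5)
  expect_lt(glance(u)$uge_24h_g, 1)
})

test_that("glucose mass is conserved along the tubule", {
  pk <- dapa_pk_10mg()
  u <- simulate_uge(pk)
  tc <- u$timecourse
  end <- nrow(tc)
  filtered_umol <- u$inflow_umol_h * tc$time_h[end]
  accounted <- tc$cumulative_uge_g[end] * 1e6 / 180.16 +
    tc$cumulative_reabsorbed_umol[end] +
    tc$s1_glucose_umol[end] + tc$s2_glucose_umol[end]
  expect_equal(accounted / filtered_umol, 1, tolerance = 5e-3)
})

test_that("full transporter inhibition excretes the filtered load", {
  u <- simulate_uge(gfr_ml_min = 105, plasma_glucose_mmol_l = 8,
                    capacity_scaling = c(SGLT1 = 0, SGLT2 = 0))
  g <- glance(u)
  expect_equal(g$uge_24h_g / g$filtered_load_g, 1, tolerance = 0.02)
  expect_equal(g$filtered_load_g, 217.9, tolerance = 1e-3)
})

test_that("UGE requires a GFR when no PK run is supplied", {
  expect_error(simulate_uge(), class = "sgltsim_validation_error")
  expect_error(simulate_uge(gfr_ml_min = -5),
               class = "sgltsim_validation_error")
})

test_that("steady-state occupancy initialization raises first-day UGE", {
  pk <- dapa_pk_10mg()
  u_day1 <- simulate_uge(pk)
  u_ss <- simulate_uge(pk, occupancy0 = "steady_state")
  expect_gt(u_ss$timecourse$occ_sglt2[1], 0.3)
  expect_gt(glance(u_ss)$uge_24h_g, glance(u_day1)$uge_24h_g)
  # drug-free run: steady-state occupancy is zero
  u0 <- simulate_uge(gfr_ml_min = 105, occupancy0 = "steady_state")
  expect_equal(max(u0$timecourse$occ_sglt2), 0)
})

test_that("the two inhibition mechanisms are individually switchable", {
  pk <- dapa_pk_10mg()
  base <- glance(simulate_uge(pk))$uge_24h_g
  no_ki <- glance(simulate_uge(pk, config = sglt_config(
    overrides = list(tubule = list(use_ki = FALSE)))))$uge_24h_g
  no_occ <- glance(simulate_uge(pk, config = sglt_config(
    overrides = list(tubule = list(use_occupancy = FALSE)))))$uge_24h_g
  neither <- glance(simulate_uge(pk, config = sglt_config(
    overrides = list(tubule = list(use_ki = FALSE,
                                   use_occupancy = FALSE)))))$uge_24h_g
  drug_free <- glance(simulate_uge(gfr_ml_min = 105))$uge_24h_g
  expect_lt(no_ki, base);  expect_lt(no_occ, base)
  expect_equal(neither, drug_free, tolerance = 1e-6)
})

test_that("luminal drug model is switchable and affects exposure", {
  pk <- dapa_pk_10mg()
  u_pl <- simulate_uge(pk)
  u_ex <- simulate_uge(pk, config = sglt_config(
    overrides = list(tubule = list(luminal_model = "excretion_flux"))))
  expect_false(isTRUE(all.equal(max(u_pl$timecourse$luminal_drug_umol_l),
                                max(u_ex$timecourse$luminal_drug_umol_l))))
  expect_error(simulate_uge(pk, config = sglt_config(
    overrides = list(tubule = list(luminal_model = "nonsense")))),
    class = "sgltsim_config_error")
})
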