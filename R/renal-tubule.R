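# Three-segment renal tubule glucodynamics: S1 (proximal tubule, carries both
# SGLT transporters), S2 (distal + collecting, pure transit with water
# reabsorption), S3 (bladder, accumulates urinary glucose). Glucose is
# filtered into S1 at GFR x plasma glucose, reabsorbed by saturable SGLT1 and
# SGLT2 transport under drug inhibition, and whatever escapes S2 accumulates
# in the bladder as urinary glucose excretion (UGE).
#
# Inhibition combines two printed mechanisms, each individually switchable:
# competitive Km inflation via Ki (instantaneous), and slow-binding occupancy
# via Kd/koff (kon = koff/Kd) reducing the available transport capacity.

#' Tubule geometry and flows
#'
#' Luminal segment volumes and the water-reabsorption split. The S2 fraction
#' is derived once so that urine flow matches the configured daily urine
#' volume at the reference GFR; fractions are then held fixed, so urine flow
#' scales proportionally with GFR.
#'
#' @param gfr_ml_min Glomerular filtration rate, mL/min.
#' @param config A [sglt_config()].
#' @return A `tubule_geometry` list: `v_s1_l`, `v_s2_l`, `q_in_l_h`,
#'   `f_reab_s1`, `f_reab_s2`, `q_s1_out_l_h`, `urine_flow_l_h`.
#' @examples
#' tubule_geometry(105)$urine_flow_l_h * 24   # ~ 1.5 L/day
#' @export
tubule_geometry <- function(gfr_ml_min, config = sglt_config()) {
  stopifnot(gfr_ml_min >= 0)
  tb <- config$tubule
  gfr_ref_l_h <- ml_min_to_l_h(tb$gfr_ref_ml_min)
  urine_ref_l_h <- tb$urine_flow_l_day / 24
  f1 <- tb$f_reab_s1
  f2 <- 1 - urine_ref_l_h / (gfr_ref_l_h * (1 - f1))
  stopifnot(f1 >= 0, f1 < 1, f2 >= 0, f2 < 1)
  q_in <- ml_min_to_l_h(gfr_ml_min)
  structure(list(
    v_s1_l = tb$v_s1_l, v_s2_l = tb$v_s2_l, q_in_l_h = q_in,
    f_reab_s1 = f1, f_reab_s2 = f2,
    q_s1_out_l_h = q_in * (1 - f1),
    urine_flow_l_h = q_in * (1 - f1) * (1 - f2)
  ), class = "tubule_geometry")
}

#' Saturable glucose reabsorption flux under competitive inhibition
#'
#' Michaelis-Menten transport with the apparent Km inflated by the luminal
#' inhibitor concentration: `vmax_eff * c / (km * (1 + d/ki) + c)`.
#'
#' @param c_lumen Luminal glucose concentration, umol/L.
#' @param vmax_eff Effective maximal transport rate, umol/h.
#' @param km Michaelis constant, umol/L.
#' @param d_lumen Luminal inhibitor concentration, umol/L.
#' @param ki Competitive inhibition constant, umol/L.
#' @return Flux in umol/h, between 0 and `vmax_eff`.
#' @examples
#' reabsorption_flux(400, 100, 400)       # half-saturation: 50
#' @export
reabsorption_flux <- function(c_lumen, vmax_eff, km, d_lumen = 0, ki = Inf) {
  if (any(c(c_lumen, vmax_eff, d_lumen) < 0) || any(km <= 0) ||
      (any(d_lumen > 0) && any(ki <= 0))) {
    abort("reabsorption_flux inputs must be non-negative (km, ki positive).",
          class = "sgltsim_validation_error")
  }
  vmax_eff * c_lumen / (km * (1 + d_lumen / ki) + c_lumen)
}

#' Rate of change of slow-binding transporter occupancy
#'
#' `d occ/dt = (koff/kd) * d * (1 - occ) - koff * occ`; the equilibrium
#' occupancy is the binding isotherm `d / (d + kd)`.
#'
#' @param d_lumen Inhibitor concentration at the transporter, umol/L.
#' @param occ Current occupancy fraction in \[0, 1\].
#' @param kd Binding dissociation constant, umol/L.
#' @param koff Dissociation rate constant, h^-1.
#' @return d occ/dt, h^-1.
#' @examples
#' occupancy_rate(1.57e-3, 0.5, 1.57e-3, 6.3e-4)  # zero at equilibrium
#' @export
occupancy_rate <- function(d_lumen, occ, kd, koff) {
  if (any(occ < 0) || any(occ > 1)) {
    abort("Occupancy must be within [0, 1].",
          class = "sgltsim_validation_error")
  }
  stopifnot(kd > 0, koff > 0, all(d_lumen >= 0))
  (koff / kd) * d_lumen * (1 - occ) - koff * occ
}

#' Filtered glucose load
#'
#' Glucose mass filtered at the glomerulus over a period, in grams.
#'
#' @param gfr_ml_min GFR, mL/min.
#' @param plasma_glucose_mmol_l Plasma glucose, mmol/L.
#' @param duration_h Duration, h.
#' @return Grams of glucose.
#' @examples
#' filtered_glucose_load(105, 8, 24)   # ~ 217.9 g/day
#' @export
filtered_glucose_load <- function(gfr_ml_min, plasma_glucose_mmol_l,
                                  duration_h) {
  stopifnot(gfr_ml_min >= 0, plasma_glucose_mmol_l >= 0, duration_h >= 0)
  ml_min_to_l_h(gfr_ml_min) * plasma_glucose_mmol_l * duration_h *
    GLUCOSE_MW / 1000
}

#' Calibrate tubular transporter amounts
#'
#' Determines the SGLT2 and SGLT1 transporter amounts so that the drug-free
#' tubule reproduces two physiological targets at the given geometry: the
#' total transport maximum (Tm, the sum of the two maximal transport rates)
#' and the renal glucose threshold, defined operationally as the plasma
#' glucose at which the steady-state urinary glucose spill equals
#' `threshold_spill_g_day` grams per day -- the onset of overt glycosuria.
#' Because the spill target and Tm both scale with GFR, the capacity split
#' between the two transporters is GFR-invariant, and at steady state the
#' split has a closed-form solution: the required S1 outflow concentration is
#' fixed by the spill target, and the two saturable fluxes are linear in the
#' SGLT2 share at that concentration.
#'
#' The spill target is expressed at `gfr_ref_ml_min` and scaled linearly to
#' the geometry's GFR, like Tm (pass `target_tm_mg_min` already scaled).
#'
#' @param glucose An [sglt_glucose()] record (Km, kcat per transporter).
#' @param geometry A [tubule_geometry()].
#' @param target_threshold_mmol_l Renal glucose threshold target, mmol/L.
#' @param target_tm_mg_min Transport maximum target, mg/min, at the
#'   geometry's GFR.
#' @param threshold_spill_g_day Urinary glucose spill (g/day, at the
#'   reference GFR) defining the threshold.
#' @param gfr_ref_ml_min Reference GFR at which the spill target and the
#'   default Tm apply.
#' @return A `tubule_calibration` list: `amounts_umol` and `vmax_umol_h`,
#'   both named by transporter, plus `sglt2_share` and the targets.
#' @examples
#' calibrate_transporter_amounts(sglt_glucose(), tubule_geometry(105))
#' @export
calibrate_transporter_amounts <- function(glucose, geometry,
                                          target_threshold_mmol_l = 10,
                                          target_tm_mg_min = 375,
                                          threshold_spill_g_day = 2,
                                          gfr_ref_ml_min = 105) {
  stopifnot(inherits(geometry, "tubule_geometry"),
            target_threshold_mmol_l > 0, target_tm_mg_min > 0,
            threshold_spill_g_day > 0, gfr_ref_ml_min > 0)
  km <- glucose$sglt_km                     # umol/L
  kcat_h <- glucose$sglt_kcat * 60          # h^-1
  tm_umol_h <- target_tm_mg_min * 60 / GLUCOSE_MW * 1000
  inflow <- geometry$q_in_l_h * target_threshold_mmol_l * 1000  # umol/h
  q1 <- geometry$q_s1_out_l_h
  # spill target scaled to this GFR, umol/h
  spill <- mg_to_umol(threshold_spill_g_day * 1000, GLUCOSE_MW) / 24 *
    geometry$q_in_l_h / ml_min_to_l_h(gfr_ref_ml_min)
  if (spill >= inflow) {
    abort("Spill target exceeds the filtered load at the threshold.",
          class = "sgltsim_calibration_error")
  }
  # at steady state all glucose leaving S1 is excreted, so the S1 outflow
  # concentration at the threshold is fixed by the spill target
  c_star <- spill / q1
  a1 <- tm_umol_h * c_star / (km[["SGLT1"]] + c_star)
  a2 <- tm_umol_h * c_star / (km[["SGLT2"]] + c_star)
  share2 <- (a1 - (inflow - spill)) / (a1 - a2)
  if (!is.finite(share2) || share2 <= 0 || share2 >= 1) {
    abort(paste0(
      "Calibration targets unattainable: no SGLT2/SGLT1 split reproduces a ",
      format(threshold_spill_g_day), " g/day spill at the threshold ",
      "(required SGLT2 share ", format(round(share2, 3)), ")."),
      class = "sgltsim_calibration_error")
  }
  vmax <- c(SGLT1 = (1 - share2) * tm_umol_h, SGLT2 = share2 * tm_umol_h)
  structure(list(
    amounts_umol = vmax / kcat_h[names(vmax)],
    vmax_umol_h = vmax,
    sglt2_share = share2,
    target_threshold_mmol_l = target_threshold_mmol_l,
    target_tm_mg_min = target_tm_mg_min,
    threshold_spill_g_day = threshold_spill_g_day
  ), class = "tubule_calibration")
}

#' Simulate urinary glucose excretion
#'
#' Runs the three-segment tubule model over 24 h (or the span of the supplied
#' PK simulation), driven by a constant plasma glucose and, when a `pk_sim`
#' is given, by the time-varying inhibitor concentration derived from it.
#' Transporter capacity is calibrated at the subject's GFR (Tm scaling
#' linearly with GFR) and then scaled by the CKD-stage capacity factors.
#'
#' @param pk A [simulate_pk()] result, or `NULL` for a drug-free run.
#' @param gfr_ml_min Subject GFR; defaults to the PK model's physiology.
#' @param plasma_glucose_mmol_l Constant plasma glucose; defaults to the
#'   configured T2DM level.
#' @param capacity_scaling Named fractions in \[0, 1\] per transporter
#'   multiplying the calibrated capacity (see [transporter_scaling()]).
#' @param config A [sglt_config()]; defaults to the PK model's config.
#' @param duration_h Simulation span, h.
#' @param occupancy0 Initial occupancy per transporter (named, default 0), or
#'   the string `"steady_state"` to start at the long-run periodic occupancy
#'   under once-daily maintenance dosing. Because the class dissociation rates
#'   are far slower than the daily exposure cycle, occupancy ratchets up over
#'   repeated doses toward the averaged-rate limit
#'   `kon * mean(d) / (kon * mean(d) + koff)`, which is used directly.
#' @param calibration Optional pre-computed [calibrate_transporter_amounts()]
#'   result (must match the geometry).
#' @return A `uge_sim` object; `$timecourse` has columns `time_h`,
#'   `s1_glucose_umol`, `s2_glucose_umol`, `cumulative_uge_g`,
#'   `flux_sglt1_umol_h`, `flux_sglt2_umol_h`, `luminal_drug_umol_l`,
#'   `occ_sglt1`, `occ_sglt2`.
#' @examples
#' \donttest{
#' pk <- simulate_pk(build_pbpk_model(sglt_drug("dapagliflozin")),
#'                   dose_regimen(10))
#' uge <- simulate_uge(pk)
#' glance(uge)$uge_24h_g
#' }
#' @export
simulate_uge <- function(pk = NULL, gfr_ml_min = NULL,
                         plasma_glucose_mmol_l = NULL,
                         capacity_scaling = c(SGLT1 = 1, SGLT2 = 1),
                         config = NULL, duration_h = 24,
                         occupancy0 = c(SGLT1 = 0, SGLT2 = 0),
                         calibration = NULL) {
  if (!is.null(pk)) {
    stopifnot(inherits(pk, "pk_sim"))
    config <- config %||% pk$model$config
    gfr_ml_min <- gfr_ml_min %||% pk$model$physiology$gfr_ml_min
    duration_h <- min(duration_h, max(pk$timecourse$time_h))
  }
  config <- config %||% sglt_config()
  if (is.null(gfr_ml_min)) {
    abort("gfr_ml_min is required when no PK simulation is supplied.",
          class = "sgltsim_validation_error")
  }
  if (gfr_ml_min < 0) {
    abort("GFR must be non-negative.", class = "sgltsim_validation_error")
  }
  plasma_glucose_mmol_l <- plasma_glucose_mmol_l %||%
    config$glucose_plasma_mmol_l$t2dm
  stopifnot(plasma_glucose_mmol_l > 0,
            all(capacity_scaling >= 0), all(capacity_scaling <= 1))

  tb <- config$tubule
  geom <- tubule_geometry(gfr_ml_min, config)
  glucose <- if (!is.null(pk) && !is.null(pk$model$glucose)) pk$model$glucose
             else sglt_glucose()
  tm_target <- tb$tm_mg_min_ref * gfr_ml_min / tb$gfr_ref_ml_min
  if (is.null(calibration)) {
    calibration <- calibrate_transporter_amounts(
      glucose, geom, tb$threshold_mmol_l, tm_target,
      tb$threshold_spill_g_day, tb$gfr_ref_ml_min)
  }
  scal <- c(SGLT1 = 1, SGLT2 = 1)
  scal[names(capacity_scaling)] <- capacity_scaling
  vmax_base <- calibration$vmax_umol_h * scal[names(calibration$vmax_umol_h)]

  # inhibitor concentration at the transporter, umol/L
  d_fun <- function(t) 0
  drug <- if (!is.null(pk)) pk$model$drug else NULL
  if (!is.null(drug)) {
    tc <- pk$timecourse
    d_fun <- switch(
      tb$luminal_model,
      plasma_unbound = {
        cu <- approxfun(tc$time_h, drug$fup * tc$conc_ng_ml / drug$molecular_weight,
                        rule = 2)
        cu
      },
      excretion_flux = {
        fl <- approxfun(tc$time_h,
                        tc$renal_flux_umol_h / max(geom$q_in_l_h, 1e-12),
                        rule = 2)
        fl
      },
      abort("Unknown luminal_model.", class = "sgltsim_config_error"))
  }
  ki <- ki_umol <- c(SGLT1 = Inf, SGLT2 = Inf)
  kd <- c(SGLT1 = 1, SGLT2 = 1); koff <- c(SGLT1 = 0, SGLT2 = 0)
  if (!is.null(drug)) {
    ki_umol <- purrr::map_dbl(drug$sglt, ~ .x$ki_nmol_l / 1000)
    kd <- purrr::map_dbl(drug$sglt, ~ .x$kd_umol_l)
    koff <- purrr::map_dbl(drug$sglt, ~ .x$koff_per_h)
    if (isTRUE(tb$use_ki)) ki <- ki_umol
  }
  use_occ <- isTRUE(tb$use_occupancy) && !is.null(drug)
  if (identical(occupancy0, "steady_state")) {
    occupancy0 <- c(SGLT1 = 0, SGLT2 = 0)
    if (use_occ) {
      d_bar <- mean(d_fun(seq(0, duration_h, by = config$solver$dt_out_h)))
      kon_bar <- koff / kd * d_bar
      occupancy0 <- kon_bar / (kon_bar + koff)
    }
  }

  km <- glucose$sglt_km
  cp_glu <- plasma_glucose_mmol_l * 1000       # umol/L
  inflow <- geom$q_in_l_h * cp_glu             # umol/h
  q1 <- geom$q_s1_out_l_h; q2 <- geom$urine_flow_l_h
  v1 <- geom$v_s1_l; v2 <- geom$v_s2_l

  # scalar locals: the right-hand side runs thousands of times per solve, so
  # named-vector lookups are hoisted out of the closure
  vmax1 <- vmax_base[["SGLT1"]]; vmax2 <- vmax_base[["SGLT2"]]
  km1 <- km[["SGLT1"]]; km2 <- km[["SGLT2"]]
  ki1 <- ki[["SGLT1"]]; ki2 <- ki[["SGLT2"]]
  kon1 <- koff[["SGLT1"]] / kd[["SGLT1"]]
  kon2 <- koff[["SGLT2"]] / kd[["SGLT2"]]
  koff1 <- koff[["SGLT1"]]; koff2 <- koff[["SGLT2"]]
  rhs <- function(t, y, p) {
    d <- d_fun(t)
    c1 <- y[[1]] / v1
    c2 <- y[[2]] / v2
    o1 <- y[[5]]; o2 <- y[[6]]
    a1 <- if (use_occ) 1 - o1 else 1
    a2 <- if (use_occ) 1 - o2 else 1
    j1 <- vmax1 * a1 * c1 / (km1 * (1 + d / ki1) + c1)
    j2 <- vmax2 * a2 * c1 / (km2 * (1 + d / ki2) + c1)
    docc1 <- if (use_occ) kon1 * d * (1 - o1) - koff1 * o1 else 0
    docc2 <- if (use_occ) kon2 * d * (1 - o2) - koff2 * o2 else 0
    list(c(inflow - j1 - j2 - q1 * c1,
           q1 * c1 - q2 * c2,
           q2 * c2,
           j1 + j2,
           docc1, docc2),
         flux_sglt1_umol_h = j1, flux_sglt2_umol_h = j2,
         luminal_drug_umol_l = d)
  }
  y0 <- c(g1 = 0, g2 = 0, uge = 0, reab = 0,
          occ1 = unname(occupancy0[["SGLT1"]]),
          occ2 = unname(occupancy0[["SGLT2"]]))
  times <- seq(0, duration_h, by = config$solver$dt_out_h)
  sol <- deSolve::lsoda(y0, times, rhs, parms = NULL,
                        rtol = config$solver$rtol, atol = 1e-6)
  if (attr(sol, "istate")[1] < 0) {
    abort("Glucodynamic integration failed.",
          class = "sgltsim_integration_error")
  }
  tc <- tibble::as_tibble(as.data.frame(sol))
  tc <- tibble::tibble(
    time_h = tc$time,
    s1_glucose_umol = pmax(tc$g1, 0),
    s2_glucose_umol = pmax(tc$g2, 0),
    cumulative_uge_g = pmax(tc$uge, 0) * GLUCOSE_MW / 1e6,
    cumulative_reabsorbed_umol = tc$reab,
    flux_sglt1_umol_h = tc$flux_sglt1_umol_h,
    flux_sglt2_umol_h = tc$flux_sglt2_umol_h,
    luminal_drug_umol_l = tc$luminal_drug_umol_l,
    occ_sglt1 = tc$occ1, occ_sglt2 = tc$occ2
  )
  structure(list(
    timecourse = tc, drug = drug, gfr_ml_min = gfr_ml_min,
    plasma_glucose_mmol_l = plasma_glucose_mmol_l,
    capacity_scaling = scal, calibration = calibration, geometry = geom,
    inflow_umol_h = inflow, duration_h = duration_h
  ), class = "uge_sim")
}

#' @export
print.uge_sim <- function(x, ...) {
  cat(sprintf(
    "<uge_sim> %s, GFR %.0f mL/min, plasma glucose %.1f mmol/L\n",
    if (!is.null(x$drug)) x$drug$name else "drug-free",
    x$gfr_ml_min, x$plasma_glucose_mmol_l))
  cat(sprintf("  24-h UGE %.2f g (filtered load %.1f g)\n",
              glance(x)$uge_24h_g, glance(x)$filtered_load_g))
  invisible(x)
}

#' @exportS3Method
tidy.uge_sim <- function(x, ...) x$timecourse

#' @exportS3Method
glance.uge_sim <- function(x, ...) {
  tc <- x$timecourse
  end <- nrow(tc)
  tibble::tibble(
    uge_24h_g = tc$cumulative_uge_g[end],
    filtered_load_g = filtered_glucose_load(
      x$gfr_ml_min, x$plasma_glucose_mmol_l, tc$time_h[end]),
    peak_occ_sglt2 = max(tc$occ_sglt2),
    peak_luminal_drug_umol_l = max(tc$luminal_drug_umol_l)
  )
}
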