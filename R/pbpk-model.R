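# Minimal whole-body perfusion-limited PBPK model.
#
# Structure: first-order absorption from the gut lumen into gut tissue,
# parallel perfusion-limited tissues exchanging with a single well-stirred
# blood pool, a portal connection gut -> liver, enzyme-specific (or
# whole-liver) hepatic metabolism on the unbound liver outflow concentration,
# linear renal plasma clearance or GFR-fraction filtration into the tubule
# lumen, and optional saturable P-gp secretion. All internal rates are in
# umol, L, h.

#' Oral dosing regimen
#'
#' @param dose_mg Dose per administration, mg (>= 0).
#' @param n_doses Number of doses (>= 1).
#' @param interval_h Dosing interval, h.
#' @param duration_h Simulation duration, h; must cover the last dose.
#' @return A `dose_regimen` object.
#' @examples
#' dose_regimen(10)                       # single 10 mg dose, 24 h
#' dose_regimen(25, n_doses = 7, interval_h = 24, duration_h = 192)
#' @export
dose_regimen <- function(dose_mg, n_doses = 1, interval_h = 24,
                         duration_h = 24) {
  stopifnot(is.numeric(dose_mg), length(dose_mg) == 1,
            n_doses >= 1, n_doses == as.integer(n_doses), interval_h > 0)
  if (dose_mg < 0) {
    abort("dose_mg must be >= 0.", class = "sgltsim_validation_error")
  }
  if (duration_h < (n_doses - 1) * interval_h) {
    abort("duration_h must cover the dosing interval span.",
          class = "sgltsim_validation_error")
  }
  structure(list(route = "oral", dose_mg = dose_mg, n_doses = n_doses,
                 interval_h = interval_h, duration_h = duration_h),
            class = "dose_regimen")
}

#' Build the whole-body PBPK model for a drug
#'
#' Assembles the ODE right-hand side with named states (gut lumen, ten
#' perfused tissues, blood, and cumulative metabolized / renally excreted /
#' unabsorbed amounts), with all rate constants converted to the internal
#' unit system (umol, L, h).
#'
#' @param drug An [sglt_drug()].
#' @param glucose An [sglt_glucose()] record (carried along for downstream
#'   glucodynamic coupling).
#' @param physiology A [reference_physiology()].
#' @param config A [sglt_config()].
#' @return A `pbpk_model` object.
#' @examples
#' mod <- build_pbpk_model(sglt_drug("dapagliflozin"))
#' mod$params$cl_renal_l_h
#' @export
build_pbpk_model <- function(drug, glucose = sglt_glucose(),
                             physiology = reference_physiology(),
                             config = sglt_config()) {
  stopifnot(inherits(drug, "sglt_drug"))
  validate_physiology(physiology)

  organs <- physiology$organs
  V <- setNames(organs$volume_l, organs$compartment)
  Q <- setNames(organs$flow_l_h, organs$compartment)
  kp_tab <- compute_partition_coefficients(drug, physiology)
  kp <- setNames(kp_tab$kp, kp_tab$compartment)
  tissues <- setdiff(organs$compartment, c("blood", "gut", "liver"))

  # absorption: ka = specific intestinal permeability x surface constant
  sa <- config$absorption$surface_per_cm[[drug$name]]
  if (is.null(sa)) sa <- 100  # generic fallback for user-defined drugs
  ka <- drug$intestinal_permeability * 60 * sa          # h^-1
  kf <- config$absorption$fecal_transit_per_h

  # hepatic elimination
  abund <- function(enzyme) {
    ea <- physiology$enzyme_abundance
    if (enzyme %in% names(ea)) ea[[enzyme]] else 1
  }
  cl_int_l_h <- 0
  if (length(drug$enzyme_clearances)) {
    cl_int_l_h <- sum(purrr::imap_dbl(
      drug$enzyme_clearances,
      function(cl, enz) cl * 60 * config$hepatic$enzyme_reference_umol * abund(enz)))
  }
  cl_h_l_h <- if (!is.null(drug$hepatic_clearance_specific)) {
    drug$hepatic_clearance_specific * physiology$body_weight
  } else 0

  # renal elimination (linear): CL_R as printed, else filtration clearance
  gfr_l_h <- ml_min_to_l_h(physiology$gfr_ml_min)
  cl_renal_l_h <- if (!is.null(drug$renal_plasma_clearance)) {
    drug$renal_plasma_clearance
  } else if (!is.null(drug$gfr_fraction)) {
    drug$gfr_fraction * drug$fup * gfr_l_h
  } else 0

  has_pgp <- !is.null(drug$pgp_km) && !is.null(drug$pgp_kcat)
  vmax_pgp <- if (has_pgp) drug$pgp_kcat * 60 * config$renal$pgp_amount_umol else 0
  pgp_site <- config$renal$pgp_site %||% "kidney"

  if (cl_int_l_h == 0 && cl_h_l_h == 0 && cl_renal_l_h == 0 && !has_pgp) {
    abort("Model has no elimination route.", class = "sgltsim_build_error")
  }

  state_names <- c("gut_lumen", "gut", "liver", tissues, "blood",
                   "metabolized", "renal_excreted", "unabsorbed")
  p <- list(
    ka = ka, kf = kf, V = V, Q = Q, kp = kp, tissues = tissues,
    fup = drug$fup, cl_int_l_h = cl_int_l_h, cl_h_l_h = cl_h_l_h,
    cl_renal_l_h = cl_renal_l_h, vmax_pgp = vmax_pgp,
    km_pgp = drug$pgp_km %||% Inf, pgp_site = pgp_site,
    mw = drug$molecular_weight
  )

  # positional indices and scalar locals: the right-hand side runs thousands
  # of times per solve, so all named lookups are hoisted out of the closure
  n_state <- length(state_names)
  i_lumen <- 1L; i_gut <- 2L; i_liv <- 3L
  i_tis <- seq.int(4L, 3L + length(tissues))
  i_blood <- match("blood", state_names)
  i_met <- match("metabolized", state_names)
  i_ren <- match("renal_excreted", state_names)
  i_unab <- match("unabsorbed", state_names)
  qt <- unname(Q[tissues]); vkp_t <- unname(V[tissues] * kp[tissues])
  q_gut <- Q[["gut"]]; q_liv <- Q[["liver"]]
  vkp_gut <- V[["gut"]] * kp[["gut"]]; vkp_liv <- V[["liver"]] * kp[["liver"]]
  v_blood <- V[["blood"]]
  q_total <- sum(qt) + q_gut + q_liv
  fup <- drug$fup; km_pgp <- drug$pgp_km %||% Inf
  cl_met <- cl_int_l_h * fup + cl_h_l_h
  pgp_gut <- identical(pgp_site, "gut")
  i_pgp <- if (pgp_gut) i_gut else 3L + match("kidney", tissues)
  vkp_pgp <- if (has_pgp) V[[state_names[i_pgp]]] * kp[[state_names[i_pgp]]]
             else 1

  rhs <- function(t, state, parms) {
    c_pl <- state[[i_blood]] / v_blood
    out_t <- state[i_tis] / vkp_t          # venous concentrations
    out_gut <- state[[i_gut]] / vkp_gut
    out_liv <- state[[i_liv]] / vkp_liv

    d <- numeric(n_state)
    abs_flux <- ka * state[[i_lumen]]
    fec_flux <- kf * state[[i_lumen]]
    d[i_lumen] <- -abs_flux - fec_flux
    d[i_unab] <- fec_flux

    d[i_tis] <- qt * (c_pl - out_t)
    d[i_gut] <- abs_flux + q_gut * (c_pl - out_gut)

    met <- cl_met * out_liv
    d[i_liv] <- q_liv * c_pl + q_gut * out_gut -
      (q_liv + q_gut) * out_liv - met
    d[i_met] <- met

    ren <- cl_renal_l_h * c_pl
    pgp <- 0
    if (vmax_pgp > 0) {
      cu <- fup * state[[i_pgp]] / vkp_pgp
      pgp <- vmax_pgp * cu / (km_pgp + cu)
      d[i_pgp] <- d[i_pgp] - pgp
      if (pgp_gut) {
        d[i_lumen] <- d[i_lumen] + pgp
        pgp <- 0  # recycled luminally, not excreted
      }
    }
    d[i_blood] <- sum(qt * out_t) + (q_liv + q_gut) * out_liv -
      q_total * c_pl - ren
    d[i_ren] <- ren + pgp
    list(d, plasma_umol_l = c_pl, renal_flux_umol_h = ren + pgp)
  }

  structure(list(
    drug = drug, glucose = glucose, physiology = physiology, config = config,
    state_names = state_names, params = p, rhs = rhs,
    dose_state = "gut_lumen", mw = drug$molecular_weight
  ), class = "pbpk_model")
}

#' One-compartment oral reference model
#'
#' A degenerate configuration collapsing the body to a single well-stirred
#' compartment with first-order absorption and elimination; runs through the
#' same solver path as the whole-body model and is mainly useful for checking
#' the integrator against the closed-form oral solution.
#'
#' @param ka Absorption rate constant, h^-1.
#' @param ke Elimination rate constant, h^-1.
#' @param v Volume of distribution, L.
#' @param mw Molecular weight used for ng/mL reporting.
#' @return A `pbpk_model` object with states gut_lumen, central, metabolized.
#' @export
onecomp_model <- function(ka, ke, v, mw = 400) {
  stopifnot(ka > 0, ke >= 0, v > 0)
  rhs <- function(t, state, parms) {
    a <- parms$ka * state[["gut_lumen"]]
    e <- parms$ke * state[["central"]]
    list(c(gut_lumen = -a, central = a - e, metabolized = e),
         plasma_umol_l = state[["central"]] / parms$v,
         renal_flux_umol_h = 0)
  }
  structure(list(
    drug = NULL, state_names = c("gut_lumen", "central", "metabolized"),
    params = list(ka = ka, ke = ke, v = v, mw = mw), rhs = rhs,
    dose_state = "gut_lumen", mw = mw,
    config = sglt_config()
  ), class = "pbpk_model")
}

#' Simulate plasma pharmacokinetics
#'
#' Integrates the model over the regimen with a stiff-capable solver
#' (`deSolve::lsoda`), dosing by discrete events into the gut lumen, on a
#' fixed output grid. The run is deterministic: identical inputs give
#' identical output.
#'
#' @param model A `pbpk_model` from [build_pbpk_model()] or [onecomp_model()].
#' @param regimen A [dose_regimen()].
#' @param solver Optional list overriding `rtol`, `atol`, `dt_out_h`.
#' @return A `pk_sim` object; its `$timecourse` tibble has columns `time_h`,
#'   `conc_ng_ml`, `renal_flux_umol_h` and one column per state amount (umol).
#' @examples
#' \donttest{
#' pk <- simulate_pk(build_pbpk_model(sglt_drug("dapagliflozin")),
#'                   dose_regimen(10))
#' glance(pk)
#' }
#' @export
simulate_pk <- function(model, regimen, solver = NULL) {
  stopifnot(inherits(model, "pbpk_model"), inherits(regimen, "dose_regimen"))
  sc <- modifyList(model$config$solver, solver %||% list())
  dt <- sc$dt_out_h
  times <- seq(0, regimen$duration_h, by = dt)
  dose_times <- (seq_len(regimen$n_doses) - 1) * regimen$interval_h
  times <- sort(unique(c(times, dose_times, regimen$duration_h)))
  dose_umol <- mg_to_umol(regimen$dose_mg, model$mw)

  y0 <- setNames(numeric(length(model$state_names)), model$state_names)
  events <- data.frame(var = model$dose_state, time = dose_times,
                       value = dose_umol, method = "add")

  sol <- deSolve::lsoda(
    y = y0, times = times, func = model$rhs, parms = model$params,
    rtol = sc$rtol, atol = sc$atol,
    events = list(data = events))
  if (attr(sol, "istate")[1] < 0) {
    abort("ODE integration failed; see deSolve diagnostics.",
          class = "sgltsim_integration_error")
  }
  tc <- tibble::as_tibble(as.data.frame(sol)) |>
    dplyr::rename(time_h = "time")
  # clamp solver-level negative round-off
  amt_cols <- model$state_names
  tc[amt_cols] <- lapply(tc[amt_cols], function(x) {
    stopifnot(all(x > -1e-6 * max(dose_umol, 1)))
    pmax(x, 0)
  })
  tc$conc_ng_ml <- tc$plasma_umol_l * model$mw
  tc <- dplyr::relocate(tc, "time_h", "conc_ng_ml", "renal_flux_umol_h")

  # output rows at event times reflect the pre-event state
  dosed <- dose_umol * findInterval(tc$time_h, dose_times, left.open = TRUE)
  cum_cols <- intersect(c("metabolized", "renal_excreted", "unabsorbed"),
                        amt_cols)
  total <- rowSums(tc[amt_cols])
  structure(list(
    timecourse = tc, model = model, regimen = regimen,
    dose_umol = dose_umol,
    mass_balance = tibble::tibble(
      time_h = tc$time_h, dosed_umol = dosed, accounted_umol = total,
      rel_error = ifelse(dosed > 0, (total - dosed) / dosed, 0))
  ), class = "pk_sim")
}

#' @export
print.pk_sim <- function(x, ...) {
  drug <- if (!is.null(x$model$drug)) x$model$drug$name else "custom model"
  cat(sprintf("<pk_sim> %s, %g mg x %d q%gh, %g h\n", drug,
              x$regimen$dose_mg, x$regimen$n_doses, x$regimen$interval_h,
              x$regimen$duration_h))
  s <- glance(x)
  cat(sprintf("  Cmax %.3g ng/mL at %.2g h; AUC(0-%g) %.4g ng*h/mL\n",
              s$cmax_ng_ml, s$tmax_h, x$regimen$duration_h, s$auc_ng_h_ml))
  invisible(x)
}

#' @exportS3Method
tidy.pk_sim <- function(x, ...) x$timecourse

#' @exportS3Method
glance.pk_sim <- function(x, ...) {
  tc <- x$timecourse
  cm <- cmax(tc$time_h, tc$conc_ng_ml)
  tibble::tibble(
    auc_ng_h_ml = auc(tc$time_h, tc$conc_ng_ml),
    cmax_ng_ml = cm$cmax, tmax_h = cm$tmax_h,
    fraction_absorbed = 1 - tail(tc$unabsorbed %||% 0, 1) / max(x$dose_umol, 1e-300),
    mass_balance_max_abs_rel_error = max(abs(x$mass_balance$rel_error))
  )
}
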