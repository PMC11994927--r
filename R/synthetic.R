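# Synthetic "observed" datasets: model-generated truth per virtual subject
# with multiplicative lognormal residual noise, plus least-squares parameter
# recovery. The noise model is purely multiplicative (no additive floor):
# observed = truth * exp(eps), eps ~ N(0, cv^2) on the natural-log scale.

#' Synthetic observed concentration-time dataset
#'
#' Simulates the PK of every subject in a virtual population, samples the
#' profile at the requested times, and perturbs each point with multiplicative
#' lognormal noise. The noiseless truth is stored alongside for recovery
#' tests, and per-subject AUC/Cmax are derived from the observed points.
#'
#' @param drug An [sglt_drug()].
#' @param regimen A [dose_regimen()].
#' @param pop A [generate_population()] tibble (or a [population_spec()],
#'   in which case the population is generated under `seed`).
#' @param cv Residual log-scale coefficient of variation (>= 0).
#' @param sampling_times_h Strictly increasing sampling times within the
#'   regimen span.
#' @param seed Integer seed (noise and, if needed, population).
#' @param config A [sglt_config()].
#' @return A `synth_pk` object with `$observations` (tibble: `id`, `time_h`,
#'   `truth_ng_ml`, `observed_ng_ml`) and `$parameters` (tibble: `id`,
#'   `quantity`, `truth`, `observed`).
#' @export
synth_observed_pk <- function(drug, regimen, pop, cv = 0.2,
                              sampling_times_h = c(0.5, 1, 2, 3, 4, 6, 8, 12, 24),
                              seed = 1, config = sglt_config()) {
  if (cv < 0) abort("cv must be >= 0.", class = "sgltsim_validation_error")
  stopifnot(all(diff(sampling_times_h) > 0))
  if (inherits(pop, "population_spec")) pop <- generate_population(pop, seed)

  sims <- purrr::map(seq_len(nrow(pop)), function(i) {
    model <- build_pbpk_model(drug, physiology = pop$physiology[[i]],
                              config = config)
    simulate_pk(model, regimen)
  })
  truth <- purrr::imap_dfr(sims, function(pk, i) {
    tc <- pk$timecourse
    tibble::tibble(
      id = pop$id[i], time_h = sampling_times_h,
      truth_ng_ml = approxfun(tc$time_h, tc$conc_ng_ml, rule = 2)(sampling_times_h))
  })
  set.seed(seed)
  obs <- truth |>
    dplyr::mutate(observed_ng_ml = .data$truth_ng_ml *
                    exp(rnorm(dplyr::n(), 0, cv)))
  params <- obs |>
    dplyr::group_by(id = .data$id) |>
    dplyr::summarise(
      auc_truth = auc(.data$time_h, .data$truth_ng_ml),
      auc_obs = auc(.data$time_h, .data$observed_ng_ml),
      cmax_truth = cmax(.data$time_h, .data$truth_ng_ml)$cmax,
      cmax_obs = cmax(.data$time_h, .data$observed_ng_ml)$cmax,
      .groups = "drop") |>
    tidyr::pivot_longer(-"id", names_to = c("quantity", "kind"),
                        names_sep = "_") |>
    tidyr::pivot_wider(names_from = "kind", values_from = "value") |>
    dplyr::rename(truth = "truth", observed = "obs")
  structure(list(
    observations = obs, parameters = params, drug = drug, regimen = regimen,
    population = pop, cv = cv, seed = seed, config = config,
    sampling_times_h = sampling_times_h
  ), class = "synth_pk")
}

#' Synthetic observed 24-h urinary glucose excretion
#'
#' As [synth_observed_pk()], applied to the per-subject 24-h UGE scalar.
#'
#' @inheritParams synth_observed_pk
#' @return A `synth_uge` object with `$observations` (tibble: `id`,
#'   `truth_g`, `observed_g`).
#' @export
synth_observed_uge <- function(drug, regimen, pop, cv = 0.2, seed = 1,
                               config = sglt_config()) {
  if (cv < 0) abort("cv must be >= 0.", class = "sgltsim_validation_error")
  if (inherits(pop, "population_spec")) pop <- generate_population(pop, seed)
  truth <- purrr::map_dbl(seq_len(nrow(pop)), function(i) {
    glance(simulate_subject(pop, drug, regimen, config, i = i)$uge)$uge_24h_g
  })
  set.seed(seed)
  obs <- tibble::tibble(
    id = pop$id, truth_g = truth,
    observed_g = truth * exp(rnorm(nrow(pop), 0, cv)))
  structure(list(observations = obs, drug = drug, regimen = regimen,
                 population = pop, cv = cv, seed = seed, config = config),
            class = "synth_uge")
}

# parameter handles the recovery routine knows how to apply
.free_parameter_handles <- c("hepatic_clearance_scalar",
                             "intestinal_permeability_scalar",
                             "sglt2_kd_umol_l",
                             "transporter_capacity_scale")

apply_free_parameters <- function(drug, config, theta) {
  extras <- list(capacity_scale = 1)
  for (nm in names(theta)) {
    v <- theta[[nm]]
    switch(nm,
      hepatic_clearance_scalar = {
        config$hepatic$enzyme_reference_umol <-
          config$hepatic$enzyme_reference_umol * v
        if (!is.null(drug$hepatic_clearance_specific)) {
          drug$hepatic_clearance_specific <- drug$hepatic_clearance_specific * v
        }
      },
      intestinal_permeability_scalar = {
        drug$intestinal_permeability <- drug$intestinal_permeability * v
      },
      sglt2_kd_umol_l = {
        drug$sglt$SGLT2$kd_umol_l <- v
      },
      transporter_capacity_scale = {
        extras$capacity_scale <- v
      },
      abort(paste0("Unknown free parameter '", nm, "'."),
            class = "sgltsim_validation_error"))
  }
  list(drug = drug, config = config, extras = extras)
}

#' Recover model parameters from a synthetic dataset
#'
#' Least-squares fit on log-scale residuals between the dataset's observed
#' values and model predictions, over a small set of free parameters with box
#' bounds. Optimization is derivative-free (golden-section for one parameter,
#' Nelder-Mead on a bound-mapping transform otherwise) initialized at the
#' bound midpoints, hence deterministic.
#'
#' @param dataset A `synth_pk` or `synth_uge` object.
#' @param free Named list of bounds, e.g.
#'   `list(hepatic_clearance_scalar = c(0.2, 5))`. Supported parameters:
#'   `hepatic_clearance_scalar`, `intestinal_permeability_scalar`,
#'   `sglt2_kd_umol_l`, `transporter_capacity_scale`.
#' @param truth Named vector of true values (defaults: scalars 1; Kd from the
#'   dataset's drug record).
#' @return A tibble: `parameter`, `estimate`, `truth`, `rel_error`,
#'   `at_bound`; attribute `objective` holds the attained residual sum.
#' @export
recover_parameters <- function(dataset, free, truth = NULL) {
  stopifnot(inherits(dataset, c("synth_pk", "synth_uge")))
  bad <- setdiff(names(free), .free_parameter_handles)
  if (length(bad)) {
    abort(paste0("Unknown free parameter(s): ", paste(bad, collapse = ", ")),
          class = "sgltsim_validation_error")
  }
  n_obs <- nrow(dataset$observations)
  if (length(free) >= n_obs) {
    abort("Non-identifiable request: at least as many free parameters as observations.",
          class = "sgltsim_diagnostic_failure")
  }
  pop <- dataset$population
  is_pk <- inherits(dataset, "synth_pk")
  obs_log <- if (is_pk) log(pmax(dataset$observations$observed_ng_ml, 1e-12))
             else log(pmax(dataset$observations$observed_g, 1e-12))

  predict_log <- function(theta) {
    ap <- apply_free_parameters(dataset$drug, dataset$config, theta)
    if (is_pk) {
      unlist(purrr::map(seq_len(nrow(pop)), function(i) {
        model <- build_pbpk_model(ap$drug, physiology = pop$physiology[[i]],
                                  config = ap$config)
        tc <- simulate_pk(model, dataset$regimen)$timecourse
        log(pmax(approxfun(tc$time_h, tc$conc_ng_ml, rule = 2)(
          dataset$sampling_times_h), 1e-12))
      }))
    } else {
      cs <- ap$extras$capacity_scale
      purrr::map_dbl(seq_len(nrow(pop)), function(i) {
        model <- build_pbpk_model(ap$drug, physiology = pop$physiology[[i]],
                                  config = ap$config)
        pk <- simulate_pk(model, dataset$regimen)
        u <- simulate_uge(
          pk, plasma_glucose_mmol_l = pop$plasma_glucose_mmol_l[i],
          capacity_scaling = c(SGLT1 = pop$sglt1_scale[i] * cs,
                               SGLT2 = pop$sglt2_scale[i] * cs))
        log(max(glance(u)$uge_24h_g, 1e-12))
      })
    }
  }
  objective <- function(theta) sum((predict_log(theta) - obs_log)^2)

  nms <- names(free)
  lower <- purrr::map_dbl(free, 1); upper <- purrr::map_dbl(free, 2)
  stopifnot(all(lower < upper), all(lower > 0))
  if (length(free) == 1) {
    op <- optimize(function(lt) objective(setNames(list(exp(lt)), nms)),
                   interval = log(c(lower, upper)), tol = 1e-6)
    est <- exp(op$minimum); val <- op$objective
  } else {
    to_theta <- function(z) setNames(
      as.list(lower + (upper - lower) * stats::plogis(z)), nms)
    op <- optim(rep(0, length(free)),
                function(z) objective(to_theta(z)), method = "Nelder-Mead",
                control = list(reltol = 1e-8, maxit = 500))
    est <- unlist(to_theta(op$par)); val <- op$value
  }
  default_truth <- setNames(rep(1, length(nms)), nms)
  if ("sglt2_kd_umol_l" %in% nms) {
    default_truth[["sglt2_kd_umol_l"]] <- dataset$drug$sglt$SGLT2$kd_umol_l
  }
  if (!is.null(truth)) default_truth[names(truth)] <- truth
  out <- tibble::tibble(
    parameter = nms, estimate = unname(est),
    truth = unname(default_truth[nms]),
    rel_error = unname(est / default_truth[nms] - 1),
    at_bound = unname(est <= lower * 1.001 | est >= upper * 0.999))
  attr(out, "objective") <- val
  out
}
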