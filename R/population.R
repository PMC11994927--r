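# Virtual subjects and populations: demographics, CKD staging by GFR,
# allometric organ scaling, lognormal inter-individual variability, and the
# stage-dependent SGLT transporter capacity reductions.

CKD_STAGES <- c("normal", "mild", "moderate", "severe")

#' Mean GFR of a CKD stage
#'
#' @param stage One of `"normal"`, `"mild"`, `"moderate"`, `"severe"`.
#' @return Mean GFR in mL/min (105, 75, 45, 15 respectively).
#' @examples
#' ckd_stage_gfr("moderate")   # 45
#' @export
ckd_stage_gfr <- function(stage) {
  check_stage(stage)
  c(normal = 105, mild = 75, moderate = 45, severe = 15)[[stage]]
}

#' Stage-dependent SGLT transporter capacity scaling
#'
#' In moderate and severe renal insufficiency the reabsorption capacity of
#' SGLT1 is reduced by 15% and 50% and that of SGLT2 by 60% and 90%
#' respectively; normal and mild stages are unscaled.
#'
#' @inheritParams ckd_stage_gfr
#' @return Named numeric vector of fractions, `c(SGLT1 = , SGLT2 = )`.
#' @examples
#' transporter_scaling("severe")
#' @export
transporter_scaling <- function(stage) {
  check_stage(stage)
  switch(stage,
         normal = ,
         mild = c(SGLT1 = 1, SGLT2 = 1),
         moderate = c(SGLT1 = 0.85, SGLT2 = 0.40),
         severe = c(SGLT1 = 0.50, SGLT2 = 0.10))
}

check_stage <- function(stage) {
  if (!is.character(stage) || length(stage) != 1 || !stage %in% CKD_STAGES) {
    abort(paste0("Unknown CKD stage '", paste(stage, collapse = ","),
                 "'; expected one of: ", paste(CKD_STAGES, collapse = ", ")),
          class = "sgltsim_validation_error")
  }
  invisible(stage)
}

#' Population specification
#'
#' @param n Number of subjects (>= 1).
#' @param stage CKD stage (sets the mean GFR via [ckd_stage_gfr()] and the
#'   transporter scaling via [transporter_scaling()]).
#' @param fraction_male Fraction of male subjects in \[0, 1\].
#' @param gfr_cv Coefficient of variation of GFR within the stage.
#' @param plasma_glucose_mmol_l Plasma glucose assigned to every subject.
#' @param config A [sglt_config()] (demographic distribution parameters).
#' @return A `population_spec` object.
#' @export
population_spec <- function(n, stage = "normal", fraction_male = 0.5,
                            gfr_cv = NULL, plasma_glucose_mmol_l = NULL,
                            config = sglt_config()) {
  stopifnot(n >= 1, n == as.integer(n),
            fraction_male >= 0, fraction_male <= 1)
  check_stage(stage)
  structure(list(
    n = as.integer(n), stage = stage, fraction_male = fraction_male,
    gfr_cv = gfr_cv %||% config$population$gfr_cv,
    plasma_glucose_mmol_l = plasma_glucose_mmol_l %||%
      config$glucose_plasma_mmol_l$t2dm,
    config = config
  ), class = "population_spec")
}

#' Generate a virtual population
#'
#' Samples demographics (age, sex, weight, BMI), a stage-specific GFR
#' (normal distribution, truncated positive), lognormal organ volume/flow
#' variability, and attaches the stage transporter scaling. Sampling is fully
#' deterministic under the seed and order-stable.
#'
#' @param spec A [population_spec()].
#' @param seed Integer seed.
#' @return A tibble of class `sglt_population` with one row per subject:
#'   `id`, `age`, `sex`, `weight_kg`, `bmi`, `gfr_ml_min`, `sglt1_scale`,
#'   `sglt2_scale`, `plasma_glucose_mmol_l`, and a list-column `physiology`.
#' @examples
#' pop <- generate_population(population_spec(10, "moderate"), seed = 1)
#' mean(pop$gfr_ml_min)
#' @export
generate_population <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "population_spec"))
  pc <- spec$config$population
  n <- spec$n
  n_male <- round(n * spec$fraction_male)
  sex <- c(rep("male", n_male), rep("female", n - n_male))
  gfr_mean <- ckd_stage_gfr(spec$stage)
  scal <- transporter_scaling(spec$stage)
  organs <- reference_physiology()$organs$compartment

  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  pop <- withr_seed({
    age <- pmax(rnorm(n, pc$age_mean, pc$age_sd), 18)
    wt_mean <- ifelse(sex == "male", pc$weight_mean_male, pc$weight_mean_female)
    weight <- pmax(rnorm(n, wt_mean, pc$weight_sd), 40)
    bmi <- pmax(rnorm(n, pc$bmi_mean, pc$bmi_sd), 16)
    gfr <- pmax(rnorm(n, gfr_mean, spec$gfr_cv * gfr_mean), 1)
    sdlog <- log(pc$organ_gsd)
    vol_fac <- matrix(rlnorm(n * length(organs), 0, sdlog), n,
                      dimnames = list(NULL, organs))
    flow_fac <- matrix(rlnorm(n * length(organs), 0, sdlog), n,
                       dimnames = list(NULL, organs))
    list(age = age, weight = weight, bmi = bmi, gfr = gfr,
         vol_fac = vol_fac, flow_fac = flow_fac)
  })

  phys <- purrr::map(seq_len(n), function(i) {
    ff <- pop$flow_fac[i, ]
    # preserve the flow-sum == cardiac-output invariant per subject
    ff <- ff / mean(ff)
    reference_physiology(
      body_weight = pop$weight[i], gfr_ml_min = pop$gfr[i],
      volume_factors = as.list(pop$vol_fac[i, ]),
      flow_factors = as.list(ff))
  })

  out <- tibble::tibble(
    id = seq_len(n), age = pop$age, sex = sex, weight_kg = pop$weight,
    bmi = pop$bmi, gfr_ml_min = pop$gfr,
    sglt1_scale = scal[["SGLT1"]], sglt2_scale = scal[["SGLT2"]],
    plasma_glucose_mmol_l = spec$plasma_glucose_mmol_l,
    physiology = phys
  )
  class(out) <- c("sglt_population", class(out))
  attr(out, "spec") <- spec
  attr(out, "seed") <- seed
  out
}

#' Pointwise population prediction bands
#'
#' Empirical pointwise quantiles of per-subject time series sharing a common
#' time grid (default 5th/95th percentile, a 90% band, plus the median).
#'
#' @param profiles A data frame with columns `id`, `time_h` and `value`
#'   (long format, one row per subject-time).
#' @param quantiles Two probabilities, lower and upper band edge.
#' @return A tibble `time_h`, `lower`, `median`, `upper`, `n`.
#' @export
population_bands <- function(profiles, quantiles = c(0.05, 0.95)) {
  stopifnot(is.data.frame(profiles),
            all(c("id", "time_h", "value") %in% names(profiles)),
            length(quantiles) == 2, quantiles[1] <= quantiles[2])
  if (nrow(profiles) == 0 || dplyr::n_distinct(profiles$id) < 2) {
    abort("population_bands needs >= 2 subjects.",
          class = "sgltsim_validation_error")
  }
  profiles |>
    dplyr::group_by(.data$time_h) |>
    dplyr::summarise(
      lower = quantile(.data$value, quantiles[1], names = FALSE, type = 7),
      median = median(.data$value),
      upper = quantile(.data$value, quantiles[2], names = FALSE, type = 7),
      n = dplyr::n(), .groups = "drop")
}

#' Export a population to CSV
#'
#' Writes one row per subject with the demographic and renal columns
#' (`id`, `age`, `sex`, `weight_kg`, `bmi`, `gfr_ml_min`, `sglt1_scale`,
#' `sglt2_scale`), dropping the physiology list-column.
#'
#' @param pop A [generate_population()] tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_population <- function(pop, path) {
  stopifnot(inherits(pop, "sglt_population"))
  readr::write_csv(
    dplyr::select(as.data.frame(pop), "id", "age", "sex", "weight_kg", "bmi",
                  "gfr_ml_min", "sglt1_scale", "sglt2_scale"), path)
  invisible(path)
}

#' Simulate one subject's PK and UGE
#'
#' Convenience wrapper: builds the subject-specific model, simulates the
#' regimen and the 24-h glucodynamics.
#'
#' @param subject One row of a [generate_population()] tibble (or the tibble
#'   itself with `i` selecting the row).
#' @param drug An [sglt_drug()].
#' @param regimen A [dose_regimen()].
#' @param config A [sglt_config()].
#' @param i Row index when `subject` has several rows.
#' @param occupancy0 Initial transporter occupancy passed to [simulate_uge()]
#'   (named numeric or `"steady_state"`).
#' @return A list with elements `pk` (`pk_sim`) and `uge` (`uge_sim`).
#' @export
simulate_subject <- function(subject, drug, regimen, config = sglt_config(),
                             i = 1, occupancy0 = c(SGLT1 = 0, SGLT2 = 0)) {
  row <- subject[i, ]
  model <- build_pbpk_model(drug, physiology = row$physiology[[1]],
                            config = config)
  pk <- simulate_pk(model, regimen)
  uge <- simulate_uge(
    pk, plasma_glucose_mmol_l = row$plasma_glucose_mmol_l,
    capacity_scaling = c(SGLT1 = row$sglt1_scale, SGLT2 = row$sglt2_scale),
    occupancy0 = occupancy0)
  list(pk = pk, uge = uge)
}
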