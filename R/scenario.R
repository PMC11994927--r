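# Dosage-regimen scenario runner: the regimen x CKD-stage grid of population
# 24-h UGE simulations, regimen ranking, and the paired-table validation
# entry point.

DEFAULT_REGIMENS <- tibble::tibble(
  drug = rep(c("dapagliflozin", "canagliflozin", "empagliflozin",
               "ipragliflozin"), each = 2),
  dose_mg = c(5, 10, 100, 300, 10, 25, 50, 100))

#' Scenario grid specification
#'
#' The default grid crosses the labeled daily doses of the four drugs
#' (dapagliflozin 5/10 mg, canagliflozin 100/300 mg, empagliflozin 10/25 mg,
#' ipragliflozin 50/100 mg) with the four renal-function stages.
#'
#' @param regimens Tibble with columns `drug`, `dose_mg`.
#' @param stages Character vector of CKD stages.
#' @param n Subjects per cell (>= 1; populations are reused across regimens
#'   within a stage).
#' @param fraction_male Fraction male.
#' @param seed Integer seed.
#' @return A `scenario_grid` object (a tibble of cells with attributes).
#' @export
scenario_grid <- function(regimens = DEFAULT_REGIMENS,
                          stages = CKD_STAGES, n = 100,
                          fraction_male = 0.5, seed = 1) {
  stopifnot(all(c("drug", "dose_mg") %in% names(regimens)),
            all(regimens$dose_mg > 0), n >= 1)
  purrr::walk(stages, check_stage)
  grid <- tidyr::crossing(regimens, stage = unique(as.character(stages))) |>
    dplyr::arrange(factor(.data$stage, levels = CKD_STAGES),
                   .data$drug, .data$dose_mg)
  structure(grid, class = c("scenario_grid", class(grid)),
            n = as.integer(n), fraction_male = fraction_male, seed = seed)
}

#' Run the scenario grid
#'
#' For every cell, simulates each subject of the stage population over one
#' dosing day of once-daily maintenance therapy -- transporter occupancy
#' starts at its long-run periodic level (see [simulate_uge()]) -- and
#' summarizes the 24-h UGE as mean with an empirical 90% interval (5th/95th
#' percentile). Deterministic under the grid seed.
#'
#' @param grid A [scenario_grid()].
#' @param config A [sglt_config()].
#' @param progress Print per-cell progress lines.
#' @return A `uge_table` tibble: `drug`, `dose_mg`, `stage`, `n`,
#'   `mean_uge_g`, `q05_uge_g`, `q95_uge_g`.
#' @export
run_scenario_grid <- function(grid, config = sglt_config(),
                              progress = FALSE) {
  stopifnot(inherits(grid, "scenario_grid"))
  n <- attr(grid, "n"); seed <- attr(grid, "seed")
  stages <- unique(grid$stage)
  pops <- setNames(purrr::imap(stages, function(st, k) {
    generate_population(
      population_spec(n, st, attr(grid, "fraction_male"), config = config),
      seed = seed + match(st, CKD_STAGES))
  }), stages)

  cell_summary <- function(drug_name, dose, st) {
    pop <- pops[[st]]
    regimen <- dose_regimen(dose, duration_h = 24)
    drug <- sglt_drug(drug_name)
    uge <- purrr::map_dbl(seq_len(nrow(pop)), function(i) {
      glance(simulate_subject(pop, drug, regimen, config, i = i,
                              occupancy0 = "steady_state")$uge)$uge_24h_g
    })
    tibble::tibble(
      n = length(uge), mean_uge_g = mean(uge),
      q05_uge_g = quantile(uge, 0.05, names = FALSE),
      q95_uge_g = quantile(uge, 0.95, names = FALSE))
  }

  rows <- purrr::pmap_dfr(
    list(grid$drug, grid$dose_mg, grid$stage),
    function(d, dose, st) {
      if (progress) message(sprintf("[scenario] %s %g mg, %s", d, dose, st))
      res <- tryCatch(cell_summary(d, dose, st), error = function(e) {
        abort(sprintf("Scenario cell failed (%s %g mg, %s): %s",
                      d, dose, st, conditionMessage(e)),
              class = "sgltsim_partial_result_error")
      })
      dplyr::bind_cols(tibble::tibble(drug = d, dose_mg = dose, stage = st), res)
    })
  structure(rows, class = c("uge_table", class(rows)))
}

#' Rank regimens by glucosuric effect
#'
#' Orders the regimens of one stage by descending mean 24-h UGE; ties are
#' broken in favor of the lower dose.
#'
#' @param table A [run_scenario_grid()] result.
#' @param stage CKD stage to rank.
#' @return The stage's rows, ranked, with a `rank` column.
#' @export
rank_regimens <- function(table, stage) {
  check_stage(stage)
  if (!stage %in% table$stage) {
    abort(paste0("Stage '", stage, "' is not in the table."),
          class = "sgltsim_validation_error")
  }
  table |>
    dplyr::filter(.data$stage == !!stage) |>
    dplyr::arrange(dplyr::desc(.data$mean_uge_g), .data$dose_mg) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
}

#' Validate predictions against paired observed/predicted tables
#'
#' Runs the full accuracy report (n, MPE, AFE, AAFE, 0.5-2 and 0.8-1.3 band
#' fractions) per table and combined. With `paths = NULL` the two tables
#' shipped with the package are used.
#'
#' @param paths Named character vector of CSV paths (see
#'   [read_paired_observations()] for the format), or `NULL` for the shipped
#'   tables.
#' @return A tibble with one row per table plus a `combined` row.
#' @examples
#' validate_against_tables()
#' @export
validate_against_tables <- function(paths = NULL) {
  tables <- if (is.null(paths)) {
    list(healthy_normal = pk_pairs_table("healthy_normal"),
         renal_impairment = pk_pairs_table("renal_impairment"))
  } else {
    if (is.null(names(paths))) names(paths) <- basename(paths)
    purrr::map(as.list(paths), read_paired_observations)
  }
  per_table <- purrr::imap_dfr(tables, function(tab, nm) {
    glance(validate_predictions(tab)) |> dplyr::mutate(table = nm, .before = 1)
  })
  combined <- glance(validate_predictions(dplyr::bind_rows(tables))) |>
    dplyr::mutate(table = "combined", .before = 1)
  dplyr::bind_rows(per_table, combined)
}
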