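# Prediction-accuracy statistics for paired observed/predicted values:
# fold error, mean prediction error (MPE), geometric average fold error (AFE),
# absolute average fold error (AAFE), and band fractions. Band fractions are
# always computed on unrounded ratios; display rounding (half-up, two
# decimals) is a presentation choice only and demonstrably changes the counts.

#' Fold error (predicted / observed)
#'
#' @param predicted,observed Positive values.
#' @param display If `TRUE`, round half-up to 2 decimals the way the ratio is
#'   customarily displayed in validation tables.
#' @return `predicted / observed`.
#' @examples
#' fold_error(397.62, 602.00, display = TRUE)   # 0.66
#' @export
fold_error <- function(predicted, observed, display = FALSE) {
  if (any(observed <= 0)) {
    abort("observed must be > 0.", class = "sgltsim_validation_error")
  }
  fe <- predicted / observed
  if (display) round_half_up(fe, 2) else fe
}

# round half away from zero at `digits` decimals (the tabular convention;
# base round() rounds half to even)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

check_pairs <- function(pairs, require_positive = TRUE) {
  if (!is.data.frame(pairs) ||
      !all(c("observed", "predicted") %in% names(pairs))) {
    abort("pairs must be a data frame with observed and predicted columns.",
          class = "sgltsim_validation_error")
  }
  if (nrow(pairs) == 0) {
    abort("pairs must contain at least one row.",
          class = "sgltsim_validation_error")
  }
  if (any(pairs$observed <= 0) ||
      (require_positive && any(pairs$predicted <= 0))) {
    abort("observed and predicted must be positive.",
          class = "sgltsim_validation_error")
  }
  invisible(pairs)
}

#' Mean prediction error
#'
#' `mean((predicted - observed) / observed)`. Note this statistic is not
#' symmetric under swapping predicted and observed.
#'
#' @param pairs Data frame with columns `observed` and `predicted`.
#' @return Dimensionless mean relative error.
#' @examples
#' mpe(data.frame(observed = c(1, 2), predicted = c(2, 1)))   # 0.25
#' @export
mpe <- function(pairs) {
  check_pairs(pairs, require_positive = FALSE)
  mean((pairs$predicted - pairs$observed) / pairs$observed)
}

#' Geometric average fold error
#'
#' `10 ^ mean(log10(predicted / observed))`: the geometric mean ratio; 1 means
#' no average bias. Inverts under swapping predicted and observed.
#'
#' @inheritParams mpe
#' @return A fold value > 0.
#' @export
afe <- function(pairs) {
  check_pairs(pairs)
  10^mean(log10(pairs$predicted / pairs$observed))
}

#' Absolute average fold error
#'
#' `10 ^ mean(|log10(predicted / observed)|)`: the average spread regardless
#' of direction; always >= 1 and >= max(AFE, 1/AFE), invariant under swapping
#' predicted and observed.
#'
#' @inheritParams mpe
#' @return A fold value >= 1.
#' @export
aafe <- function(pairs) {
  check_pairs(pairs)
  10^mean(abs(log10(pairs$predicted / pairs$observed)))
}

#' Fraction of pairs inside a fold-error band
#'
#' Counts pairs whose unrounded fold error lies within `[low, high]`
#' (inclusive) and returns the percentage rounded to one decimal.
#'
#' @inheritParams mpe
#' @param low,high Band endpoints, `low < high`.
#' @return Percent of pairs inside the band (one decimal).
#' @examples
#' band_fraction(pk_pairs_table("healthy_normal"), 0.8, 1.3)   # 76.8
#' @export
band_fraction <- function(pairs, low = 0.8, high = 1.3) {
  check_pairs(pairs)
  stopifnot(low < high)
  fe <- pairs$predicted / pairs$observed
  round_half_up(100 * mean(fe >= low & fe <= high), 1)
}

#' Shipped observed/predicted PK parameter tables
#'
#' Loads the paired AUC/Cmax validation tables shipped with the package:
#' `"healthy_normal"` (healthy subjects and T2DM patients with normal renal
#' function, 56 values), `"renal_impairment"` (renal-insufficiency studies,
#' 42 values), or `"pooled"` (both).
#'
#' @param which One of `"healthy_normal"`, `"renal_impairment"`, `"pooled"`.
#' @return A tibble with columns `drug`, `source_ref`, `regimen`,
#'   `population`, `quantity`, `observed`, `predicted`.
#' @export
pk_pairs_table <- function(which = c("healthy_normal", "renal_impairment",
                                     "pooled")) {
  which <- match.arg(which)
  load1 <- function(nm) read_paired_observations(
    system.file("extdata", paste0("pk_pairs_", nm, ".csv"),
                package = "sgltsim"))
  switch(which,
         healthy_normal = load1("healthy_normal"),
         renal_impairment = load1("renal_impairment"),
         pooled = dplyr::bind_rows(load1("healthy_normal"),
                                   load1("renal_impairment")))
}

#' Read a paired-observation CSV
#'
#' @param path CSV with columns `drug`, `source_ref`, `regimen`,
#'   `population`, `quantity`, `observed`, `predicted`.
#' @return A validated tibble.
#' @export
read_paired_observations <- function(path) {
  out <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(paste0("Cannot parse '", path, "': ",
                                     conditionMessage(e)),
                              class = "sgltsim_parse_error"))
  req <- c("drug", "regimen", "quantity", "observed", "predicted")
  missing <- setdiff(req, names(out))
  if (length(missing)) {
    abort(paste0("Missing columns in ", path, ": ",
                 paste(missing, collapse = ", ")),
          class = "sgltsim_parse_error")
  }
  check_pairs(out)
  out
}

#' Full prediction-accuracy report for paired tables
#'
#' Computes n, MPE, AFE, AAFE and the band fractions for the acceptable
#' (0.5-2 fold) and tight (0.8-1.3 fold) bands, optionally per group.
#'
#' @param pairs Data frame with `observed`/`predicted` (and optional grouping
#'   columns).
#' @param by Optional character vector of grouping columns.
#' @return An object of class `pk_validation`; `tidy()` returns the per-group
#'   table, `glance()` the overall one-row summary.
#' @examples
#' validate_predictions(pk_pairs_table("pooled"), by = "drug")
#' @export
validate_predictions <- function(pairs, by = NULL) {
  check_pairs(pairs)
  summarise_one <- function(d) tibble::tibble(
    n = nrow(d), mpe = mpe(d), afe = afe(d), aafe = aafe(d),
    pct_within_0.5_2 = band_fraction(d, 0.5, 2),
    pct_within_0.8_1.3 = band_fraction(d, 0.8, 1.3))
  overall <- summarise_one(pairs)
  per_group <- if (!is.null(by)) {
    pairs |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::group_modify(~ summarise_one(.x)) |>
      dplyr::ungroup()
  } else overall
  structure(list(overall = overall, per_group = per_group, pairs = pairs,
                 by = by), class = "pk_validation")
}

#' @export
print.pk_validation <- function(x, ...) {
  o <- x$overall
  cat(sprintf(
    paste0("<pk_validation> n = %d | MPE %.3f | AFE %.3f | AAFE %.3f | ",
           "%.1f%% in 0.5-2, %.1f%% in 0.8-1.3\n"),
    o$n, o$mpe, o$afe, o$aafe, o$pct_within_0.5_2, o$pct_within_0.8_1.3))
  if (!is.null(x$by)) print(x$per_group)
  invisible(x)
}

#' @exportS3Method
tidy.pk_validation <- function(x, ...) x$per_group

#' @exportS3Method
glance.pk_validation <- function(x, ...) x$overall
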