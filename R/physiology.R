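# Whole-body physiology container. Organ volumes/flows and tissue composition
# are versioned data files under inst/extdata, not code.

# per-session cache for the shipped data files (they are immutable within an
# installed package, and population runs rebuild physiology thousands of times)
.extdata_cache <- new.env(parent = emptyenv())

read_extdata_cached <- function(filename) {
  if (!exists(filename, envir = .extdata_cache, inherits = FALSE)) {
    assign(filename, readr::read_csv(
      system.file("extdata", filename, package = "sgltsim"),
      comment = "#", show_col_types = FALSE, progress = FALSE),
      envir = .extdata_cache)
  }
  get(filename, envir = .extdata_cache, inherits = FALSE)
}

#' Reference human physiology
#'
#' Builds the physiology object the PBPK model runs on: organ volumes and
#' regional blood flows for a reference 70-kg adult, fractional tissue
#' composition used for partition-coefficient calculation, hematocrit, body
#' weight and glomerular filtration rate. Volumes scale linearly with body
#' weight and flows allometrically (exponent 0.75) relative to the 70-kg
#' reference.
#'
#' @param body_weight Body weight, kg.
#' @param gfr_ml_min Glomerular filtration rate, mL/min.
#' @param hematocrit Hematocrit fraction (0, 1).
#' @param enzyme_abundance Named numeric vector of dimensionless enzyme
#'   abundance scalars (1 = reference); unnamed enzymes default to 1.
#' @param volume_factors,flow_factors Optional named multipliers per
#'   compartment (used for inter-individual variability).
#' @return An object of class `sglt_physiology` with elements `organs`
#'   (tibble: compartment, volume_l, flow_l_h), `composition` (tibble),
#'   `hematocrit`, `body_weight`, `gfr_ml_min`, `cardiac_output_l_h`,
#'   `enzyme_abundance`.
#' @examples
#' phys <- reference_physiology()
#' phys$organs
#' @export
reference_physiology <- function(body_weight = 70, gfr_ml_min = 105,
                                 hematocrit = 0.45,
                                 enzyme_abundance = numeric(),
                                 volume_factors = NULL, flow_factors = NULL) {
  stopifnot(body_weight > 0, gfr_ml_min >= 0,
            hematocrit > 0, hematocrit < 1)
  organs <- read_extdata_cached("reference_physiology.csv")
  comp <- read_extdata_cached("tissue_composition.csv")

  wt_ratio <- body_weight / 70
  organs <- organs |>
    dplyr::mutate(volume_l = .data$volume_l * wt_ratio,
                  flow_l_h = .data$flow_l_h * wt_ratio^0.75)
  apply_factors <- function(tab, col, fac) {
    if (is.null(fac)) return(tab)
    idx <- match(names(fac), tab$compartment)
    stopifnot(!anyNA(idx))
    tab[[col]][idx] <- tab[[col]][idx] * unlist(fac)
    tab
  }
  organs <- apply_factors(organs, "volume_l", volume_factors)
  organs <- apply_factors(organs, "flow_l_h", flow_factors)

  phys <- structure(list(
    organs = organs,
    composition = comp,
    hematocrit = hematocrit,
    body_weight = body_weight,
    gfr_ml_min = gfr_ml_min,
    cardiac_output_l_h = sum(organs$flow_l_h, na.rm = TRUE),
    enzyme_abundance = enzyme_abundance
  ), class = "sglt_physiology")
  validate_physiology(phys)
}

validate_physiology <- function(phys) {
  organs <- phys$organs
  stopifnot(all(organs$volume_l > 0),
            all(is.na(organs$flow_l_h) | organs$flow_l_h >= 0),
            phys$gfr_ml_min >= 0)
  flow_sum <- sum(organs$flow_l_h, na.rm = TRUE)
  if (abs(flow_sum - phys$cardiac_output_l_h) > 0.01 * phys$cardiac_output_l_h) {
    abort("Tissue blood flows do not sum to cardiac output within 1%.",
          class = "sgltsim_invalid_physiology")
  }
  missing_comp <- setdiff(setdiff(organs$compartment, "blood"),
                          phys$composition$tissue)
  if (length(missing_comp)) {
    abort(paste0("Missing tissue composition for: ",
                 paste(missing_comp, collapse = ", ")),
          class = "sgltsim_config_error")
  }
  invisible(phys)
}

#' @export
print.sglt_physiology <- function(x, ...) {
  cat(sprintf(
    "<sglt_physiology> BW %.1f kg, GFR %.1f mL/min, CO %.0f L/h, Hct %.2f\n",
    x$body_weight, x$gfr_ml_min, x$cardiac_output_l_h, x$hematocrit))
  print(x$organs, n = 3)
  invisible(x)
}

#' @exportS3Method
tidy.sglt_physiology <- function(x, ...) x$organs
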