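# Built-in parameter registry for the four gliflozins and glucose.
# Values are stored exactly as printed in the source compilations; where an
# alternative literature value exists it is kept as an annotation and can be
# selected with `use_alternates = TRUE`.

# Shared dissociation rate constants per transporter (h^-1), one value for the
# gliflozin class per transporter.
KOFF_CLASS <- c(SGLT1 = 1.1e-4, SGLT2 = 6.3e-4)

.drug_registry <- function() {
  list(
    dapagliflozin = list(
      name = "dapagliflozin",
      molecular_weight = 408.87,
      logP = 2.67,
      solubility = 0.22,
      fup = 0.09,
      pKa = 12.75,
      intestinal_permeability = 5.45e-5,
      organ_permeability = 1.13e-3,
      hepatic_clearance_specific = NULL,
      enzyme_clearances = list(UGT1A9 = 0.40, UGT2B7 = 6.6e-3, OtherEnzyme = 0.14),
      renal_plasma_clearance = 0.79,
      gfr_fraction = NULL,
      pgp_km = NULL,
      pgp_kcat = NULL,
      sglt = list(
        SGLT1 = list(transporter_id = "SGLT1", ki_nmol_l = 119.29,
                     kd_umol_l = 2.5, koff_per_h = KOFF_CLASS[["SGLT1"]]),
        SGLT2 = list(transporter_id = "SGLT2", ki_nmol_l = 0.1,
                     kd_umol_l = 1.57e-3, koff_per_h = KOFF_CLASS[["SGLT2"]])
      ),
      alternates = list(logP = 2.52)
    ),
    canagliflozin = list(
      name = "canagliflozin",
      molecular_weight = 444.52,
      logP = 3.89,
      solubility = 0.1,
      fup = 0.017,
      pKa = 12.57,
      intestinal_permeability = 0.02196,
      organ_permeability = 6.65e-5,
      hepatic_clearance_specific = NULL,
      enzyme_clearances = list(UGT1A9 = 1.2, UGT2B4 = 0.14, OtherEnzyme = 0.06),
      renal_plasma_clearance = NULL,
      gfr_fraction = 0.33,
      pgp_km = 0.19,
      pgp_kcat = 2.4,
      sglt = list(
        SGLT1 = list(transporter_id = "SGLT1", ki_nmol_l = 770.5,
                     kd_umol_l = 1.25, koff_per_h = KOFF_CLASS[["SGLT1"]]),
        SGLT2 = list(transporter_id = "SGLT2", ki_nmol_l = 4,
                     kd_umol_l = 3.14e-3, koff_per_h = KOFF_CLASS[["SGLT2"]])
      ),
      alternates = list(logP = 3.52)
    ),
    empagliflozin = list(
      name = "empagliflozin",
      molecular_weight = 450.9,
      logP = 1.21,
      solubility = 0.13,
      fup = 0.14,
      pKa = 12.57,
      intestinal_permeability = 5.71e-4,
      organ_permeability = 3.30e-6,
      hepatic_clearance_specific = 0.09,
      enzyme_clearances = NULL,
      renal_plasma_clearance = NULL,
      gfr_fraction = 0.44,
      pgp_km = NULL,
      pgp_kcat = NULL,
      sglt = list(
        SGLT1 = list(transporter_id = "SGLT1", ki_nmol_l = 797.61,
                     kd_umol_l = 15, koff_per_h = KOFF_CLASS[["SGLT1"]]),
        # empagliflozin has its own, much faster SGLT2 off-rate
        SGLT2 = list(transporter_id = "SGLT2", ki_nmol_l = 0.64,
                     kd_umol_l = 0.057, koff_per_h = 0.6)
      ),
      alternates = list(logP = 1.79, gfr_fraction = 0.286)
    ),
    ipragliflozin = list(
      name = "ipragliflozin",
      molecular_weight = 404.5,
      logP = 2.40,
      solubility = 0.0299,
      fup = 0.054,
      pKa = 12.57,
      intestinal_permeability = 2.91e-5,
      organ_permeability = 1.31e-4,
      hepatic_clearance_specific = 0.16,
      enzyme_clearances = NULL,
      renal_plasma_clearance = NULL,
      gfr_fraction = 0.014,
      pgp_km = NULL,
      pgp_kcat = NULL,
      sglt = list(
        SGLT1 = list(transporter_id = "SGLT1", ki_nmol_l = 860,
                     kd_umol_l = 5, koff_per_h = KOFF_CLASS[["SGLT1"]]),
        SGLT2 = list(transporter_id = "SGLT2", ki_nmol_l = 2.8,
                     kd_umol_l = 6.93e-3, koff_per_h = KOFF_CLASS[["SGLT2"]])
      ),
      alternates = list()
    )
  )
}

#' Names of the built-in drugs
#' @return Character vector of supported drug identifiers.
#' @export
sglt_drugs <- function() names(.drug_registry())

#' Built-in drug parameter record
#'
#' Returns the full model parameterization of one of the four SGLT2
#' inhibitors: physicochemistry (molecular weight, logP, solubility, fraction
#' unbound, pKa), permeabilities, clearance routes (enzyme-specific hepatic,
#' whole-liver specific, renal plasma clearance or GFR fraction), optional
#' P-gp kinetics, and the SGLT1/SGLT2 interaction constants (competitive Ki,
#' slow-binding Kd and koff).
#'
#' @param name One of `sglt_drugs()`.
#' @param use_alternates If `TRUE`, fields with an annotated alternative
#'   literature value (e.g. DrugBank logP) use the alternative instead of the
#'   canonical value.
#' @return An object of class `sglt_drug` (a named list).
#' @examples
#' sglt_drug("dapagliflozin")$renal_plasma_clearance
#' sglt_drug("ipragliflozin")$gfr_fraction
#' @export
sglt_drug <- function(name, use_alternates = FALSE) {
  reg <- .drug_registry()
  if (!is.character(name) || length(name) != 1 || !name %in% names(reg)) {
    abort(paste0(
      "Unknown drug '", paste(name, collapse = ","), "'. Supported drugs: ",
      paste(names(reg), collapse = ", "), "."
    ), class = "sgltsim_unknown_drug")
  }
  drug <- reg[[name]]
  if (use_alternates && length(drug$alternates)) {
    for (field in names(drug$alternates)) drug[[field]] <- drug$alternates[[field]]
  }
  drug <- structure(drug, class = "sglt_drug")
  validate_drug(drug)
  drug
}

#' Built-in glucose parameter record
#'
#' Glucose physicochemistry plus the Michaelis constants and catalytic
#' turnover numbers of the two renal sodium-glucose cotransporters.
#'
#' @return An object of class `sglt_glucose`.
#' @examples
#' sglt_glucose()$sglt_km[["SGLT2"]]   # umol/L
#' @export
sglt_glucose <- function() {
  structure(list(
    name = "glucose",
    molecular_weight = GLUCOSE_MW,
    logP = -3.3,
    solubility = 909,
    fup = 1,
    intestinal_permeability = 4.22e-7,
    organ_permeability = 5.66e-10,
    sglt_km = c(SGLT1 = 400, SGLT2 = 2000),          # umol/L
    sglt_kcat = c(SGLT1 = 65000, SGLT2 = 17895.76)   # min^-1
  ), class = "sglt_glucose")
}

validate_drug <- function(drug) {
  stopifnot(
    drug$molecular_weight > 0,
    drug$solubility > 0,
    drug$fup > 0, drug$fup <= 1
  )
  routes <- c(
    !is.null(drug$hepatic_clearance_specific),
    length(drug$enzyme_clearances) > 0,
    !is.null(drug$renal_plasma_clearance),
    !is.null(drug$gfr_fraction)
  )
  if (!any(routes)) {
    abort(paste0("Drug '", drug$name, "' has no elimination route."),
          class = "sgltsim_invalid_drug")
  }
  for (tr in c("SGLT1", "SGLT2")) {
    ia <- drug$sglt[[tr]]
    if (is.null(ia)) abort(paste0("Missing ", tr, " interaction."),
                           class = "sgltsim_invalid_drug")
    kon <- ia$koff_per_h / ia$kd_umol_l
    stopifnot(ia$ki_nmol_l > 0, ia$kd_umol_l > 0, ia$koff_per_h > 0,
              is.finite(kon), kon > 0)
  }
  invisible(drug)
}

#' Residual clearance of an enzyme partition
#'
#' Splits a total specific clearance among named enzymes and returns the
#' unassigned remainder, i.e. `total - sum(assigned)`. Used to attribute the
#' non-glucuronidation ("other enzyme") share of canagliflozin's hepatic
#' clearance.
#'
#' @param total_clearance Total specific clearance, L/umol/min; must be > 0.
#' @param assigned Named numeric vector or list of per-enzyme specific
#'   clearances, L/umol/min; all >= 0 and summing to at most `total_clearance`.
#' @return The residual clearance (L/umol/min).
#' @examples
#' derive_enzyme_clearances(1.4, c(UGT1A9 = 1.2, UGT2B4 = 0.14))  # 0.06
#' @export
derive_enzyme_clearances <- function(total_clearance, assigned = numeric()) {
  assigned <- unlist(assigned)
  if (length(assigned) == 0) assigned <- numeric()
  stopifnot(is.numeric(total_clearance), length(total_clearance) == 1,
            total_clearance > 0, all(assigned >= 0))
  if (sum(assigned) > total_clearance) {
    abort(sprintf(
      "Infeasible partition: assigned clearances sum to %.6g > total %.6g.",
      sum(assigned), total_clearance), class = "sgltsim_infeasible_partition")
  }
  total_clearance - sum(assigned)
}

#' @export
print.sglt_drug <- function(x, ...) {
  cat("<sglt_drug> ", x$name, "\n", sep = "")
  cat(sprintf("  MW %.2f g/mol, logP %.2f, fup %.3f, pKa %.2f\n",
              x$molecular_weight, x$logP, x$fup, x$pKa))
  routes <- c(
    if (!is.null(x$renal_plasma_clearance))
      sprintf("CL_R %.3g L/h", x$renal_plasma_clearance),
    if (!is.null(x$gfr_fraction)) sprintf("GFR fraction %.3g", x$gfr_fraction),
    if (!is.null(x$hepatic_clearance_specific))
      sprintf("CL_H %.3g L/h/kg", x$hepatic_clearance_specific),
    if (length(x$enzyme_clearances))
      paste0("enzymes: ", paste(names(x$enzyme_clearances), collapse = "+"))
  )
  cat("  elimination:", paste(routes, collapse = "; "), "\n")
  invisible(x)
}

#' @exportS3Method
tidy.sglt_drug <- function(x, ...) {
  scalars <- c("molecular_weight", "logP", "solubility", "fup", "pKa",
               "intestinal_permeability", "organ_permeability",
               "hepatic_clearance_specific", "renal_plasma_clearance",
               "gfr_fraction", "pgp_km", "pgp_kcat")
  rows <- purrr::map_dfr(scalars, function(f) {
    v <- x[[f]]
    if (is.null(v)) return(tibble::tibble())
    tibble::tibble(parameter = f, value = as.numeric(v))
  })
  enz <- purrr::imap_dfr(x$enzyme_clearances %||% list(), function(v, nm)
    tibble::tibble(parameter = paste0("CL_", nm), value = v))
  sglt <- purrr::imap_dfr(x$sglt, function(ia, tr) tibble::tibble(
    parameter = paste0(tr, c("_ki_nmol_l", "_kd_umol_l", "_koff_per_h")),
    value = c(ia$ki_nmol_l, ia$kd_umol_l, ia$koff_per_h)
  ))
  dplyr::bind_rows(rows, enz, sglt) |>
    dplyr::mutate(drug = x$name, .before = 1)
}

#' Write / read a drug parameter file
#'
#' Serializes a drug record to a YAML document (field names as in
#' [sglt_drug()], units fixed by field name) and reads it back. Round-tripping
#' a built-in record reproduces every field exactly.
#'
#' @param drug An `sglt_drug` object.
#' @param path File path.
#' @return `write_drug_parameters()` returns `path` invisibly;
#'   `read_drug_parameters()` returns an `sglt_drug`.
#' @export
write_drug_parameters <- function(drug, path) {
  stopifnot(inherits(drug, "sglt_drug"))
  yaml::write_yaml(unclass(drug), path, precision = 15)
  invisible(path)
}

#' @rdname write_drug_parameters
#' @export
read_drug_parameters <- function(path) {
  raw <- yaml::read_yaml(path)
  if (length(raw$enzyme_clearances) == 0) raw["enzyme_clearances"] <- list(NULL)
  drug <- structure(raw, class = "sglt_drug")
  validate_drug(drug)
  drug
}
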