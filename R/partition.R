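# Tissue-to-plasma partition coefficients, Rodgers-Rowland method.
# The gliflozins are very weak acids (pKa ~ 12.6), effectively neutral at
# physiological pH, so the neutral-species equations apply: partitioning into
# tissue water, neutral lipid, neutral phospholipid, plus albumin-mediated
# binding in the tissue interstitium. Adipose uses the vegetable-oil:water
# partition coefficient estimated from logP.

# plasma neutral lipid / neutral phospholipid volume fractions
PLASMA_F_NL <- 0.0023
PLASMA_F_NP <- 0.0013

#' Tissue-to-plasma partition coefficients
#'
#' Computes one partition coefficient (Kp, tissue:plasma) per perfused
#' compartment from the drug's lipophilicity and plasma protein binding and
#' the physiology's fractional tissue composition, using the published
#' neutral-species tissue-composition equations. For adipose the
#' octanol-water logP is converted to a vegetable-oil:water value
#' (`log Pvow = 1.115 logP - 1.35`).
#'
#' @param drug An [sglt_drug()] (needs `logP`, `fup`, `pKa`) or any list with
#'   those fields.
#' @param physiology A [reference_physiology()] object.
#' @return A tibble with columns `compartment`, `kp`; all `kp > 0`.
#' @examples
#' compute_partition_coefficients(sglt_drug("dapagliflozin"),
#'                                reference_physiology())
#' @export
compute_partition_coefficients <- function(drug, physiology) {
  if (is.null(drug$logP) || is.null(drug$fup)) {
    abort("Drug needs logP and fup for partitioning.",
          class = "sgltsim_config_error")
  }
  comp <- physiology$composition
  if (is.null(comp)) {
    abort("Physiology carries no tissue composition table.",
          class = "sgltsim_config_error")
  }
  P <- 10^drug$logP
  Pvow <- 10^(1.115 * drug$logP - 1.35)
  fup <- drug$fup

  kp_one <- function(tissue, f_ew, f_iw, f_nl, f_np, ar) {
    Pt <- if (identical(tissue, "adipose")) Pvow else P
    plasma_lipid <- P * PLASMA_F_NL + (0.3 * P + 0.7) * PLASMA_F_NP
    kpu <- f_ew + f_iw +
      Pt * f_nl + (0.3 * Pt + 0.7) * f_np +
      pmax(1 / fup - 1 - plasma_lipid, 0) * ar
    kpu * fup
  }
  out <- comp |>
    dplyr::mutate(kp = purrr::pmap_dbl(
      list(.data$tissue, .data$f_ew, .data$f_iw, .data$f_nl, .data$f_np,
           .data$albumin_ratio), kp_one)) |>
    dplyr::select(compartment = "tissue", "kp")
  stopifnot(all(out$kp > 0))
  out
}
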