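# Internal unit system: amount in umol, volume in L, time in h.
# Table-style inputs keep their printed units; conversion happens once, at
# model-build time, through these helpers.

#' Unit conversion helpers
#'
#' Convert between the units drug parameters are customarily printed in and
#' the internal simulation unit system (micromole, litre, hour).
#'
#' @param mg,umol Mass in milligrams / amount in micromoles.
#' @param mw Molecular weight in g/mol.
#' @param umol_per_l Concentration in umol/L.
#' @param ng_per_ml Concentration in ng/mL.
#' @param ml_min Flow in mL/min.
#'
#' @return A numeric vector in the target unit.
#' @name units
#' @examples
#' mg_to_umol(10, 408.87)           # a 10 mg dapagliflozin dose in umol
#' umol_l_to_ng_ml(0.5, 408.87)     # plasma concentration back to ng/mL
NULL

#' @rdname units
#' @export
mg_to_umol <- function(mg, mw) {
  stopifnot(mw > 0)
  mg / mw * 1000
}

#' @rdname units
#' @export
umol_to_mg <- function(umol, mw) {
  stopifnot(mw > 0)
  umol * mw / 1000
}

#' @rdname units
#' @export
umol_l_to_ng_ml <- function(umol_per_l, mw) {
  stopifnot(mw > 0)
  umol_per_l * mw
}

#' @rdname units
#' @export
ng_ml_to_umol_l <- function(ng_per_ml, mw) {
  stopifnot(mw > 0)
  ng_per_ml / mw
}

#' @rdname units
#' @export
ml_min_to_l_h <- function(ml_min) ml_min * 60 / 1000

# molecular weight of glucose, g/mol
GLUCOSE_MW <- 180.16
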