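# Non-compartmental summaries of a concentration-time profile.

#' Area under the concentration-time curve
#'
#' Linear trapezoidal AUC over the observation grid. With
#' `method = "extrapolate"` a log-linear tail (terminal slope fitted to the
#' last `n_tail` positive observations) is added beyond the last observation.
#'
#' @param time Strictly increasing time grid, h.
#' @param conc Non-negative concentrations (same length as `time`).
#' @param method `"last"` (truncate at last observation) or `"extrapolate"`.
#' @param n_tail Number of terminal points used for the tail slope.
#' @return AUC in concentration x hour units (e.g. ng*h/mL).
#' @examples
#' auc(c(0, 1, 2), c(0, 2, 2))   # 3
#' @export
auc <- function(time, conc, method = c("last", "extrapolate"), n_tail = 3) {
  method <- match.arg(method)
  check_profile(time, conc)
  a <- sum(diff(time) * (head(conc, -1) + tail(conc, -1)) / 2)
  if (method == "extrapolate") {
    idx <- tail(which(conc > 0), n_tail)
    if (length(idx) >= 2) {
      fit <- stats::lm(log(conc[idx]) ~ time[idx])
      lambda_z <- -unname(stats::coef(fit)[2])
      if (is.finite(lambda_z) && lambda_z > 0) {
        a <- a + tail(conc, 1) / lambda_z
      }
    }
  }
  a
}

#' Peak concentration and its time
#'
#' @inheritParams auc
#' @return A one-row tibble with `cmax` and `tmax_h` (first time the maximum
#'   is reached).
#' @examples
#' cmax(c(0, 1, 2), c(0, 2, 1))
#' @export
cmax <- function(time, conc) {
  check_profile(time, conc)
  i <- which.max(conc)   # first maximum
  tibble::tibble(cmax = conc[i], tmax_h = time[i])
}

check_profile <- function(time, conc) {
  if (length(time) == 0 || length(conc) == 0) {
    abort("Empty concentration-time series.",
          class = "sgltsim_validation_error")
  }
  if (length(time) != length(conc)) {
    abort("time and conc must have equal length.",
          class = "sgltsim_validation_error")
  }
  if (length(time) < 2 || any(diff(time) <= 0)) {
    abort("time must be strictly increasing with >= 2 points.",
          class = "sgltsim_validation_error")
  }
  if (any(conc < 0)) {
    abort("Concentrations must be non-negative.",
          class = "sgltsim_validation_error")
  }
  invisible(TRUE)
}
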