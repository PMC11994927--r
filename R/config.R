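#' Model configuration
#'
#' Loads the default configuration shipped with the package, optionally merges
#' a user YAML file on top, then merges any in-call overrides (a nested list).
#'
#' @param path Optional path to a YAML file with the same block structure as
#'   the default (`absorption`, `hepatic`, `renal`, `blood`, `solver`,
#'   `tubule`, `glucose_plasma_mmol_l`, `population`).
#' @param overrides Optional nested list of overrides, merged last.
#' @return A nested list of class `sglt_config`.
#' @examples
#' cfg <- sglt_config(overrides = list(tubule = list(use_occupancy = FALSE)))
#' cfg$tubule$use_occupancy
#' @export
sglt_config <- function(path = NULL, overrides = NULL) {
  cfg <- yaml::read_yaml(
    system.file("extdata", "default_config.yaml", package = "sgltsim"))
  if (!is.null(path)) cfg <- modifyList(cfg, yaml::read_yaml(path))
  if (!is.null(overrides)) cfg <- modifyList(cfg, overrides)
  structure(cfg, class = c("sglt_config", "list"))
}
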