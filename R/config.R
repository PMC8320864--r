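#' Run configuration
#'
#' Flat key-value configuration for the command-line interface and the demo
#' pipeline, merged as defaults <- config file <- explicit overrides.
#' Unknown keys are rejected.  Keys cover the evolution parameters
#' (`alpha`, `K`, `tol`, `max_iter`, `rect_iter`, `band_width`,
#' `force_clip`) and `spacing_cm_per_px`.
#'
#' @param file optional YAML config file of flat key-value pairs.
#' @param overrides named list of explicit overrides (e.g. from CLI flags).
#' @return Named list of resolved configuration values.
#' @export
run_config <- function(file = NULL, overrides = list()) {
  defaults <- list(alpha = 1, K = 90, tol = 1e-4, max_iter = 5000,
                   rect_iter = 200, band_width = 10, force_clip = 2,
                   spacing_cm_per_px = 0.04)
  cfg <- defaults
  apply_layer <- function(cfg, layer, where) {
    if (length(layer) == 0) return(cfg)
    unknown <- setdiff(names(layer), names(defaults))
    if (length(unknown) > 0)
      stop("unknown config key(s) in ", where, ": ",
           paste(unknown, collapse = ", "))
    cfg[names(layer)] <- layer
    cfg
  }
  if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file)
    cfg <- apply_layer(cfg, yaml::read_yaml(file), file)
  }
  apply_layer(cfg, overrides, "overrides")
}

#' Build evolution parameters from a run configuration
#'
#' @param cfg a list from [run_config()].
#' @return An [evolution_params()] object.
#' @export
config_params <- function(cfg) {
  evolution_params(alpha = cfg$alpha, K = cfg$K, tol = cfg$tol,
                   max_iter = cfg$max_iter, rect_iter = cfg$rect_iter,
                   band_width = cfg$band_width, force_clip = cfg$force_clip)
}

#' Serialize a resolved configuration next to run outputs
#'
#' @param cfg configuration list.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, path)
  invisible(path)
}
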