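#' Default pipeline configuration
#'
#' Nested list describing a full simulate-and-reduce run: bundle layout,
#' detector, common Raman-shift axis, simulation options (phantom choice,
#' target SNR, throughput scatter, cosmic hits), baseline and wavelength
#' calibration parameters, normalization options, and the peak table for
#' chemical maps (characteristic shift and fit window per substance).
#'
#' @param ... named overrides merged (recursively) into the defaults.
#' @return a list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(...) {
  cfg <- list(
    layout = list(n_rows = 20L, n_cols = 20L, pitch_mm = 0.5,
                  core_um = 110, cladding_um = 132,
                  dead_fibers = list(c(12L, 5L))),
    detector = list(n_rows_px = 1200L, n_cols_px = 600L, bias_level = 100,
                    read_noise = 3, gain = 1),
    axis = list(from = 200, to = 2000, by = 2),
    simulate = list(phantom = "beads", snr = 30, n_bias = 3L,
                    illumination_ratio = 10, throughput_sd = 0.1,
                    n_cosmics = 20L, reference_level = 3000,
                    background_level = 200, noise = TRUE),
    traces = list(pitch_px = 2.9, sigma_px = 0.55, bow_px = 0.8),
    wavelength = list(degree = 3L, excitation_nm = 785,
                      lines = as.numeric(default_arc_lines())),
    baseline = list(order = 4L, iterations = 15L),
    normalization = list(window = NULL),
    maps = list(list(substance = "PS", shift = 1035, window = 40),
                list(substance = "PMMA", shift = 600, window = 40)),
    seed = 42L)
  cfg <- merge_config(cfg, list(...))
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

# recursive merge: named lists merge key-wise, anything else (scalars,
# vectors, unnamed lists such as dead_fibers or the maps table) replaces
# the default wholesale
merge_config <- function(base, over) {
  for (nm in names(over)) {
    b <- base[[nm]]; o <- over[[nm]]
    if (is.list(b) && is.list(o) && length(o) > 0 &&
        !is.null(names(o)) && all(names(o) != ""))
      base[[nm]] <- merge_config(b, o)
    else base[nm] <- list(o)
  }
  base
}

#' Read / write a pipeline configuration as YAML
#'
#' User-supplied keys are merged into [default_pipeline_config()], so a
#' config file only needs to state what differs from the defaults.
#'
#' @param path YAML file path.
#' @param config a `pipeline_config`.
#' @return `read_pipeline_config`: a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- merge_config(default_pipeline_config(), user)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Stable hash of a configuration
#'
#' Recorded in every output product for provenance.
#'
#' @param config a `pipeline_config`.
#' @return character hash.
#' @export
config_hash <- function(config) rlang::hash(unclass(config))

layout_from_config <- function(cfg) {
  lc <- cfg$layout
  bundle_layout(lc$n_rows, lc$n_cols, lc$pitch_mm, lc$core_um,
                lc$cladding_um, dead_fibers = lc$dead_fibers)
}

detector_from_config <- function(cfg) {
  dc <- cfg$detector
  detector_config(dc$n_rows_px, dc$n_cols_px, dc$bias_level, dc$read_noise,
                  dc$gain)
}

axis_from_config <- function(cfg) {
  default_shift_axis(cfg$axis$from, cfg$axis$to, cfg$axis$by)
}
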