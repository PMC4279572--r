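#' Simulate the raw frames of one imaging run
#'
#' Generates the full frame set the reduction consumes: bias stack, flat,
#' arc, science exposure of the configured phantom, a blank exposure
#' (optics background only) and a uniform reference exposure (CaF2-plate
#' stand-in). Fiber-to-fiber throughput scatter, dead fibers, fluorescence
#' baseline, center-weighted illumination and cosmic-ray hits are all
#' applied. All randomness derives from `seed` via [stage_seed()].
#'
#' @param config a [default_pipeline_config()].
#' @param seed top-level seed (defaults to `config$seed`).
#' @param phantom optional `phantom` overriding `config$simulate$phantom`
#'   (`"beads"`, `"half_field"` or `"teflon"`).
#' @return list with the frames, the ground-truth models and the phantom.
#' @export
simulate_run <- function(config = default_pipeline_config(),
                         seed = config$seed, phantom = NULL) {
  layout <- layout_from_config(config)
  detector <- detector_from_config(config)
  axis <- axis_from_config(config)
  sim <- config$simulate
  nf <- n_fibers(layout)

  traces <- default_trace_model(nf, detector, config$traces$pitch_px,
                                config$traces$sigma_px, config$traces$bow_px)
  dispersion <- default_dispersion_model(nf, detector,
                                         excitation_nm =
                                           config$wavelength$excitation_nm)
  illum <- illumination_profile(layout, sim$illumination_ratio)
  if (is.null(phantom)) {
    phantom <- switch(sim$phantom,
      beads = bead_phantom_fig(layout, illum),
      half_field = half_field_phantom(layout, illumination = illum),
      teflon = uniform_phantom(layout, "teflon", illum),
      fc_abort(sprintf("unknown phantom '%s'", sim$phantom),
               "fibercube_config_error"))
  }

  # fiber-to-fiber sensitivity scatter; dead fibers transmit nothing
  throughput <- with_seed(stage_seed(seed, "throughput"),
                          exp(stats::rnorm(nf, 0, sim$throughput_sd)))
  dead_slits <- layout$slit_order[dead_fiber_mask(layout)]
  throughput[dead_slits + 1L] <- 0

  background <- if (sim$background_level > 0) {
    u <- rescale_unit(axis)
    sim$background_level * (1 + 0.3 * u + 0.2 * u^2)
  } else NULL

  bias <- make_bias(detector, sim$n_bias, noise = sim$noise,
                    seed = stage_seed(seed, "bias"))
  flat <- make_flat(traces, dispersion, detector, throughput = throughput,
                    noise = sim$noise, seed = stage_seed(seed, "flat"))
  arc <- make_arc(config$wavelength$lines, traces, dispersion, detector,
                  noise = sim$noise, seed = stage_seed(seed, "arc"))
  science <- make_science(phantom, spectral_library(), traces, dispersion,
                          detector, axis, snr = sim$snr,
                          background = background, throughput = throughput,
                          noise = sim$noise,
                          seed = stage_seed(seed, "science"))
  if (sim$n_cosmics > 0)
    science <- inject_cosmics(science, sim$n_cosmics,
                              seed = stage_seed(seed, "cosmics"))
  blank_phantom <- new_phantom(
    array(0, dim = c(layout$n_rows, layout$n_cols, 1),
          dimnames = list(NULL, NULL, "none")), layout, illum)
  blank <- make_science(blank_phantom, spectral_library(), traces, dispersion,
                        detector, axis, snr = sim$snr,
                        background = background, throughput = throughput,
                        noise = sim$noise, seed = stage_seed(seed, "blank"))
  reference <- make_reference(layout, traces, dispersion, detector, axis,
                              level = sim$reference_level,
                              illumination = illum, throughput = throughput,
                              noise = sim$noise,
                              seed = stage_seed(seed, "reference"))

  list(bias = bias, flat = flat, arc = arc, science = science,
       blank = blank, reference = reference, layout = layout,
       detector = detector, axis = axis, phantom = phantom,
       truth = list(traces = traces, dispersion = dispersion,
                    throughput = throughput))
}

#' Reduce a frame set to calibrated row-stacked spectra and a data cube
#'
#' The calibration chain: master bias, trace finding (gap-filling dead
#' fibers), throughput flat, arc wavelength solutions, aperture extraction,
#' cosmic-ray cleaning, resampling to the common Raman-shift axis and cube
#' assembly.
#'
#' @param frames list as produced by [simulate_run()] (fields `bias`,
#'   `flat`, `arc`, `science`, optional `blank` and `reference`).
#' @param layout a [bundle_layout()].
#' @param config a [default_pipeline_config()].
#' @return list with `cube` (blank-subtracted, normalized when reference
#'   frames are present), `cube_raw`, `rss`, `traces`, `dispersion`,
#'   `throughput` and a `report` list.
#' @export
reduce_run <- function(frames, layout, config = default_pipeline_config()) {
  axis <- axis_from_config(config)
  nf <- n_fibers(layout)
  report <- list(config_hash = config_hash(config))

  for (nm in c("bias", "flat", "arc", "science"))
    if (is.null(frames[[nm]]))
      fc_abort(sprintf("missing %s frame(s): supply them or run simulate_run()",
                       nm), "fibercube_stage_error")

  master <- combine_bias(frames$bias)
  traces <- find_traces(frames$flat, expected_n = nf, master_bias = master,
                        fill_missing = TRUE)
  report$n_traces_detected <- attr(traces, "n_detected")
  report$trace_sigma_px <- traces$sigma_px

  flat_rss <- extract_spectra(frames$flat, traces, master)
  thr <- measure_throughput(flat_rss)
  report$n_dead_fibers <- sum(thr$dead)

  arc_rss <- extract_spectra(frames$arc, traces, master, throughput = thr)
  dispersion <- fit_wavelength(arc_rss, config$wavelength$lines,
                               degree = config$wavelength$degree,
                               excitation_nm = config$wavelength$excitation_nm)
  report$wavelength_rms_nm <- max(dispersion$residual_rms, na.rm = TRUE)

  reduce_one <- function(frame, clean = FALSE) {
    rss <- extract_spectra(frame, traces, master, throughput = thr)
    rss$dispersion <- dispersion
    n_replaced <- 0L
    if (clean) {
      rss <- clean_cosmics(rss)
      n_replaced <- nrow(attr(rss, "replaced"))
    }
    spec <- resample_common_axis(rss, axis)
    list(rss = rss, cube = assemble_cube(spec, layout, axis, dead = rss$dead),
         n_replaced = n_replaced)
  }

  sci <- reduce_one(frames$science, clean = TRUE)
  report$n_cosmics_replaced <- sci$n_replaced
  cube <- sci$cube
  cube_raw <- cube
  if (!is.null(frames$blank))
    cube <- subtract_reference(cube, reduce_one(frames$blank)$cube)
  if (!is.null(frames$reference)) {
    ref_cube <- reduce_one(frames$reference)$cube
    cube <- normalize_by_reference(cube, ref_cube,
                                   window = config$normalization$window)
  }
  cube$meta <- c(cube$meta, list(CFGHASH = report$config_hash))
  list(cube = cube, cube_raw = cube_raw, rss = sci$rss, traces = traces,
       dispersion = dispersion, throughput = thr, report = report)
}

#' Run the full imaging pipeline
#'
#' Simulation (unless frames are supplied), reduction to a normalized data
#' cube, and chemical-map construction for every configured substance.
#' When `out_dir` is given, all intermediates are written: FITS frames,
#' row-stacked spectra, cube, maps (FITS + PNG), the effective config
#' (YAML) and a JSON run report. Every product records the config hash and
#' seed.
#'
#' @param config a [default_pipeline_config()] or a YAML path.
#' @param seed top-level seed; defaults to `config$seed`.
#' @param out_dir optional output directory.
#' @param phantom optional `phantom` object overriding the configured one.
#' @param frames optional pre-simulated (or loaded) frame set.
#' @return list with `cube`, `maps` (named list of [chemical_map()]s),
#'   `report`, `rss`, `phantom`, `layout` and the simulation `truth`.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         seed = NULL, out_dir = NULL, phantom = NULL,
                         frames = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (is.null(seed)) seed <- config$seed
  t0 <- Sys.time()

  if (is.null(frames)) {
    message("stage: simulate")
    frames <- simulate_run(config, seed = seed, phantom = phantom)
  }
  layout <- frames$layout %||% layout_from_config(config)

  message("stage: reduce")
  red <- reduce_run(frames, layout, config)

  message("stage: map")
  lib <- spectral_library()
  maps <- list()
  for (m in config$maps) {
    maps[[m$substance]] <- chemical_map(
      red$cube, m$substance, shift = m$shift, window = m$window,
      library = lib, baseline_order = config$baseline$order,
      baseline_iter = config$baseline$iterations)
  }

  report <- red$report
  report$seed <- seed
  report$n_maps <- length(maps)
  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    prov <- list(CFGHASH = report$config_hash, SEED = seed)
    write_frame_fits(combine_bias(frames$bias),
                     file.path(out_dir, "master_bias.fits"), prov)
    write_frame_fits(frames$science, file.path(out_dir, "science.fits"), prov)
    write_rss_fits(red$rss, file.path(out_dir, "science_rss.fits"), prov)
    write_cube_fits(red$cube, file.path(out_dir, "cube.fits"), prov)
    for (nm in names(maps)) {
      write_map_fits(maps[[nm]],
                     file.path(out_dir, sprintf("map_%s.fits", nm)), prov)
      render_map(maps[[nm]],
                 file = file.path(out_dir, sprintf("map_%s.png", nm)))
    }
    write_pipeline_config(config, file.path(out_dir, "config.yml"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  list(cube = red$cube, cube_raw = red$cube_raw, maps = maps,
       report = report, rss = red$rss, phantom = frames$phantom,
       layout = layout, truth = frames$truth, traces = red$traces,
       dispersion = red$dispersion)
}
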