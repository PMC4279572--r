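#' Detector frames
#'
#' A `frame` is one 2D detector exposure: a counts matrix plus frame type
#' (`bias`, `flat`, `arc`, `science`, `master-bias`), exposure time and
#' header metadata.
#'
#' @param data numeric matrix of counts.
#' @param type frame type.
#' @param exptime exposure time in s.
#' @param header named list of metadata.
#' @return object of class `frame`.
#' @export
new_frame <- function(data, type, exptime = 0,
                      header = list()) {
  stopifnot(is.matrix(data), all(is.finite(data)))
  type <- match.arg(type, c("bias", "flat", "arc", "science", "master-bias"))
  structure(list(data = data, type = type, exptime = exptime, header = header),
            class = "frame")
}

#' @export
print.frame <- function(x, ...) {
  cat(sprintf("<frame:%s> %d x %d px, exptime %gs\n", x$type,
              nrow(x$data), ncol(x$data), x$exptime))
  invisible(x)
}

# Deposit per-fiber, per-column fluxes onto the detector as Gaussian
# cross-dispersion profiles. Discrete profile weights are normalized per
# column so the injected flux is conserved exactly.
deposit_traces <- function(flux_cols, traces, detector) {
  nf <- nrow(flux_cols)
  stopifnot(nf == nrow(traces$coef))
  cols <- seq_len(detector$n_cols_px) - 1L
  centers <- trace_centers(traces, cols)
  h <- max(2L, ceiling(4 * traces$sigma_px))
  img <- matrix(0, detector$n_rows_px, detector$n_cols_px)
  offs <- -h:h
  for (i in seq_len(nf)) {
    if (all(flux_cols[i, ] == 0)) next
    c0 <- centers[i, ]
    r0 <- round(c0)
    # rows x cols weights for this fiber
    rr <- outer(offs, r0, `+`)                     # (2h+1) x ncols, 0-based
    w <- exp(-(rr - rep(c0, each = length(offs)))^2 / (2 * traces$sigma_px^2))
    w <- sweep(w, 2, colSums(w), "/")
    val <- sweep(w, 2, flux_cols[i, ], "*")
    ok <- rr >= 0 & rr < detector$n_rows_px
    idx <- cbind(rr[ok] + 1L, rep(seq_len(detector$n_cols_px),
                                  each = length(offs))[ok])
    img[idx] <- img[idx] + val[ok]
  }
  img
}

apply_detector_noise <- function(signal, detector, noise, seed) {
  if (!noise) return(signal + detector$bias_level)
  with_seed(seed, {
    e <- suppressWarnings(stats::rpois(length(signal),
                                       pmax(signal, 0) * detector$gain))
    shot <- matrix(e / detector$gain, nrow(signal), ncol(signal))
    shot + detector$bias_level +
      matrix(stats::rnorm(length(signal), 0, detector$read_noise),
             nrow(signal), ncol(signal))
  })
}

#' Render a raw detector frame from per-fiber spectra
#'
#' Forward model of the spectrograph: each live fiber's spectrum is mapped
#' through its wavelength solution to dispersion-axis columns and deposited
#' as a Gaussian cross-dispersion profile around its trace; the bias level is
#' added, and optionally Poisson shot noise plus Gaussian read noise.
#'
#' @param spectra `n_fibers x length(axis)` intensity matrix (one row per
#'   slit position; dead fibers all-zero), or `NULL` for a dark field.
#' @param axis spectral axis of `spectra`.
#' @param axis_type `"shift"` (Raman shift, cm^-1) or `"wavelength"` (nm).
#' @param traces a [trace_model()].
#' @param dispersion a [dispersion_model()].
#' @param detector a [detector_config()].
#' @param noise add Poisson + read noise?
#' @param seed RNG seed for the noise draw (same seed, same frame).
#' @param type,exptime frame metadata.
#' @return a `frame`.
#' @export
render_frame <- function(spectra, axis, axis_type = c("shift", "wavelength"),
                         traces, dispersion, detector = detector_config(),
                         noise = TRUE, seed = NULL, type = "science",
                         exptime = 1) {
  axis_type <- match.arg(axis_type)
  cols <- seq_len(detector$n_cols_px) - 1L
  if (is.null(spectra)) {
    signal <- matrix(0, detector$n_rows_px, detector$n_cols_px)
  } else {
    if (nrow(spectra) != nrow(traces$coef))
      fc_abort("one spectrum per trace required", "fibercube_shape_error")
    lam <- fiber_wavelengths(dispersion, cols)
    flux_cols <- matrix(0, nrow(spectra), length(cols))
    for (i in seq_len(nrow(spectra))) {
      x <- if (axis_type == "shift")
        to_raman_shift(pmax(lam[i, ], dispersion$excitation_nm),
                       dispersion$excitation_nm)
      else lam[i, ]
      flux_cols[i, ] <- stats::approx(axis, spectra[i, ], xout = x,
                                      yleft = 0, yright = 0)$y
    }
    signal <- deposit_traces(flux_cols, traces, detector)
  }
  data <- apply_detector_noise(signal, detector, noise, seed)
  new_frame(data, type, exptime,
            header = list(SEED = if (is.null(seed)) NA else seed,
                          NOISE = noise))
}

#' Simulate bias frames
#'
#' Zero-second exposures carrying only the electronic offset (plus read
#' noise when `noise = TRUE`).
#'
#' @param detector a [detector_config()].
#' @param n_frames number of bias frames.
#' @param noise,seed noise switch and seed.
#' @return list of `frame`s of type `bias`, exposure 0 s.
#' @export
make_bias <- function(detector = detector_config(), n_frames = 3,
                      noise = TRUE, seed = NULL) {
  lapply(seq_len(n_frames), function(k) {
    s <- if (is.null(seed)) NULL else stage_seed(seed, k)
    data <- apply_detector_noise(
      matrix(0, detector$n_rows_px, detector$n_cols_px), detector, noise, s)
    new_frame(data, "bias", 0, header = list(SEED = if (is.null(s)) NA else s))
  })
}

#' Simulate a flat-field frame
#'
#' Exposure to the smooth continuum of an integrating sphere fed by a
#' halogen lamp: every live fiber carries a gently curved continuum times
#' its throughput factor. Used downstream to locate traces and measure
#' fiber-to-fiber sensitivity variations.
#'
#' @param traces,dispersion,detector instrument models.
#' @param throughput per-fiber relative throughput (0 suppresses a trace,
#'   emulating a dead fiber). Default all 1.
#' @param flux continuum flux per column (counts) at throughput 1.
#' @param noise,seed noise switch and seed.
#' @return a `frame` of type `flat`.
#' @export
make_flat <- function(traces, dispersion, detector = detector_config(),
                      throughput = NULL, flux = 5000, noise = TRUE,
                      seed = NULL) {
  nf <- nrow(traces$coef)
  if (is.null(throughput)) throughput <- rep(1, nf)
  stopifnot(length(throughput) == nf)
  cols <- seq_len(detector$n_cols_px) - 1L
  u <- rescale_unit(cols)
  shape <- 1 - 0.25 * u^2               # smooth lamp continuum
  flux_cols <- outer(throughput, shape) * flux
  signal <- deposit_traces(flux_cols, traces, detector)
  data <- apply_detector_noise(signal, detector, noise, seed)
  new_frame(data, "flat", 10,
            header = list(SEED = if (is.null(seed)) NA else seed))
}

#' Default synthetic arc line list
#'
#' Eight emission lines evenly placed in 790-930 nm. The calibration math is
#' line-list agnostic; this list stands in for an arc lamp.
#'
#' @return wavelengths in nm.
#' @export
default_arc_lines <- function() seq(790, 930, length.out = 8)

#' Simulate an arc (wavelength calibration) frame
#'
#' Narrow emission lines at the listed wavelengths are placed per fiber at
#' the columns given by inverting that fiber's dispersion polynomial, then
#' deposited along the traces. Lines outside a fiber's wavelength range are
#' dropped for that fiber.
#'
#' @param line_list emission-line wavelengths (nm); must be non-empty.
#' @param traces,dispersion,detector instrument models.
#' @param line_flux integrated counts per line.
#' @param line_sigma_px line width (Gaussian sigma) along dispersion, px.
#' @param noise,seed noise switch and seed.
#' @return a `frame` of type `arc`.
#' @export
make_arc <- function(line_list = default_arc_lines(), traces, dispersion,
                     detector = detector_config(), line_flux = 20000,
                     line_sigma_px = 0.9, noise = TRUE, seed = NULL) {
  if (length(line_list) == 0)
    fc_abort("empty arc line list", "fibercube_config_error")
  nf <- nrow(traces$coef)
  cols <- seq_len(detector$n_cols_px) - 1L
  lam <- fiber_wavelengths(dispersion, cols)
  flux_cols <- matrix(0, nf, length(cols))
  for (i in seq_len(nf)) {
    centers_px <- stats::approx(lam[i, ], cols, xout = line_list)$y
    for (cpx in centers_px[!is.na(centers_px)]) {
      w <- exp(-(cols - cpx)^2 / (2 * line_sigma_px^2))
      flux_cols[i, ] <- flux_cols[i, ] + line_flux * w / sum(w)
    }
  }
  signal <- deposit_traces(flux_cols, traces, detector)
  data <- apply_detector_noise(signal, detector, noise, seed)
  new_frame(data, "arc", 5,
            header = list(SEED = if (is.null(seed)) NA else seed))
}

# Per-column peak flux needed so that the tophat-extracted peak reaches a
# given SNR, accounting for shot noise of peak + baseline and read noise
# over the extraction aperture.
flux_for_snr <- function(snr, detector, traces, baseline_ratio = 2,
                         half_width = NULL) {
  if (is.null(half_width)) half_width <- 2.5 * traces$sigma_px
  n_ap <- 2 * floor(half_width) + 1
  b <- 1 + baseline_ratio
  r2 <- n_ap * detector$read_noise^2
  # F / sqrt(b F / gain + r2) = snr
  g <- detector$gain
  (snr^2 * b / g + sqrt((snr^2 * b / g)^2 + 4 * snr^2 * r2)) / 2
}

#' Simulate a science frame from a phantom
#'
#' Each spaxel's spectrum is the phantom's substance mixture rendered from
#' the spectral library, plus a 4th-order polynomial fluorescence baseline,
#' all scaled by the spaxel's illumination factor and optionally an additive
#' optics background shared by all spaxels. Dead fibers receive zero flux.
#'
#' @param phantom a `phantom` (see [make_bead_phantom()]).
#' @param library a [spectral_library()].
#' @param traces,dispersion,detector instrument models.
#' @param axis Raman-shift axis used to synthesize spectra.
#' @param snr target extracted peak signal-to-noise at the *dimmest*
#'   substance-bearing spaxel (sets the peak flux, compensating the
#'   illumination profile); ignored when `peak_flux` is given.
#' @param peak_flux per-column peak flux in counts, overrides `snr`.
#' @param baseline_ratio fluorescence baseline amplitude relative to the
#'   peak flux (the baseline polynomial is scaled so its maximum is
#'   `baseline_ratio * peak_flux`).
#' @param baseline_coef ascending baseline polynomial coefficients on the
#'   axis rescaled to `[-1, 1]`; must be non-negative valued.
#' @param background optional intensity vector on `axis` added to every
#'   live spaxel (optics background), scaled by illumination.
#' @param throughput per-fiber (slit-ordered) sensitivity factors applied to
#'   the emitted spectra; `NULL` for uniform.
#' @param noise,seed noise switch and seed.
#' @param exptime exposure time recorded in the header (s).
#' @return a `frame` of type `science`.
#' @export
make_science <- function(phantom, library = spectral_library(), traces,
                         dispersion, detector = detector_config(),
                         axis = default_shift_axis(), snr = 30,
                         peak_flux = NULL, baseline_ratio = 2,
                         baseline_coef = default_baseline_coef(),
                         background = NULL, throughput = NULL, noise = TRUE,
                         seed = NULL, exptime = 120) {
  layout <- phantom$layout
  nf <- n_fibers(layout)
  stopifnot(nrow(traces$coef) == nf)
  if (is.null(peak_flux)) {
    peak_flux <- flux_for_snr(snr, detector, traces, baseline_ratio)
    lit <- apply(phantom$weights > 0, c(1, 2), any) & !dead_fiber_mask(layout)
    if (any(lit)) peak_flux <- peak_flux / min(phantom$illumination[lit])
  }
  # synthesize on an axis padded beyond the requested range so the rendered
  # frames carry no artificial spectral edges inside the detector span
  step <- stats::median(diff(axis))
  axis0 <- axis
  axis <- seq(max(min(axis0) - 220, step), max(axis0) + 220, by = step)
  if (!is.null(background))
    background <- stats::approx(axis0, background, xout = axis, rule = 2)$y
  u <- rescale_unit(axis)
  bl <- polyval(baseline_coef, u)
  if (any(bl < 0)) fc_abort("baseline polynomial must be non-negative",
                            "fibercube_config_error")
  bl <- bl / max(bl) * baseline_ratio * peak_flux
  dead <- dead_fiber_mask(layout)
  spectra <- matrix(0, nf, length(axis))
  for (r in seq_len(layout$n_rows)) {
    for (cc in seq_len(layout$n_cols)) {
      if (dead[r, cc]) next
      w <- phantom$weights[r, cc, ]
      names(w) <- phantom$substances
      spec <- rep(0, length(axis))
      if (any(w > 0)) spec <- make_spectrum(library, w, axis) * peak_flux + bl
      if (!is.null(background)) spec <- spec + background
      spec <- spec * phantom$illumination[r, cc]
      slit <- layout$slit_order[r, cc]
      if (!is.null(throughput)) spec <- spec * throughput[slit + 1L]
      spectra[slit + 1L, ] <- spec
    }
  }
  fr <- render_frame(spectra, axis, "shift", traces, dispersion, detector,
                     noise = noise, seed = seed, type = "science",
                     exptime = exptime)
  fr$header$PEAKFLUX <- peak_flux
  fr
}

#' Default fluorescence baseline shape
#'
#' Ascending coefficients of a positive 4th-order polynomial on `[-1, 1]`,
#' the shape used for simulated fluorescence backgrounds.
#'
#' @return numeric coefficient vector.
#' @export
default_baseline_coef <- function() c(1.2, 0.4, 0.5, 0.3, 0.5)

#' Simulate a uniform reference frame
#'
#' Stand-in for the CaF2 reference plate: every live spaxel carries the same
#' flat continuum, scaled by the illumination profile. Dividing a science
#' cube by this reference removes the illumination pattern.
#'
#' @param layout a [bundle_layout()].
#' @param traces,dispersion,detector instrument models.
#' @param axis Raman-shift axis.
#' @param level continuum level in counts per column.
#' @param illumination illumination matrix shared with the science frames.
#' @param throughput per-fiber (slit-ordered) sensitivity factors.
#' @param noise,seed noise switch and seed.
#' @return a `frame` of type `science`.
#' @export
make_reference <- function(layout, traces, dispersion,
                           detector = detector_config(),
                           axis = default_shift_axis(), level = 3000,
                           illumination = illumination_profile(layout),
                           throughput = NULL, noise = TRUE, seed = NULL) {
  nf <- n_fibers(layout)
  step <- stats::median(diff(axis))
  axis <- seq(max(min(axis) - 220, step), max(axis) + 220, by = step)
  dead <- dead_fiber_mask(layout)
  spectra <- matrix(0, nf, length(axis))
  for (r in seq_len(layout$n_rows)) for (cc in seq_len(layout$n_cols)) {
    if (dead[r, cc]) next
    f <- if (is.null(throughput)) 1 else throughput[layout$slit_order[r, cc] + 1L]
    spectra[layout$slit_order[r, cc] + 1L, ] <- level * illumination[r, cc] * f
  }
  render_frame(spectra, axis, "shift", traces, dispersion, detector,
               noise = noise, seed = seed, type = "science", exptime = 30)
}

#' Inject cosmic-ray hits into a frame
#'
#' Adds `n_hits` high-amplitude single-pixel spikes at seeded random,
#' distinct positions (cosmics are narrower than the instrument profile
#' along the dispersion axis, which is what the cleaner exploits). Hit
#' coordinates are attached as attribute `"cosmic_hits"` (1-based
#' `row, col`) for test assertions.
#'
#' @param frame a `frame`.
#' @param n_hits number of hits (>= 0).
#' @param amplitude spike amplitude in counts.
#' @param seed RNG seed.
#' @return the frame with spikes added.
#' @export
inject_cosmics <- function(frame, n_hits, amplitude = 5000, seed = NULL) {
  stopifnot(n_hits >= 0)
  if (n_hits == 0) {
    attr(frame, "cosmic_hits") <- matrix(integer(0), ncol = 2,
                                         dimnames = list(NULL, c("row", "col")))
    return(frame)
  }
  d <- dim(frame$data)
  pix <- with_seed(seed, sample.int(prod(d), n_hits))
  pos <- cbind(row = (pix - 1L) %% d[1] + 1L, col = (pix - 1L) %/% d[1] + 1L)
  out <- frame
  out$data[pos] <- out$data[pos] + amplitude
  attr(out, "cosmic_hits") <- pos
  out
}
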