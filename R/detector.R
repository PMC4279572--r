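#' Detector configuration
#'
#' Desk-scale stand-in for the science CCD. The dispersion axis runs along
#' columns (wavelength increases with column index); fiber traces are
#' stacked along rows. Defaults give a 1200 x 600 px frame: 400 traces at
#' 2.9 px pitch need ~1160 px of cross-dispersion extent.
#'
#' @param n_rows_px,n_cols_px frame dimensions (cross-dispersion rows,
#'   dispersion columns).
#' @param bias_level electronic offset in counts.
#' @param read_noise Gaussian read noise rms in counts.
#' @param gain electrons per count.
#' @return object of class `detector_config`.
#' @export
detector_config <- function(n_rows_px = 1200L, n_cols_px = 600L,
                            bias_level = 100, read_noise = 3, gain = 1) {
  stopifnot(n_rows_px >= 1, n_cols_px >= 1, read_noise >= 0, gain > 0)
  structure(list(n_rows_px = as.integer(n_rows_px),
                 n_cols_px = as.integer(n_cols_px),
                 bias_level = bias_level, read_noise = read_noise,
                 gain = gain),
            class = "detector_config")
}

#' Fiber trace model
#'
#' Per fiber, the cross-dispersion trace center as a low-order polynomial of
#' the 0-based dispersion-axis column, plus a common Gaussian cross-profile
#' sigma. Traces are ordered by slit position (ascending center).
#'
#' @param coef `n_fibers x (degree+1)` matrix of ascending polynomial
#'   coefficients (`center = c0 + c1*x + c2*x^2 + ...`).
#' @param sigma_px Gaussian cross-dispersion profile sigma in px.
#' @param dead optional logical vector flagging trace positions known dead.
#' @return object of class `trace_model`.
#' @export
trace_model <- function(coef, sigma_px, dead = NULL) {
  coef <- as.matrix(coef)
  stopifnot(sigma_px > 0)
  if (is.null(dead)) dead <- rep(FALSE, nrow(coef))
  if (is.unsorted(coef[, 1])) fc_abort("traces must be ordered by slit position",
                                       "fibercube_trace_error")
  structure(list(coef = coef, sigma_px = sigma_px, dead = dead),
            class = "trace_model")
}

#' @export
print.trace_model <- function(x, ...) {
  cat(sprintf("<trace_model> %d traces, sigma %.3g px, degree %d\n",
              nrow(x$coef), x$sigma_px, ncol(x$coef) - 1L))
  invisible(x)
}

#' Evaluate trace centers
#'
#' @param traces a [trace_model()].
#' @param cols 0-based column indices (default: all detector columns are the
#'   caller's responsibility).
#' @return `n_fibers x length(cols)` matrix of row centers (0-based).
#' @export
trace_centers <- function(traces, cols) {
  t(vapply(seq_len(nrow(traces$coef)),
           function(i) polyval(traces$coef[i, ], cols),
           numeric(length(cols))))
}

#' Default trace model for a bundle
#'
#' Evenly pitched traces with a gentle common bow along the dispersion axis
#' (real fiber traces are slightly curved). Default sigma 0.55 px keeps
#' adjacent traces (2.9 px pitch) cleanly separable for tophat extraction.
#'
#' @param n_fibers number of traces.
#' @param detector a [detector_config()].
#' @param pitch_px trace pitch in px.
#' @param sigma_px cross-dispersion Gaussian sigma in px.
#' @param bow_px amplitude of the common quadratic bow in px.
#' @return a [trace_model()].
#' @export
default_trace_model <- function(n_fibers = 400L, detector = detector_config(),
                                pitch_px = 2.9, sigma_px = 0.55,
                                bow_px = 0.8) {
  span <- (n_fibers - 1L) * pitch_px
  need <- span + 8 * sigma_px + 2 * bow_px + 4
  if (need > detector$n_rows_px)
    fc_abort(sprintf("detector too small: %d traces need %.0f rows",
                     n_fibers, need), "fibercube_config_error")
  margin <- (detector$n_rows_px - span) / 2
  # bow in normalized column u = 2x/(N-1) - 1: center = y0 + bow * u^2
  N <- detector$n_cols_px
  a <- 2 / (N - 1)
  coef <- cbind(margin + (seq_len(n_fibers) - 1L) * pitch_px + bow_px,
                rep(-2 * a * bow_px, n_fibers),
                rep(a^2 * bow_px, n_fibers))
  trace_model(coef, sigma_px)
}

#' Wavelength dispersion model
#'
#' Per fiber, the wavelength (nm) at each 0-based dispersion column as an
#' ascending-coefficient polynomial, plus the excitation wavelength used to
#' convert to Raman shift (Stokes side only).
#'
#' @param coef `n_fibers x (degree+1)` matrix of ascending coefficients of
#'   `wavelength(pixel)`.
#' @param excitation_nm excitation laser wavelength (default 785 nm).
#' @param residual_rms optional per-fiber calibration residual rms (nm).
#' @return object of class `dispersion_model`.
#' @export
dispersion_model <- function(coef, excitation_nm = 785, residual_rms = NULL) {
  coef <- as.matrix(coef)
  structure(list(coef = coef, excitation_nm = excitation_nm,
                 residual_rms = residual_rms),
            class = "dispersion_model")
}

#' @export
print.dispersion_model <- function(x, ...) {
  cat(sprintf("<dispersion_model> %d fibers, degree %d, excitation %g nm\n",
              nrow(x$coef), ncol(x$coef) - 1L, x$excitation_nm))
  invisible(x)
}

#' Evaluate per-fiber wavelengths
#'
#' @param dispersion a [dispersion_model()].
#' @param cols 0-based column indices.
#' @return `n_fibers x length(cols)` matrix of wavelengths (nm).
#' @export
fiber_wavelengths <- function(dispersion, cols) {
  t(vapply(seq_len(nrow(dispersion$coef)),
           function(i) polyval(dispersion$coef[i, ], cols),
           numeric(length(cols))))
}

#' Default dispersion model
#'
#' Near-linear dispersion spanning `lambda_range` over the detector columns,
#' with a small quadratic term and a deterministic per-fiber zero-point
#' offset (fibers never share an identical wavelength solution). Strictly
#' increasing along the dispersion axis; covers the default Raman-shift axis
#' (200-2000 cm^-1 Stokes of 785 nm, i.e. 797.5-931.2 nm) for every fiber.
#'
#' @param n_fibers number of fibers.
#' @param detector a [detector_config()].
#' @param lambda_range wavelength span (nm) across the columns.
#' @param excitation_nm excitation wavelength (nm).
#' @param offset_amp_nm amplitude of the per-fiber zero-point offsets.
#' @return a [dispersion_model()].
#' @export
default_dispersion_model <- function(n_fibers = 400L,
                                     detector = detector_config(),
                                     lambda_range = c(788, 938),
                                     excitation_nm = 785,
                                     offset_amp_nm = 0.3) {
  N <- detector$n_cols_px
  quad <- 2e-7                        # nm/px^2, mild curvature
  slope <- (lambda_range[2] - lambda_range[1] - quad * (N - 1)^2) / (N - 1)
  i <- seq_len(n_fibers)
  off <- offset_amp_nm * sin(2 * pi * i / max(n_fibers, 2))
  coef <- cbind(lambda_range[1] + off, rep(slope, n_fibers),
                rep(quad, n_fibers))
  dispersion_model(coef, excitation_nm)
}
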