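#' Iterative modified-polyfit fluorescence baseline removal
#'
#' Estimates the broad fluorescence background beneath Raman peaks by the
#' modified polynomial curve fitting of Lieber and Mahadevan-Jansen: fit a
#' polynomial of the given order to the working spectrum, replace the
#' working spectrum by the pointwise minimum of itself and the fit, and
#' iterate (default 15 times, order 4). The final fit is the baseline; the
#' corrected spectrum is `input - baseline`. The working spectrum is
#' pointwise non-increasing across iterations, so the baseline relaxes
#' under the peaks while following the smooth background.
#'
#' The fit is ordinary least squares on the axis rescaled to `[-1, 1]` for
#' numerical conditioning.
#'
#' @param spectrum intensity vector.
#' @param axis spectral axis (any monotone grid); defaults to sample index.
#' @param order polynomial order (default 4).
#' @param n_iter number of iterations (default 15).
#' @return object of class `lmj_baseline` with elements `baseline`,
#'   `corrected`, `order`, `n_iter` and `delta` (max baseline change in the
#'   final iteration).
#' @examples
#' ax <- default_shift_axis()
#' y <- 50 * exp(-(ax - 1035)^2 / 50) + 0.001 * (ax - 1000)^2
#' bf <- lmj_baseline(y, ax)
#' max(bf$corrected)  # ~50
#' @export
lmj_baseline <- function(spectrum, axis = seq_along(spectrum), order = 4,
                         n_iter = 15) {
  stopifnot(order >= 0, n_iter >= 1)
  if (!all(is.finite(spectrum)))
    fc_abort("spectrum contains non-finite values",
             "fibercube_validation_error")
  if (length(spectrum) <= order + 1)
    fc_abort(sprintf("spectrum too short for order-%d fit", order),
             "fibercube_validation_error")
  u <- rescale_unit(axis)
  X <- outer(u, 0:order, `^`)
  work <- spectrum
  fit_prev <- NULL
  fit <- NULL
  for (k in seq_len(n_iter)) {
    fit_prev <- fit
    fit <- drop(X %*% stats::lm.fit(X, work)$coefficients)
    work <- pmin(work, fit)
  }
  delta <- if (is.null(fit_prev)) Inf else max(abs(fit - fit_prev))
  structure(list(baseline = fit, corrected = spectrum - fit,
                 order = order, n_iter = n_iter, delta = delta),
            class = "lmj_baseline")
}

#' @export
print.lmj_baseline <- function(x, ...) {
  cat(sprintf("<lmj_baseline> order %d, %d iterations, final delta %.3g\n",
              x$order, x$n_iter, x$delta))
  invisible(x)
}

#' Fit a Gaussian peak in a spectral window
#'
#' Nonlinear least squares of
#' `offset + amplitude * exp(-(x - center)^2 / (2 sigma^2))` over the
#' samples within `window` of `center_guess`. Non-convergence is not an
#' error: the result is flagged (`converged = FALSE`) with amplitude 0.
#'
#' @param spectrum intensity vector.
#' @param axis spectral axis (cm^-1).
#' @param center_guess initial peak position (must lie inside the window).
#' @param window full window width in axis units (default 40 cm^-1).
#' @return object of class `gaussian_fit`: `center`, `amplitude` (fitted
#'   height above offset), `sigma`, `offset`, `window`, `converged`, `rms`.
#' @export
fit_gaussian <- function(spectrum, axis, center_guess, window = 40) {
  lo <- center_guess - window / 2
  hi <- center_guess + window / 2
  sel <- which(axis >= lo & axis <= hi & is.finite(spectrum))
  if (length(sel) < 5)
    fc_abort("fit window must contain at least 5 samples",
             "fibercube_validation_error")
  x <- axis[sel]; y <- spectrum[sel]
  off0 <- stats::quantile(y, 0.1, names = FALSE)
  amp0 <- max(y) - off0
  c0 <- x[which.max(y)]
  step <- stats::median(diff(x))
  # sigma is confined to widths a genuine peak inside the window can have:
  # an unconstrained Gaussian + offset degenerates into a broad pedestal
  s_max <- window / 4
  s0 <- min(max(window / 8, step), 0.9 * s_max)
  failed <- list(center = NA_real_, amplitude = 0, sigma = NA_real_,
                 offset = NA_real_, window = c(lo, hi), converged = FALSE,
                 rms = NA_real_)
  fit <- tryCatch(
    stats::nls(y ~ off + A * exp(-(x - ctr)^2 / (2 * s^2)),
               start = list(off = off0, A = amp0, ctr = c0, s = s0),
               algorithm = "port",
               lower = c(off = -Inf, A = -Inf, ctr = lo, s = step / 2),
               upper = c(off = Inf, A = Inf, ctr = hi, s = s_max),
               control = stats::nls.control(maxiter = 100, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) return(structure(failed, class = "gaussian_fit"))
  p <- stats::coef(fit)
  structure(list(center = unname(p["ctr"]), amplitude = unname(p["A"]),
                 sigma = unname(p["s"]), offset = unname(p["off"]),
                 window = c(lo, hi), converged = TRUE,
                 rms = sqrt(mean(stats::resid(fit)^2))),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("<gaussian_fit> center %.2f, height %.3g, sigma %.2f, offset %.3g\n",
                x$center, x$amplitude, x$sigma, x$offset))
  else cat("<gaussian_fit> did not converge (amplitude 0)\n")
  invisible(x)
}

check_cube_compatible <- function(a, b) {
  if (!isTRUE(all.equal(a$axis, b$axis)) ||
      !identical(dim(a$data), dim(b$data)))
    fc_abort("cubes differ in shape or spectral axis",
             "fibercube_validation_error")
}

#' Subtract a reference (blank) cube
#'
#' Per-spaxel, per-channel subtraction of a blank measurement (no sample),
#' removing the background arising from the optics. Masks are OR-combined.
#'
#' @param cube,blank [raman_cube()]s with matching shapes and axes.
#' @return a [raman_cube()].
#' @export
subtract_reference <- function(cube, blank) {
  check_cube_compatible(cube, blank)
  raman_cube(cube$data - blank$data, cube$axis, cube$mask | blank$mask,
             cube$meta)
}

#' Normalize a cube by a reference measurement
#'
#' Divides each spaxel's spectrum by a per-spaxel scalar summary of the
#' reference cube (default: its mean intensity over the configured window),
#' removing the illumination profile of the excitation laser. Spaxels with
#' a non-positive reference summary are masked with a warning.
#'
#' @param cube a [raman_cube()].
#' @param reference a [raman_cube()] of the reference (e.g. CaF2 plate).
#' @param window `NULL` for the full axis, or `c(lo, hi)` in cm^-1.
#' @return a [raman_cube()].
#' @export
normalize_by_reference <- function(cube, reference, window = NULL) {
  check_cube_compatible(cube, reference)
  sel <- if (is.null(window)) seq_along(cube$axis)
         else which(cube$axis >= window[1] & cube$axis <= window[2])
  if (length(sel) == 0) fc_abort("empty normalization window",
                                 "fibercube_validation_error")
  out <- cube$data
  mask <- cube$mask | reference$mask
  n_bad <- 0L
  for (r in seq_len(dim(out)[1])) for (cc in seq_len(dim(out)[2])) {
    if (mask[r, cc]) next
    s <- mean(reference$data[r, cc, sel], na.rm = TRUE)
    if (!is.finite(s) || s <= 0) {
      mask[r, cc] <- TRUE; n_bad <- n_bad + 1L
    } else out[r, cc, ] <- out[r, cc, ] / s
  }
  if (n_bad > 0)
    warning(sprintf("%d spaxel(s) had non-positive reference summary; masked",
                    n_bad))
  raman_cube(out, cube$axis, mask, cube$meta)
}
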