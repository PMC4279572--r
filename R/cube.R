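#' Convert wavelength to Stokes Raman shift
#'
#' `shift = 1e7 * (1/excitation - 1/wavelength)` with both wavelengths in
#' nm, giving cm^-1. Strictly increasing in wavelength; the excitation line
#' maps to 0. Anti-Stokes wavelengths (below the excitation) are a domain
#' error.
#'
#' @param wavelength wavelength(s) in nm.
#' @param excitation excitation laser wavelength in nm (default 785).
#' @return Raman shift(s) in cm^-1.
#' @examples
#' to_raman_shift(854.42)   # ~1035 cm^-1
#' @export
to_raman_shift <- function(wavelength, excitation = 785) {
  if (any(wavelength < excitation))
    fc_abort("wavelength below excitation: anti-Stokes side not supported",
             "fibercube_domain_error")
  1e7 * (1 / excitation - 1 / wavelength)
}

#' @rdname to_raman_shift
#' @param shift Raman shift(s) in cm^-1.
#' @export
from_raman_shift <- function(shift, excitation = 785) {
  if (any(shift < 0)) fc_abort("negative Raman shift",
                               "fibercube_domain_error")
  1e7 / (1e7 / excitation - shift)
}

#' Default common Raman-shift axis
#'
#' 200-2000 cm^-1 in 2 cm^-1 steps: covers all characteristic peaks in the
#' shipped spectral library (292-1703 cm^-1).
#'
#' @param from,to,by axis limits and step, cm^-1.
#' @return numeric vector.
#' @export
default_shift_axis <- function(from = 200, to = 2000, by = 2) {
  seq(from, to, by = by)
}

#' Resample row-stacked spectra onto a common Raman-shift axis
#'
#' Each fiber's spectrum, calibrated by its own dispersion polynomial, is
#' linearly interpolated onto the common target grid. Samples outside a
#' fiber's calibrated range become `NA` (masked).
#'
#' @param rss an `rss`.
#' @param axis strictly increasing target Raman-shift grid (cm^-1).
#' @param dispersion a [dispersion_model()]; defaults to `rss$dispersion`.
#' @return `n_fibers x length(axis)` matrix.
#' @export
resample_common_axis <- function(rss, axis = default_shift_axis(),
                                 dispersion = rss$dispersion) {
  if (is.null(dispersion))
    fc_abort("no dispersion model: run fit_wavelength first",
             "fibercube_validation_error")
  stopifnot(all(diff(axis) > 0))
  nf <- nrow(rss$intensity)
  cols <- seq_len(ncol(rss$intensity)) - 1L
  lam <- fiber_wavelengths(dispersion, cols)
  out <- matrix(NA_real_, nf, length(axis))
  for (i in seq_len(nf)) {
    li <- lam[i, ]
    shift <- 1e7 * (1 / dispersion$excitation_nm - 1 / li)
    if (max(shift) < min(axis) || min(shift) > max(axis))
      fc_abort(sprintf("fiber %d: no overlap with target axis", i - 1L),
               "fibercube_range_error")
    out[i, ] <- stats::approx(shift, rss$intensity[i, ], xout = axis,
                              rule = 1)$y
  }
  out
}

#' Spatial-spectral Raman data cube
#'
#' `(n_rows, n_cols, n_shift)` intensity array on a uniform Raman-shift
#' axis, with a dead-fiber mask and provenance metadata.
#'
#' @param data 3D intensity array.
#' @param axis Raman-shift axis (strictly increasing, uniform).
#' @param mask logical `n_rows x n_cols` dead-spaxel mask.
#' @param meta named list of provenance metadata.
#' @return object of class `raman_cube`.
#' @export
raman_cube <- function(data, axis, mask = NULL, meta = list()) {
  stopifnot(length(dim(data)) == 3, dim(data)[3] == length(axis))
  d <- diff(axis)
  if (any(d <= 0) || (max(d) - min(d)) / mean(d) > 1e-9)
    fc_abort("axis must be strictly increasing and uniform",
             "fibercube_validation_error")
  if (is.null(mask)) mask <- matrix(FALSE, dim(data)[1], dim(data)[2])
  stopifnot(identical(dim(mask), dim(data)[1:2]))
  structure(list(data = data, axis = axis, mask = mask, meta = meta),
            class = "raman_cube")
}

#' @export
print.raman_cube <- function(x, ...) {
  cat(sprintf("<raman_cube> %d x %d spaxels x %d channels (%.0f-%.0f cm^-1), %d masked\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$axis), max(x$axis), sum(x$mask)))
  invisible(x)
}

#' Spectrum of one spaxel
#'
#' @param cube a [raman_cube()].
#' @param row,col 0-based spaxel coordinates.
#' @return intensity vector on `cube$axis`.
#' @export
cube_spectrum <- function(cube, row, col) {
  cube$data[row + 1L, col + 1L, ]
}

#' Assemble resampled spectra into a data cube
#'
#' Pure re-indexing: `cube[row, col, ] = spectra[slit_order(row, col), ]`.
#' The dead-fiber mask combines the layout's dead fibers with any all-`NA`
#' spectra and the optional per-fiber flags.
#'
#' @param spectra `n_fibers x n_shift` matrix (one row per slit position),
#'   e.g. from [resample_common_axis()].
#' @param layout a [bundle_layout()].
#' @param axis the Raman-shift axis of `spectra`.
#' @param dead optional per-fiber (slit-ordered) logical dead flags.
#' @param meta provenance metadata.
#' @return a [raman_cube()].
#' @export
assemble_cube <- function(spectra, layout, axis = default_shift_axis(),
                          dead = NULL, meta = list()) {
  nf <- n_fibers(layout)
  if (nrow(spectra) != nf)
    fc_abort(sprintf("expected %d spectra (one per slit position), got %d",
                     nf, nrow(spectra)), "fibercube_shape_error")
  stopifnot(ncol(spectra) == length(axis))
  cube <- array(NA_real_, dim = c(layout$n_rows, layout$n_cols, length(axis)))
  mask <- dead_fiber_mask(layout)
  for (r in seq_len(layout$n_rows)) {
    for (cc in seq_len(layout$n_cols)) {
      s <- layout$slit_order[r, cc] + 1L
      cube[r, cc, ] <- spectra[s, ]
      if (!is.null(dead) && dead[s]) mask[r, cc] <- TRUE
      if (all(is.na(spectra[s, ]))) mask[r, cc] <- TRUE
    }
  }
  raman_cube(cube, axis, mask, meta)
}
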