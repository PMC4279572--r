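#' Spectral library of characteristic Raman peaks
#'
#' Loads the library of characteristic Raman peak positions used to identify
#' substances. Each entry is a Gaussian line with a center (Raman shift,
#' cm^-1), a relative amplitude and a FWHM (cm^-1). The shipped fixture
#' carries the fingerprint peaks of Teflon (292, 385, 734, 1218, 1302,
#' 1382 cm^-1), pork tissue (1064, 1300, 1441, 1656 cm^-1), polystyrene
#' (1035 cm^-1), PMMA (600 cm^-1), paracetamol (800, 860 cm^-1), aspirin
#' (752, 1047 cm^-1) and caffeine (1703 cm^-1). Only the peak positions are
#' measured quantities; relative amplitudes (1) and FWHMs (12 cm^-1) are
#' simulator defaults.
#'
#' @param path CSV file with columns `substance, center, amplitude, fwhm`;
#'   defaults to the shipped fixture.
#' @return data.frame of class `spectral_library`.
#' @export
spectral_library <- function(path = system.file("extdata", "spectral_library.csv",
                                                package = "fibercube")) {
  lib <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("substance", "center", "amplitude", "fwhm") %in% names(lib)))
  if (any(lib$center <= 0) || any(lib$amplitude < 0) || any(lib$fwhm <= 0))
    fc_abort("invalid spectral library: need center > 0, amplitude >= 0, fwhm > 0",
             "fibercube_library_error")
  class(lib) <- c("spectral_library", "data.frame")
  lib
}

#' Peaks of one substance
#'
#' @param library a [spectral_library()].
#' @param substance substance name.
#' @return data.frame of that substance's peaks, ordered as listed.
#' @export
library_peaks <- function(library, substance) {
  sel <- library$substance == substance
  if (!any(sel))
    fc_abort(sprintf("substance '%s' not in spectral library", substance),
             "fibercube_lookup_error")
  library[sel, , drop = FALSE]
}

#' Synthesize a Raman spectrum from library peaks
#'
#' Renders a mixture spectrum on a Raman-shift axis: for each substance with
#' a positive weight, its library peaks are summed as Gaussian profiles
#' (`amplitude * exp(-(x - center)^2 / (2 sigma^2))`, `sigma = fwhm/2.3548`)
#' and scaled by the mixture weight; an optional polynomial baseline
#' (coefficients on the axis rescaled to `[-1, 1]`, ascending order) is
#' added, emulating fluorescence background.
#'
#' @param library a [spectral_library()].
#' @param mixture named numeric vector of non-negative substance weights.
#' @param axis strictly increasing Raman-shift grid (cm^-1).
#' @param baseline `NULL` or ascending polynomial coefficients evaluated on
#'   the axis rescaled to `[-1, 1]`.
#' @return intensity vector on `axis`.
#' @examples
#' ax <- default_shift_axis()
#' y <- make_spectrum(spectral_library(), c(teflon = 1), ax)
#' @export
make_spectrum <- function(library, mixture, axis, baseline = NULL) {
  stopifnot(length(axis) > 1, all(diff(axis) > 0))
  if (any(mixture < 0)) fc_abort("mixture weights must be >= 0",
                                 "fibercube_domain_error")
  y <- rep(0, length(axis))
  for (sub in names(mixture)) {
    w <- mixture[[sub]]
    if (w == 0) next
    pk <- library_peaks(library, sub)
    for (i in seq_len(nrow(pk))) {
      s <- sigma_from_fwhm(pk$fwhm[i])
      y <- y + w * pk$amplitude[i] * exp(-(axis - pk$center[i])^2 / (2 * s^2))
    }
  }
  if (!is.null(baseline)) y <- y + polyval(baseline, rescale_unit(axis))
  y
}
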