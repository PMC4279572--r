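#' Sample phantoms on the spaxel grid
#'
#' A phantom is the simulated sample as seen by the probe head: for every
#' spaxel of the grid a vector of substance weights, plus an illumination
#' profile (the excitation laser is brightest at the field center, about an
#' order of magnitude above the corners).
#'
#' @name phantom
NULL

new_phantom <- function(weights, layout, illumination = NULL) {
  if (is.null(illumination))
    illumination <- matrix(1, layout$n_rows, layout$n_cols)
  structure(list(weights = weights, substances = dimnames(weights)[[3]],
                 illumination = illumination, layout = layout),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cov <- apply(x$weights > 0, 3, sum)
  cat(sprintf("<phantom> %d x %d spaxels; substances: %s\n",
              dim(x$weights)[1], dim(x$weights)[2],
              paste(sprintf("%s (%d)", names(cov), cov), collapse = ", ")))
  invisible(x)
}

#' Build a bead phantom
#'
#' Places circular beads (microspheres) on the probe-head field. A spaxel
#' carries a bead's substance weight if its center lies inside the bead's
#' circle. Field coordinates are mm, with spaxel `(row, col)` centered at
#' `(x, y) = (col * pitch, row * pitch)`. Beads reaching outside the field
#' are clipped with a warning.
#'
#' @param layout a [bundle_layout()].
#' @param beads data.frame with columns `substance, x_mm, y_mm, diameter_mm`.
#' @param illumination `NULL` (uniform), or an illumination matrix such as
#'   [illumination_profile()].
#' @return a `phantom`.
#' @export
make_bead_phantom <- function(layout, beads, illumination = NULL) {
  subs <- unique(beads$substance)
  w <- array(0, dim = c(layout$n_rows, layout$n_cols, length(subs)),
             dimnames = list(NULL, NULL, subs))
  edge_x <- (layout$n_cols - 1L) * layout$pitch_mm
  edge_y <- (layout$n_rows - 1L) * layout$pitch_mm
  xs <- (seq_len(layout$n_cols) - 1L) * layout$pitch_mm
  ys <- (seq_len(layout$n_rows) - 1L) * layout$pitch_mm
  for (i in seq_len(nrow(beads))) {
    r <- beads$diameter_mm[i] / 2
    if (beads$x_mm[i] - r < 0 || beads$x_mm[i] + r > edge_x ||
        beads$y_mm[i] - r < 0 || beads$y_mm[i] + r > edge_y)
      warning(sprintf("bead %d extends outside the field; clipped", i))
    d2 <- outer((ys - beads$y_mm[i])^2, (xs - beads$x_mm[i])^2, `+`)
    hit <- d2 <= r^2
    k <- match(beads$substance[i], subs)
    w[, , k][hit] <- w[, , k][hit] + 1
  }
  new_phantom(w, layout, illumination)
}

#' Default bead-phantom fixture: one large PMMA bead plus three PS beads
#'
#' Desk-scale stand-in for the microbead sample: one large PMMA sphere and
#' three smaller polystyrene spheres placed within the field, scaled from
#' bead size to spaxel units so each bead covers several spaxels.
#'
#' @param layout a [bundle_layout()].
#' @param illumination passed to [make_bead_phantom()]; defaults to the
#'   center-weighted [illumination_profile()].
#' @return a `phantom`.
#' @export
bead_phantom_fig <- function(layout = bundle_layout(),
                             illumination = illumination_profile(layout)) {
  beads <- data.frame(
    substance   = c("PMMA", "PS", "PS", "PS"),
    x_mm        = c(5.5, 2.0, 2.5, 7.0),
    y_mm        = c(3.5, 2.0, 6.5, 7.0),
    diameter_mm = c(2.6, 1.3, 1.3, 1.3))
  make_bead_phantom(layout, beads, illumination)
}

#' Half-field tablet phantom
#'
#' Two polished tablet halves pushed together so the boundary passes the
#' field center: the top half-field carries one substance, the bottom half
#' the other (200 spaxels each on the default grid).
#'
#' @param layout a [bundle_layout()] with an even number of rows.
#' @param top,bottom substance names.
#' @param illumination optional illumination matrix.
#' @return a `phantom`.
#' @export
half_field_phantom <- function(layout = bundle_layout(),
                               top = "paracetamol", bottom = "aspirin",
                               illumination = illumination_profile(layout)) {
  subs <- c(top, bottom)
  w <- array(0, dim = c(layout$n_rows, layout$n_cols, 2),
             dimnames = list(NULL, NULL, subs))
  half <- layout$n_rows %/% 2
  w[seq_len(half), , 1] <- 1
  w[(half + 1):layout$n_rows, , 2] <- 1
  new_phantom(w, layout, illumination)
}

#' Uniform single-substance phantom
#'
#' Every spaxel carries weight 1 of one substance; used e.g. for a Teflon
#' slab filling the field.
#'
#' @param layout a [bundle_layout()].
#' @param substance substance name.
#' @param illumination optional illumination matrix.
#' @return a `phantom`.
#' @export
uniform_phantom <- function(layout = bundle_layout(), substance = "teflon",
                            illumination = illumination_profile(layout)) {
  w <- array(1, dim = c(layout$n_rows, layout$n_cols, 1),
             dimnames = list(NULL, NULL, substance))
  new_phantom(w, layout, illumination)
}

#' Center-weighted illumination profile
#'
#' 2D Gaussian illumination over the spaxel grid, normalized to 1 at the
#' field center, with the corner intensity a configurable factor below the
#' center (default 10x, i.e. about one order of magnitude).
#'
#' @param layout a [bundle_layout()].
#' @param center_to_corner ratio of center to corner intensity.
#' @return `n_rows x n_cols` matrix of positive factors.
#' @export
illumination_profile <- function(layout = bundle_layout(),
                                 center_to_corner = 10) {
  stopifnot(center_to_corner >= 1)
  edge_x <- (layout$n_cols - 1L) * layout$pitch_mm
  edge_y <- (layout$n_rows - 1L) * layout$pitch_mm
  xs <- (seq_len(layout$n_cols) - 1L) * layout$pitch_mm - edge_x / 2
  ys <- (seq_len(layout$n_rows) - 1L) * layout$pitch_mm - edge_y / 2
  d2 <- outer(ys^2, xs^2, `+`)
  corner2 <- (edge_x / 2)^2 + (edge_y / 2)^2
  if (center_to_corner == 1) return(matrix(1, layout$n_rows, layout$n_cols))
  s2 <- corner2 / (2 * log(center_to_corner))
  exp(-d2 / (2 * s2))
}
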