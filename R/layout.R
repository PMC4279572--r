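#' Fiber-bundle probe-head layout
#'
#' Describes the imaging probe head: a rectangular grid of step-index fibers
#' (default 20 x 20 at 0.5 mm pitch, 110 um core / 132 um cladding) whose far
#' ends are rearranged into a one-dimensional pseudo-slit feeding the
#' spectrograph. The layout records which grid positions hold damaged
#' ("dead") fibers and the bijection between grid coordinates and pseudo-slit
#' positions.
#'
#' Grid coordinates are 0-based `(row, col)` with row 0 at the top of the
#' rendered image. The default slit order is a row-major raster
#' (`slit = row * n_cols + col`); real bundles differ, so an arbitrary
#' bijection can be supplied.
#'
#' @param n_rows,n_cols grid dimensions (fibers).
#' @param pitch_mm center-to-center fiber pitch in mm.
#' @param core_um,cladding_um fiber core and cladding diameters in um.
#' @param dead_fibers `NULL`, or a 2-column matrix / list of `c(row, col)`
#'   0-based grid coordinates of damaged fibers.
#' @param slit_order `NULL` for row-major, or an `n_rows x n_cols` integer
#'   matrix giving the 0-based slit index of each grid position (must be a
#'   bijection onto `0:(n_rows*n_cols - 1)`).
#' @return an object of class `bundle_layout`.
#' @examples
#' lay <- bundle_layout()
#' active_edge_length(lay)   # 9.5 mm
#' fill_factor(lay)          # ~4.2 %
#' @export
bundle_layout <- function(n_rows = 20L, n_cols = 20L, pitch_mm = 0.5,
                          core_um = 110, cladding_um = 132,
                          dead_fibers = NULL, slit_order = NULL) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 1L, n_cols >= 1L, pitch_mm > 0, core_um > 0)
  if (core_um >= cladding_um)
    fc_abort("core diameter must be smaller than cladding diameter",
             "fibercube_layout_error")
  if (pitch_mm * 1000 <= cladding_um)
    fc_abort("pitch must exceed cladding diameter (fibers cannot overlap)",
             "fibercube_layout_error")

  n <- n_rows * n_cols
  if (is.null(slit_order)) {
    slit_order <- matrix(seq_len(n) - 1L, nrow = n_rows, ncol = n_cols,
                         byrow = TRUE)
  } else {
    slit_order <- matrix(as.integer(slit_order), n_rows, n_cols)
    if (!identical(sort(as.integer(slit_order)), seq_len(n) - 1L))
      fc_abort("slit_order must be a bijection onto 0:(n_rows*n_cols - 1)",
               "fibercube_layout_error")
  }

  dead <- normalize_dead(dead_fibers)
  if (nrow(dead) > 0 &&
      (any(dead[, 1] < 0 | dead[, 1] >= n_rows) ||
       any(dead[, 2] < 0 | dead[, 2] >= n_cols)))
    fc_abort("dead_fibers outside grid", "fibercube_layout_error")

  structure(list(n_rows = n_rows, n_cols = n_cols, pitch_mm = pitch_mm,
                 core_um = core_um, cladding_um = cladding_um,
                 dead_fibers = dead, slit_order = slit_order),
            class = "bundle_layout")
}

normalize_dead <- function(dead_fibers) {
  if (is.null(dead_fibers) || length(dead_fibers) == 0L)
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("row", "col"))))
  if (is.list(dead_fibers)) dead_fibers <- do.call(rbind, dead_fibers)
  dead_fibers <- matrix(as.integer(dead_fibers), ncol = 2)
  dimnames(dead_fibers) <- list(NULL, c("row", "col"))
  unique(dead_fibers)
}

#' @export
print.bundle_layout <- function(x, ...) {
  cat(sprintf("<bundle_layout> %d x %d fibers, pitch %.3g mm, core %g um (%d dead)\n",
              x$n_rows, x$n_cols, x$pitch_mm, x$core_um, nrow(x$dead_fibers)))
  invisible(x)
}

n_fibers <- function(layout) layout$n_rows * layout$n_cols

n_live_fibers <- function(layout) n_fibers(layout) - nrow(layout$dead_fibers)

#' Dead-fiber mask of a layout
#'
#' @param layout a [bundle_layout()].
#' @return logical `n_rows x n_cols` matrix, `TRUE` at damaged fibers.
#' @export
dead_fiber_mask <- function(layout) {
  m <- matrix(FALSE, layout$n_rows, layout$n_cols)
  if (nrow(layout$dead_fibers) > 0)
    m[layout$dead_fibers + 1L] <- TRUE
  m
}

#' Grid-to-pseudo-slit mapping
#'
#' `grid_to_slit()` returns the 0-based pseudo-slit position of the fiber at
#' grid coordinate `(row, col)`; `slit_to_grid()` is its inverse and returns
#' a matrix of `(row, col)` coordinates. The two round-trip exactly for any
#' valid slit order.
#'
#' @param layout a [bundle_layout()].
#' @param row,col 0-based grid coordinates (vectorized).
#' @param slit 0-based slit position(s).
#' @return `grid_to_slit`: integer slit indices. `slit_to_grid`: integer
#'   matrix with columns `row`, `col`.
#' @export
grid_to_slit <- function(layout, row, col) {
  if (any(row < 0 | row >= layout$n_rows | col < 0 | col >= layout$n_cols))
    fc_abort("grid coordinate out of range", "fibercube_range_error")
  layout$slit_order[cbind(row + 1L, col + 1L)]
}

#' @rdname grid_to_slit
#' @export
slit_to_grid <- function(layout, slit) {
  n <- n_fibers(layout)
  if (any(slit < 0 | slit >= n))
    fc_abort("slit index out of range", "fibercube_range_error")
  inv <- slit_inverse(layout)
  inv[slit + 1L, , drop = FALSE]
}

# (n_fibers x 2) matrix: slit index + 1 -> (row, col)
slit_inverse <- function(layout) {
  ord <- order(as.vector(layout$slit_order))
  rc <- cbind(row = as.vector(row(layout$slit_order)) - 1L,
              col = as.vector(col(layout$slit_order)) - 1L)
  rc[ord, , drop = FALSE]
}

#' Center-to-center span of the square fiber array
#'
#' The "active edge length" of the probe head: `(n_rows - 1) * pitch`. For
#' the default 20-fiber, 0.5 mm pitch bundle this is 9.5 mm, so the probe
#' surface is about 90 mm^2.
#'
#' @param layout a [bundle_layout()] with `n_rows == n_cols`.
#' @return length in mm.
#' @export
active_edge_length <- function(layout) {
  stopifnot(layout$n_rows == layout$n_cols, layout$n_rows >= 1L)
  (layout$n_rows - 1L) * layout$pitch_mm
}

#' Total light-collecting core area of the bundle
#'
#' Sum of the front-surface areas of the live fiber cores,
#' `n_live * pi * (core/2)^2`. For 400 fibers with 110 um cores this is
#' 3.80 mm^2, i.e. about 4 mm^2.
#'
#' @param layout a [bundle_layout()].
#' @return area in mm^2.
#' @export
total_core_area <- function(layout) {
  n_live_fibers(layout) * pi * (layout$core_um / 2000)^2
}

#' Fill factor of the probe head
#'
#' Percentage of the probe surface covered by light-collecting fiber cores:
#' `100 * total_core_area / probe_surface`. With the default geometry only
#' about 4% of the light falling onto the probe head enters a fiber core.
#'
#' @param layout a [bundle_layout()].
#' @param probe_surface probe-head surface in mm^2; defaults to the square of
#'   the active edge length.
#' @return fill factor in percent.
#' @export
fill_factor <- function(layout, probe_surface = NULL) {
  if (is.null(probe_surface)) probe_surface <- active_edge_length(layout)^2
  if (!is.finite(probe_surface) || probe_surface <= 0)
    fc_abort("probe_surface must be positive", "fibercube_domain_error")
  100 * total_core_area(layout) / probe_surface
}
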