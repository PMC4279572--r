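#' Build a chemical map from a data cube
#'
#' For every live spaxel, the fluorescence baseline is removed
#' ([lmj_baseline()]) and a Gaussian is fitted at the substance's
#' characteristic Raman shift ([fit_gaussian()]); the map value is the
#' fitted peak height above the fitted offset (clamped at 0), which serves
#' as a relative measure of the substance concentration. Dead spaxels are
#' masked. `method = "raw"` skips the fit and takes the baseline-corrected
#' intensity at the nearest channel (quick look).
#'
#' @param cube a [raman_cube()].
#' @param substance substance name (label; also used to look up `shift` in
#'   the library when `shift` is missing).
#' @param shift characteristic Raman shift, cm^-1. Defaults to the first
#'   library peak of `substance`.
#' @param window fit window width, cm^-1.
#' @param library a [spectral_library()] for the shift lookup.
#' @param baseline apply [lmj_baseline()] first?
#' @param baseline_order,baseline_iter baseline parameters.
#' @param method `"fit"` (Gaussian height) or `"raw"` (channel intensity).
#' @return object of class `chemical_map`: `values` (matrix), `substance`,
#'   `shift`, `mask`.
#' @export
chemical_map <- function(cube, substance, shift = NULL, window = 40,
                         library = spectral_library(), baseline = TRUE,
                         baseline_order = 4, baseline_iter = 15,
                         method = c("fit", "raw")) {
  method <- match.arg(method)
  if (is.null(shift)) shift <- library_peaks(library, substance)$center[1]
  if (shift < min(cube$axis) || shift > max(cube$axis))
    fc_abort(sprintf("shift %g cm^-1 outside cube axis", shift),
             "fibercube_range_error")
  d <- dim(cube$data)
  values <- matrix(NA_real_, d[1], d[2])
  for (r in seq_len(d[1])) for (cc in seq_len(d[2])) {
    if (cube$mask[r, cc]) next
    y <- cube$data[r, cc, ]
    ok <- is.finite(y)
    if (sum(ok) < baseline_order + 2) next
    yy <- y[ok]; ax <- cube$axis[ok]
    if (baseline)
      yy <- lmj_baseline(yy, ax, order = baseline_order,
                         n_iter = baseline_iter)$corrected
    if (method == "raw") {
      values[r, cc] <- max(yy[which.min(abs(ax - shift))], 0)
    } else {
      fit <- fit_gaussian(yy, ax, shift, window)
      values[r, cc] <- if (fit$converged) max(fit$amplitude, 0) else 0
    }
  }
  structure(list(values = values, substance = substance, shift = shift,
                 mask = cube$mask),
            class = "chemical_map")
}

#' @export
print.chemical_map <- function(x, ...) {
  cat(sprintf("<chemical_map> %s at %g cm^-1, %d x %d spaxels (%d masked), max %.3g\n",
              x$substance, x$shift, nrow(x$values), ncol(x$values),
              sum(x$mask), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Blue-to-red pseudo-color scale
#'
#' Rainbow-style palette running from blue (lowest intensity) to red
#' (highest), the conventional display for Raman maps.
#'
#' @param n number of colors.
#' @return vector of hex colors; first is blue, last is red.
#' @export
raman_palette <- function(n = 256) {
  grDevices::colorRampPalette(
    c("#0000FF", "#00FFFF", "#00FF00", "#FFFF00", "#FF0000"))(n)
}

#' Render a chemical map as a pseudo-color image
#'
#' Live spaxels are colored on a blue (map minimum) to red (map maximum)
#' scale; masked (damaged-fiber) spaxels are rendered white. Optionally
#' writes a PNG.
#'
#' @param map a [chemical_map()].
#' @param file optional PNG path.
#' @param palette color scale (blue-to-red by default).
#' @param masked_color color for dead spaxels.
#' @param cell_px PNG cell size in pixels per spaxel.
#' @return invisibly, the matrix of hex colors.
#' @export
render_map <- function(map, file = NULL, palette = raman_palette(256),
                       masked_color = "#FFFFFF", cell_px = 16) {
  v <- map$values
  live <- !map$mask & is.finite(v)
  if (!any(live)) fc_abort("all spaxels masked: nothing to render",
                           "fibercube_render_error")
  rng <- range(v[live])
  idx <- if (rng[2] > rng[1])
    1L + as.integer(round((v - rng[1]) / (rng[2] - rng[1]) *
                          (length(palette) - 1L)))
  else matrix(1L, nrow(v), ncol(v))
  colors <- matrix(palette[pmin(pmax(idx, 1L), length(palette))],
                   nrow(v), ncol(v))
  colors[!live] <- masked_color
  if (!is.null(file)) write_color_png(colors, file, cell_px)
  invisible(colors)
}

#' Overlay several chemical maps as a contour-color image
#'
#' Per spaxel, each map is normalized by its own maximum; the spaxel takes
#' the color of the map with the largest normalized height, provided it
#' exceeds `threshold` (default 20% of that map's maximum — the map's
#' "detected locations"). Ties resolve deterministically to the first map
#' in the list. Below-threshold spaxels are neutral; masked spaxels are
#' marked brown (a damaged fiber).
#'
#' @param maps list of [chemical_map()]s sharing one shape.
#' @param colors one color per map.
#' @param threshold detection threshold as a fraction of each map's maximum.
#' @param neutral,masked_color colors for undetected and masked spaxels.
#' @param file optional PNG path.
#' @param cell_px PNG cell size.
#' @return invisibly, the matrix of hex colors.
#' @export
overlay_maps <- function(maps, colors, threshold = 0.2,
                         neutral = "#D9D9D9", masked_color = "#8B4513",
                         file = NULL, cell_px = 16) {
  stopifnot(length(maps) >= 1, length(colors) == length(maps))
  d <- dim(maps[[1]]$values)
  for (m in maps)
    if (!identical(dim(m$values), d))
      fc_abort("maps differ in shape", "fibercube_validation_error")
  norm <- lapply(maps, function(m) {
    mx <- max(m$values[!m$mask], na.rm = TRUE)
    if (!is.finite(mx) || mx <= 0) matrix(0, d[1], d[2])
    else {
      v <- m$values / mx
      v[!is.finite(v)] <- 0
      v
    }
  })
  mask <- Reduce(`|`, lapply(maps, function(m) m$mask))
  out <- matrix(neutral, d[1], d[2])
  for (r in seq_len(d[1])) for (cc in seq_len(d[2])) {
    if (mask[r, cc]) { out[r, cc] <- masked_color; next }
    vals <- vapply(norm, function(v) v[r, cc], numeric(1))
    if (max(vals) > threshold) out[r, cc] <- colors[which.max(vals)]
  }
  if (!is.null(file)) write_color_png(out, file, cell_px)
  invisible(out)
}

# Write a matrix of hex colors as a PNG (one cell per matrix element).
write_color_png <- function(colors, file, cell_px = 16) {
  nr <- nrow(colors); nc <- ncol(colors)
  grDevices::png(file, width = nc * cell_px, height = nr * cell_px)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 1), ylim = c(0, 1),
                        xaxs = "i", yaxs = "i")
  graphics::rasterImage(grDevices::as.raster(colors), 0, 0, 1, 1,
                        interpolate = FALSE)
  invisible(file)
}
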