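#' Combine bias frames into a master bias
#'
#' Per-pixel median of a stack of zero-second bias frames. The median makes
#' the master robust to stray outliers in individual frames.
#'
#' @param frames list of `frame`s of type `bias`, all the same shape and
#'   exposure 0 s.
#' @return a `frame` of type `master-bias`.
#' @export
combine_bias <- function(frames) {
  if (length(frames) < 1) fc_abort("need at least one bias frame",
                                   "fibercube_validation_error")
  dims <- lapply(frames, function(f) dim(f$data))
  if (length(unique(dims)) != 1)
    fc_abort("bias frames differ in shape", "fibercube_validation_error")
  if (any(vapply(frames, function(f) f$type != "bias" || f$exptime != 0,
                 logical(1))))
    fc_abort("all frames must be bias with 0 s exposure",
             "fibercube_validation_error")
  n <- length(frames)
  if (n == 1) {
    master <- frames[[1]]$data
  } else if (n == 3) {
    a <- frames[[1]]$data; b <- frames[[2]]$data; c <- frames[[3]]$data
    master <- a + b + c - pmax(a, b, c) - pmin(a, b, c)
  } else {
    stack <- vapply(frames, function(f) as.vector(f$data),
                    numeric(length(frames[[1]]$data)))
    master <- matrix(apply(stack, 1, stats::median), dims[[1]][1], dims[[1]][2])
  }
  new_frame(master, "master-bias", 0, header = list(NCOMBINE = n))
}

# Local maxima of a vector above a threshold
local_maxima <- function(p, thr) {
  n <- length(p)
  i <- 2:(n - 1)
  which(p[i] > p[i - 1] & p[i] >= p[i + 1] & p[i] > thr) + 1L
}

# Log-parabola (three-point Gaussian) estimation of trace centers, widths
# and amplitudes in a cross-dispersion cut: exact for a sampled Gaussian.
# A second pass subtracts the modelled wings of neighbouring traces, which
# matters when traces sit only a few sigma apart.
refine_centers <- function(cut, centers, n_iter = 2) {
  n <- length(centers)
  nr <- length(cut)
  sig <- rep(NA_real_, n)
  amp <- rep(0, n)
  for (it in seq_len(n_iter)) {
    prev_c <- centers; prev_s <- sig; prev_a <- amp
    for (i in seq_len(n)) {
      r0 <- as.integer(round(prev_c[i]))
      r0 <- min(max(r0, 1L), nr - 2L)          # keep r0-1..r0+1 in range
      # snap to the local max within one pixel
      tri <- cut[(r0 - 1L):(r0 + 1L) + 1L]
      r0 <- r0 + which.max(tri) - 2L
      r0 <- min(max(r0, 1L), nr - 2L)
      w <- (r0 - 1L):(r0 + 1L)
      v <- cut[w + 1L]
      if (it > 1 && !any(is.na(prev_s))) {
        for (j in c(i - 2L, i - 1L, i + 1L, i + 2L)) {
          if (j < 1L || j > n || is.na(prev_s[j])) next
          v <- v - prev_a[j] * exp(-(w - prev_c[j])^2 / (2 * prev_s[j]^2))
        }
      }
      if (any(v <= 0)) {                        # centroid fallback
        vv <- pmax(cut[w + 1L], 0)
        if (sum(vv) > 0) centers[i] <- sum(w * vv) / sum(vv)
        next
      }
      l <- log(v)
      c2 <- (l[1] + l[3] - 2 * l[2]) / 2
      if (c2 >= -1e-12) {
        vv <- pmax(v, 0)
        centers[i] <- sum(w * vv) / sum(vv)
        next
      }
      b <- (l[3] - l[1]) / 2
      dx <- -b / (2 * c2)
      dx <- min(max(dx, -1), 1)
      centers[i] <- r0 + dx
      sig[i] <- sqrt(-1 / (2 * c2))
      amp[i] <- exp(l[2] - b^2 / (4 * c2))
    }
  }
  list(centers = centers, sigma = sig, amps = amp)
}

#' Locate fiber traces on a flat-field frame
#'
#' Detects the light trace of every fiber on a (bias-subtracted) flat:
#' local maxima of the column-averaged cross-dispersion profile give initial
#' centers; per column-bin the centers are refined by neighbour-subtracted
#' Gaussian centroiding; a low-order polynomial along the dispersion axis is
#' then fitted per fiber. Traces are returned ordered by slit position.
#'
#' If the number of detected traces differs from `expected_n`, a trace-count
#' error reporting the count found is raised — unless `fill_missing = TRUE`,
#' in which case interior gaps (dead fibers leave no trace on the flat) are
#' inferred from the trace pitch and filled with interpolated, dead-flagged
#' traces.
#'
#' @param flat a flat `frame`.
#' @param expected_n expected number of traces, or `NULL` to accept the
#'   detected count.
#' @param master_bias optional master bias to subtract.
#' @param n_bins number of column bins for centroiding along dispersion.
#' @param degree trace polynomial degree.
#' @param threshold_frac peak detection threshold, fraction of profile max.
#' @param fill_missing fill interior gaps instead of erroring?
#' @return a [trace_model()]; attribute `"n_detected"` carries the raw count.
#' @export
find_traces <- function(flat, expected_n = NULL, master_bias = NULL,
                        n_bins = 12, degree = 2, threshold_frac = 0.05,
                        fill_missing = FALSE) {
  img <- flat$data
  if (!is.null(master_bias)) img <- img - master_bias$data
  profile <- rowMeans(img)
  base <- stats::quantile(profile, 0.02, names = FALSE)  # inter-trace floor
  thr <- base + threshold_frac * (max(profile) - base)
  peaks <- local_maxima(profile, thr)
  k <- length(peaks)
  if (k < 1) fc_abort("no traces detected", "fibercube_trace_count_error")

  missing_idx <- integer(0)
  idx <- seq_len(k) - 1L
  if (!is.null(expected_n) && k != expected_n) {
    ok <- FALSE
    if (fill_missing && k < expected_n && k >= 2) {
      d <- diff(peaks)
      pitch <- stats::median(d)
      steps <- pmax(1L, as.integer(round(d / pitch)))
      idx <- cumsum(c(0L, steps))
      if (max(idx) + 1L == expected_n) {
        missing_idx <- setdiff(seq_len(expected_n) - 1L, idx)
        ok <- TRUE
      }
    }
    if (!ok)
      stop(structure(
        class = c("fibercube_trace_count_error", "fibercube_error",
                  "error", "condition"),
        list(message = sprintf("found %d traces, expected %d", k, expected_n),
             call = sys.call(), count = k)))
  }

  ncols <- ncol(img)
  edges <- floor(seq(0, ncols, length.out = n_bins + 1))
  xb <- numeric(n_bins)
  cent <- matrix(NA_real_, k, n_bins)
  sigs <- matrix(NA_real_, k, n_bins)
  centers <- peaks - 1
  for (b in seq_len(n_bins)) {
    cols <- (edges[b] + 1):edges[b + 1]
    xb[b] <- mean(cols) - 1
    cut <- rowMeans(img[, cols, drop = FALSE]) - base
    rc <- refine_centers(cut, centers)
    cent[, b] <- rc$centers
    sigs[, b] <- rc$sigma
  }
  sigma_est <- max(stats::median(sigs, na.rm = TRUE), 0.3)

  X <- outer(xb, 0:degree, `^`)
  coef_live <- t(vapply(seq_len(k), function(i)
    stats::lm.fit(X, cent[i, ])$coefficients, numeric(degree + 1)))

  n_out <- if (is.null(expected_n)) k else expected_n
  coef <- matrix(NA_real_, n_out, degree + 1)
  coef[idx + 1L, ] <- coef_live
  dead <- rep(FALSE, n_out)
  if (length(missing_idx) > 0) {
    dead[missing_idx + 1L] <- TRUE
    for (j in seq_len(degree + 1))
      coef[missing_idx + 1L, j] <- stats::approx(idx, coef_live[, j],
                                                 xout = missing_idx,
                                                 rule = 2)$y
  }
  tm <- trace_model(coef, sigma_est, dead = dead)
  attr(tm, "n_detected") <- k
  tm
}

#' Row-stacked spectra
#'
#' One extracted 1D spectrum per pseudo-slit position, with per-fiber
#' throughput factors, quality flags and (after wavelength calibration) a
#' dispersion model.
#'
#' @param intensity `n_fibers x n_pixels` matrix.
#' @param dead logical per-fiber dead flags.
#' @param throughput per-fiber throughput factors or `NULL`.
#' @param dispersion a [dispersion_model()] or `NULL`.
#' @return object of class `rss`.
#' @export
new_rss <- function(intensity, dead = rep(FALSE, nrow(intensity)),
                    throughput = NULL, dispersion = NULL) {
  structure(list(intensity = intensity, dead = dead, throughput = throughput,
                 dispersion = dispersion),
            class = "rss")
}

#' @export
print.rss <- function(x, ...) {
  cat(sprintf("<rss> %d fibers x %d px (%d dead)%s\n", nrow(x$intensity),
              ncol(x$intensity), sum(x$dead),
              if (is.null(x$dispersion)) "" else ", wavelength-calibrated"))
  invisible(x)
}

#' Measure fiber-to-fiber throughput from an extracted flat
#'
#' Each fiber's factor is its mean flat flux divided by the grand mean over
#' live fibers, so factors have unit mean over live fibers. Fibers whose
#' flux falls below `dead_threshold` times the median are flagged dead and
#' excluded from the mean.
#'
#' @param flat_rss extracted flat spectra (`rss`).
#' @param dead_threshold dead-fiber flux threshold, fraction of the median
#'   fiber flux.
#' @return list with `factors` (NA for dead fibers) and logical `dead`.
#' @export
measure_throughput <- function(flat_rss, dead_threshold = 0.05) {
  means <- rowMeans(flat_rss$intensity)
  if (all(means <= 0)) fc_abort("flat has no signal (all-zero extraction)",
                                "fibercube_degenerate_error")
  dead <- flat_rss$dead | means < dead_threshold * stats::median(means)
  factors <- means / mean(means[!dead])
  factors[dead] <- NA_real_
  list(factors = factors, dead = dead)
}

#' Extract row-stacked spectra from a frame
#'
#' Tophat aperture extraction: per fiber and dispersion column, counts are
#' summed over the pixels within `half_width` of the trace center, divided
#' by the modelled in-aperture fraction of the Gaussian cross-profile (so
#' flux is conserved, not just sampled), and divided by the fiber's
#' throughput factor. Dead fibers are flagged, not deleted.
#'
#' @param frame a `frame`.
#' @param traces a [trace_model()].
#' @param master_bias optional master bias to subtract.
#' @param throughput result of [measure_throughput()], a bare numeric vector
#'   of factors, or `NULL` for no correction.
#' @param half_width aperture half-width in px (default `2 * sigma`; the
#'   in-aperture renormalization keeps flux exact while the tighter tophat
#'   keeps neighbour-trace crosstalk below ~1%).
#' @return an `rss`.
#' @export
extract_spectra <- function(frame, traces, master_bias = NULL,
                            throughput = NULL, half_width = NULL) {
  img <- frame$data
  if (!is.null(master_bias)) img <- img - master_bias$data
  if (is.null(half_width)) half_width <- 2 * traces$sigma_px
  nf <- nrow(traces$coef)
  pitch <- min(diff(traces$coef[, 1]))
  if (is.finite(pitch) && pitch < 2 * half_width)
    warning(sprintf(
      "aperture half-width %.2f px overlaps adjacent traces (pitch %.2f px): cross-talk likely",
      half_width, pitch))

  dead <- traces$dead
  factors <- NULL
  if (!is.null(throughput)) {
    if (is.list(throughput)) {
      factors <- throughput$factors
      dead <- dead | throughput$dead
    } else factors <- throughput
  }

  ncols <- ncol(img)
  cols <- seq_len(ncols) - 1L
  centers <- trace_centers(traces, cols)
  hh <- as.integer(ceiling(half_width))
  H <- max(hh, ceiling(4 * traces$sigma_px))
  out <- matrix(0, nf, ncols)
  for (i in seq_len(nf)) {
    c0 <- centers[i, ]
    r0 <- round(c0)
    apsum <- numeric(ncols)
    win_in <- numeric(ncols); win_all <- numeric(ncols)
    for (off in -H:H) {
      rows <- r0 + off
      w <- exp(-(rows - c0)^2 / (2 * traces$sigma_px^2))
      win_all <- win_all + w
      inside <- abs(rows - c0) <= half_width & rows >= 0 & rows < nrow(img)
      if (any(inside)) {
        win_in <- win_in + w * inside
        ridx <- rows[inside] + 1L
        apsum[inside] <- apsum[inside] + img[cbind(ridx, cols[inside] + 1L)]
      }
    }
    capture <- win_in / win_all
    spec <- ifelse(capture > 0, apsum / pmax(capture, 1e-12), 0)
    f <- if (!is.null(factors)) factors[i] else 1
    if (is.na(f) || f <= 0) { dead[i] <- TRUE; f <- 1 }
    out[i, ] <- spec / f
  }
  new_rss(out, dead = dead, throughput = factors)
}

#' Fit per-fiber wavelength solutions from an extracted arc
#'
#' Per live fiber: emission-line centroids are measured in pixel space,
#' matched in order to the (sorted) line list, and a polynomial
#' `wavelength(pixel)` of the given degree is least-squares fitted. Dead
#' fibers inherit the median solution of the live fibers (they stay
#' flagged). The per-fiber residual RMS is attached to the model.
#'
#' @param arc_rss extracted arc spectra (`rss`).
#' @param line_list arc line wavelengths in nm.
#' @param degree polynomial degree (default 3).
#' @param excitation_nm excitation wavelength recorded in the model.
#' @param threshold_frac line detection threshold, fraction of spectrum max.
#' @return a [dispersion_model()] with `residual_rms` (nm) per fiber.
#' @export
fit_wavelength <- function(arc_rss, line_list, degree = 3,
                           excitation_nm = 785, threshold_frac = 0.2) {
  line_list <- sort(line_list)
  nl <- length(line_list)
  nf <- nrow(arc_rss$intensity)
  if (nl < degree + 1)
    fc_abort(sprintf("need at least %d arc lines for degree %d", degree + 1,
                     degree), "fibercube_calibration_error")
  coef <- matrix(NA_real_, nf, degree + 1)
  rms <- rep(NA_real_, nf)
  for (i in seq_len(nf)) {
    if (arc_rss$dead[i]) next
    y <- arc_rss$intensity[i, ]
    pk <- local_maxima(y, threshold_frac * max(y))
    if (length(pk) > nl) pk <- sort(pk[order(y[pk], decreasing = TRUE)][1:nl])
    if (length(pk) < degree + 1 || length(pk) != nl)
      fc_abort(sprintf("fiber %d: matched %d of %d arc lines", i - 1L,
                       length(pk), nl), "fibercube_calibration_error")
    cent <- vapply(pk, function(p) {
      w <- max(1L, p - 3L):min(length(y), p + 3L)
      v <- pmax(y[w], 0)
      sum((w - 1L) * v) / sum(v)            # 0-based pixel centroid
    }, numeric(1))
    X <- outer(cent, 0:degree, `^`)
    fit <- stats::lm.fit(X, line_list)
    coef[i, ] <- fit$coefficients
    rms[i] <- sqrt(mean(fit$residuals^2))
  }
  if (any(is.na(coef[, 1]))) {
    med <- apply(coef[!is.na(coef[, 1]), , drop = FALSE], 2, stats::median)
    for (i in which(is.na(coef[, 1]))) coef[i, ] <- med
  }
  dispersion_model(coef, excitation_nm, residual_rms = rms)
}

#' Clean cosmic-ray hits from extracted spectra
#'
#' Spectral-domain cleaning: a sample is replaced by the running-median
#' value when it deviates more than `k` robust sigma from the running median
#' *and* is narrower than the instrument profile (its higher neighbour's
#' deviation is below `ratio` times its own — genuine Raman peaks are
#' several samples wide and survive). The noise scale is allowed to grow
#' with the local signal level (shot noise), estimated from the low- and
#' high-signal halves of each spectrum. The pass is iterated to a fixpoint,
#' which makes the operation idempotent.
#'
#' @param rss an `rss`.
#' @param k sigma-clipping threshold.
#' @param window running-median window (odd).
#' @param ratio single-sample narrowness threshold.
#' @return the cleaned `rss`; attribute `"replaced"` holds a matrix of
#'   1-based `(fiber, pixel)` positions replaced.
#' @export
clean_cosmics <- function(rss, k = 6, window = 9, ratio = 0.35) {
  out <- rss
  replaced <- NULL
  for (i in seq_len(nrow(rss$intensity))) {
    y <- out$intensity[i, ]
    for (pass in 1:5) {
      b <- stats::runmed(y, window)
      resid <- y - b
      # signal-dependent noise scale: interpolate the robust sigma between
      # the low- and high-signal halves (shot noise grows with the signal)
      bm <- stats::median(b)
      lo <- b <= bm
      s_lo <- stats::mad(resid[lo])
      s_hi <- stats::mad(resid[!lo])
      b_lo <- stats::median(b[lo]); b_hi <- stats::median(b[!lo])
      v <- if (s_hi > s_lo && b_hi > b_lo)
        pmax(s_lo^2 + (s_hi^2 - s_lo^2) * (b - b_lo) / (b_hi - b_lo),
             0.25 * s_lo^2)
      else rep(max(s_lo, s_hi)^2, length(b))
      sig <- sqrt(v)
      sig <- pmax(sig, 1e-12 + 1e-9 * max(abs(y), 0))
      cand <- which(resid > k * sig)
      if (length(cand) == 0) break
      n <- length(y)
      nb <- vapply(cand, function(j) {
        max(if (j > 1) resid[j - 1] else 0,
            if (j < n) resid[j + 1] else 0, 0)
      }, numeric(1))
      hit <- cand[nb < ratio * resid[cand]]
      if (length(hit) == 0) break
      y[hit] <- b[hit]
      replaced <- rbind(replaced, cbind(fiber = i, pixel = hit))
    }
    out$intensity[i, ] <- y
  }
  if (is.null(replaced))
    replaced <- matrix(integer(0), ncol = 2,
                       dimnames = list(NULL, c("fiber", "pixel")))
  attr(out, "replaced") <- replaced
  out
}
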