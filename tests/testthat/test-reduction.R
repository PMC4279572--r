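test_that("combine_bias medians the stack and validates inputs", {
  mk <- function(v) new_frame(matrix(v, 4, 5), "bias", 0)
  expect_equal(combine_bias(list(mk(100), mk(100), mk(100)))$data,
               matrix(100, 4, 5))
  # median rejects the outlier (oracle: median(98,100,300) = 100)
  expect_equal(combine_bias(list(mk(98), mk(100), mk(300)))$data[1, 1], 100)
  expect_equal(combine_bias(list(mk(98), mk(100), mk(101), mk(103),
                                 mk(300)))$data[2, 3], 101)
  one <- combine_bias(list(mk(77)))
  expect_equal(one$data, matrix(77, 4, 5))
  expect_identical(one$type, "master-bias")
  expect_error(combine_bias(list(mk(1), new_frame(matrix(1, 2, 2), "bias", 0))),
               class = "fibercube_validation_error")
  expect_error(combine_bias(list(new_frame(matrix(1, 4, 5), "bias", 10))),
               class = "fibercube_validation_error")
  expect_error(combine_bias(list()), class = "fibercube_validation_error")
})

test_that("find_traces recovers all centers to better than 0.1 px", {
  s <- small_setup()
  mb <- combine_bias(make_bias(s$det, 3, seed = 2))
  fl <- make_flat(s$traces, s$dispersion, s$det, seed = 1)
  tr <- find_traces(fl, expected_n = 30, master_bias = mb)
  cols <- 0:(s$det$n_cols_px - 1)
  err <- trace_centers(tr, cols) - trace_centers(s$traces, cols)
  expect_lt(max(abs(err)), 0.1)
  expect_equal(attr(tr, "n_detected"), 30)
  expect_equal(tr$sigma_px, s$traces$sigma_px, tolerance = 0.05)
})

test_that("a missing trace raises a count error unless gaps are filled", {
  s <- small_setup()
  thr <- rep(1, 30); thr[13] <- 0
  fl <- make_flat(s$traces, s$dispersion, s$det, throughput = thr,
                  noise = FALSE)
  err <- expect_error(find_traces(fl, expected_n = 30),
                      class = "fibercube_trace_count_error")
  expect_match(conditionMessage(err), "29")
  tr <- find_traces(fl, expected_n = 30, fill_missing = TRUE)
  expect_equal(nrow(tr$coef), 30)
  expect_true(tr$dead[13])
  expect_equal(sum(tr$dead), 1)
  # the interpolated trace sits at the true (unlit) position
  cols <- 0:(s$det$n_cols_px - 1)
  expect_lt(max(abs(polyval_test(tr$coef[13, ], cols) -
                    polyval_test(s$traces$coef[13, ], cols))), 0.2)
})

test_that("straight traces fit with vanishing slope and curvature", {
  s <- small_setup()
  straight <- default_trace_model(30, s$det, bow_px = 0)
  fl <- make_flat(straight, s$dispersion, s$det, noise = FALSE)
  tr <- find_traces(fl, expected_n = 30)
  expect_lt(max(abs(tr$coef[, 2])), 1e-3)
  expect_lt(max(abs(tr$coef[, 3])) * s$det$n_cols_px^2, 0.2)
})

test_that("throughput factors normalize to unit mean and flag dead fibers", {
  ident <- new_rss(matrix(500, 10, 50))
  t1 <- measure_throughput(ident)
  expect_equal(t1$factors, rep(1, 10))
  expect_false(any(t1$dead))
  # one fiber at half flux: closed-form factors
  m <- matrix(500, 10, 50); m[4, ] <- 250
  t2 <- measure_throughput(new_rss(m))
  grand <- mean(c(rep(500, 9), 250))
  expect_equal(t2$factors[4], 250 / grand, tolerance = 1e-12)
  expect_equal(t2$factors[1], 500 / grand, tolerance = 1e-12)
  expect_equal(mean(t2$factors), 1, tolerance = 1e-12)
  # zero-flux fiber flagged dead and excluded from the mean
  m[4, ] <- 0
  t3 <- measure_throughput(new_rss(m))
  expect_true(t3$dead[4])
  expect_true(is.na(t3$factors[4]))
  expect_equal(t3$factors[1], 1, tolerance = 1e-12)
  expect_error(measure_throughput(new_rss(matrix(0, 5, 20))),
               class = "fibercube_degenerate_error")
})

test_that("extraction conserves flux and corrects throughput", {
  s <- small_setup()
  thr <- rep(0, 30); thr[11] <- 1
  fl <- make_flat(s$traces, s$dispersion, s$det, throughput = thr,
                  flux = 1000, noise = FALSE)
  rss <- extract_spectra(fl, s$traces, master_bias = s$bias0)
  u <- 2 * (0:199) / 199 - 1
  truth <- 1000 * (1 - 0.25 * u^2)
  expect_equal(rss$intensity[11, ], truth, tolerance = 1e-3)
  # zero frame -> all-zero spectra
  z <- extract_spectra(new_frame(matrix(100, 120, 200), "science", 1),
                       s$traces, master_bias = s$bias0)
  expect_true(all(abs(z$intensity) < 1e-9))
  # twin fibers at throughput 1 and 0.5 extract to equal corrected spectra
  thr2 <- rep(1, 30); thr2[11] <- 0.5
  fl2 <- make_flat(s$traces, s$dispersion, s$det, throughput = thr2,
                   noise = FALSE)
  rss2 <- extract_spectra(fl2, s$traces, master_bias = s$bias0,
                          throughput = thr2)
  # equal to within residual neighbour-trace crosstalk (~0.3%)
  expect_equal(rss2$intensity[11, ], rss2$intensity[12, ], tolerance = 5e-3)
  # oversized aperture triggers the cross-talk warning
  expect_warning(extract_spectra(fl, s$traces, master_bias = s$bias0,
                                 half_width = 2), "cross-talk")
})

test_that("trace finding plus extraction recovers spectra to < 2% at SNR 50", {
  s <- small_setup()
  mb <- combine_bias(make_bias(s$det, 3, seed = 21))
  fl <- make_flat(s$traces, s$dispersion, s$det, flux = 2500, seed = 22)
  tr <- find_traces(fl, expected_n = 30, master_bias = mb)
  rss <- extract_spectra(fl, tr, master_bias = mb)
  u <- 2 * (0:199) / 199 - 1
  truth <- 2500 * (1 - 0.25 * u^2)
  rel <- sweep(rss$intensity, 2, truth, `/`) - 1
  # per-sample scatter sits at the shot-noise floor (1/SNR)...
  expect_lt(sqrt(mean(rel^2)), 0.025)
  # ...while the systematic recovery error (per-fiber mean over 200
  # columns, noise averaged down ~14x) stays well below 2%
  expect_lt(sqrt(mean(rowMeans(rel)^2)), 0.02)
  expect_lt(max(abs(rowMeans(rel))), 0.02)
})

test_that("wavelength solutions recover the dispersion model", {
  s <- small_setup()
  # linear dispersion, degree-1 fit: coefficients recover truth
  lin <- dispersion_model(cbind(rep(790, 30), rep(0.5, 30)))
  arc <- make_arc(seq(800, 880, 20), s$traces, lin, s$det, noise = FALSE)
  rss <- extract_spectra(arc, s$traces, master_bias = s$bias0)
  fit <- fit_wavelength(rss, seq(800, 880, 20), degree = 1)
  expect_equal(unname(fit$coef[, 1]), rep(790, 30), tolerance = 1e-2)
  expect_equal(unname(fit$coef[, 2]), rep(0.5, 30), tolerance = 1e-4)
  expect_lt(max(fit$residual_rms), 0.01)
  # noise-off quadratic model, degree-3 fit: residuals essentially zero
  arc2 <- make_arc(default_arc_lines(), s$traces, s$dispersion, s$det,
                   noise = FALSE)
  rss2 <- extract_spectra(arc2, s$traces, master_bias = s$bias0)
  fit2 <- fit_wavelength(rss2, default_arc_lines())
  expect_lt(max(fit2$residual_rms), 1e-3)
  expect_error(fit_wavelength(rss2, c(800, 900)),
               class = "fibercube_calibration_error")
})

test_that("wavelength solution error shrinks (non-strictly) with more arc lines", {
  s <- small_setup()
  cols <- 0:(s$det$n_cols_px - 1)
  truth <- fiber_wavelengths(s$dispersion, cols)
  err_for <- function(n_lines) {
    lines <- seq(795, 925, length.out = n_lines)
    arc <- make_arc(lines, s$traces, s$dispersion, s$det, seed = 33)
    rss <- extract_spectra(arc, s$traces, master_bias = s$bias0)
    fit <- fit_wavelength(rss, lines, degree = 2)
    sqrt(mean((fiber_wavelengths(fit, cols) - truth)^2))
  }
  errs <- vapply(c(4, 6, 8, 12), err_for, numeric(1))
  expect_true(all(diff(errs) <= 0.05 * errs[-length(errs)] + 1e-6))
})

test_that("cosmic cleaning removes spikes, spares peaks, and is idempotent", {
  ax <- default_shift_axis()
  sigma <- 12 / (2 * sqrt(2 * log(2)))
  base <- 30 + 0.01 * (ax - 1000)^2 / 100
  peak <- 100 * exp(-(ax - 1035)^2 / (2 * sigma^2))
  set.seed(77)
  noise <- rnorm(length(ax), 0, 2)
  clean <- new_rss(rbind(base + peak + noise))
  out0 <- clean_cosmics(clean)
  expect_equal(nrow(attr(out0, "replaced")), 0)
  expect_identical(out0$intensity, clean$intensity)
  # three 50-sigma spikes are replaced at exactly the injected positions
  spiked <- clean
  pos <- c(120, 430, 800)
  spiked$intensity[1, pos] <- spiked$intensity[1, pos] + 50 * 2
  out <- clean_cosmics(spiked)
  rep <- attr(out, "replaced")
  expect_equal(sort(rep[, "pixel"]), pos)
  expect_equal(out$intensity[1, -pos], spiked$intensity[1, -pos])
  # a genuine noiseless Raman peak is never touched
  pure <- new_rss(rbind(base + peak))
  expect_equal(nrow(attr(clean_cosmics(pure), "replaced")), 0)
  # idempotence on seeded random spectra
  for (sd in 1:4) {
    set.seed(sd)
    y <- rbind(50 + rnorm(500, 0, 3))
    y[1, sample(500, 3)] <- y[1, sample(500, 3)] + 200
    once <- clean_cosmics(new_rss(y))
    twice <- clean_cosmics(once)
    expect_identical(once$intensity, twice$intensity)
    expect_equal(nrow(attr(twice, "replaced")), 0)
  }
})
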