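test_that("noise-off frames are exact forward-model evaluations", {
  s <- small_setup()
  fr <- render_frame(NULL, NULL, "shift", s$traces, s$dispersion, s$det,
                     noise = FALSE)
  expect_true(all(fr$data == s$det$bias_level))
  # no stochastic term: two noise-off renders are identical
  fl1 <- make_flat(s$traces, s$dispersion, s$det, noise = FALSE)
  fl2 <- make_flat(s$traces, s$dispersion, s$det, noise = FALSE)
  expect_identical(fl1$data, fl2$data)
})

test_that("seeded generators are deterministic and seeds matter", {
  s <- small_setup()
  a <- make_flat(s$traces, s$dispersion, s$det, seed = 42)
  b <- make_flat(s$traces, s$dispersion, s$det, seed = 42)
  c <- make_flat(s$traces, s$dispersion, s$det, seed = 43)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c$data))
})

test_that("injected flux is conserved along a single trace", {
  s <- small_setup()
  thr <- rep(0, 30); thr[11] <- 1
  fl <- make_flat(s$traces, s$dispersion, s$det, throughput = thr,
                  flux = 1000, noise = FALSE)
  sig <- fl$data - s$det$bias_level
  colsum <- colSums(sig)
  u <- 2 * (0:199) / 199 - 1
  expect_equal(colsum, 1000 * (1 - 0.25 * u^2), tolerance = 1e-6)
  # flat with zero-throughput fiber: that trace is absent (sample each
  # column at the bowed trace center)
  thr2 <- rep(1, 30); thr2[20] <- 0
  fl2 <- make_flat(s$traces, s$dispersion, s$det, throughput = thr2,
                   noise = FALSE)
  cols <- 0:(s$det$n_cols_px - 1)
  ctr20 <- round(trace_centers(s$traces, cols)[20, ])
  on_trace <- fl2$data[cbind(ctr20 + 1L, cols + 1L)] - s$det$bias_level
  # only the faint wings of the neighbouring traces remain
  expect_lt(max(on_trace), 0.01 * 5000)
})

test_that("bias frames carry zero exposure and pure offset", {
  s <- small_setup()
  frames <- make_bias(s$det, 3, noise = FALSE)
  expect_length(frames, 3)
  for (f in frames) {
    expect_identical(f$type, "bias")
    expect_identical(f$exptime, 0)
    expect_true(all(f$data == s$det$bias_level))
  }
})

test_that("arc lines land at the dispersion-predicted columns", {
  s <- small_setup()
  lines <- c(820, 854.42, 900)
  arc <- make_arc(lines, s$traces, s$dispersion, s$det, noise = FALSE)
  sig <- arc$data - s$det$bias_level
  i <- 15  # a mid-bundle fiber
  cols <- 0:(s$det$n_cols_px - 1)
  ctr <- round(trace_centers(s$traces, cols)[i, ])
  spec <- sig[cbind(ctr, cols + 1L)] + sig[cbind(ctr + 1L, cols + 1L)] +
    sig[cbind(ctr + 2L, cols + 1L)]        # 3 rows tracking the bowed trace
  lam <- fiber_wavelengths(s$dispersion, cols)[i, ]
  for (L in lines) {
    truth <- approx(lam, cols, xout = L)$y
    w <- (round(truth) - 3):(round(truth) + 3)       # 0-based columns
    cen <- sum(w * spec[w + 1L]) / sum(spec[w + 1L])
    expect_lt(abs(cen - truth), 0.1)
  }
  expect_error(make_arc(numeric(0), s$traces, s$dispersion, s$det),
               class = "fibercube_config_error")
})

test_that("bead phantoms cover the expected spaxels", {
  lay <- bundle_layout()
  hf <- half_field_phantom(lay)
  expect_equal(sum(hf$weights[, , "paracetamol"] > 0), 200)
  expect_equal(sum(hf$weights[, , "aspirin"] > 0), 200)
  empty <- make_bead_phantom(lay, data.frame(substance = character(0),
                                             x_mm = numeric(0),
                                             y_mm = numeric(0),
                                             diameter_mm = numeric(0)))
  expect_equal(dim(empty$weights)[3], 0)
  ph <- bead_phantom_fig(lay)
  # connected PS components equal the number of placed PS beads (oracle:
  # flood fill in the test helper)
  expect_equal(count_components(ph$weights[, , "PS"] > 0), 3)
  expect_equal(count_components(ph$weights[, , "PMMA"] > 0), 1)
  expect_warning(
    make_bead_phantom(lay, data.frame(substance = "PS", x_mm = 9.4,
                                      y_mm = 9.4, diameter_mm = 2)),
    "clipped")
})

test_that("illumination profile is positive with the stated dynamic range", {
  lay <- bundle_layout()
  ill <- illumination_profile(lay, center_to_corner = 10)
  expect_true(all(ill > 0))
  expect_equal(max(ill) / ill[1, 1], 10, tolerance = 0.05)
  expect_equal(ill[1, 1], ill[20, 20], tolerance = 1e-12)
})

test_that("cosmic injection records exactly the requested hits", {
  s <- small_setup()
  fr <- make_flat(s$traces, s$dispersion, s$det, noise = FALSE)
  same <- inject_cosmics(fr, 0)
  expect_identical(same$data, fr$data)
  # on a structure-free frame every spike towers over the local statistics
  blank <- make_bias(s$det, 1, seed = 4)[[1]]
  hit <- inject_cosmics(blank, 5, amplitude = 5000, seed = 9)
  hits <- attr(hit, "cosmic_hits")
  expect_equal(nrow(hits), 5)
  for (i in seq_len(nrow(hits))) {
    r <- hits[i, 1]; cc <- hits[i, 2]
    nb <- hit$data[max(1, r - 3):min(nrow(hit$data), r + 3),
                   max(1, cc - 3):min(ncol(hit$data), cc + 3)]
    # spike exceeds the local median by >= 10 local sigma
    expect_gt(hit$data[r, cc] - median(nb), 10 * s$det$read_noise)
  }
})

test_that("science frames scale substance flux with illumination and throughput", {
  lay <- small_layout()
  s <- small_setup()
  ph <- uniform_phantom(lay, "PS", illumination = matrix(1, 5, 6))
  # isolate two fibers so neighbouring traces cannot contaminate the sums
  thr <- rep(0, 30); thr[5] <- 0.5; thr[20] <- 1
  fr <- make_science(ph, spectral_library(), s$traces, s$dispersion, s$det,
                     axis = seq(800, 1300, 2), peak_flux = 500,
                     baseline_ratio = 0, throughput = thr, noise = FALSE)
  sig <- fr$data - s$det$bias_level
  cols <- 0:(s$det$n_cols_px - 1)
  tsum <- function(i) {
    ctr <- round(trace_centers(s$traces, cols)[i, ])
    sum(vapply(-3:3, function(o) sum(sig[cbind(ctr + o + 1L, cols + 1L)]),
               numeric(1)))
  }
  # the 200-column test detector undersamples the 12 cm^-1 peaks, so the
  # summed flux carries a percent-level sampling-phase ripple
  expect_equal(tsum(5) / tsum(20), 0.5, tolerance = 0.02)
})
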