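test_that("lmj_baseline reproduces polynomial inputs exactly", {
  ax <- default_shift_axis()
  u <- 2 * (ax - min(ax)) / (max(ax) - min(ax)) - 1
  poly <- 300 * (1 + 0.2 * u - 0.4 * u^2 + 0.1 * u^3 + 0.3 * u^4)
  bf <- lmj_baseline(poly, ax)
  expect_lt(max(abs(bf$corrected)), 1e-6 * max(abs(poly)))
  expect_equal(bf$baseline + bf$corrected, poly, tolerance = 1e-12)
  const <- lmj_baseline(rep(42, 100))
  expect_lt(max(abs(const$corrected)), 1e-9)
  expect_error(lmj_baseline(1:4, order = 4),
               class = "fibercube_validation_error")
  expect_error(lmj_baseline(c(1:50, NA)), class = "fibercube_validation_error")
})

test_that("lmj_baseline recovers a peak over a 4th-order background", {
  ax <- default_shift_axis()
  u <- 2 * (ax - min(ax)) / (max(ax) - min(ax)) - 1
  bg <- 500 * (1.2 + 0.4 * u + 0.5 * u^2 + 0.3 * u^3 + 0.5 * u^4)
  sig <- 12 / (2 * sqrt(2 * log(2)))
  peak <- 100 * exp(-(ax - 734)^2 / (2 * sig^2))
  bf <- lmj_baseline(bg + peak, ax)
  expect_equal(max(bf$corrected), 100, tolerance = 0.05)
  # baseline stays at or below the input away from the peak (1% slack)
  off_peak <- abs(ax - 734) > 60
  rng <- diff(range(bg + peak))
  expect_true(all(bf$baseline[off_peak] <=
                  (bg + peak)[off_peak] + 0.01 * rng))
})

test_that("lmj iteration converges for large iteration counts", {
  ax <- default_shift_axis()
  u <- 2 * (ax - min(ax)) / (max(ax) - min(ax)) - 1
  y <- 200 * (1 + 0.5 * u^2) + 80 * exp(-(ax - 1035)^2 / 50) +
    30 * exp(-(ax - 600)^2 / 80)
  bf <- lmj_baseline(y, ax, n_iter = 3000)
  expect_lt(bf$delta, 1e-8)
  # successive baselines are pointwise non-increasing in the fit sense:
  # longer runs never raise the corrected peak estimate
  h <- vapply(c(1, 5, 15, 50), function(k)
    max(lmj_baseline(y, ax, n_iter = k)$corrected), numeric(1))
  expect_true(all(diff(h) >= -1e-9))
})

test_that("fit_gaussian recovers exact and noisy peaks", {
  ax <- default_shift_axis()
  y <- 50 * exp(-(ax - 1035)^2 / (2 * 25))
  g <- fit_gaussian(y, ax, 1035, 40)
  expect_true(g$converged)
  expect_equal(g$center, 1035, tolerance = 1e-6)
  expect_equal(g$amplitude, 50, tolerance = 1e-6)
  expect_equal(g$sigma, 5, tolerance = 1e-6)
  expect_equal(g$offset, 0, tolerance = 1e-6)
  expect_error(fit_gaussian(y, ax, 1035, 4),
               class = "fibercube_validation_error")
})

test_that("noisy centers land within 1 cm^-1 in at least 95% of trials", {
  ax <- seq(950, 1120, 2)
  truth <- 50 * exp(-(ax - 1035)^2 / (2 * 25))
  hits <- 0L
  n_trials <- 100L
  for (i in seq_len(n_trials)) {
    set.seed(1000 + i)
    g <- fit_gaussian(truth + rnorm(length(ax), 0, 50 / 20), ax, 1035, 40)
    if (g$converged && abs(g$center - 1035) <= 1) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("pure-noise windows do not yield significant amplitudes", {
  ax <- seq(950, 1120, 2)
  for (i in 1:10) {
    set.seed(200 + i)
    g <- fit_gaussian(rnorm(length(ax), 0, 2), ax, 1035, 40)
    expect_true(!g$converged || abs(g$amplitude) < 3 * 2)
  }
})

test_that("reference subtraction and axis checks behave", {
  ax <- default_shift_axis()
  a <- raman_cube(array(rnorm(4 * 5 * length(ax)), c(4, 5, length(ax))), ax)
  z <- subtract_reference(a, a)
  expect_true(all(z$data == 0))
  zero <- raman_cube(array(0, dim(a$data)), ax)
  expect_equal(subtract_reference(a, zero)$data, a$data)
  b <- raman_cube(a$data, ax + 1)
  expect_error(subtract_reference(a, b), class = "fibercube_validation_error")
  # round trip: background added then subtracted leaves only the sample
  set.seed(3)
  bg_true <- array(rep(100 + 5 * sin(ax / 100), each = 20), c(4, 5, length(ax)))
  noise1 <- array(rnorm(length(bg_true), 0, 2), dim(bg_true))
  noise2 <- array(rnorm(length(bg_true), 0, 2), dim(bg_true))
  sample_only <- a$data * 10
  sci <- raman_cube(sample_only + bg_true + noise1, ax)
  blank <- raman_cube(bg_true + noise2, ax)
  rec <- subtract_reference(sci, blank)
  expect_lt(sqrt(mean((rec$data - sample_only)^2)), 2 * sqrt(2) * 2)
})

test_that("reference normalization removes a shared illumination profile", {
  ax <- default_shift_axis()
  lay <- small_layout()
  ill <- illumination_profile(lay, 10)
  spec <- 50 + 20 * exp(-(ax - 800)^2 / 200)
  mk <- function(noise_sd, seed) {
    set.seed(seed)
    d <- array(0, c(5, 6, length(ax)))
    for (r in 1:5) for (cc in 1:6)
      d[r, cc, ] <- spec * ill[r, cc] +
        rnorm(length(ax), 0, noise_sd * sqrt(ill[r, cc]))
    raman_cube(d, ax)
  }
  sci <- mk(0.5, 1); ref <- mk(0.5, 2)
  norm <- normalize_by_reference(sci, ref)
  per_spax <- apply(norm$data, c(1, 2), mean)
  expect_lt(stats::sd(per_spax) / mean(per_spax), 0.03)
  # uniform reference only rescales globally
  unif <- raman_cube(array(4, dim(sci$data)), ax)
  n1 <- normalize_by_reference(sci, unif)
  expect_equal(n1$data, sci$data / 4, tolerance = 1e-12)
  # idempotence up to a scalar with the same uniform reference
  n2 <- normalize_by_reference(n1, unif)
  expect_equal(n2$data * 4^2, sci$data, tolerance = 1e-12)
  # zero reference at one spaxel: masked with warning, others untouched
  bad <- ref
  bad$data[2, 3, ] <- 0
  expect_warning(nb <- normalize_by_reference(sci, bad), "masked")
  expect_true(nb$mask[2, 3])
  expect_equal(sum(nb$mask), 1)
  expect_equal(nb$data[1, 1, ], norm$data[1, 1, ], tolerance = 1e-12)
})
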