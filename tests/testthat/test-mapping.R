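# small synthetic cube with PS signal in chosen spaxels
toy_cube <- function(ps_mask, amp = 80, noise_sd = 0, seed = 1,
                     baseline = TRUE) {
  ax <- seq(800, 1300, 2)
  u <- 2 * (ax - min(ax)) / (max(ax) - min(ax)) - 1
  bg <- if (baseline) 200 * (1 + 0.3 * u + 0.4 * u^2 + 0.2 * u^4) else 0
  sig <- 12 / (2 * sqrt(2 * log(2)))
  peak <- exp(-(ax - 1035)^2 / (2 * sig^2))
  set.seed(seed)
  d <- array(0, c(nrow(ps_mask), ncol(ps_mask), length(ax)))
  for (r in seq_len(nrow(ps_mask))) for (cc in seq_len(ncol(ps_mask)))
    d[r, cc, ] <- bg + (if (ps_mask[r, cc]) amp * peak else 0) +
      rnorm(length(ax), 0, noise_sd)
  raman_cube(d, ax)
}

test_that("chemical_map measures fitted peak heights where the substance is", {
  msk <- matrix(FALSE, 4, 5); msk[2, 2] <- msk[3, 4] <- TRUE
  cube <- toy_cube(msk, amp = 80, noise_sd = 1)
  m <- chemical_map(cube, "PS", shift = 1035, window = 40)
  expect_equal(dim(m$values), c(4, 5))
  expect_equal(m$values[2, 2], 80, tolerance = 0.1)
  expect_equal(m$values[3, 4], 80, tolerance = 0.1)
  expect_lt(max(m$values[!msk]), 3 * 1 + 1)   # absent substance ~ noise level
  expect_error(chemical_map(cube, "PS", shift = 5000),
               class = "fibercube_range_error")
  # library lookup supplies the shift when omitted
  m2 <- chemical_map(cube, "PS", window = 40)
  expect_equal(m2$shift, 1035)
})

test_that("chemical_map is permutation-equivariant and homogeneous", {
  msk <- matrix(FALSE, 4, 5); msk[1, 1] <- msk[4, 5] <- msk[2, 3] <- TRUE
  cube <- toy_cube(msk, amp = 60, noise_sd = 0)
  m <- chemical_map(cube, "PS", shift = 1035, window = 40)
  # permute rows of the cube -> map permutes identically
  perm <- c(3, 1, 4, 2)
  cube_p <- raman_cube(cube$data[perm, , ], cube$axis, cube$mask[perm, ])
  m_p <- chemical_map(cube_p, "PS", shift = 1035, window = 40)
  expect_equal(m_p$values, m$values[perm, ], tolerance = 1e-6)
  # positive scaling of the cube scales the map
  cube_s <- raman_cube(cube$data * 2.5, cube$axis, cube$mask)
  m_s <- chemical_map(cube_s, "PS", shift = 1035, window = 40)
  expect_equal(m_s$values, m$values * 2.5, tolerance = 1e-4)
})

test_that("dead-fiber masks propagate into maps and renders", {
  msk <- matrix(TRUE, 3, 3)
  cube <- toy_cube(msk, amp = 50, noise_sd = 0)
  cube$mask[2, 2] <- TRUE
  m <- chemical_map(cube, "PS", shift = 1035, window = 40)
  expect_true(is.na(m$values[2, 2]))
  cols <- render_map(m)
  expect_equal(sum(cols == "#FFFFFF"), 1)
  expect_equal(cols[2, 2], "#FFFFFF")
})

test_that("render_map uses the blue-to-red convention", {
  m <- structure(list(values = matrix(c(0, 1, 2, 3), 2, 2), substance = "PS",
                      shift = 1035, mask = matrix(FALSE, 2, 2)),
                 class = "chemical_map")
  cols <- render_map(m)
  expect_equal(cols[1, 1], "#0000FF")   # minimum -> blue
  expect_equal(cols[2, 2], "#FF0000")   # maximum -> red
  # constant map -> one single color
  mc <- m; mc$values <- matrix(5, 2, 2)
  expect_equal(length(unique(as.vector(render_map(mc)))), 1)
  # all-masked map refuses to render
  mm <- m; mm$mask <- matrix(TRUE, 2, 2)
  expect_error(render_map(mm), class = "fibercube_render_error")
  # PNG writing works
  f <- tempfile(fileext = ".png")
  render_map(m, file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
})

test_that("overlays color the dominant substance with deterministic ties", {
  mk <- function(v) structure(list(values = v, substance = "x", shift = 1,
                                   mask = matrix(FALSE, 3, 3)),
                              class = "chemical_map")
  a <- matrix(0, 3, 3); a[1, ] <- 1
  b <- matrix(0, 3, 3); b[2, ] <- 1
  c3 <- matrix(0, 3, 3); c3[3, ] <- 1
  out <- overlay_maps(list(mk(a), mk(b), mk(c3)),
                      c("#FF0000", "#00FF00", "#0000FF"))
  expect_true(all(out[1, ] == "#FF0000"))
  expect_true(all(out[2, ] == "#00FF00"))
  expect_true(all(out[3, ] == "#0000FF"))
  # all-zero maps -> fully neutral
  z <- overlay_maps(list(mk(matrix(0, 3, 3))), "#FF0000")
  expect_true(all(z == "#D9D9D9"))
  # exact tie resolves to the first map in the list
  t1 <- matrix(1, 3, 3); t2 <- matrix(1, 3, 3)
  tie <- overlay_maps(list(mk(t1), mk(t2)), c("#111111", "#222222"))
  expect_true(all(tie == "#111111"))
  # masked spaxels are marked brown
  mm <- mk(a); mm$mask[3, 3] <- TRUE
  o2 <- overlay_maps(list(mm), "#FF0000")
  expect_equal(o2[3, 3], "#8B4513")
  bad <- structure(list(values = matrix(0, 2, 2), substance = "x", shift = 1,
                        mask = matrix(FALSE, 2, 2)), class = "chemical_map")
  expect_error(overlay_maps(list(mk(a), bad), c("#FF0000", "#00FF00")),
               class = "fibercube_validation_error")
})
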