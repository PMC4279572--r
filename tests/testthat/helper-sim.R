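# Desk-scale fixtures shared across the suite: a 30-fiber (5 x 6) bundle on
# a small detector so reduction tests run in well under a second each.

small_detector <- function() {
  detector_config(n_rows_px = 120L, n_cols_px = 200L, bias_level = 100,
                  read_noise = 3, gain = 1)
}

small_layout <- function(dead_fibers = NULL) {
  bundle_layout(5L, 6L, pitch_mm = 0.5, dead_fibers = dead_fibers)
}

small_setup <- function(n_fibers = 30L, seed = 1L) {
  det <- small_detector()
  list(det = det,
       traces = default_trace_model(n_fibers, det),
       dispersion = default_dispersion_model(n_fibers, det),
       bias0 = new_frame(matrix(det$bias_level, det$n_rows_px, det$n_cols_px),
                         "master-bias", 0),
       seed = seed)
}

small_config <- function(...) {
  cfg <- default_pipeline_config(
    layout = list(n_rows = 5L, n_cols = 6L, dead_fibers = list()),
    detector = list(n_rows_px = 120L, n_cols_px = 400L),
    axis = list(from = 400, to = 1400, by = 4),
    simulate = list(n_cosmics = 5L, phantom = "half_field"))
  cfg <- fibercube:::merge_config(cfg, list(...))
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

# connected components (4-neighbour) of a logical matrix: independent oracle
# for bead-phantom topology
count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  n <- 0L
  for (r in seq_len(nrow(mask))) for (cc in seq_len(ncol(mask))) {
    if (!mask[r, cc] || lab[r, cc] != 0L) next
    n <- n + 1L
    queue <- list(c(r, cc))
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      if (p[1] < 1 || p[1] > nrow(mask) || p[2] < 1 || p[2] > ncol(mask)) next
      if (!mask[p[1], p[2]] || lab[p[1], p[2]] != 0L) next
      lab[p[1], p[2]] <- n
      queue <- c(queue, list(p + c(1, 0)), list(p - c(1, 0)),
                 list(p + c(0, 1)), list(p - c(0, 1)))
    }
  }
  n
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

polyval_test <- function(coef, x) {
  y <- rep(0, length(x))
  for (k in rev(seq_along(coef))) y <- y * x + coef[k]
  y
}
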