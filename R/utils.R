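#' @keywords internal
"_PACKAGE"

# FWHM of a Gaussian = 2*sqrt(2*log(2)) * sigma
FWHM_FACTOR <- 2 * sqrt(2 * log(2))

sigma_from_fwhm <- function(fwhm) fwhm / FWHM_FACTOR

#' Derive a reproducible per-stage seed from a top-level seed
#'
#' All stochastic stages of the pipeline draw their seed from a single
#' top-level integer so that a run is reproducible end to end while
#' stages remain statistically independent.
#'
#' @param seed top-level integer seed.
#' @param stage stage name (character) or small integer index.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (is.character(stage)) {
    stage <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  }
  as.integer((as.double(seed) * 48271 + as.double(stage) * 7919) %% 2147483587)
}

# Evaluate per-seed RNG state locally, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Evaluate polynomial with ascending coefficients at x
polyval <- function(coef, x) {
  y <- rep(0, length(x))
  for (k in rev(seq_along(coef))) y <- y * x + coef[k]
  y
}

# Rescale x to [-1, 1] for numerically conditioned polynomial fits
rescale_unit <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(0, length(x)))
  2 * (x - r[1]) / (r[2] - r[1]) - 1
}

fc_abort <- function(msg, class) {
  stop(structure(class = c(class, "fibercube_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
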