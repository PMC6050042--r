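#' @keywords internal
"_PACKAGE"

#' @import stats
#' @import utils
NULL

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
# Every stochastic operation in the package funnels through this so that
# identical (arguments, seed) pairs give bit-identical output.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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

# Otsu's threshold on a numeric matrix (256-bin histogram between the
# observed min and max). Returns a value strictly separating the classes.
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  rng <- range(x, finite = TRUE)
  if (diff(rng) <= 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  # between-class variance; guard 0/0 at the tails
  denom <- w0 * (1 - w0)
  bcv <- (mu_t * w0 - mu0)^2 / ifelse(denom > 0, denom, Inf)
  breaks[which.max(bcv) + 1L]
}

# Population (divide-by-N) standard deviation.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

`%||%` <- function(a, b) if (is.null(a)) b else a
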