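# Seed plumbing: every stochastic entry point takes an integer seed and
# derives named substream seeds from it, so schedule, responses, attrition
# and questionnaire draws are independently reproducible.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards so library callers are unaffected.
#'
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a named substream seed
#'
#' Maps (root seed, stream name, index) to a deterministic 31-bit integer so
#' that distinct pipeline stages draw from unrelated streams.
#'
#' @param seed root integer seed.
#' @param stream character stream name, e.g. `"responses"`.
#' @param index optional integer index (participant or session number).
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, stream, index = 0L) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.double(seed %% m)
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% m
  h <- (h * 131 + as.double(index) %% m) %% m
  as.integer(h)
}

#' Sample from an ex-Gaussian distribution
#'
#' Sum of a Gaussian (`mu`, `sigma`) and an exponential with mean `tau`; the
#' standard positively skewed model for reaction-time data.
#'
#' @param n number of draws.
#' @param mu,sigma Gaussian component mean and SD (ms).
#' @param tau exponential component mean (ms).
#' @return numeric vector of length `n`.
#' @export
rexgauss <- function(n, mu, sigma, tau) {
  rnorm(n, mu, sigma) + rexp(n, rate = 1 / tau)
}

# Truncated ex-Gaussian on (lo, hi] by resampling; used for response
# latencies that must land within the stimulus display window.
rexgauss_trunc <- function(n, mu, sigma, tau, lo = 0, hi = 900) {
  x <- rexgauss(n, mu, sigma, tau)
  bad <- which(x <= lo | x > hi)
  guard <- 0L
  while (length(bad) > 0L) {
    x[bad] <- rexgauss(length(bad), mu, sigma, tau)
    bad <- bad[x[bad] <= lo | x[bad] > hi]
    guard <- guard + 1L
    if (guard > 1000L) stop("truncation bounds incompatible with parameters")
  }
  x
}

#' Half-up rounding for on-screen point display
#'
#' Scores are kept at full precision internally; this is the rounding the
#' task's score display applies.
#'
#' @param x numeric vector.
#' @return `x` rounded to the nearest integer, ties away from zero upward.
#' @export
round_half_up <- function(x) floor(x + 0.5)
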