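# Internal helpers shared across modules.

#' Derive a child seed for a named generator stream
#'
#' Every generator draws from its own stream derived from the master seed by
#' a fixed hash of the stream name, so any module can be regenerated
#' independently of the others while staying fully deterministic.
#'
#' @param seed master seed (single integer).
#' @param stream stream name, e.g. `"annotation"`.
#' @return an integer seed below 2^31.
#' @keywords internal
.childSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(stream) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483629)
}

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

# Negative-binomial draw parameterised by mean and dispersion alpha, with
# var = mu + alpha * mu^2; alpha = 0 collapses to Poisson.
.rcounts <- function(n, mu, dispersion) {
  if (dispersion == 0) rpois(n, lambda = mu)
  else rnbinom(n, mu = mu, size = 1 / dispersion)
}

.assertScalarNumber <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name,
                 format(min), format(max)), call. = FALSE)
  invisible(x)
}
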