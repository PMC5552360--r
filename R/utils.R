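# internal numerical helpers

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Derive a child seed from a master seed
#'
#' Deterministic integer hash used to give every consumer of randomness
#' (trajectory noise, observation noise, each likelihood evaluation, each
#' sampler) its own stream, all reproducible from one master seed. The
#' result is always in `[1, 2^31 - 2]`.
#'
#' @param seed master seed (integer).
#' @param ... further integer labels identifying the consumer.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, ...) {
  ids <- c(seed, ...)
  h <- 0
  for (v in ids) h <- (h * 69069 + as.numeric(v) + 12345) %% 2147483629
  as.integer(h + 1)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# run expr with R's RNG seeded at `seed`, restoring the caller's stream
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  expr
}

# log-density of a multivariate normal via the Cholesky factor
dmvnorm_log <- function(x, mu, Sigma) {
  L <- chol(Sigma)
  d <- length(mu)
  z <- backsolve(L, x - mu, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z^2)
}
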