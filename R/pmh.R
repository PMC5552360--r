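# Particle Metropolis-Hastings: pseudo-marginal MCMC over the unknown
# parameters, with the bootstrap-filter likelihood estimate standing in
# for the intractable marginal likelihood.

#' PMH sampler configuration
#'
#' @param L chain length (even, >= 2).
#' @param scale2 kernel scale sigma^2 of the truncated Gaussian random-walk
#'   proposal. The tuned values are 0.1 for data from stochastic
#'   trajectories and 0.04 for data from deterministic trajectories.
#' @param diag per-parameter variance multipliers; the proposal covariance
#'   is `scale2 * diag(diag)`. The large entry belongs to alpha, whose
#'   support is 250 units wide.
#' @param n_particles particles for the likelihood estimate.
#' @param seed master seed of the run.
#' @return A list of class `pmh_config`.
#' @export
pmh_config <- function(L = 4000, scale2 = 0.1,
                       diag = c(Q = 0.01, m = 0.01, alpha = 100,
                                beta_a = 0.01),
                       n_particles = 100, seed = 1) {
  stopifnot(L >= 2, L %% 2 == 0, scale2 > 0, all(diag > 0),
            length(diag) == 4, n_particles >= 1)
  structure(list(L = as.integer(L), scale2 = scale2, diag = diag,
                 n_particles = as.integer(n_particles), seed = seed),
            class = "pmh_config")
}

proposal_sds <- function(cfg) sqrt(cfg$scale2 * cfg$diag)

#' Draw a candidate from the truncated Gaussian random-walk kernel
#'
#' Gaussian centred at `theta_prev` with diagonal covariance
#' `scale2 * diag`, truncated to the prior support box by rejection.
#'
#' @param theta_prev current parameter vector (must lie in the support).
#' @param cfg a [pmh_config()].
#' @return A parameter vector inside the support. Uses R's global RNG.
#' @export
propose <- function(theta_prev, cfg) {
  if (!in_support(theta_prev)) stop("theta_prev outside the support")
  sds <- proposal_sds(cfg)
  for (i in seq_len(1e6)) {
    cand <- theta_prev + rnorm(4, 0, sds)
    if (in_support(cand)) {
      names(cand) <- names(theta_prev)
      return(cand)
    }
  }
  stop("proposal kernel scale grossly inconsistent with the support set")
}

#' Log-density of the truncated Gaussian proposal kernel
#'
#' Includes the centre-dependent normalisation over the support box,
#' which for a diagonal covariance is the product of four univariate
#' Gaussian interval probabilities. Needed because the truncated kernel is
#' not symmetric near the support boundary.
#'
#' @param theta_to evaluated point (in the support).
#' @param theta_from kernel centre (in the support).
#' @param cfg a [pmh_config()].
#' @return The log-density.
#' @export
kernel_logdensity <- function(theta_to, theta_from, cfg) {
  if (!in_support(theta_to) || !in_support(theta_from))
    stop("kernel density requested outside the support")
  sds <- proposal_sds(cfg)
  s <- theta_support()
  lo <- s["lower", ]; hi <- s["upper", ]
  mass <- pnorm(hi, theta_from, sds) - pnorm(lo, theta_from, sds)
  sum(dnorm(theta_to, theta_from, sds, log = TRUE)) - sum(log(mass))
}

#' Metropolis-Hastings acceptance probability
#'
#' Standard pseudo-marginal ratio: target is likelihood times prior, with
#' the backward/forward kernel correction. A degenerate (`-Inf`) candidate
#' log-likelihood yields probability zero.
#'
#' @param loglik_new,loglik_old log likelihood estimates.
#' @param logprior_new,logprior_old log prior densities.
#' @param logkernel_fwd log kernel density of candidate given current.
#' @param logkernel_bwd log kernel density of current given candidate.
#' @return Acceptance probability in `[0, 1]`.
#' @export
acceptance_prob <- function(loglik_new, loglik_old, logprior_new,
                            logprior_old, logkernel_fwd, logkernel_bwd) {
  if (!is.finite(loglik_new)) return(0)
  lr <- (loglik_new + logprior_new + logkernel_bwd) -
    (loglik_old + logprior_old + logkernel_fwd)
  min(1, exp(lr))
}

#' Run the particle Metropolis-Hastings sampler
#'
#' The chain starts from a prior draw; at every step a candidate is drawn
#' from the truncated Gaussian kernel, its likelihood is estimated with a
#' fresh bootstrap-filter seed, and the move is accepted with the
#' pseudo-marginal probability. The stored likelihood estimate of the
#' current state is retained across rejections.
#'
#' @param y a `repress_obs` object (or observation matrix).
#' @param cfg a [pmh_config()].
#' @param model a [repress_model()] describing the inference model.
#' @param loglik_fn optional replacement likelihood: `function(theta, seed)`
#'   returning a log-likelihood value. Used for validation against models
#'   with tractable likelihoods; when supplied, `y` and `model` are not
#'   touched.
#' @param theta0 optional starting point (defaults to a prior draw).
#' @return A list of class `pmh_result`: `chain` (L x 4 matrix),
#'   `accepted` (logical, length L, first element NA), `loglik_trace`,
#'   `acc_rate` and `cfg`.
#' @export
run_pmh <- function(y, cfg, model = repress_model(), loglik_fn = NULL,
                    theta0 = NULL) {
  if (is.null(loglik_fn)) {
    loglik_fn <- function(theta, seed) {
      bf_loglik(theta, y, model, cfg$n_particles, seed)$log_value
    }
  }
  with_seed(derive_seed(cfg$seed, 7L), {
    L <- cfg$L
    chain <- matrix(NA_real_, L, 4,
                    dimnames = list(NULL, c("Q", "m", "alpha", "beta_a")))
    accepted <- rep(NA, L)
    ll_trace <- numeric(L)
    theta <- if (is.null(theta0)) sample_prior() else theta0
    ll <- loglik_fn(theta, derive_seed(cfg$seed, 11L, 0L))
    chain[1, ] <- theta
    ll_trace[1] <- ll
    for (k in 2:L) {
      cand <- propose(theta, cfg)
      ll_cand <- loglik_fn(cand, derive_seed(cfg$seed, 11L, k))
      ap <- acceptance_prob(ll_cand, ll, log_prior(cand), log_prior(theta),
                            kernel_logdensity(cand, theta, cfg),
                            kernel_logdensity(theta, cand, cfg))
      if (runif(1) < ap) {
        theta <- cand
        ll <- ll_cand
        accepted[k] <- TRUE
      } else {
        accepted[k] <- FALSE
      }
      chain[k, ] <- theta
      ll_trace[k] <- ll
    }
    structure(list(chain = chain, accepted = accepted,
                   loglik_trace = ll_trace,
                   acc_rate = mean(accepted[-1]), cfg = cfg),
              class = "pmh_result")
  })
}

#' Posterior estimates from a PMH chain
#'
#' Sample mean and covariance computed from the second half of the chain
#' only; the first half is discarded as burn-in.
#'
#' @param res a `pmh_result`.
#' @return A list with `mean` (named 4-vector) and `cov` (4 x 4 matrix).
#' @export
pmh_estimates <- function(res) {
  L <- nrow(res$chain)
  half <- res$chain[(L / 2 + 1):L, , drop = FALSE]
  mu <- colMeans(half)
  centred <- sweep(half, 2, mu)
  list(mean = mu, cov = crossprod(centred) / nrow(half))
}

#' @export
print.pmh_result <- function(x, ...) {
  est <- pmh_estimates(x)
  cat("<pmh_result> L =", nrow(x$chain),
      " acceptance rate =", signif(x$acc_rate, 3), "\n",
      " posterior mean (burn-in half discarded):",
      paste(signif(est$mean, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.pmh_result <- function(x, ...) {
  data.frame(step = seq_len(nrow(x$chain)), x$chain,
             accepted = x$accepted, loglik = x$loglik_trace)
}
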