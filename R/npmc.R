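# Nonlinear population Monte Carlo: iterated importance sampling whose
# Gaussian proposals are adapted from clipped ("transformed") importance
# weights, mitigating weight degeneracy.

#' NPMC sampler configuration
#'
#' @param M samples per iteration.
#' @param K number of adaptation iterations.
#' @param Mc clipping parameter, `1 <= Mc <= M`; the default
#'   `floor(sqrt(M))` is the largest value guaranteeing asymptotic
#'   convergence of TIW-based estimators.
#' @param n_particles particles for the likelihood estimate.
#' @param seed master seed.
#' @return A list of class `npmc_config`.
#' @export
npmc_config <- function(M = 200, K = 20, Mc = floor(sqrt(M)),
                        n_particles = 100, seed = 1) {
  stopifnot(M >= 1, K >= 1, Mc >= 1, Mc <= M, n_particles >= 1)
  structure(list(M = as.integer(M), K = as.integer(K), Mc = as.integer(Mc),
                 n_particles = as.integer(n_particles), seed = seed),
            class = "npmc_config")
}

#' Clip importance weights
#'
#' The clipping transformation flattens the `Mc` largest raw importance
#' weights to the value of the `Mc`-th largest; all smaller weights are
#' left unchanged. Ties are broken by original index (stable order).
#'
#' When fewer than `Mc` weights are positive the literal rule would
#' flatten every positive weight to zero and annihilate the ensemble;
#' in that case the positive weights among the top `Mc` are flattened to
#' the smallest positive one instead.
#'
#' @param raw non-negative raw importance weights.
#' @param Mc clipping parameter, `1 <= Mc <= length(raw)`.
#' @return The clipped weight vector, same length and order as `raw`.
#' @export
clip_weights <- function(raw, Mc) {
  M <- length(raw)
  if (Mc < 1 || Mc > M) stop("Mc must lie in [1, length(raw)]")
  stopifnot(all(raw >= 0))
  ord <- order(raw, seq_len(M), decreasing = TRUE)
  thresh <- raw[ord[Mc]]
  if (thresh == 0 && any(raw > 0)) thresh <- min(raw[raw > 0])
  out <- raw
  out[ord[seq_len(Mc)]] <- pmin(raw[ord[seq_len(Mc)]], thresh)
  out
}

#' Fit the Gaussian proposal from a weighted ensemble
#'
#' Weighted mean and weighted covariance of the samples under the
#' normalised (clipped) weights. If the covariance is numerically
#' singular, a jitter of `1e-8 * (support width)^2` per diagonal element
#' is added so the proposal stays proper.
#'
#' @param samples M x 4 matrix of parameter vectors.
#' @param norm_weights normalised weights (sum to 1).
#' @return A list with `mu` (4-vector) and `Sigma` (4 x 4 matrix).
#' @export
fit_proposal <- function(samples, norm_weights) {
  samples <- as.matrix(samples)
  stopifnot(abs(sum(norm_weights) - 1) < 1e-8)
  mu <- colSums(samples * norm_weights)
  centred <- sweep(samples, 2, mu)
  Sigma <- crossprod(centred * norm_weights, centred)
  Sigma <- (Sigma + t(Sigma)) / 2
  if (inherits(try(chol(Sigma), silent = TRUE), "try-error")) {
    s <- theta_support()
    widths <- s["upper", ] - s["lower", ]
    Sigma <- Sigma + diag(1e-8 * widths^2)
  }
  list(mu = mu, Sigma = Sigma)
}

new_ensemble <- function(samples, log_raw, Mc, k) {
  # raw weights are carried as shifted exponentials of the log weights;
  # clipping and normalisation are invariant to the common scale factor
  finite <- is.finite(log_raw)
  if (!any(finite))
    stop("degenerate NPMC iteration ", k,
         ": all raw weights are zero; increase N or M")
  raw <- exp(log_raw - max(log_raw[finite]))
  raw[!finite] <- 0
  clipped <- clip_weights(raw, Mc)
  structure(list(samples = samples, raw_weights = raw,
                 clipped_weights = clipped,
                 norm_weights = clipped / sum(clipped), k = k),
            class = "npmc_ensemble")
}

#' One NPMC iteration
#'
#' For `k = 0`, draws from the uniform prior and weights by the likelihood
#' estimate alone (the prior density cancels). For `k >= 1`, fits a
#' Gaussian proposal to the previous ensemble, draws from it, and computes
#' raw importance weights `l^N(y | theta) p0(theta) / q_k(theta)`; samples
#' falling outside the prior support get raw weight zero. Raw weights are
#' then clipped and normalised.
#'
#' @param prev previous `npmc_ensemble`, or `NULL` for the initial
#'   iteration.
#' @param y observation record (passed to the likelihood).
#' @param cfg an [npmc_config()].
#' @param model a [repress_model()].
#' @param loglik_fn optional replacement likelihood `function(theta, seed)`.
#' @param k iteration index (0 for initialisation).
#' @return An `npmc_ensemble`: `samples`, `raw_weights`, `clipped_weights`,
#'   `norm_weights`, `k`.
#' @export
npmc_iteration <- function(prev, y, cfg, model = repress_model(),
                           loglik_fn = NULL, k = if (is.null(prev)) 0L
                           else prev$k + 1L) {
  if (is.null(loglik_fn)) {
    loglik_fn <- function(theta, seed) {
      bf_loglik(theta, y, model, cfg$n_particles, seed)$log_value
    }
  }
  M <- cfg$M
  with_seed(derive_seed(cfg$seed, 13L, k), {
    if (is.null(prev)) {
      samples <- sample_prior(M)
      if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1)
      log_q <- rep(0, M)  # cancels against the prior for k = 0
      log_p0 <- rep(0, M)
    } else {
      prop <- fit_proposal(prev$samples, prev$norm_weights)
      samples <- MASS::mvrnorm(M, prop$mu, prop$Sigma)
      if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1)
      colnames(samples) <- c("Q", "m", "alpha", "beta_a")
      log_q <- apply(samples, 1, dmvnorm_log, mu = prop$mu,
                     Sigma = prop$Sigma)
      log_p0 <- apply(samples, 1, log_prior)
    }
    log_raw <- vapply(seq_len(M), function(i) {
      if (!is.finite(log_p0[i])) return(-Inf)
      ll <- loglik_fn(samples[i, ], derive_seed(cfg$seed, 17L, k, i))
      ll + log_p0[i] - log_q[i]
    }, numeric(1))
    new_ensemble(samples, log_raw, cfg$Mc, k)
  })
}

#' Run the NPMC sampler
#'
#' Initialisation from the prior followed by `K` adaptation iterations.
#'
#' @inheritParams npmc_iteration
#' @return A list of class `npmc_result` holding `K + 1` ensembles
#'   (element 1 is the initialisation, element `K + 1` the final
#'   iteration) and the configuration.
#' @export
run_npmc <- function(y, cfg, model = repress_model(), loglik_fn = NULL) {
  ensembles <- vector("list", cfg$K + 1)
  ensembles[[1]] <- npmc_iteration(NULL, y, cfg, model, loglik_fn)
  for (k in seq_len(cfg$K)) {
    ensembles[[k + 1]] <- npmc_iteration(ensembles[[k]], y, cfg, model,
                                         loglik_fn)
  }
  structure(list(ensembles = ensembles, cfg = cfg), class = "npmc_result")
}

#' Posterior estimates from an NPMC ensemble
#'
#' Mean and covariance under the normalised transformed (clipped)
#' importance weights.
#'
#' @param ensemble an `npmc_ensemble` (e.g. the last element of a run).
#' @return A list with `mean` and `cov`.
#' @export
npmc_estimates <- function(ensemble) {
  w <- ensemble$norm_weights
  mu <- colSums(ensemble$samples * w)
  centred <- sweep(ensemble$samples, 2, mu)
  list(mean = mu, cov = crossprod(centred * w, centred))
}

#' @export
print.npmc_result <- function(x, ...) {
  est <- npmc_estimates(x$ensembles[[length(x$ensembles)]])
  cat("<npmc_result> M =", x$cfg$M, " K =", x$cfg$K, " Mc =", x$cfg$Mc, "\n",
      " final posterior mean:", paste(signif(est$mean, 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
as.data.frame.npmc_result <- function(x, ...) {
  do.call(rbind, lapply(x$ensembles, function(e) {
    data.frame(iteration = e$k, sample = seq_len(nrow(e$samples)),
               e$samples, raw_weight = e$raw_weights,
               clipped_weight = e$clipped_weights,
               norm_weight = e$norm_weights)
  }))
}
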