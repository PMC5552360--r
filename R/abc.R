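# Likelihood-free ABC sequential Monte Carlo over the unknown parameters,
# with a decreasing tolerance schedule and the quadratic data distance.

#' ABC-SMC configuration
#'
#' The final tolerance is limited from below by the observation-noise
#' power: with the quadratic distance, the expected distance between two
#' records generated from the same parameters and the same initial
#' condition converges to `2 * sigma_y^2`, so a schedule ending at or
#' below that floor cannot fill its last population.
#'
#' @param tolerances strictly decreasing positive tolerances, one per
#'   population.
#' @param J target accepted samples per population.
#' @param max_draws_factor cap on candidate draws per population, as a
#'   multiple of `J`; a population is closed (possibly short) when
#'   `max_draws_factor * J` draws have been tried.
#' @param kernel_scale multiplier on the weighted per-parameter standard
#'   deviation of the previous population, giving the std of the
#'   component-wise Gaussian perturbation kernel.
#' @param seed master seed.
#' @param sigma_y observation-noise std used only for the schedule check.
#' @return A list of class `abc_config`.
#' @export
abc_config <- function(tolerances = c(3.0, 2.4, 2.3, 2.2, 2.1), J = 800,
                       max_draws_factor = 4000, kernel_scale = sqrt(2),
                       seed = 1, sigma_y = 1) {
  stopifnot(all(tolerances > 0), all(diff(tolerances) < 0), J >= 1,
            max_draws_factor >= 1, kernel_scale > 0)
  if (min(tolerances) <= 2 * sigma_y^2)
    warning("final tolerance does not exceed the observation-noise floor ",
            "2 * sigma_y^2 = ", 2 * sigma_y^2,
            "; the last population is unreachable on long records")
  structure(list(tolerances = tolerances, J = as.integer(J),
                 max_draws_factor = max_draws_factor,
                 kernel_scale = kernel_scale, seed = seed),
            class = "abc_config")
}

#' Quadratic distance between observation records
#'
#' Mean over observation times of the squared Euclidean norm of the
#' difference between the two 2-dimensional records.
#'
#' @param y,y_sim `repress_obs` objects or `n x 2` matrices of equal length.
#' @return A non-negative scalar.
#' @export
abc_distance <- function(y, y_sim) {
  a <- if (inherits(y, "repress_obs")) y$y else as.matrix(y)
  b <- if (inherits(y_sim, "repress_obs")) y_sim$y else as.matrix(y_sim)
  if (!all(dim(a) == dim(b))) stop("observation records differ in length")
  mean(rowSums((a - b)^2))
}

#' Simulate a synthetic observation record for ABC
#'
#' Runs the state equations from the fixed initial condition and reads the
#' observable components (a1, a2) at the observation times, without adding
#' observation noise. (Only the noiseless read-out makes the quadratic
#' distance converge to the `2 * sigma_y^2` floor; a noisy one would
#' converge to `4 * sigma_y^2`.) Dynamical noise follows `model$noise`:
#' fresh realisation per candidate in the stochastic regime, none in the
#' deterministic regime.
#'
#' @param theta candidate parameter vector.
#' @param x0 fixed initial state (the true realised initial condition of
#'   the data-generating run).
#' @param model a [repress_model()].
#' @param seed integer seed for the dynamical noise.
#' @return An `n_obs x 2` matrix, or `NULL` if the integration blew up
#'   (the candidate is then treated as rejected).
#' @export
simulate_synthetic <- function(theta, x0, model = repress_model(), seed = 1) {
  if (!in_support(theta)) stop("theta outside the support")
  check_state(x0)
  out <- synth_obs_cpp(as.numeric(x0), model$grid$n_obs, model$grid$m0,
                       full_pars(theta, model$fixed), unname(model$noise),
                       model$grid$h, model$noise_convention == "literal",
                       seed)
  if (nrow(out) == 0) return(NULL)
  colnames(out) <- c("a1", "a2")
  out
}

#' Importance weight of an accepted ABC sample
#'
#' Population 1 samples get weight 1. Later populations get
#' `p0(theta) / sum_l w_l K_t(theta | theta_l)`, the prior density over
#' the mixture density of the perturbation kernel centred at the previous
#' population.
#'
#' @param theta accepted parameter vector.
#' @param prev_samples previous population's samples (matrix).
#' @param prev_weights previous population's normalised weights.
#' @param kernel_sd per-parameter std of the Gaussian perturbation kernel.
#' @param t population index (1-based).
#' @return The raw (unnormalised) weight.
#' @export
abc_weight <- function(theta, prev_samples = NULL, prev_weights = NULL,
                       kernel_sd = NULL, t = 1) {
  if (t <= 1) return(1)
  dens <- vapply(seq_len(nrow(prev_samples)), function(l) {
    prod(dnorm(theta, prev_samples[l, ], kernel_sd))
  }, numeric(1))
  denom <- sum(prev_weights * dens)
  if (denom <= 0) stop("degenerate ABC mixture density (zero denominator)")
  exp(log_prior(theta)) / denom
}

weighted_sd <- function(x, w) {
  mu <- sum(w * x)
  sqrt(max(sum(w * (x - mu)^2), 0))
}

#' Run the ABC sequential Monte Carlo sampler
#'
#' Population 1 is filled with prior draws whose synthetic records fall
#' within the first tolerance; each later population draws candidates from
#' the weighted mixture of component-wise Gaussian kernels centred at the
#' previous population, rejects candidates outside the prior support or
#' beyond the current tolerance, and weights acceptances by
#' [abc_weight()]. A population is closed early (possibly with fewer than
#' `J` members) once `max_draws_factor * J` candidates have been tried.
#'
#' @param y the observed record (`repress_obs` or matrix).
#' @param cfg an [abc_config()].
#' @param model a [repress_model()]; `model$noise` decides whether the
#'   synthetic records carry dynamical noise.
#' @param x0 fixed initial state of the data-generating run.
#' @return A list of class `abc_result`: `populations` (one list per
#'   tolerance with `samples`, `weights`, `distances`, `draws_used`,
#'   `accept_rate`, `t`) and `cfg`.
#' @export
run_abc_smc <- function(y, cfg, model = repress_model(), x0) {
  ym <- if (inherits(y, "repress_obs")) y$y else as.matrix(y)
  T_pop <- length(cfg$tolerances)
  populations <- vector("list", T_pop)
  prev <- NULL
  for (t in seq_len(T_pop)) {
    eps <- cfg$tolerances[t]
    if (!is.null(prev)) {
      kernel_sd <- cfg$kernel_scale *
        vapply(1:4, function(j) weighted_sd(prev$samples[, j], prev$weights),
               numeric(1))
      kernel_sd <- pmax(kernel_sd, 1e-12)
    }
    samples <- matrix(NA_real_, cfg$J, 4,
                      dimnames = list(NULL, c("Q", "m", "alpha", "beta_a")))
    raw_w <- numeric(cfg$J)
    dists <- numeric(cfg$J)
    accepted <- 0L
    draws <- 0L
    cap <- as.integer(cfg$max_draws_factor * cfg$J)
    with_seed(derive_seed(cfg$seed, 19L, t), {
      while (accepted < cfg$J && draws < cap) {
        draws <- draws + 1L
        if (t == 1) {
          cand <- sample_prior()
        } else {
          l <- sample.int(nrow(prev$samples), 1, prob = prev$weights)
          cand <- prev$samples[l, ] + rnorm(4, 0, kernel_sd)
          names(cand) <- c("Q", "m", "alpha", "beta_a")
          if (!in_support(cand)) next  # prior density zero
        }
        # on-the-fly distance with early stopping at eps (exact accept/
        # reject decisions; blow-ups come back as Inf)
        d <- abc_sim_distance_cpp(ym, as.numeric(x0), model$grid$m0,
                                  full_pars(cand, model$fixed),
                                  unname(model$noise), model$grid$h,
                                  model$noise_convention == "literal",
                                  derive_seed(cfg$seed, 23L, t, draws), eps)
        if (d < eps) {
          accepted <- accepted + 1L
          samples[accepted, ] <- cand
          dists[accepted] <- d
          raw_w[accepted] <- if (t == 1) 1 else
            abc_weight(cand, prev$samples, prev$weights, kernel_sd, t)
        }
      }
    })
    if (accepted == 0L)
      stop("ABC schedule error: no acceptances for tolerance eps_", t,
           " = ", eps, " within the draw cap")
    samples <- samples[seq_len(accepted), , drop = FALSE]
    raw_w <- raw_w[seq_len(accepted)]
    prev <- list(samples = samples, weights = raw_w / sum(raw_w),
                 distances = dists[seq_len(accepted)],
                 draws_used = draws, accept_rate = accepted / draws,
                 t = t)
    populations[[t]] <- prev
  }
  structure(list(populations = populations, cfg = cfg),
            class = "abc_result")
}

#' Posterior point estimate from an ABC population
#'
#' Weighted mean of the (final) population.
#'
#' @param pop one population of an `abc_result` (default usage:
#'   `abc_estimate(res$populations[[length(res$populations)]])`).
#' @return A named 4-component parameter estimate.
#' @export
abc_estimate <- function(pop) {
  if (length(pop$weights) == 0) stop("empty ABC population")
  colSums(pop$samples * pop$weights)
}

#' Minimum achievable acceptance rate under the draw cap
#'
#' A population closed at the cap with a single acceptance has rate
#' `1 / max_draws_factor`.
#'
#' @param cfg an [abc_config()].
#' @return The minimum acceptance rate.
#' @export
abc_min_accept_rate <- function(cfg = abc_config()) {
  1 / cfg$max_draws_factor
}

#' @export
print.abc_result <- function(x, ...) {
  last <- x$populations[[length(x$populations)]]
  cat("<abc_result>", length(x$populations), "populations;",
      "final population:", nrow(last$samples), "samples,",
      "acceptance rate", signif(last$accept_rate, 3), "\n",
      " estimate:", paste(signif(abc_estimate(last), 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
as.data.frame.abc_result <- function(x, ...) {
  do.call(rbind, lapply(x$populations, function(p) {
    data.frame(population = p$t, sample = seq_len(nrow(p$samples)),
               p$samples, weight = p$weights, distance = p$distances)
  }))
}
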