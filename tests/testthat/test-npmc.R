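test_that("clipping flattens exactly the Mc largest weights", {
  expect_equal(clip_weights(c(5, 4, 3, 2, 1), 2), c(4, 4, 3, 2, 1))
  expect_equal(clip_weights(c(5, 4, 3, 2, 1), 1), c(5, 4, 3, 2, 1))
  expect_equal(clip_weights(rep(2, 6), 4), rep(2, 6))
  expect_error(clip_weights(c(1, 2), 3), "Mc")
  # sparse ensembles survive: a single positive weight is not zeroed out
  # even when the Mc-th largest weight is 0
  expect_equal(clip_weights(c(0, 0, 7, 0, 0), 2), c(0, 0, 7, 0, 0))
  expect_equal(clip_weights(c(0, 5, 2, 0, 0), 3), c(0, 2, 2, 0, 0))
  # order of sub-threshold weights is untouched
  set.seed(3)
  for (i in 1:20) {
    raw <- rexp(30)
    Mc <- sample(1:30, 1)
    cl <- clip_weights(raw, Mc)
    thresh <- sort(raw, decreasing = TRUE)[Mc]
    below <- raw < thresh
    expect_identical(cl[below], raw[below])
    expect_true(all(cl <= thresh + 1e-12))
  }
})

test_that("normalised clipped weights obey the 1/Mc bound", {
  set.seed(11)
  for (i in 1:20) {
    M <- sample(20:200, 1)
    Mc <- floor(sqrt(M))
    raw <- rexp(M)^3  # heavy-tailed, prone to degeneracy
    w <- clip_weights(raw, Mc)
    nw <- w / sum(w)
    expect_true(all(nw <= 1 / Mc + 1e-12))
    # clipping never increases the weight variance
    expect_lte(var(nw), var(raw / sum(raw)) + 1e-15)
  }
})

test_that("proposal fit is the weighted mean and covariance", {
  s1 <- c(0.8, 2, 200, 0.8)
  s2 <- c(0.9, 2, 200, 0.8)
  fit <- fit_proposal(rbind(s1, s2), c(0.5, 0.5))
  expect_equal(unname(fit$mu), c(0.85, 2, 200, 0.8))
  expect_equal(fit$Sigma[1, 1], 0.0025, tolerance = 1e-4)
  expect_true(all(abs(fit$Sigma[-1, -1]) <= 1e-8 * 250^2))
  # concentrated weights: mean collapses onto the dominant sample
  fit2 <- fit_proposal(rbind(s1, s2), c(1 - 1e-12, 1e-12))
  expect_equal(unname(fit2$mu), s1, tolerance = 1e-6)
  # single sample: jittered identity keeps the proposal proper
  fit3 <- fit_proposal(matrix(s1, 1), 1)
  expect_true(all(diag(fit3$Sigma) > 0))
  expect_silent(chol(fit3$Sigma))
})

test_that("constant likelihood gives uniform weights and prior recovery", {
  cfg <- npmc_config(M = 400, K = 3, seed = 2)
  flat <- function(theta, seed) 0
  e0 <- npmc_iteration(NULL, NULL, cfg, loglik_fn = flat)
  expect_equal(e0$norm_weights, rep(1 / 400, 400))
  expect_equal(sum(e0$norm_weights), 1, tolerance = 1e-12)
  res <- run_npmc(NULL, cfg, loglik_fn = flat)
  last <- res$ensembles[[4]]
  est <- npmc_estimates(last)
  prior_sd <- c(1, 4, 250, 1) / sqrt(12)
  expect_true(all(abs(est$mean - c(0.5, 3, 175, 0.5)) <
                    4 * prior_sd / sqrt(400 / 4)))
})

test_that("ensemble weights are normalised and supported samples retained", {
  ds <- desk_dataset()
  cfg <- npmc_config(M = 30, K = 2, n_particles = 20, seed = 6)
  res <- run_npmc(ds$obs, cfg, ds$model)
  expect_length(res$ensembles, 3)
  for (e in res$ensembles) {
    expect_equal(sum(e$norm_weights), 1, tolerance = 1e-12)
    keep <- e$norm_weights > 0
    expect_true(all(apply(e$samples[keep, , drop = FALSE], 1, in_support)))
    # clipping reduces (or preserves) the normalised-weight variance
    expect_lte(var(e$norm_weights),
               var(e$raw_weights / sum(e$raw_weights)) + 1e-15)
  }
  # reproducibility from the master seed
  res2 <- run_npmc(ds$obs, cfg, ds$model)
  expect_identical(res$ensembles[[3]]$samples, res2$ensembles[[3]]$samples)
})

test_that("NPMC reproduces the conjugate-toy posterior", {
  set.seed(72)
  y_toy <- rnorm(25, 0.55, 0.3)
  post_mean <- mean(y_toy)
  post_var <- 0.3^2 / 25
  cfg <- npmc_config(M = 300, K = 5, seed = 8)
  res <- run_npmc(NULL, cfg, loglik_fn = toy_loglik_factory(y_toy, 0.3))
  last <- res$ensembles[[6]]
  est <- npmc_estimates(last)
  ess <- 1 / sum(last$norm_weights^2)
  se <- sqrt(post_var / ess)
  expect_lt(abs(est$mean[["Q"]] - post_mean), 3 * se)
  expect_equal(est$cov[1, 1], post_var, tolerance = 0.5)
})

test_that("estimates are the TIW-weighted moments", {
  samples <- rbind(theta_vector(0.2, 2, 100, 0.3),
                   theta_vector(0.4, 3, 150, 0.5),
                   theta_vector(0.8, 4, 200, 0.7))
  ens <- list(samples = samples, norm_weights = c(0.5, 0.3, 0.2))
  est <- npmc_estimates(ens)
  expect_equal(est$mean[["Q"]], 0.5 * 0.2 + 0.3 * 0.4 + 0.2 * 0.8)
  # point mass: zero covariance
  ens2 <- list(samples = samples, norm_weights = c(1, 0, 0))
  expect_equal(npmc_estimates(ens2)$mean, samples[1, ])
  expect_true(all(npmc_estimates(ens2)$cov == 0))
  # uniform weights: population moments
  ens3 <- list(samples = samples, norm_weights = rep(1 / 3, 3))
  expect_equal(npmc_estimates(ens3)$mean, colMeans(samples))
})
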