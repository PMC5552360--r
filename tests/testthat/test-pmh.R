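test_that("proposals stay in the support and have the configured spread", {
  cfg <- pmh_config(L = 100, scale2 = 0.1,
                    diag = c(0.01, 0.01, 100, 0.01), seed = 1)
  centre <- theta_vector(0.5, 3, 175, 0.5)
  set.seed(23)
  draws <- t(replicate(1e4, propose(centre, cfg)))
  s <- theta_support()
  expect_true(all(draws > rep(s["lower", ], each = 1e4)))
  expect_true(all(draws < rep(s["upper", ], each = 1e4)))
  # alpha std = sqrt(0.1 * 100) = sqrt(10), centre deep in the interior
  expect_equal(sd(draws[, "alpha"]), sqrt(10), tolerance = 0.05)

  # vanishing scale pins the proposal at the centre
  tiny <- pmh_config(L = 2, scale2 = 1e-18)
  expect_equal(propose(centre, tiny), centre, tolerance = 1e-8)
})

test_that("truncated-kernel log-density normalises over the support box", {
  cfg <- pmh_config(L = 2, scale2 = 0.1)
  u <- theta_vector(0.5, 3, 175, 0.5)
  v <- theta_vector(0.55, 3.1, 180, 0.45)
  # interior: truncation mass negligible, matches the plain Gaussian
  sds <- sqrt(cfg$scale2 * cfg$diag)
  expect_equal(kernel_logdensity(v, u, cfg),
               sum(dnorm(v, u, sds, log = TRUE)), tolerance = 1e-6)
  expect_equal(kernel_logdensity(u, v, cfg), kernel_logdensity(v, u, cfg),
               tolerance = 1e-6)

  # near-boundary centre: normalisation equals the quadrature of the
  # truncated density over the support
  centre <- theta_vector(0.01, 3, 175, 0.5)
  at <- theta_vector(0.2, 3, 175, 0.5)
  num_norm <- prod(vapply(1:4, function(j) {
    s <- theta_support()
    integrate(function(x) dnorm(x, centre[j], sds[j]),
              s["lower", j], s["upper", j])$value
  }, numeric(1)))
  expect_equal(kernel_logdensity(at, centre, cfg),
               sum(dnorm(at, centre, sds, log = TRUE)) - log(num_norm),
               tolerance = 1e-6)
  expect_error(kernel_logdensity(theta_vector(2, 3, 175, 0.5), u, cfg),
               "support")
})

test_that("acceptance probability implements the pseudo-marginal ratio", {
  expect_equal(acceptance_prob(-5, -5, 1, 1, 2, 2), 1)
  expect_equal(acceptance_prob(log(2), log(1), 0, 0, 0, 0), 1)
  expect_equal(acceptance_prob(log(0.5), log(1), 0, 0, 0, 0), 0.5)
  expect_equal(acceptance_prob(-Inf, -5, 0, 0, 0, 0), 0)
})

test_that("chain estimates use only the second half of the chain", {
  u <- theta_vector(0.4, 2, 100, 0.4)
  v <- theta_vector(0.6, 4, 200, 0.6)
  chain <- rbind(matrix(runif(8 * 4), 8, 4),
                 do.call(rbind, rep(list(u, v), 4)))
  colnames(chain) <- c("Q", "m", "alpha", "beta_a")
  res <- structure(list(chain = chain), class = "pmh_result")
  est <- pmh_estimates(res)
  expect_equal(est$mean, (u + v) / 2)
  expect_equal(est$cov, outer((u - v) / 2, (u - v) / 2),
               ignore_attr = TRUE)
  # first half is ignored entirely
  res$chain[1:8, ] <- 99
  expect_equal(pmh_estimates(res), est)
  # constant chain: zero covariance
  const <- structure(list(chain = do.call(rbind, rep(list(u), 10))),
                     class = "pmh_result")
  expect_equal(pmh_estimates(const)$mean, u)
  expect_true(all(pmh_estimates(const)$cov == 0))
})

test_that("with a constant likelihood the chain recovers the uniform prior", {
  cfg <- pmh_config(L = 10000, scale2 = 4, seed = 3)
  res <- run_pmh(NULL, cfg, loglik_fn = function(theta, seed) 0)
  expect_true(all(apply(res$chain, 1, in_support)))
  # thinned draws are nearly independent at this kernel scale
  thin <- res$chain[seq(5001, 10000, by = 25), ]
  expect_gt(ks.test(thin[, "Q"], "punif")$p.value, 0.01)
  expect_gt(ks.test(thin[, "alpha"], "punif", 50, 300)$p.value, 0.01)
})

test_that("PMH reproduces the conjugate-toy posterior", {
  set.seed(71)
  y_toy <- rnorm(25, 0.55, 0.3)
  post_mean <- mean(y_toy)
  post_var <- 0.3^2 / 25
  cfg <- pmh_config(L = 8000, scale2 = 0.5, seed = 5)
  res <- run_pmh(NULL, cfg, loglik_fn = toy_loglik_factory(y_toy, 0.3))
  half <- res$chain[4001:8000, "Q"]
  # batch-means standard error for the correlated chain
  bm <- tapply(half, rep(1:40, each = 100), mean)
  se <- sd(bm) / sqrt(length(bm))
  expect_lt(abs(mean(half) - post_mean), 3 * se)
  bv <- tapply((half - mean(half))^2, rep(1:40, each = 100), mean)
  se_v <- sd(bv) / sqrt(length(bv))
  expect_lt(abs(var(half) - post_var), 3 * se_v)
  expect_true(res$acc_rate > 0 && res$acc_rate < 1)
})

test_that("PMH runs are reproducible and respect rejections", {
  ds <- desk_dataset()
  cfg <- pmh_config(L = 10, scale2 = 0.1, n_particles = 20, seed = 9)
  r1 <- run_pmh(ds$obs, cfg, ds$model)
  r2 <- run_pmh(ds$obs, cfg, ds$model)
  expect_identical(r1$chain, r2$chain)
  rejected <- which(!r1$accepted[-1]) + 1
  for (k in rejected)
    expect_identical(r1$chain[k, ], r1$chain[k - 1, ])
})
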