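test_that("drift matches hand-evaluated Hill kinetics", {
  th <- theta_standard()
  st <- init_state_mean()

  # C1 = 0, a1 = alpha: the a1 equation sits at its fixed point
  st1 <- st; st1["C1"] <- 0; st1["a1"] <- 216
  expect_equal(unname(drift(st1, th)["a1"]), 0)

  # C1 = 1 makes C^m = 1, so da1/dt = alpha/2 - a1 = 108 at a1 = 0
  st2 <- st; st2["C1"] <- 1; st2["a1"] <- 0
  expect_equal(unname(drift(st2, th)["a1"]), 108)

  # all AI terms vanish: S1 = S2 = 0 and B1 = 0
  st3 <- st; st3["S1"] <- 0; st3["S2"] <- 0; st3["B1"] <- 0
  expect_equal(unname(drift(st3, th)["S1"]), 0)

  expect_error(drift(replace(st, 1, Inf), th), "non-finite")
})

test_that("extracellular AI is the Q-scaled two-cell mean", {
  expect_equal(extracellular_ai(0, 0, 0.5), 0)
  expect_equal(extracellular_ai(2, 4, 1), 3)
  expect_equal(extracellular_ai(1, 1, 0.85), 0.85)
  # linear in (S1, S2), homogeneous in Q
  expect_equal(extracellular_ai(3 * 1.5, 3 * 2.5, 0.7),
               3 * extracellular_ai(1.5, 2.5, 0.7))
  expect_error(extracellular_ai(-1, 0, 0.5), "non-negative")
})

test_that("noise-free Euler step reproduces state + h * drift exactly", {
  th <- theta_standard()
  model <- repress_model(grid = sim_grid(t_total = 1), noise = noise_scales(0))
  st <- init_state_mean()
  stepped <- em_step(st, th, model, seed = 5)
  expect_equal(stepped, st + model$grid$h * drift(st, th, model$fixed))
})

test_that("per-step noise increment has the Euler-Maruyama variance", {
  # a-component only: increment = h * drift_a + 0.05 * a * sqrt(h) * z
  th <- theta_standard()
  st <- init_state_mean()
  n <- 1e5
  X <- matrix(rep(st, each = n), nrow = n)
  out <- repinfer:::propagate_cpp(
    X, 1L, repinfer:::full_pars(th, fixed_params()),
    c(0.05, 0, 0, 0, 0, 0, 0), 1e-3, FALSE, 99)
  incr <- out[, 1] - st["a1"]
  expect_equal(var(incr), (0.05 * st[["a1"]])^2 * 1e-3, tolerance = 0.02)
  # deterministic part is the mean
  expect_equal(mean(incr), 1e-3 * drift(st, th)[["a1"]], tolerance = 0.01)
  # components without a noise scale are untouched (sigma_a acts on the
  # a-component of both cells, so a2 is excluded too)
  det <- st + 1e-3 * drift(st, th)
  quiet <- c(2:7, 9:14)
  expect_equal(out[1, quiet], unname(det[quiet]))
})

test_that("propagate composes m0 Euler-Maruyama steps reproducibly", {
  th <- theta_standard()
  model <- desk_model()
  st <- init_state_mean()
  # m0 = 1 is a single em_step under the same seed
  expect_equal(propagate(st, th, model, m0 = 1, seed = 7),
               em_step(st, th, model, seed = 7))
  # identical seeds give identical outputs
  expect_equal(propagate(st, th, model, m0 = 20, seed = 3),
               propagate(st, th, model, m0 = 20, seed = 3))
  # noise off: 20 composed deterministic steps
  det <- repress_model(grid = model$grid, noise = noise_scales(0))
  x <- st
  for (k in 1:20) x <- em_step(x, th, det, seed = k)
  expect_equal(propagate(st, th, det, m0 = 20, seed = 1), x)
})

test_that("simulate produces the advertised number of steps and is seed-deterministic", {
  th <- theta_standard()
  grid <- sim_grid(h = 1e-3, m0 = 20, t_total = 80)
  expect_identical(grid$n_steps, 80000L)
  expect_identical(grid$n_obs, 4000L)

  model <- desk_model()
  tr <- simulate_repressilator(th, init_state_mean(), model, seed = 42)
  expect_equal(nrow(tr$states), model$grid$n_steps + 1)
  expect_equal(simulate_repressilator(th, init_state_mean(), model, seed = 42)$states,
               tr$states)
  # noise off: seed-independent
  det <- repress_model(grid = desk_grid(), noise = noise_scales(0))
  expect_equal(simulate_repressilator(th, init_state_mean(), det, seed = 1)$states,
               simulate_repressilator(th, init_state_mean(), det, seed = 2)$states)
})

test_that("deterministic trajectories stay bounded and keep oscillating", {
  # sustained irregular oscillation of a1 at standard parameters: period
  # is roughly 40 time units, so 500 units give >= 10 local maxima with
  # unequal inter-peak intervals (values frozen from an independent
  # adaptive ODE integration of the same vector field)
  model <- repress_model(grid = sim_grid(h = 1e-3, m0 = 20, t_total = 500),
                         noise = noise_scales(0))
  tr <- simulate_repressilator(theta_standard(), init_state_mean(), model)
  expect_true(all(tr$states < 10 * 216))
  a1 <- tr$states[, "a1"]
  peaks <- which(diff(sign(diff(a1))) == -2) + 1
  expect_gte(length(peaks), 10)
  gaps <- diff(peaks) * model$grid$h
  expect_gt(max(gaps) - min(gaps), 1e-3)  # not a fixed period
})

test_that("deterministic Euler error at t = 1 scales linearly in h", {
  th <- theta_standard()
  x0 <- init_state_mean()
  state_at <- function(h) {
    m <- repress_model(grid = sim_grid(h = h, m0 = 1, t_total = 1),
                       noise = noise_scales(0))
    tr <- simulate_repressilator(th, x0, m)
    tr$states[nrow(tr$states), ]
  }
  ref <- state_at(1e-5)
  errs <- vapply(c(4e-3, 2e-3, 1e-3), function(h) max(abs(state_at(h) - ref)),
                 numeric(1))
  ratios <- errs[-length(errs)] / errs[-1]
  expect_true(all(ratios > 1.5 & ratios < 2.5))
})

test_that("observation records have the right bookkeeping and noise level", {
  ds <- desk_dataset()
  expect_equal(nrow(ds$obs$y), ds$model$grid$n_obs)

  # near-zero observation noise returns the latent observables
  tiny <- observe(ds$traj, sigma_y = 1e-12, seed = 1)
  idx <- seq(20, nrow(ds$traj$states) - 1, by = 20) + 1
  expect_equal(tiny$y[, "a1"], unname(ds$traj$states[idx, "a1"]),
               tolerance = 1e-9)

  # empirical residual variance close to sigma_y^2 = 1
  model <- repress_model(grid = sim_grid(t_total = 80),
                         noise = noise_scales(0))
  tr <- simulate_repressilator(theta_standard(), init_state_mean(), model)
  ob <- observe(tr, sigma_y = 1, seed = 8)
  lat <- tr$states[seq(20, 80000, by = 20) + 1, c("a1", "a2")]
  expect_equal(var(as.numeric(ob$y - lat)), 1, tolerance = 0.05)

  expect_error(observe(ds$traj, m0 = 1e6), "exceeds")
})

test_that("prior draws cover the support with the right moments", {
  set.seed(31)
  draws <- sample_prior(1e5)
  s <- theta_support()
  expect_true(all(draws > rep(s["lower", ], each = 1e5)))
  expect_true(all(draws < rep(s["upper", ], each = 1e5)))
  expect_equal(unname(colMeans(draws)), c(0.5, 3, 175, 0.5), tolerance = 0.01)
  set.seed(7); d1 <- sample_prior()
  set.seed(7); d2 <- sample_prior()
  expect_identical(d1, d2)
})

test_that("initial-state draws follow the configured Gaussian spread", {
  init <- init_state_model()
  expect_equal(init$mean,
               c(4.5, 6, 3, 4.2, 19, 4.3, 0.1, 7.3, 1.5, 3.4, 7, 6.5, 3.6, 0.08))
  # sigma0 = 0 is a point mass
  expect_equal(unname(sample_initial_state(init_state_model(sigma0 = 0))),
               init$mean)
  set.seed(13)
  draws <- t(replicate(2e4, sample_initial_state(init)))
  expect_equal(mean(apply(draws[, 1:6], 2, sd)), 0.05, tolerance = 0.03)
})

test_that("the literal noise convention applies the printed update term", {
  th <- theta_standard()
  grid <- sim_grid(h = 1e-3, m0 = 1, t_total = 1)
  m_std <- repress_model(grid = grid, noise = noise_scales(0.05))
  m_lit <- repress_model(grid = grid, noise = noise_scales(0.05),
                         noise_convention = "literal")
  st <- init_state_mean()
  n <- 2e4
  X <- matrix(rep(st, each = n), nrow = n)
  sig <- c(0.05, 0, 0, 0, 0, 0, 0)
  fp <- repinfer:::full_pars(th, fixed_params())
  std <- repinfer:::propagate_cpp(X, 1L, fp, sig, 1e-3, FALSE, 21)
  lit <- repinfer:::propagate_cpp(X, 1L, fp, sig, 1e-3, TRUE, 21)
  # literal increments have variance (s^2 * a)^2 (no h), standard (s a)^2 h
  expect_equal(var(lit[, 1]) / var(std[, 1]), 0.05^2 / 1e-3, tolerance = 0.05)
})
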