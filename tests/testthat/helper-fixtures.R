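# Shared fixtures, built in code. `desk_*` objects use a short record
# (2 time units, 100 observations) so individual unit tests stay fast;
# the longer scenarios live in the acceptance suite.

desk_grid <- function(t_total = 2) sim_grid(h = 1e-3, m0 = 20, t_total = t_total)

desk_model <- function(noise_sd = 0.05, t_total = 2) {
  repress_model(grid = desk_grid(t_total), noise = noise_scales(noise_sd))
}

# one small stochastic dataset, memoised across tests
.desk_cache <- new.env()
desk_dataset <- function() {
  if (is.null(.desk_cache$ds)) {
    model <- desk_model()
    traj <- simulate_repressilator(theta_standard(), init_state_mean(),
                                   model, seed = 11)
    obs <- observe(traj, sigma_y = 1, seed = 12)
    .desk_cache$ds <- list(model = model, traj = traj, obs = obs)
  }
  .desk_cache$ds
}

# exact Kalman-filter log-likelihood for the scalar AR(1) + noise model
#   x_n = phi x_{n-1} + q e_n,  y_n = x_n + r v_n,  x_0 ~ N(0, p0)
# (independent closed-form oracle for the bootstrap filter)
kalman_loglik <- function(y, phi, q, r, p0) {
  mu <- 0
  P <- p0
  ll <- 0
  for (n in seq_along(y)) {
    mu_pred <- phi * mu
    P_pred <- phi^2 * P + q^2
    S <- P_pred + r^2
    ll <- ll + dnorm(y[n], mu_pred, sqrt(S), log = TRUE)
    K <- P_pred / S
    mu <- mu_pred + K * (y[n] - mu_pred)
    P <- (1 - K) * P_pred
  }
  ll
}

# bootstrap-filter samplers for the same AR(1) model
ar1_filter_parts <- function(phi, q, r, p0) {
  list(
    init = function(n) rnorm(n, 0, sqrt(p0)),
    trans = function(X, n) phi * X + rnorm(length(X), 0, q),
    obsll = function(yn, X, n) dnorm(yn, X[, 1], r, log = TRUE)
  )
}

# conjugate toy: likelihood depends on Q alone through n_toy pseudo-data
# points y_i ~ N(Q, s_toy^2); with the flat prior on (0,1) the posterior
# of Q is N(mean(y), s_toy^2 / n_toy) (truncation negligible for the
# values used here), and the other three parameters keep their priors.
toy_loglik_factory <- function(y_toy, s_toy) {
  function(theta, seed) sum(dnorm(y_toy, theta[["Q"]], s_toy, log = TRUE))
}
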