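#' @useDynLib repinfer, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif dnorm pnorm qnorm sd cov quantile
NULL

# ---- parameter containers ----------------------------------------------

#' Unknown-parameter vector of the coupled repressilator
#'
#' The four parameters treated as unknown and estimated by the inference
#' methods: the quorum-sensing coupling strength `Q`, the Hill coefficient
#' `m`, the dimensionless transcription rate `alpha` and the mRNA/protein
#' lifetime ratio `beta_a` of the TetR protein. All are dimensionless.
#'
#' @param Q coupling strength, in (0, 1).
#' @param m Hill coefficient, in (1, 5).
#' @param alpha transcription rate in the absence of repressor, in (50, 300).
#' @param beta_a TetR lifetime ratio, in (0, 1).
#' @return A named numeric vector of length 4.
#' @export
#' @examples
#' theta_vector(0.85, 2.6, 216, 0.85)
theta_vector <- function(Q, m, alpha, beta_a) {
  th <- c(Q = Q, m = m, alpha = alpha, beta_a = beta_a)
  stopifnot(all(is.finite(th)))
  th
}

#' Standard ("true") parameter values of the chaotic regime
#'
#' @return The parameter vector (Q, m, alpha, beta_a) = (0.85, 2.6, 216, 0.85).
#' @export
theta_standard <- function() theta_vector(0.85, 2.6, 216, 0.85)

#' Support of the unknown parameters
#'
#' The prior is uniform on the box
#' S = (0,1) x (1,5) x (50,300) x (0,1).
#'
#' @return A 2 x 4 matrix with rows `lower`, `upper`.
#' @export
theta_support <- function() {
  rbind(lower = c(Q = 0, m = 1, alpha = 50, beta_a = 0),
        upper = c(Q = 1, m = 5, alpha = 300, beta_a = 1))
}

#' Test whether a parameter vector lies in the prior support
#' @param theta numeric vector (Q, m, alpha, beta_a).
#' @return Logical scalar.
#' @export
in_support <- function(theta) {
  s <- theta_support()
  all(is.finite(theta)) && all(theta > s["lower", ]) && all(theta < s["upper", ])
}

#' Log-density of the uniform prior over the support box
#' @param theta numeric vector (Q, m, alpha, beta_a).
#' @return `-log(1000)` inside the support, `-Inf` outside.
#' @export
log_prior <- function(theta) {
  if (in_support(theta)) -log(1000) else -Inf
}

#' Draw parameter vectors from the uniform prior
#'
#' Components are independent: Q ~ U(0,1), m ~ U(1,5), alpha ~ U(50,300),
#' beta_a ~ U(0,1). Uses R's global RNG stream.
#'
#' @param n number of draws.
#' @return If `n == 1`, a named vector; otherwise an `n` x 4 matrix.
#' @export
sample_prior <- function(n = 1) {
  s <- theta_support()
  out <- cbind(Q = runif(n, s[1, 1], s[2, 1]),
               m = runif(n, s[1, 2], s[2, 2]),
               alpha = runif(n, s[1, 3], s[2, 3]),
               beta_a = runif(n, s[1, 4], s[2, 4]))
  if (n == 1) out[1, ] else out
}

#' Fixed (known) model parameters
#'
#' Lifetime ratios of the CI and LacI proteins, the autoinducer diffusion
#' coefficient, the maximum LuxR-promoter transcription rate and the
#' autoinducer degradation/synthesis constants. Defaults are the standard
#' values of the chaotic regime.
#'
#' @param beta_b,beta_c mRNA/protein lifetime ratios (CI, LacI).
#' @param eta autoinducer membrane diffusion coefficient.
#' @param kappa maximum LuxR-promoter transcription rate.
#' @param k_s0,k_s1 intracellular AI degradation and synthesis constants.
#' @return Named numeric vector of length 6.
#' @export
fixed_params <- function(beta_b = 0.1, beta_c = 0.1, eta = 2, kappa = 25,
                         k_s0 = 1, k_s1 = 0.01) {
  fp <- c(beta_b = beta_b, beta_c = beta_c, eta = eta, kappa = kappa,
          k_s0 = k_s0, k_s1 = k_s1)
  stopifnot(all(fp > 0))
  fp
}

#' Multiplicative dynamical-noise scales
#'
#' One non-negative scale factor per state component within a cell, in the
#' order (a, b, c, A, B, C, S). All zero recovers the deterministic
#' modified repressilator.
#'
#' @param sd common scale applied to all seven components (convenience).
#' @param sigma_a,sigma_b,sigma_c,sigma_A,sigma_B,sigma_C,sigma_S
#'   individual scales, overriding `sd`.
#' @return Named numeric vector of length 7.
#' @export
noise_scales <- function(sd = 0.05, sigma_a = sd, sigma_b = sd, sigma_c = sd,
                         sigma_A = sd, sigma_B = sd, sigma_C = sd,
                         sigma_S = sd) {
  ns <- c(sigma_a = sigma_a, sigma_b = sigma_b, sigma_c = sigma_c,
          sigma_A = sigma_A, sigma_B = sigma_B, sigma_C = sigma_C,
          sigma_S = sigma_S)
  stopifnot(all(ns >= 0))
  ns
}

#' Time grid of the Euler-Maruyama integration and observation schedule
#'
#' @param h integration step in continuous time units (mRNA lifetimes).
#' @param m0 number of integration steps between consecutive observations.
#' @param t_total record length in continuous time units; must be an
#'   integer multiple of `m0 * h`.
#' @return A list with `h`, `m0`, `t_total`, the total number of
#'   integration steps `n_steps` and the number of observations `n_obs`.
#' @export
sim_grid <- function(h = 1e-3, m0 = 20, t_total = 80) {
  stopifnot(h > 0, m0 >= 1, m0 == round(m0), t_total > 0)
  n_obs <- t_total / (m0 * h)
  if (abs(n_obs - round(n_obs)) > 1e-8)
    stop("t_total must be an integer multiple of m0 * h")
  n_obs <- as.integer(round(n_obs))
  list(h = h, m0 = as.integer(m0), t_total = t_total,
       n_steps = n_obs * as.integer(m0), n_obs = n_obs)
}

#' State component names, cell 1 then cell 2
#' @return Character vector of length 14.
#' @export
state_names <- function() {
  c(t(outer(1:2, c("a", "b", "c", "A", "B", "C", "S"),
            function(i, v) paste0(v, i))))
}

#' Default initial-state mean of the two-cell system
#' @return Named numeric vector of length 14 in the order
#'   (a1, b1, c1, A1, B1, C1, S1, a2, ..., S2).
#' @export
init_state_mean <- function() {
  x <- c(4.5, 6, 3, 4.2, 19, 4.3, 0.1, 7.3, 1.5, 3.4, 7, 6.5, 3.6, 0.08)
  names(x) <- state_names()
  x
}

#' Gaussian initial-state model
#'
#' Initial conditions are drawn from an isotropic Gaussian around `mean`
#' with standard deviation `sigma0`; `sigma0 = 0` yields a point mass.
#'
#' @param mean 14-component state vector.
#' @param sigma0 per-component standard deviation (>= 0).
#' @return A list with elements `mean` and `sigma0`.
#' @export
init_state_model <- function(mean = init_state_mean(), sigma0 = 0.05) {
  stopifnot(length(mean) == 14, sigma0 >= 0)
  list(mean = as.numeric(mean), sigma0 = sigma0)
}

#' Draw an initial state
#'
#' A Gaussian draw around the model mean followed by the positivity floor
#' (components clamped at zero). Uses R's global RNG.
#'
#' @param init an [init_state_model()].
#' @return A named 14-component state vector.
#' @export
sample_initial_state <- function(init = init_state_model()) {
  x <- init$mean
  if (init$sigma0 > 0) x <- x + rnorm(14, 0, init$sigma0)
  x <- pmax(x, 0)
  names(x) <- state_names()
  x
}

# ---- model bundle -------------------------------------------------------

#' Bundle of model settings shared by simulation and inference
#'
#' Collects everything that defines the state-space model apart from the
#' unknown parameters: the time grid, fixed parameters, dynamical noise
#' scales, observation noise, initial-state model and the noise convention
#' of the Euler-Maruyama discretisation.
#'
#' @param grid a [sim_grid()].
#' @param fixed a [fixed_params()] vector.
#' @param noise a [noise_scales()] vector.
#' @param sigma_y observation-noise standard deviation (> 0).
#' @param init an [init_state_model()]; the particle filter draws its
#'   initial particles from it.
#' @param noise_convention `"em_standard"` (per-step increment
#'   `s * x * sqrt(h) * z`, `z ~ N(0,1)`) or `"literal"` (increment
#'   `s * x * w` with `w ~ N(0, s^2)`, no step-size scaling).
#' @return An object of class `repress_model`.
#' @export
repress_model <- function(grid = sim_grid(), fixed = fixed_params(),
                          noise = noise_scales(0.05), sigma_y = 1,
                          init = init_state_model(),
                          noise_convention = c("em_standard", "literal")) {
  noise_convention <- match.arg(noise_convention)
  stopifnot(sigma_y > 0)
  structure(list(grid = grid, fixed = fixed, noise = noise,
                 sigma_y = sigma_y, init = init,
                 noise_convention = noise_convention),
            class = "repress_model")
}

# full 10-parameter vector in the order the C++ core expects
full_pars <- function(theta, fixed) {
  unname(c(theta[c("Q", "m", "alpha", "beta_a")], fixed))
}

check_state <- function(state) {
  if (length(state) != 14) stop("state must have 14 components")
  if (!all(is.finite(state))) stop("invalid state: non-finite component")
  invisible(state)
}

# ---- dynamics -----------------------------------------------------------

#' Quasi-steady-state extracellular autoinducer concentration
#'
#' The fast extracellular AI dynamics is eliminated by its equilibrium,
#' `Se = Q * (S1 + S2) / 2` for the two-cell system.
#'
#' @param S1,S2 intracellular AI concentrations (>= 0).
#' @param Q coupling strength.
#' @return The extracellular concentration.
#' @export
extracellular_ai <- function(S1, S2, Q) {
  if (any(c(S1, S2) < 0) || any(!is.finite(c(S1, S2))))
    stop("invalid state: AI concentrations must be finite and non-negative")
  Q * (S1 + S2) / 2
}

#' Deterministic drift of the coupled repressilator
#'
#' The right-hand side of the 14-dimensional SDE system with the noise
#' terms removed: Hill-type repression of each mRNA by the upstream
#' protein, LuxR-promoter activation of lacI by the autoinducer, linear
#' protein synthesis/degradation, and AI synthesis, degradation and
#' membrane diffusion against the quasi-steady-state extracellular pool.
#'
#' @param state 14-component state vector (a1..S1, a2..S2).
#' @param theta unknown-parameter vector (Q, m, alpha, beta_a).
#' @param fixed fixed-parameter vector.
#' @return The 14-component rate vector d(state)/dt.
#' @export
drift <- function(state, theta, fixed = fixed_params()) {
  check_state(state)
  Se <- extracellular_ai(state[7], state[14], theta[["Q"]])
  out <- numeric(14)
  for (cell in 0:1) {
    i <- 7 * cell
    a <- state[i + 1]; b <- state[i + 2]; cc <- state[i + 3]
    A <- state[i + 4]; B <- state[i + 5]; C <- state[i + 6]; S <- state[i + 7]
    al <- theta[["alpha"]]; m <- theta[["m"]]
    out[i + 1] <- -(a - al / (1 + C^m))
    out[i + 2] <- -(b - al / (1 + A^m))
    out[i + 3] <- -(cc - al / (1 + B^m) - fixed[["kappa"]] * S / (1 + S))
    out[i + 4] <- theta[["beta_a"]] * (a - A)
    out[i + 5] <- fixed[["beta_b"]] * (b - B)
    out[i + 6] <- fixed[["beta_c"]] * (cc - C)
    out[i + 7] <- -(fixed[["k_s0"]] * S - fixed[["k_s1"]] * B +
                      fixed[["eta"]] * (S - Se))
  }
  names(out) <- state_names()
  out
}

#' One Euler-Maruyama step
#'
#' Advances the state by `state + h * drift + noise increment`, then clamps
#' components at zero. The noise increment per component is
#' `s * x * sqrt(h) * z` with `z ~ N(0,1)` under the standard convention.
#' Reproducible from `seed` alone.
#'
#' @param state 14-component state vector.
#' @param theta unknown-parameter vector.
#' @param model a [repress_model()].
#' @param seed integer seed for the noise stream.
#' @return The updated 14-component state vector.
#' @export
em_step <- function(state, theta, model = repress_model(), seed = 1) {
  check_state(state)
  out <- propagate_cpp(matrix(state, nrow = 1), 1L,
                       full_pars(theta, model$fixed), unname(model$noise),
                       model$grid$h, model$noise_convention == "literal",
                       seed)[1, ]
  names(out) <- state_names()
  out
}

#' Propagate a state through `m0` Euler-Maruyama substeps
#'
#' One draw from the composite Markov kernel that moves the state from one
#' observation time to the next.
#'
#' @inheritParams em_step
#' @param m0 number of substeps; defaults to the model grid value.
#' @return The state after `m0` substeps.
#' @export
propagate <- function(state, theta, model = repress_model(),
                      m0 = model$grid$m0, seed = 1) {
  check_state(state)
  stopifnot(m0 >= 1)
  out <- propagate_cpp(matrix(state, nrow = 1), as.integer(m0),
                       full_pars(theta, model$fixed), unname(model$noise),
                       model$grid$h, model$noise_convention == "literal",
                       seed)[1, ]
  names(out) <- state_names()
  out
}

#' Simulate a full state trajectory
#'
#' Euler-Maruyama integration over the whole grid, `n_steps = t_total / h`
#' steps after the initial state. Bit-reproducible from
#' `(theta, x0, grid, noise scales, seed)`.
#'
#' @param theta unknown-parameter vector (Q, m, alpha, beta_a).
#' @param x0 initial 14-component state.
#' @param model a [repress_model()].
#' @param seed integer seed for the dynamical-noise stream.
#' @return An object of class `repress_trajectory`: list with `states`
#'   (`(n_steps + 1) x 14` matrix, row 1 = `x0`), `grid`, `theta`, `seed`.
#' @export
simulate_repressilator <- function(theta, x0 = init_state_mean(),
                                   model = repress_model(), seed = 1) {
  check_state(x0)
  states <- sim_path_cpp(as.numeric(x0), model$grid$n_steps,
                         full_pars(theta, model$fixed), unname(model$noise),
                         model$grid$h, model$noise_convention == "literal",
                         seed)
  colnames(states) <- state_names()
  structure(list(states = states, grid = model$grid, theta = theta,
                 seed = seed),
            class = "repress_trajectory")
}

#' Generate noisy partial observations of a trajectory
#'
#' The observable components are the tetR mRNA concentrations of the two
#' cells, read every `m0` integration steps starting at step `m0` (the
#' state at time 0 is never observed) and contaminated with isotropic
#' Gaussian noise of standard deviation `sigma_y`.
#'
#' @param traj a `repress_trajectory`.
#' @param sigma_y observation-noise standard deviation.
#' @param m0 thinning (defaults to the trajectory grid value).
#' @param seed integer seed for the observation-noise stream.
#' @return An object of class `repress_obs`: list with `y` (`n_obs x 2`
#'   matrix with columns `a1`, `a2`), `grid`, `sigma_y`, `seed`.
#' @export
observe <- function(traj, sigma_y = 1, m0 = traj$grid$m0, seed = 1) {
  stopifnot(inherits(traj, "repress_trajectory"), sigma_y > 0, m0 >= 1)
  n_rows <- nrow(traj$states) - 1L
  if (m0 > n_rows) stop("m0 exceeds trajectory length")
  idx <- seq(m0, n_rows, by = m0) + 1L  # +1: row 1 is time 0
  latent <- traj$states[idx, c("a1", "a2"), drop = FALSE]
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  y <- latent + matrix(rnorm(2 * length(idx), 0, sigma_y), ncol = 2)
  colnames(y) <- c("a1", "a2")
  grid <- traj$grid
  grid$m0 <- as.integer(m0)
  grid$n_obs <- length(idx)
  structure(list(y = y, grid = grid, sigma_y = sigma_y, seed = seed),
            class = "repress_obs")
}

#' @export
print.repress_trajectory <- function(x, ...) {
  cat("<repress_trajectory>", nrow(x$states) - 1, "steps, h =", x$grid$h,
      "\n  theta =", paste(signif(x$theta, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.repress_obs <- function(x, ...) {
  cat("<repress_obs>", nrow(x$y), "observations, sigma_y =", x$sigma_y, "\n")
  invisible(x)
}

#' @export
as.data.frame.repress_trajectory <- function(x, ...) {
  data.frame(time = seq(0, by = x$grid$h, length.out = nrow(x$states)),
             x$states)
}

#' @export
as.data.frame.repress_obs <- function(x, ...) {
  data.frame(time = seq_len(nrow(x$y)) * x$grid$m0 * x$grid$h, x$y)
}
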