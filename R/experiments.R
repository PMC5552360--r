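# Scenario orchestration and benchmarking: dataset generation under the
# stochastic- and deterministic-trajectory regimes, NMSE aggregation
# across methods and seeds, likelihood profiles and weighted density
# estimates.

#' Study scenario configuration
#'
#' Defines the data-generating regime. In the stochastic regime every
#' state equation carries multiplicative noise with standard deviation
#' `noise_sd`; in the deterministic regime the trajectories are noiseless
#' (observations stay noisy in both). The inference model used by the
#' particle filter keeps dynamical noise `filter_noise_sd` even in the
#' deterministic regime, since a noiseless transition kernel collapses all
#' particles onto one path.
#'
#' @param regime `"stochastic"` or `"deterministic"` trajectories.
#' @param t_total record length in time units.
#' @param h Euler-Maruyama step.
#' @param m0 integration steps per observation.
#' @param sigma_y observation-noise standard deviation.
#' @param noise_sd dynamical-noise scale of the data-generating run
#'   (stochastic regime).
#' @param filter_noise_sd dynamical-noise scale assumed by the inference
#'   model.
#' @param sigma0 initial-condition spread (0 gives a fixed initial state).
#' @param theta_truth true parameter vector used to generate data.
#' @return A list of class `scenario_config` with the derived
#'   data-generating and inference [repress_model()]s.
#' @export
scenario_config <- function(regime = c("stochastic", "deterministic"),
                            t_total = 80, h = 1e-3, m0 = 20, sigma_y = 1,
                            noise_sd = 0.05, filter_noise_sd = 0.05,
                            sigma0 = 0.05, theta_truth = theta_standard()) {
  regime <- match.arg(regime)
  stopifnot(in_support(theta_truth))
  grid <- sim_grid(h = h, m0 = m0, t_total = t_total)
  data_noise <- if (regime == "stochastic") noise_scales(noise_sd)
                else noise_scales(0)
  data_model <- repress_model(grid = grid, noise = data_noise,
                              sigma_y = sigma_y,
                              init = init_state_model(sigma0 = sigma0))
  infer_model <- repress_model(grid = grid,
                               noise = noise_scales(filter_noise_sd),
                               sigma_y = sigma_y,
                               init = init_state_model(sigma0 = 0.05))
  structure(list(regime = regime, data_model = data_model,
                 infer_model = infer_model, theta_truth = theta_truth),
            class = "scenario_config")
}

#' Generate one dataset under a scenario
#'
#' Draws the initial state, integrates the trajectory and produces the
#' noisy observation record, all from streams derived from `seed`. The
#' realised initial state is returned because ABC-SMC conditions on it.
#'
#' @param scenario a [scenario_config()].
#' @param seed master seed of the dataset.
#' @return A list with `traj` (`repress_trajectory`), `obs`
#'   (`repress_obs`) and `x0` (realised initial state).
#' @export
generate_dataset <- function(scenario, seed = 1) {
  x0 <- with_seed(derive_seed(seed, 29L),
                  sample_initial_state(scenario$data_model$init))
  traj <- simulate_repressilator(scenario$theta_truth, x0,
                                 scenario$data_model,
                                 seed = derive_seed(seed, 31L))
  obs <- observe(traj, sigma_y = scenario$data_model$sigma_y,
                 seed = derive_seed(seed, 37L))
  list(traj = traj, obs = obs, x0 = x0)
}

#' Normalised mean square error of parameter estimates
#'
#' Mean over runs and over the four parameters of the squared estimation
#' error divided by the squared true value.
#'
#' @param estimates a matrix with one estimate per row (or a list of
#'   4-vectors, or a single 4-vector).
#' @param theta_truth true parameter vector with nonzero components.
#' @return A non-negative scalar.
#' @export
nmse <- function(estimates, theta_truth) {
  if (is.list(estimates)) estimates <- do.call(rbind, estimates)
  if (!is.matrix(estimates)) estimates <- matrix(estimates, nrow = 1)
  if (any(theta_truth == 0)) stop("theta_truth components must be nonzero")
  rel2 <- sweep(estimates, 2, theta_truth)^2 /
    matrix(theta_truth^2, nrow(estimates), 4, byrow = TRUE)
  mean(rowMeans(rel2))
}

#' Benchmark inference methods on a scenario
#'
#' For each of `n_runs` seeds, generates one dataset and runs every
#' configured method on the identical observation record, then aggregates
#' per-method NMSE. Runs where a sampler degenerates are recorded as
#' failures and excluded from the NMSE (never silently dropped).
#'
#' @param scenario a [scenario_config()].
#' @param methods named list of method configurations; names among
#'   `"pmh"` ([pmh_config()]), `"npmc"` ([npmc_config()]) and
#'   `"abc_smc"` ([abc_config()]).
#' @param n_runs number of independent runs.
#' @param seed master seed; run `j` uses seed `derive_seed(seed, 41, j)`.
#' @return A list of class `benchmark_result`: `estimates` (per method, a
#'   matrix of per-run estimates), `nmse` (named vector), `failures`
#'   (named count), `run_seeds`.
#' @export
run_benchmark <- function(scenario, methods, n_runs = 5, seed = 1) {
  stopifnot(length(methods) >= 1, !is.null(names(methods)))
  run_seeds <- vapply(seq_len(n_runs), function(j) derive_seed(seed, 41L, j),
                      integer(1))
  estimates <- lapply(methods, function(m)
    matrix(NA_real_, n_runs, 4,
           dimnames = list(NULL, c("Q", "m", "alpha", "beta_a"))))
  failures <- stats::setNames(integer(length(methods)), names(methods))
  for (j in seq_len(n_runs)) {
    ds <- generate_dataset(scenario, run_seeds[j])
    for (name in names(methods)) {
      cfg <- methods[[name]]
      cfg$seed <- derive_seed(run_seeds[j], match(name, names(methods)))
      est <- tryCatch(switch(
        name,
        pmh = pmh_estimates(run_pmh(ds$obs, cfg, scenario$infer_model))$mean,
        npmc = {
          res <- run_npmc(ds$obs, cfg, scenario$infer_model)
          npmc_estimates(res$ensembles[[length(res$ensembles)]])$mean
        },
        abc_smc = {
          res <- run_abc_smc(ds$obs, cfg, scenario$data_model, ds$x0)
          abc_estimate(res$populations[[length(res$populations)]])
        },
        stop("unknown method: ", name)
      ), error = function(e) {
        warning("run ", j, ", method ", name, " failed: ",
                conditionMessage(e))
        NULL
      })
      if (is.null(est)) failures[name] <- failures[name] + 1L
      else estimates[[name]][j, ] <- est
    }
  }
  nmse_vals <- vapply(names(methods), function(name) {
    ok <- stats::complete.cases(estimates[[name]])
    if (!any(ok)) return(NA_real_)
    nmse(estimates[[name]][ok, , drop = FALSE], scenario$theta_truth)
  }, numeric(1))
  structure(list(estimates = estimates, nmse = nmse_vals,
                 failures = failures, run_seeds = run_seeds,
                 scenario = scenario),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result>", length(x$run_seeds), "runs\n  NMSE:\n")
  for (name in names(x$nmse))
    cat(sprintf("    %-8s %.4g  (%d failures)\n", name, x$nmse[name],
                x$failures[name]))
  invisible(x)
}

#' Cumulative log-likelihood profiles across parameter values
#'
#' Runs the bootstrap filter once per parameter vector (same filter seed
#' for all of them) and returns the running log-likelihood
#' `log l^N(y_{1:n} | theta)` as a function of the observation index `n`.
#' Used to visualise how flat the likelihood surface is along selected
#' directions of parameter space.
#'
#' @param theta_list list of parameter vectors.
#' @param y observation record.
#' @param model a [repress_model()].
#' @param n_particles particles per filter run.
#' @param seed shared filter seed.
#' @return A matrix with one column per theta and one row per observation;
#'   attribute `degenerate` flags per-theta degeneracy.
#' @export
likelihood_profile <- function(theta_list, y, model = repress_model(),
                               n_particles = 600, seed = 1) {
  ests <- lapply(theta_list, function(th)
    bf_loglik(th, y, model, n_particles, seed))
  traces <- vapply(ests, function(e) cumsum(e$step_loglik),
                   numeric(if (inherits(y, "repress_obs")) nrow(y$y)
                           else nrow(y)))
  degen <- vapply(ests, function(e) e$degenerate, logical(1))
  attr(traces, "degenerate") <- degen
  traces
}

#' Weighted Gaussian kernel density estimate
#'
#' Direct evaluation of the weighted kernel sum
#' `sum_i w_i * dnorm(x, sample_i, bw)` on a grid, with the bandwidth
#' given by Silverman's rule of thumb on the raw sample.
#'
#' @param samples numeric sample values.
#' @param weights normalised weights (sum to 1); default uniform.
#' @param grid evaluation points.
#' @param bw bandwidth; default Silverman's rule ([stats::bw.nrd0()]).
#' @return A list with `x` (grid), `y` (density values) and `bw`.
#' @export
weighted_density_estimate <- function(samples,
                                      weights = rep(1 / length(samples),
                                                    length(samples)),
                                      grid = seq(min(samples) - 3 * bw,
                                                 max(samples) + 3 * bw,
                                                 length.out = 512),
                                      bw = stats::bw.nrd0(samples)) {
  if (length(unique(samples)) < 2)
    stop("bandwidth selection needs at least 2 distinct samples")
  stopifnot(abs(sum(weights) - 1) < 1e-8)
  dens <- vapply(grid, function(g) sum(weights * dnorm(g, samples, bw)),
                 numeric(1))
  list(x = grid, y = dens, bw = bw)
}
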