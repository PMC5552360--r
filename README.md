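# repinfer

Bayesian parameter inference for a stochastic two-cell coupled
repressilator — a synthetic genetic clock in which each of three genes
represses the next in a cycle, and a diffusible autoinducer molecule
couples the two cells through a phase-repulsive quorum-sensing loop. The
package is aimed at researchers in systems/synthetic biology and
computational statistics who want to simulate this 14-dimensional SDE
model and compare Monte Carlo methods for estimating its parameters from
sparse, noisy data.

The model is a system of Itô SDEs with multiplicative noise; for the
mRNA of *tetR* in cell *i*,

    da_i = -(a_i - α / (1 + C_i^m)) dt + σ_a a_i dW_i,

with analogous equations for the other two mRNAs, linear
protein-synthesis equations (rates β_a, β_b, β_c), and an autoinducer
balance coupled across cells through the quasi-steady-state
extracellular concentration S_e = Q (S_1 + S_2)/2. Only the two tetR
mRNA levels are observed, every 20 Euler–Maruyama steps (h = 10⁻³),
through Gaussian noise with σ_y = 1. The unknown parameter vector is
θ = (Q, m, α, β_a), uniform a priori on
(0,1) × (1,5) × (50,300) × (0,1).

Three posterior samplers are implemented over the same model surface:

* **PMH** — particle Metropolis–Hastings: pseudo-marginal MCMC using a
  bootstrap-filter estimate ℓᴺ(y|θ) of the intractable likelihood and a
  truncated Gaussian random-walk kernel.
* **NPMC** — nonlinear population Monte Carlo: iterated importance
  sampling with Gaussian proposals adapted from *clipped* importance
  weights (the M_c largest raw weights are flattened to the M_c-th
  largest, bounding each normalised weight by 1/M_c).
* **ABC-SMC** — likelihood-free sequential Monte Carlo with a decreasing
  tolerance schedule on the quadratic trajectory distance
  d(y, y(θ)) = (1/R) Σₙ ‖yₙ − yₙ(θ)‖².

A benchmarking harness runs all methods on shared synthetic records and
compares them by normalised mean square error (NMSE), the squared
relative estimation error averaged over runs and parameters.

## Worked example

Simulate a short deterministic-trajectory dataset (2 time units = 100
observations) and fit it with a small NPMC run:

```r
library(repinfer)
sc  <- scenario_config("deterministic", t_total = 2)
ds  <- generate_dataset(sc, seed = 5)
ds$obs
#> <repress_obs> 100 observations, sigma_y = 1

cfg <- npmc_config(M = 30, K = 3, n_particles = 30, seed = 6)
fit <- run_npmc(ds$obs, cfg, sc$infer_model)
fit
#> <npmc_result> M = 30  K = 3  Mc = 5
#>   final posterior mean: 0.8872, 2.62, 192.4, 0.5941
```

The final posterior mean (Q, m, α, β_a) = (0.887, 2.620, 192.4, 0.594)
is to be read against the true generating values (0.85, 2.6, 216, 0.85):
on a record this short the Hill coefficient m is pinned down tightly,
α approximately, while Q and β_a remain close to their prior means
(0.5 for β_a) because the record is far shorter than the ~40-time-unit
oscillation period through which those parameters express themselves.
A single likelihood evaluation,

```r
bf_loglik(theta_standard(), ds$obs, sc$infer_model,
          n_particles = 100, seed = 1)
#> <likelihood_estimate> log l^N = -288.1894  (N = 100 )
```

returns the bootstrap-filter log-likelihood of the record, the quantity
both PMH and NPMC drive their sampling with.

See `vignettes/repressilator-inference.Rmd` for the model, the three
algorithms, all tunable parameters and the package's numerical choices.

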