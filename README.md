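# noisebm

Sampling networks with private, shared and network-generated noise.

Stochastic neural-network models — Boltzmann machines (BMs) in particular —
usually assume that every unit has its own private source of randomness. In a
physical substrate that randomness has to be delivered by something: a finite
pool of background inputs, or the activity of another circuit. A finite pool
forces units to *share* noise sources, which correlates their inputs and
distorts the sampled distribution; a recurrent, inhibition-dominated
*deterministic* network can supply noise whose small negative correlations
cancel most of that shared-input correlation.

`noisebm` implements this whole program for networks of binary units, for
computational neuroscientists and neuromorphic-engineering researchers who
want to quantify what a realistic noise source costs:

* **Sampling networks** `s_i ∈ {0,1}` with symmetric weights `W`, biases `b`
  and inverse temperature `β`, whose exact stationary law is the Boltzmann
  distribution `p(s) ∝ exp(β/2 Σ w_ij s_i s_j + β Σ b_i s_i)` (enumerated
  exactly up to 20 units).
* **Event-driven asynchronous simulation** (C++ core): every unit carries an
  exponential clock with mean interval `τ`; intrinsically stochastic units
  implement Gibbs sampling, deterministic Heaviside units are driven by one
  of three noise backends — private Gaussian `N(μ, σ²)`, a shared pool of `N`
  independent stochastic binary sources (in-degree `K`, Dale's law,
  excitatory fraction `γ`, weights `w` and `−gw`), or a recurrent
  deterministic noise network with the same connectivity statistics.
* **Calibration**: the noise strength maps to an effective inverse
  temperature via integral matching, `β_eff = ln2·√(2π)/σ` (Taylor matching
  `σ = 2√2/(√π β)` retained for comparison), and the sampling network is
  rescaled `w → (β/β_eff)w`, `b → (β/β_eff)b − μ` to emulate the target BM.
* **Mean-field theory** of the noise network: self-consistent E/I rates,
  population-averaged covariances from the linearized fluctuation equations,
  and the input-correlation decomposition `C_in = C_shared + C_corr` with
  its prediction that `C_corr < 0` in the inhibition-dominated regime.
* **Evaluation**: empirical state distributions, Kullback–Leibler divergence
  (nats) to exact or sampled references, entropies, pairwise unit
  correlations, and the empirical `C_shared`/`C_corr` decomposition from
  background-input snapshots.
* **A generative task**: CD-1 training of a fully visible BM on synthetic
  digit-like prototype patterns (pixel grid + one-hot labels) with a
  class-rebalancing outer loop, evaluated per noise backend on the
  label-state distribution.
* **Config-driven sweeps** (`run_experiment()`, YAML/JSON in, tidy CSV +
  manifest out) reproducing the figure-style experiments at desk scale, with
  `autoplot()` methods for the results.

## Worked example

Build a 10-unit random sampling network, calibrate a shared pool of 400
sources against it, sample, and compare against the exact target:

```r
library(noisebm)

net    <- make_random_sampling_network(M = 10, mu_BM = -0.15 / sqrt(10), seed = 1)
target <- boltzmann_distribution(net)        # exact, 2^10 states
entropy(target)
#> [1] 6.802109

noise <- build_backend("shared", M = 10, np = noise_params(K = 200, N = 400),
                       seed = 1)
glance(calibrate_backend(noise, beta_target = 1))
#> # A tibble: 1 × 6
#>   kind   method      mu sigma2 beta_eff alpha
#>   <chr>  <chr>    <dbl>  <dbl>    <dbl> <dbl>
#> 1 shared integral    -4    1.7     1.33 0.750

simnet <- calibrated_network(net, noise)     # rescaled weights and biases
cfg    <- simulation_config(n_samples = 2e5, seed = 7, record_subset = 1:6)
trace  <- run_simulation(simnet, noise, cfg)

ref <- marginal_distribution(target, 1:6)
kl_divergence(empirical_distribution(trace), ref)
#> [1] 0.1372196
```

The shared pool's mean background input is −4 with variance 1.7, so the
Heaviside units behave like logistic units at `β_eff ≈ 1.33`; the weights are
rescaled by `α = 0.75` and the bias shift removes the −4 offset. The
divergence of 0.137 nats over the 6 observed units is the cost of sharing
`K²/N = 100` sources per unit pair. The same pipeline with private Gaussian
noise of matched strength reaches 0.0016 nats, and with a recurrent
noise network of the same `(N, K)` 0.039 nats — shared-input correlations,
not noise per se, are what hurts, and recurrent inhibition cancels most of
them:

```r
for (kind in c("private", "network")) {
  nb <- build_backend(kind, 10, noise_params(K = 200, N = 400), 1)
  tr <- run_simulation(calibrated_network(net, nb), nb, cfg)
  cat(kind, kl_divergence(empirical_distribution(tr), ref), "\n")
}
#> private 0.001625843
#> network 0.03906774
```

Figure-style sweeps return tidy tibbles and plot directly:

```r
sw <- sweep_dkl_vs_N(N_values = c(222, 400, 800, 1600), seeds = 1:3)
autoplot(sw)   # DKL vs N, one line per noise backend
```

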