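---
title: "Sampling networks and their noise sources: models, calibration and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sampling networks and their noise sources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noisebm)
```

## The scientific question

Stochastic neural-network models — Boltzmann machines foremost — assume that
every unit carries its own private source of randomness. In any physical
substrate, biological or neuromorphic, randomness instead has to come from
*somewhere*: a finite pool of background inputs, or the activity of another
network. `noisebm` implements and quantifies the consequences of that
substitution. It simulates Boltzmann-machine-like *sampling networks* of `M`
binary units whose stochasticity is supplied in one of four ways:

* **intrinsic** — units update stochastically with the logistic probability
  $F(h) = (1 + e^{-\beta h})^{-1}$ of their input field
  $h_i = \sum_j w_{ij} s_j + b_i$. This is exact Gibbs sampling from the
  Boltzmann distribution
  $p(\mathbf{s}) \propto \exp(\tfrac{\beta}{2}\sum_{ij} w_{ij} s_i s_j +
  \beta \sum_i b_i s_i)$ and serves as the ground truth.
* **private** — units are deterministic Heaviside units,
  $s_i = \Theta(h_i + \xi_i)$, with fresh Gaussian noise
  $\xi_i \sim \mathcal{N}(\mu, \sigma^2)$ at every update. The noise-averaged
  activation is the error function
  $F(h) = \tfrac{1}{2}\,\mathrm{erfc}\!\big(-\frac{h+\mu}{\sqrt{2}\sigma}\big)$.
* **shared** — the Gaussian noise is replaced by input from a finite pool of
  `N` mutually unconnected stochastic binary units; each sampling unit draws
  exactly `K` of them (fraction $\gamma$ excitatory with weight $w$, the rest
  inhibitory with weight $-gw$, Dale's law per source). Two sampling units
  then share on average $K^2/N$ sources, which correlates their inputs.
* **network** — the pool is replaced by a recurrent network of *deterministic*
  Heaviside units with the same in-degree, weights and excitatory fraction.
  When the recurrent coupling is inhibition-dominated
  ($\gamma - (1-\gamma)g < 0$), inhibitory feedback generates small negative
  correlations between sources that counteract the shared-input correlations.

The central decomposition (for two unconnected units $i, j$ reading the same
source population, with centred source activities $\bar z_k$) is

$$C^{\mathrm{in}}_{ij}
  = \underbrace{\sum_k m_{ik} m_{jk} \langle \bar z_k^2\rangle}_{C_{\mathrm{shared}}}
  + \underbrace{\sum_{k \neq l} m_{ik} m_{jl} \langle \bar z_k \bar z_l\rangle}_{C_{\mathrm{corr}}}.$$

Under Dale's law $C_{\mathrm{shared}} > 0$ always; an uncorrelated pool has
$C_{\mathrm{corr}} = 0$, while an inhibition-dominated recurrent source makes
$C_{\mathrm{corr}} < 0$, cancelling most of the shared-input term.

## Event-driven simulation

Every unit — sampling and noise alike — carries an independent exponential
clock with mean interval $\tau$ (default 1 ms; it only sets the time scale,
so all experiments are parameterized by recorded sample counts). Events are
processed from a global priority queue; ties break toward the lowest unit
index. At its event a unit recomputes its field from the *current* global
state (its own previous state never enters; there are no self-connections)
and sets its new state by its activation rule. The recorded subset's state is
appended at every sampling-unit event with $t \geq T_{\mathrm{warmup}}$
(default $10^3$ ms, which removes the dependence on the fair-coin initial
state); a switch extends recording to noise-unit events. This asynchronous
schedule is the standard Glauber/Gibbs dynamics for binary networks.

Three independent RNG streams drive (i) the event schedule, (ii) stochastic
unit updates and (iii) private-noise draws, so exchanging the noise backend
does not perturb the schedule, and jointly rescaling
$(\tau, T, T_{\mathrm{warmup}})$ reproduces the identical state sequence.
Noise delivery is purely feed-forward: there are no connections from sampling
units back to the noise source. The event loop is implemented in C++ (Rcpp),
as multi-million-event runs with hundreds of noise units are otherwise not
practical.

## Calibration

A Heaviside unit with Gaussian input noise of strength $\sigma$ behaves like
a logistic unit at an *effective* inverse temperature. Two matchings are
implemented:

* Taylor matching (slope at $h=0$): $\sigma(\beta) = \frac{2\sqrt{2}}{\sqrt{\pi}\beta}$;
* integral matching ($\int_{-\infty}^{0} F\,\mathrm{d}h = \ln 2 / \beta$ for
  both activations): $\sigma(\beta) = \frac{\ln 2\,\sqrt{2\pi}}{\beta}$.

The integral matching fits the logistic far better away from $h = 0$ and is
the package default; its inverse
$\beta_{\mathrm{eff}}(\sigma) = \ln 2 \sqrt{2\pi}/\sigma$ converts a measured
or predicted noise strength into an effective temperature. To emulate a
target machine at inverse temperature $\beta$, weights and biases are
rescaled globally,

$$w_{ij} \to \frac{\beta}{\beta_{\mathrm{eff}}} w_{ij}, \qquad
  b_i \to \frac{\beta}{\beta_{\mathrm{eff}}} b_i - \mu,$$

absorbing the noise mean $\mu$ into the bias (never into the noise source).
The backend moments come from closed forms for the shared pool
($\mu = Kw(\gamma - (1-\gamma)g)\langle z\rangle$,
$\sigma^2 = Kw^2(\gamma + (1-\gamma)g^2)\langle z\rangle(1-\langle z\rangle)$;
the defaults $K=200$, $w=0.05$, $\gamma=0.8$, $g=8$,
$\langle z\rangle = 0.5$ give $\mu=-4$, $\sigma^2=1.7$), from mean-field
theory for the recurrent network (below), or empirically from recorded
background-input snapshots (`input_stats_empirical()`), which is the fallback
the method prescribes for heterogeneous or analytically intractable sources.
The private backend uses the same $\sigma$ as the matched pool so all
backends share one $\beta_{\mathrm{eff}}$.

Heterogeneous mode computes per-unit $(\mu_i, \sigma_i^2)$ from the realized
projection rows; the weight rescaling itself stays global (a per-unit weight
rescale would break the symmetry of `W`), while per-unit means enter the bias
shift.

## Mean-field theory of the noise network

With homogeneous E/I populations the `N`-unit problem reduces to two
self-consistency equations for the rates,
$\langle s_\alpha\rangle = \tfrac12\,\mathrm{erfc}\big(-\frac{\mu_\alpha+b_\alpha}{\sqrt2 \sigma_\alpha}\big)$,
with $\mu_\alpha = \sum_\beta K_{\alpha\beta} w_{\alpha\beta}\langle s_\beta\rangle$ and
$\sigma^2_\alpha = \sum_\beta K_{\alpha\beta} w_{\alpha\beta}^2 a_\beta +
\sum_{\beta\gamma}(Kw)_{\alpha\beta}(Kw)_{\alpha\gamma} c_{\beta\gamma}$,
$a_\beta = \langle s_\beta\rangle(1-\langle s_\beta\rangle)$, solved by a
damped fixed-point iteration (damping 0.5, tolerance $10^{-10}$). The
population-averaged covariances solve the exact 3×3 linear system

$$2 c_{\alpha\beta} = \sum_\gamma (\tilde w_{\alpha\gamma} c_{\gamma\beta}
 + \tilde w_{\beta\gamma} c_{\gamma\alpha})
 + \tilde w_{\alpha\beta}\frac{a_\beta}{N_\beta}
 + \tilde w_{\beta\alpha}\frac{a_\alpha}{N_\alpha},
 \qquad \tilde w_{\alpha\beta} = S(\mu_\alpha,\sigma_\alpha) K_{\alpha\beta} w_{\alpha\beta},$$

and the outer loop alternates rates and covariances to joint convergence.
Two deliberate readings of ambiguous formulas, both exposed behind flags:

* the susceptibility is implemented as the Gaussian density at threshold,
  $S = \exp\!\big(-\frac{(\mu+b)^2}{2\sigma^2}\big)/(\sqrt{2\pi}\sigma)$ —
  the slope of the erfc activation; the dimensionally inconsistent variant
  with $2\sigma$ in the exponent is available as `form = "printed"`;
* population in-degrees use the fixed-in-degree reading
  $K_{\alpha E} = \mathrm{round}(\gamma K)$, $K_{\alpha I} = K - K_{\alpha E}$
  (consistent with each unit receiving exactly `K` inputs); the density-based
  reading $K_{\alpha E} = \gamma N$ is available as `indegree_rule = "printed"`.

At the default operating point ($N=300$, $K=100$, target activity 0.5) the
predicted rates match simulation to $<0.005$ and the three covariances agree
in sign and within 50% in magnitude; the linearization degrades gracefully at
very dense connectivity ($K/N \to 1$), where the predicted input variance is
~30% above the measured one — one reason the empirical calibration mode
exists.

The same statistics feed the predicted decomposition
$C_{\mathrm{shared}} = \frac{K_E^2}{N_E} w^2 a_E + \frac{K_I^2}{N_I}(gw)^2 a_I$,
$C_{\mathrm{corr}} = (K_E w)^2 c_{EE} - 2 K_E K_I g w^2 c_{EI} + (K_I g w)^2 c_{II}$,
with $C_{\mathrm{corr}} < 0$ throughout the inhibition-dominated regime.

## Choices where the design was genuinely open

* **Weight distribution.** Sampling-network weights are centred
  Beta(2, 2) draws (finite support, no nearly-isolated states) shifted to
  mean $\mu_{BM}$ ($-0.15/\sqrt{M}$ in the figure-style experiments); the
  biases cancel the expected recurrent input at the target activity,
  $b_i = -(M{-}1)\mu_{BM}\langle s\rangle$. The variant with the opposite
  sign convention is exposed as `bias_rule = "printed"`, but cancellation is
  what keeps the operating point centred.
* **Noise-source defaults.** $\gamma = 0.8$, $g = 8$, $w = 0.05$,
  $\langle z\rangle = 0.5$, $\beta_{\mathrm{pool}} = 1$: a standard
  inhibition-dominated parameter set (net coupling $\gamma-(1-\gamma)g = -0.8$)
  whose pool variance $\sigma^2 = 1.7$ at $K = 200$ puts
  $\beta_{\mathrm{eff}}$ near 1.33. These are fixed once and reused across
  all experiments.
* **Exact E/I split.** Each target receives exactly
  $\mathrm{round}(\gamma K)$ excitatory inputs, so the homogeneous moment
  formulas hold exactly; fully random draws are available via
  `split = "random"`.
* **Recording.** Only sampling-unit updates trigger recording by default —
  they are the natural Monte-Carlo draws; a documented switch records at
  noise-unit events too (used when simulating a noise network on its own).
* **Noise update rate.** Noise units run on the same $1/\tau$ clocks as
  sampling units. Their state therefore decorrelates on the same time scale
  at which sampling units are updated — a physical property of
  binary-unit noise sources, not an artifact.
* **KL divergences** are reported in nats. Sampled references (needed when
  the target cannot be enumerated, as in the generative task) get one
  pseudo-count per state; exact Boltzmann references have full support and
  need none.
* **Rebalanced training.** The class-resampling rule
  $q(c) \leftarrow \mathrm{normalize}\big(q(c)\, q^*(c)/\max(\hat p(c), 10^{-3})\big)$
  is the minimal multiplicative update with fixed point $\hat p = q^*$.
  It reacts with a one-session lag, so aggressive schedules oscillate; the
  defaults ($\eta = 0.01$, 20 CD-1 steps per session, 20 sessions) keep the
  loop in the damped regime. $\hat p$ is estimated by winner-take-all over
  label units (200-sample windows, ties to the lowest index) pooled over
  independent restart chains: the trained distribution is multimodal and a
  single chain mixes between modes too slowly for an unbiased estimate. CD-1's
  negative phase uses one asynchronous Gibbs sweep per data vector; one random
  unit permutation per step is shared across the batch, which is a valid
  asynchronous schedule and lets the sweep vectorize.

## What the synthetic generators do and do not emulate

The random-network generator reproduces the *ensemble* the evaluation is
defined over — symmetric Beta-distributed weights, cancellation biases — not
any particular trained model. The prototype generator for the generative task
reproduces the structure of a downscaled handwritten-digit setup (a pixel
grid plus a one-hot label block, 12×12+10 = 154-dimensional at full scale)
with random, well-separated binary patterns (pairwise Hamming distance at
least 25% of the pixels); it does not reproduce the statistics of real
handwritten digits — strokes, pixel correlations, within-class variability.
Tests passing on these synthetic patterns show that the training loop,
calibration and evaluation machinery work end to end at toy scale (4 classes
on a 6×6 grid by default), not that the pipeline reaches any particular
accuracy on real image data.

## Problem sizes and numerical choices

Experiments default to desk scale: sampling networks of $M = 20$ (exact
enumeration of the $2^{20}$-state target remains feasible; the enumeration
cap is 20 units and raising it is a memory decision, $2^M$ doubles), observed
subsets of $m = 6$ units, $10^6$ recorded samples for headline comparisons
and $3\times10^5$ for sweeps, 3–5 network realizations per condition, and
noise sources of $N$ = a few hundred to a few thousand. Larger networks
($M = 50, 100$) are evaluated against smoothed sampled references from long
intrinsic runs. Convergence tolerances: $10^{-10}$ on mean-field rates,
$10^{-8}$ on the joint rate/covariance loop, with non-convergence reported as
an error, never returned silently. Degenerate inputs (empty traces,
zero-variance units, references without full support) raise errors or
`NA`-with-warning rather than silent zeros.

## Known limitations

* The linearized covariance theory loses accuracy for $K/N \gtrsim 0.7$; use
  empirical calibration there.
* Very dense noise networks ($K$ close to $N$) freeze into fixed points
  (detectable with `detect_fixed_point()`) and stop being useful noise
  sources — this is a property of the model, reproduced, not worked around.
* With the default inhibition-dominated parameters the network source
  suppresses shared-input *covariance* to ~10–20% of the shared-pool value,
  but because it also cancels ~80% of the per-unit input variance, its
  residual input *correlation coefficient* plateaus near a quarter of the
  pool's, and its sampling error — while an order of magnitude below the
  shared pool's at $N \approx K$ — stays several-fold above the private
  Gaussian floor at desk scale. The package reports these quantities as
  measured.
* Spiking (integrate-and-fire) implementations and Poisson spike-train
  backends are out of scope; the binary-unit machinery is the substrate.
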