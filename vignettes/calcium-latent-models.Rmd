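---
title: "Latent variable models for calcium imaging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent variable models for calcium imaging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calatent)
```

## The observation model

Calcium imaging reports neural spiking indirectly: each action potential
produces a rapid rise in somatic calcium and hence in indicator
fluorescence, followed by a slow exponential decay. Latent variable models
for population activity, however, are almost universally formulated for
spike counts. `calatent` bridges the two with a single observation
likelihood that is shared by every model in the package. For neuron $i$
with dF/F trace $y_t$, latent Poisson count $n_t$ and rate $\lambda_t$:

$$
n_t \sim \mathrm{Poisson}(\lambda_t), \qquad
y_t \mid n_t, y_{t-p:t-1} \sim
\mathcal{N}\!\Big(\textstyle\sum_{j=1}^{p}\alpha_j y_{t-j} + c\, n_t,\;
\sigma^2\Big).
$$

The AR coefficients $\alpha_j$ capture the decay (and for $p=2$ the finite
rise) of the calcium transient, $c$ is the fluorescence influx per spike,
and $\sigma^2$ is per-bin process noise. The key computational fact is that
the count can be summed out numerically,

$$
p(y_t \mid y_{t-p:t-1}, \lambda_t)
 = \sum_{n=0}^{R} \mathcal{N}(\delta_t;\, c\,n,\, \sigma^2)\,
   \mathrm{Poisson}(n; \lambda_t),
\qquad \delta_t = y_t - \sum_j \alpha_j y_{t-j},
$$

which turns any spike-count latent variable model into a fluorescence model
by substituting this marginal for the Poisson likelihood. The sum is
evaluated in log space (log-sum-exp; Poisson log-pmf via `lgamma`) because
$\sigma^2$ of order $10^{-2}$ underflows direct exponentiation. Alongside
the log-density the kernel returns the posterior count moments
$E[n_t \mid \delta_t]$ and $E[n_t^2 \mid \delta_t]$; every fitting
algorithm in the package is built from these two moments, which is why no
automatic differentiation framework is needed (gradients of the marginal
with respect to $\lambda$, $c$, $\sigma^2$ and $\alpha$ are all closed
forms in them).

**Truncation.** The default cap is $R = 10$ counts per bin, which at the
firing rates relevant here ($\lambda \le 0.5$ spikes/bin) discards Poisson
mass below $10^{-10}$. Whenever rates are larger the cap is raised
automatically to $\lceil \lambda_{\max} + 10\sqrt{\lambda_{\max}}\rceil$,
and an explicit user-supplied cap that leaves more than $10^{-8}$ of tail
mass triggers a warning with the discarded mass.

**Initial conditions.** Lags reaching before the first bin of a recording
(or of each trial) are treated as zero, matching a dF/F baseline of zero.
The first $p$ bins therefore use a truncated AR prediction.

**Interpreting $c$ and $\sigma^2$.** $c$ is constant per neuron over time.
Measurement noise added by simulators (shot/readout noise) is deliberately
*outside* the model: the generators add it on top of the AR recursion, so
fitted models always face a degree of misspecification, as real data would
impose.

## Hidden Markov models

`calcium_hmm()` fits a $K$-state HMM where each state carries a per-neuron
Poisson rate vector $\lambda_k$ and the observation parameters
$(\alpha, c, \sigma^2)$ are shared across states. The E-step marginalizes
counts to obtain state-conditional likelihoods and runs scaled
forward–backward per trial. For the M-step, rather than a gradient inner
loop, the package exploits a second augmentation: conditioning on the
posterior moments of the latent counts makes every update closed-form —
$\lambda_{k,i}$ from responsibility-weighted expected counts, $(\alpha_i,
c_i)$ from a $(p{+}1)$-dimensional weighted least-squares system, and
$\sigma_i^2$ from expected squared innovations. Each conditional update
maximizes the same expected complete-data objective exactly, so the
marginal likelihood is monotone (the fitter warns if float error ever
violates this). The AR(1) coefficient is clipped to $[0.6, 0.95]$ during
fitting (configurable), keeping the recursion stable.

Baselines use the same E-step machinery with different emissions:
time-independent Gaussian emissions with a state-dependent mean and full
covariance (ridge-regularized; note that with $N(N{+}1)/2$ covariance
parameters per state this model can overfit moderate recordings, which is
part of why it recovers states poorly), AR(1) Gaussian emissions with
per-neuron decay and state-dependent offsets (the calcium model with the
spiking component ablated), and Poisson emissions for fitting spike-count
data directly.

Initialization is k-means on lightly smoothed observation columns, with
perturbed restarts (default 3) scored by final training likelihood; a
known-label warm start (`init_states`) and a full warm start (`init`) are
also available. The number of states is chosen by held-out marginal
likelihood (`select_num_states`).

`occupancy_stats()` summarizes when a state occurs across trials: the
occupancy curve is the per-bin fraction of trials in the state; the peak
time is the maximum of a 3-bin moving-average smoothed curve, and the
width is the full width at half maximum of the contiguous block around the
peak. The light smoothing removes single-bin spikes in the curve without
displacing a genuine peak by more than one bin.

## Gaussian process factor analysis

`calcium_gpfa()` places independent squared-exponential GP priors on $p$
latent time courses, maps them to rates through
$\lambda_t = f(Cx_t + d)$ (softplus by default; exponential optional) and
pushes rates through the calcium likelihood (AR order 1 or 2). Inference is
black-box stochastic variational inference with a mean-field Gaussian
posterior over the latents (means and scales per latent and bin),
reparameterized Monte Carlo estimates of the expected log-likelihood
(default 5 samples/step), a closed-form KL to the GP prior, and Adam
(step size $10^{-2}$ decayed linearly to a tenth).

Design choices worth knowing:

* **Fixed length-scales.** Length-scales are set at initialization
  (default 350 bins) and not optimized: learning them requires a fresh
  $O(T^3)$ Cholesky per step, whereas fixing them lets the prior inverse
  Gram be factored once. Because latents are only identified up to an
  affine map — and evaluation regresses inferred onto true latents — a
  moderate smoothness mismatch is absorbed by the alignment.
* **Mean-field posterior.** A diagonal Gaussian across time and latent
  dimensions is the simplest family compatible with the black-box
  estimator. It underestimates posterior smoothness; a banded family is a
  natural extension point.
* **AR(2) initial values.** AR(1) models initialize the decay at 0.51;
  AR(2) models at $(1.81, -0.81)$ (a pair of real roots near 0.9,
  approximating a fast-rise/slow-decay transient). Influx starts at 1 and
  the noise variance at the variance of one-step trace differences.
* **Baselines.** `obs = "gaussian"` models traces directly as Gaussian
  around the linear readout; `obs = "poisson"` fits count data (true
  spikes, or spike estimates produced by an external deconvolution tool)
  with the same latent machinery.

## Sequential VAE with recurrent dynamics

`calcium_lfads()` fits nonlinear trial dynamics: per trial an initial state
$x_0 \sim \mathcal{N}(0, \sigma^2_{ic})$ and inferred inputs $u_t$ with an
AR(1) prior drive a GRU generator; generator states read out to rates
through $\exp(Cx_t + d)$; observations follow the calcium likelihood (or a
Gaussian readout baseline). The approximate posterior is amortized: a
bidirectional GRU encodes each trial into $q(x_0)$, and a forward GRU over
the encoder's per-step outputs yields $q(u_t)$. Both networks are trained
jointly with the generator by reparameterized gradients of the ELBO, with
a linear KL warmup (default 500 steps), Adam, and gradient-norm clipping.
The package implements backpropagation-through-time for the GRU layers
directly (verified against finite differences in the test suite), and the
likelihood gradients again come from the posterior count moments, so the
calcium head's $(\alpha, c, \sigma^2)$ are refined during training after a
data-driven initialization: $\alpha$ by lag regression on decreasing trace
segments, $c$ by a grid sweep over $[0.8, 2.2]$ aligning positive trace
increments with jump sizes $\{0, c, 2c, 3c\}$.

Topology choices: the controller sees the bidirectional encoding but not
the generator state (the canonical architecture feeds the generator state
back; dropping the feedback decouples the encoder and generator
backpropagation passes at a modest cost in posterior expressiveness), and
rates are read directly from the generator state without a separate
low-dimensional factors layer. Defaults: generator 32 units, encoder 64,
controller 32, one inferred input; initial-state prior variance 1; input
prior $u_t \sim \mathcal{N}(0.9\,u_{t-1}, 0.1)$.

## Simulators

Three generators export ground truth (states or latents, spikes, and all
parameters) alongside traces; all are deterministic given a seed, and all
add Gaussian measurement noise (default sd 0.2) *outside* the AR recursion
so that no fitted model matches the data-generating process exactly.

* **Chain HMM** (`simulate_chain_hmm`): 5 states, cyclic transitions
  (stay 5/6, advance 1/6), 5 groups of 5 neurons, each neuron firing at
  0.2 spikes/bin only in its group's state; decay coefficients drawn from
  $\mathcal{N}(0.8, 0.1)$ (variance 0.1) clipped to $[0.6, 0.95]$ — an
  appreciable fraction of neurons sits at the bounds, including very slow
  decays — influx 1, process noise $10^{-2}$; two independent sequences of
  2000 bins (train/test).
* **GP latents** (`simulate_gp_latents`): three latents with length-scales
  $\{250, 450, 500\}$ bins over 4000 bins, 30 neurons, softplus rates.
  The generative calcium dynamics default to AR(2) with a fast-rise and a
  slow-decay root per neuron: real indicator transients have finite rise
  times, and this is precisely the feature that rewards an AR(2)
  observation model over AR(1). An AR(1) generator would make the two
  likelihoods nearly indistinguishable.
* **Lorenz trials** (`simulate_lorenz`): the canonical chaotic Lorenz
  system $(\sigma, \rho, \beta) = (10, 28, 8/3)$ integrated by RK4 at
  $\Delta t = 0.025$ with a 50-step burn-in per trial, standardized and
  read out to 30 neurons through unit-norm loadings with offsets
  calibrated so the realized mean count is 0.42 spikes/bin; decay
  $\sim U(0.8, 0.95)$, influx $\sim U(0.8, 1.2)$, process noise $10^{-3}$.

What the simulators do *not* emulate: optics (point-spread, neuropil
contamination, motion), indicator saturation and dye buffering, bursting
nonlinearities, and cell-extraction errors. Passing the package's
benchmarks therefore demonstrates correct inference under realistic noise
and model mismatch of the additive kind, not robustness to every artifact
of a real microscope.

## Evaluation metrics

Discrete states are identified only up to relabeling: `align_states()`
maximizes agreement over permutations (Hungarian assignment on the
confusion matrix) and then reports the Pearson correlation of the aligned
integer label sequences, plus the raw agreement fraction. The correlation
is meaningful here because the chain states are ordinally arranged; for
unordered state spaces the agreement fraction is the better summary.
Continuous latents are identified up to affine maps: `align_latents()`
regresses true onto inferred latents (with intercept, pooled across time
and trials) and reports per-dimension and mean $R^2$ and MSE, with
per-trial $R^2$ under the pooled map when trials are present.

## Numerical choices and degenerate inputs

* Transition-matrix and initial-distribution updates add $10^{-8}$
  pseudo-counts; rates and variances are floored ($10^{-6}$ and
  $10^{-10}$–$10^{-6}$ respectively) to keep log-likelihoods finite.
* Forward–backward scales per bin; an all-zero likelihood row raises a
  numerical-failure error naming the bin. Viterbi ties break toward the
  lower state index.
* GP Gram matrices get diagonal jitter $10^{-5}$ (escalated up to
  $1000\times$ before raising an error with a condition estimate).
* Constant (degenerate) traces fall back to default observation
  parameters with a warning in the initializers.
* All stochastic entry points accept a seed and are reproducible given
  it; every CLI run writes a manifest with the seed and input digests.

## Problem sizes used in the test-suite benchmarks

The package's own validation experiments run at sizes chosen to make the
full suite convenient on a single CPU: the chain-HMM recovery experiment
runs at the generator's native size (25 neurons, 2000 train + 2000 test
bins, five seeds); state-number selection scans $K = 3..7$ over three
seeds; the GP-latents comparison uses 1000 bins and 2000 VI steps over
three seeds; and the Lorenz experiment uses 100 trials (80 train, 20
evaluation) with a reduced network (generator 16, encoder 32, controller
16) and a few hundred training steps. The full-scale Lorenz protocol (400
trials, defaults) is available through the same functions.

## Known limitations

* The HMM assumes emission parameters shared across states and no
  state-duration modeling; input-driven transitions and semi-Markov
  variants are out of scope.
* GPFA's mean-field posterior and fixed length-scales trade posterior
  calibration for speed; reported latents are posterior means.
* The sequential VAE omits the generator-feedback controller and a
  separate factors layer, and uses modest network sizes by default.
* Spike inference (deconvolution) is intentionally not provided; the
  Poisson baselines accept externally produced spike estimates instead.
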