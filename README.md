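# calatent

Latent variable models fitted **directly to calcium-imaging fluorescence
traces**, without deconvolution and without pretending the traces are
Gaussian.

## The problem

Two-photon calcium imaging records hundreds of neurons at once, but what it
measures is a slow, noisy fluorescence transient driven by spiking, not the
spikes themselves. The standard latent variable models of systems
neuroscience — hidden Markov models for discrete population states,
Gaussian-process factor analysis (GPFA) for smooth latent trajectories,
sequential autoencoders with recurrent dynamics for nonlinear dynamics —
are formulated for spike counts. Practitioners therefore either deconvolve
traces into uncertain spike estimates, or model dF/F with Gaussian noise;
the first discards spike-count uncertainty, the second ignores the
asymmetry and long autocorrelation of calcium signals.

`calatent` instead equips all three model families with a calcium
observation likelihood: for neuron $i$, latent Poisson spike counts drive
an autoregressive fluorescence process,

$$
n_t \sim \mathrm{Poisson}(\lambda_t),\qquad
y_t \mid n_t \sim \mathcal{N}\!\Big(\sum_{j=1}^{p}\alpha_j y_{t-j}
  + c\,n_t,\ \sigma^2\Big),
$$

and the count is marginalized numerically,
$p(y_t \mid \lambda_t) = \sum_{n=0}^{R}
\mathcal{N}(\delta_t; c\,n, \sigma^2)\,\mathrm{Poisson}(n;\lambda_t)$ with
$\delta_t = y_t - \sum_j \alpha_j y_{t-j}$, evaluated stably in log space.
Because the marginal and its derivatives reduce to the posterior count
moments $E[n_t|\delta_t]$ and $E[n_t^2|\delta_t]$, the package fits every
model with exact conditional-maximization or reparameterized-gradient
updates — no automatic-differentiation framework required.

Models provided (each with conventional baselines for comparison):

| function | latent structure | observation models |
|---|---|---|
| `calcium_hmm()` | discrete Markov states | calcium, Gaussian, AR-Gaussian, Poisson-on-spikes |
| `calcium_gpfa()` | GP latent trajectories | calcium AR(1)/AR(2), Gaussian, Poisson-on-spikes |
| `calcium_lfads()` | GRU dynamics, sequential VAE | calcium, Gaussian |

Plus simulators with exported ground truth (`simulate_chain_hmm`,
`simulate_gp_latents`, `simulate_lorenz`), alignment metrics
(`align_states`, `align_latents`), and a CLI (`exec/calatent`).

## Worked example

Five groups of five neurons fire sequentially under a cyclic 5-state chain;
we observe only noisy calcium traces and ask the HMM to recover the states
of a held-out sequence:

```r
library(calatent)

sim <- simulate_chain_hmm(seed = 1)          # 25 neurons, 2000 + 2000 bins
fit <- calcium_hmm(sim$train, K = 5, seed = 1)
print(fit)
#> <calcium_hmm> K = 5 states, 25 neurons, obs = 'calcium'
#>   logLik -12031.81 after 50 EM iterations

states <- predict(fit, newdata = sim$test, type = "states")
align_states(sim$test_states, states, K = 5)
#> <state_alignment> rho = 0.914, agreement = 0.924
```

`rho` is the Pearson correlation between the true and inferred state
sequences after the state labels are optimally matched (Hungarian
assignment); `agreement` is the fraction of bins labeled identically. A
Gaussian-observation HMM on the same traces reaches only `rho` ≈ 0.6–0.7
because it has no account of the slow transient decay, while the calcium
HMM performs nearly as well as a Poisson HMM given the true spikes — the
information lost by observing fluorescence instead of spikes is largely
recovered by modeling the transient explicitly.

## Documentation

The methods vignette (`vignettes/calcium-latent-models.Rmd`) describes the
observation model, the fitting algorithms, every tunable that matters, the
simulators' scope, and known limitations. All exported functions carry
roxygen documentation.
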