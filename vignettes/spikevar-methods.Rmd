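---
title: "Variational learning in recurrent spiking networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variational learning in recurrent spiking networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikevar)
```

## The generative model

`spikevar` treats a recurrent network of stochastic spiking neurons as a
generative model of spike-train histories. Each neuron is a Spike Response
Model with escape noise: its membrane potential is

$$u_i(t) = \sum_j w_{ij}\,\phi_j(t) + \eta_i(t),$$

where $\phi_j$ is the presynaptic EPSP trace (an exponential filter of
neuron $j$'s spikes with time constant $\tau$) and $\eta_i$ is a
spike-triggered adaptation potential (each own spike subtracts $\eta_0$,
decaying with $\tau_{\mathrm{adapt}}$). Spikes are emitted by a conditional
Poisson process with exponential escape rate
$\rho_i(t) = \rho_0 \exp[(u_i - \vartheta)/\Delta u]$. In discrete time
with bin width $dt$ the sampler emits at most one spike per bin with
probability $1 - e^{-\rho\,dt}$.

The population is split into *visible* neurons, which can be clamped to
data, and *hidden* neurons, whose spikes are latent variables. A single
population carries two switchable synapse sets: the generative weights
$w^G$ define the joint distribution over all spike trains, while the
recognition weights $w^Q$ — which never target visible neurons — define,
with the visible neurons clamped, an approximate posterior
$q(X_H \mid X_V)$ over hidden spike trains. Running the network with $w^Q$
off produces generative samples; running with $w^G$ off and the data
clamped produces approximate posterior samples.

### Default parameters

| parameter | meaning | default |
|---|---|---|
| `dt` | bin width | 1 ms |
| `tau` | membrane/EPSP time constant | 10 ms |
| `eta0` | adaptation strength | 0.1 mV |
| `tau_adapt` | adaptation time constant | 10 ms |
| `rho0` | rate scale | 1 kHz |
| `theta` | threshold | 0 mV |
| `delta_u` | firing sensitivity | 1 mV |
| `mu_g`, `mu_q` | learning rates | $10^{-5}$ |
| `tau_g` | fast averaging time constant | 10 ms |
| `tau_baseline` | baseline time constant | 100 ms |
| batch | training window $T$ | 200 ms |

Weights are initialized i.i.d. Gaussian with mean 0 and sd 0.01. Intensities
are expressed in kHz and time in ms, so log-likelihoods are in nats with
$\log\rho = \log\rho_0 + (u-\vartheta)/\Delta u$ computed directly from the
potential (never by exponentiating and taking the log again). The exponent
of the escape rate is clipped at $\pm 500$ purely as overflow protection.

## Two likelihood forms

The package distinguishes two per-bin log-likelihood conventions and keeps
both available through a `form` argument:

* **continuous limit**: $X\log\rho - \rho\,dt$, the density of the point
  process, the form in which the classical learning rules are derived.
* **discrete exact**: $X\log(1-e^{-\rho dt}) - (1-X)\rho\,dt$, the exact
  log probability mass of the Bernoulli sampler. Summed over all rasters
  of a small network it is exactly normalized, which makes it the basis
  for the enumeration oracle and for exactness tests of the
  score-function identities; the corresponding exact score factor is
  $[X\,z/(e^{z}-1) - (1-X)\,z]/\Delta u$ with $z=\rho\,dt$.

The two agree to first order in $\rho\,dt$, and the continuous limit is
the form in which the learning rules are usually derived. That derivation,
however, assumes $\rho\,dt \ll 1$, and the default physical constants put
an untrained network at $z = \rho\,dt \approx 0.6$ (rate scale 1 kHz at
threshold, 1-ms bins). At such $z$ the continuous forms are not merely
imprecise — they destabilize learning in two distinct ways:

* the continuous-limit post factor $X - \rho\,dt$ has per-bin mean
  $(1-e^{-z}) - z \approx -0.17$ under the sampler, so the summed batch
  score acquires a large *deterministic* component (on the order of
  $-0.17\,\bar\phi\,T$ per synapse onto active inputs); multiplied by
  free-energy fluctuations it produces coherent, catastrophic weight
  kicks;
* the continuous generative gradient of a neuron that fires in every bin
  never vanishes — matching $p = 1$ requires $\rho \to \infty$ — so a
  transiently saturated hidden neuron drags its generative weights off to
  infinity, whereas the discrete gradient $z/(e^z - 1)$ decays to zero as
  the fit approaches saturation.

Training therefore differentiates the *exact* likelihood of the
finite-bin process the simulator implements (`learn_form =
"discrete_exact"` in `learner_config()`, applied to the post factors, the
batch free-energy modulator and the online novelty input alike); the
discrete score has exactly zero mean under the sampler and all terms stay
bounded under saturation. The continuous-limit forms remain the defaults
of the fully observed maximum-likelihood gradient,
`complete_log_likelihood()` and `instantaneous_free_energy()`, and remain
available everywhere through `form`/`learn_form` arguments; in the
$\rho\,dt \to 0$ regime the two conventions coincide. The
importance-sampling evaluator and the benchmark probes default to the
discrete form for the reasons given in the evaluation section. The
enumeration oracle always uses the discrete form, which is what makes its
normalization and unbiasedness identities exact to machine precision.

## Free energy and learning rules

With hidden neurons, the data log-likelihood
$\log p(X_V) = \log \int p(X_V, X_H)\,dX_H$ is intractable; the package
minimizes the variational free energy
$F = \langle -\log p(X_V, X_H) + \log q(X_H|X_V)\rangle_q$, an upper bound
on $-\log p(X_V)$ whose gap is $KL(q\,\|\,p(X_H|X_V))$. On a clamped
("learn"-mode) simulation the per-bin *instantaneous free energy* is

$$\hat F_t = -\sum_{i \in V\cup H}\left[X_i\log\rho^G_i - \rho^G_i dt\right]
           + \sum_{i\in H}\left[X_i\log\rho^Q_i - \rho^Q_i dt\right],$$

and its sum over a window is the point estimate $\hat F(T)$.

Four rule variants share the same primitive, the product of a
post-synaptic factor (spike minus expected spike, scaled by the
intensity's log-derivative $1/\Delta u$; written here in its
continuous-limit form $[X_i - \rho_i\,dt]/\Delta u$, with the
discrete-exact variant substituted per `learn_form`) and the presynaptic
trace $\phi_j$:

* **fully observed**: gradient ascent on the complete-data log-likelihood
  (convex without hidden neurons).
* **naive batch**: generative weights follow the same Hebbian gradient;
  recognition weights follow the score-function (REINFORCE) estimator,
  modulated by the whole-batch free energy $\hat F(T)$.
* **variance-reduced batch**: the modulator becomes the error signal
  $e(T) = \hat F(T) - \bar F$ with $\bar F$ an exponential moving average
  over previous batches (decay 0.9, an effective window of roughly ten
  batches). The expectation of the update is unchanged — the baseline is
  independent of the current batch's hidden spikes — but its variance
  growth with network size drops from roughly quadratic to roughly
  linear. The error signal is only defined relative to a baseline
  averaged over several previous batches, so the first
  `baseline_warmup` batches (default 10) estimate $\bar F$ as a plain
  running mean while the recognition weights are held; without the
  warm-up, a raw batch-to-batch free-energy swing — thousands of nats on
  structured data — would enter as the modulator of the very first
  updates and can destabilize the weights outright.
* **online**: batch sums are replaced by per-synapse Hebbian traces
  $H_{ij}$ (exponential moving averages with time constant $\tau_G$) and
  the batch baseline by the running novelty signal $e_N(t)$; updates are
  applied every bin, scaled by $dt$ so that learning-rate semantics are
  per-ms and survive re-binning. The generative update
  $\Delta w^G = \mu^G H^G dt$ is two-factor Hebbian; the recognition
  update $\Delta w^Q = -\mu^Q e_N H^Q dt$ is a three-factor rule whose
  global factor is the novelty signal: positive covariance between the
  Hebbian trace and the free energy depresses the synapse.

A *simplified* (merged-network) variant ties the recognition weights onto
hidden neurons to the generative ones, so the generative forward dynamics
doubles as the posterior proposal. Under tying the hidden generative and
recognition terms of $\hat F_t$ cancel exactly and the free energy reduces
to the visible terms. Applying the tying constraint to the online rules
splits the single weight set by postsynaptic target: synapses onto visible
neurons keep the two-factor rule, synapses onto hidden neurons keep the
three-factor rule. This split is our reading of the merged model's update;
it is the unique assignment consistent with differentiating the tied free
energy.

Sign conventions follow descent on $F$ throughout: the generative update
ascends the complete-data likelihood, the recognition update descends the
(score-estimated) free energy.

### The novelty signal

$e_N(t)$ is the difference of two cascaded exponential averages of
$\hat F_t$: a fast one (time constant $\tau_G$) and a slow baseline that
filters the fast average (time constant $\tau_{\mathrm{baseline}}$, so the
effective baseline time scale depends on both constants). It measures
instantaneous surprise relative to the slowly adapting background level
and doubles as the global third factor of recognition plasticity. Both
averages warm-start at the first observed value during training runs;
a cold start at zero would manufacture a large spurious novelty transient
(and, at higher learning rates, destabilize early learning) that reflects
the initialization rather than the data.

### Divergence

Weights are not clipped; the unmodified naive score-function rule can
and does blow up when $|\hat F(T)|$ is large (it scales with network size
times batch length). Training halts with a diagnostic at the last finite
weights rather than silently constraining the dynamics — the instability
*is* the documented failure mode that motivates baseline removal.

## Evaluation

The marginal likelihood of held-out data is estimated by importance
sampling: hidden rasters are drawn from the recognition network clamped to
the data, and $\log p(X_V) \approx \log\,\mathrm{mean}\,e^{-\hat F}$ via a
stable log-sum-exp. The default protocol is 500 samples of 100 ms; longer
data is tiled into non-overlapping 100-ms windows that are evaluated
independently (traces restart at window boundaries) and summed. The
estimator is consistent and biased low at finite sample counts. With no
hidden neurons it reduces exactly to the complete-data log-likelihood.

The estimator defaults to the discrete-exact likelihood form. Importance
weights are probability ratios, and only the discrete form is a
probability at all operating points: the continuous-limit form assigns,
e.g., log-probability $z - \log z$ below zero to a near-certain spike at
large $z = \rho\,dt$, so whenever the recognition proposal visits high
intensities the continuous-form "weights" explode and the estimate is
meaningless (it can exceed zero by astronomical amounts). The
continuous-limit form remains available via `form` for the
$\rho\,dt \ll 1$ regime it is valid in.

On tiny instances (at most $2^{20}$ hidden configurations) an
exhaustive-enumeration oracle computes the exact marginal, posterior,
expected free energy and KL gap using the discrete-exact form, and the
exact expectations of the batch updates. These identities back the test
suite: the score has exactly zero mean, baseline removal leaves the
expected update unchanged, both equal the finite-difference gradient of
the exact expected free energy, and
$\langle\hat F\rangle_q + \log p(X_V) = KL \ge 0$.

## Synthetic benchmarks

**Stairs patterns.** Three groups of ten visible neurons activate in fixed
cyclic order; the active group fires at 700 Hz, inactive groups at 1 Hz,
and activation durations are Gaussian (mean 30 ms, sd 10 ms) truncated at
positive values, sampled by rejection. At 1-ms bins a 700 Hz rate gives a
per-bin spike probability of $1-e^{-0.7}\approx 0.50$ — the exact
finite-bin form, not the saturating first-order one. The task needs memory
about three membrane time constants long plus the transition structure,
which is exactly what a fully observed network lacks.

**Maze environment.** Rooms on a square lattice (only lattice neighbors
accessible) each present a grayscale view image; pixels map affinely onto
firing rates in [0.01, 9] Hz and drive one visible neuron per pixel with
the exact per-step spike probability over 100-ms steps (time is abstract:
one raster bin per step, network constants unchanged). The test maze
equals the target maze except for a configurable number of rooms with
fresh images. Room views are procedural glyphs (seeded random strokes,
box-blurred) so no external images are needed; an adapter accepts
user-supplied images such as handwritten digits. Glyphs are normalized to
a common mean brightness — rooms should differ in *which* pixels are
bright, not in how many, otherwise total image brightness alone separates
the mazes and confounds the free-energy comparison. Replacement glyphs
are additionally redrawn until their pixel correlation with every
familiar view is below 0.5: on a small pixel grid a random glyph can come
out as a near-copy of a familiar one, in which case the replaced room is
not actually novel and the detection task is ill-posed (distinct
handwritten digits satisfy this naturally). The agent performs a
uniform random walk over neighbors with geometric dwell times (default
mean 5 steps; the dwell distribution is a modeling choice — only the
existence of multi-step dwells is constrained by the task design).

What the generators do *not* emulate: real sensory statistics (natural
images, place-field structure), goal-directed behavior, trial-to-trial
nonstationarity, or recording noise. Passing benchmarks therefore shows
that the learning machinery works as specified on controlled statistics,
not that it fits any particular biological dataset.

## Scaled-down study sizes

The reference training protocol (200-ms batches, 500 presentations per
epoch, evaluations of 500 importance samples every 500 epochs, up to
$10^5$ epochs) is far beyond a test suite. The package's experiment
drivers default to desk-scale counts and accept `full_scale = TRUE` to
restore the reference protocol. The shipped checks use:

* **Stairs comparisons**: 30 visible + 12 hidden neurons, 2 400 batches
  (8 m of data) per variant, 300-sample evaluations on 1 s of held-out
  data. At this length the latent-variable model's advantage over the
  visible-only model and the agreement between online and batch learning
  are already resolved; "agreement" is operationalized as checkpoint
  correlation above 0.9 plus a final-value gap small relative to the batch
  rule's own improvement, since at short horizons the two rules differ in
  effective speed more than in attainable likelihood. The hidden-model
  variants run the recognition learning rate at $10^{-6}$: with
  unit-amplitude EPSPs the reference rates are effectively two orders of
  magnitude larger in potential space than under a $1/\tau$-normalized
  kernel (which is why desk-scale runs learn in thousands of batches at
  all), and at the online rate the *batch* rule's whole-batch modulated
  kicks diffuse hidden potentials into the saturated, score-dead region
  within a few hundred batches. The online rule, whose per-bin steps are
  two orders of magnitude smaller and whose novelty signal corrects on
  the 100-ms scale, is stable at either rate. Batch recognition updates
  also begin only after a 100-batch baseline warm-up here, clear of the
  steep initial generative transient during which any lagging baseline
  is systematically stale.
* **Variance scaling**: 500 batches per network size
  $N \in \{4, 8, 16, 32\}$, fixed weights drawn with sd
  $0.01/\sqrt{2N}$. The $1/\sqrt{N}$ normalization keeps each neuron's
  input variance constant across the sweep, i.e. keeps the network in the
  weak-coupling regime the quadratic-vs-linear variance argument assumes;
  at a size-independent weight scale, recurrent correlations grow with
  $N$ and inflate both slopes.
* **Maze novelty**: a miniature 2x2-room maze with 8x8-pixel views, two
  replaced rooms, 12 hidden neurons, 4 000 training trajectories of 100
  steps, a generative rate of $10^{-4}$ and a recognition rate of
  $10^{-5}$. The miniature task presents roughly two orders of magnitude
  less data than the reference protocol, and the online rule's per-step
  updates are correspondingly rare events per synapse; the higher
  desk-scale generative rate compensates for the shorter exposure, while
  the recognition rate stays a factor ten below it for the same
  stability reason as in the stairs comparisons. Probe free energies use
  the discrete-exact form (probes are likelihood evaluations; see the
  evaluator section). Probes average several paired walks — the two
  mazes are probed along the *same* room sequence — because hidden-spike
  sampling makes single-walk free energies noisy; the fine-grained
  novelty traces are likewise pooled over several slow walks (mean dwell
  20 steps, so that the fast average, with $\tau_G$ of 10 steps, has
  time to develop within a room visit), since a single walk visits too
  few rooms for stable segment statistics. The probe's novelty tracker is anchored at
  the *target* maze's mean free energy for both mazes — the agent carries
  the background surprise level of the environment it has learned into the
  altered one — so novelty in replaced rooms appears as one-sided positive
  excursions instead of being split symmetrically around a within-probe
  average.

## Numerical choices

* EPSP and adaptation traces are propagated *exactly* per bin (decay
  $e^{-dt/\tau}$, then add the spike), the closed-form solution of the
  trace ODE — no forward-Euler step-size bias at $dt = \tau/10$.
* Within a bin, potentials and intensities are computed from traces
  reflecting spikes up to the previous bin; the bin's spikes update the
  traces afterwards, so a spike never influences its own emission
  probability.
* Self-connections are structurally zero; self-influence is carried by
  the adaptation potential. Recognition rows onto visible neurons are
  structurally zero. All update rules preserve these zeros.
* Traces start at zero at window boundaries by default; a carry-state
  option threads $\phi,\eta$ across consecutive batches of one continuous
  trajectory.
* Evaluation windows are independent (traces restart), matching the
  independent-sample reading of the evaluation protocol.

## Known limitations

* Pure-R simulation loops cap practical sizes at a few hundred neurons
  and minutes of simulated data; the reference-scale protocol is
  expressible but slow.
* The importance-sampling evaluator degrades when $q$ is far from the
  posterior (weight degeneracy); no annealing or resampling is provided.
* The novelty experiment's free-energy separation at desk scale is a few
  nats per step; detecting it reliably needs the paired multi-walk probes
  described above.
* Learning assumes clamped visible data ("learn" mode); there is no
  semi-supervised or partially clamped mode.
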