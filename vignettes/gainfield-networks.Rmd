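---
title: "Self-organising gain-field networks: model, protocols and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-organising gain-field networks: model, protocols and analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gainfieldnet)
library(dplyr)
```

## The scientific problem

Visual neurons early in the primate dorsal pathway encode target locations
on the retina (eye-centred coordinates), while downstream parietal neurons
can encode them relative to the head.  Because the head-centred location of
a target decomposes as $h = r + e$ (retinal location plus eye position), a
coordinate transformation is needed, and the experimentally ubiquitous
ingredient for it is *gain modulation*: retinotopic neurons whose response
amplitude depends on eye position.  `gainfieldnet` simulates a two-layer
competitive network that receives such gain-modulated input and asks under
which conditions unsupervised, biologically local synaptic learning makes
output neurons *head-centred* — responding to the same head-centred location
at every eye position.

## The model

### Input layer

Each input neuron has a preferred retinal location $\alpha$ and an
eye-position parameter $\beta$, tiling the preference space in 1° steps
(retinal preferences span $[-100°, 100°]$, eye-position preferences
$[-30°, 30°]$, giving $201 \times 61 = 12{,}261$ peaked neurons and twice
that for the sigmoidal population).  Two gain forms are implemented:

* **peaked**: $v_j = \exp(-\|e-\beta_j\|^2/2\rho^2)\,
  \exp(-\|r-\alpha_j\|^2/2\sigma^2)$, a Gaussian eye-position gain of width
  $\rho$;
* **sigmoidal (monotonic)**: $v_j = [1+\exp(\kappa_j(e-\beta_j))]^{-1}
  \exp(-\|r-\alpha_j\|^2/2\sigma^2)$, with signed gain parameter
  $\kappa_j$; half of a pure sigmoidal population carries each gain
  direction.  Mixed populations convert each grid neuron to sigmoidal
  independently with probability $p$ (the *sigmoid modulation rate*), the
  gain sign then drawn with equal probability.

The nominal retinal input space is $[-90°, 90°]$; we tile preferences out to
$\pm 100°$ so that the canonical population counts hold exactly — the extra
margin neurons are essentially never driven during training and are harmless.

### Output layer

Each of $N$ output neurons integrates its afferent drive through a leaky
activation $\tau_h \dot h_i = -h_i + \sum_j w_{ij} v^I_j$ and fires at
$v_i = [1+\exp(-2\varphi(h_i - p_\pi - \theta))]^{-1}$, where $p_\pi$ is the
$\pi$-th percentile of the current activation distribution.  The percentile
term is an implicit model of lateral inhibition: it guarantees that only
about $(100-\pi)\%$ of the population can be strongly active at once.  The
percentile uses linear interpolation between order statistics (the default
convention of `stats::quantile`), computed on the freshly updated
activations of the current Euler step; the alternative (pre-update
activations) differs by $O(\Delta t)$ and decays in the same way as the
integration error.  A memory trace $\tau_q \dot q_i = -q_i + v_i$ low-pass
filters each neuron's rate.

### Learning rules

All rules update only the stored sparse synapses (each output neuron
receives a random `round(connectivity * N_I)`-subset of the input
population) and renormalise each output neuron's weight vector to unit
Euclidean norm after every update, which bounds weight growth:

| rule | derivative of $w_{ij}$ |
|---|---|
| standard trace | $\varrho\, q_i v_j$ |
| Hebbian control | $\varrho\, y_i v_j$ |
| delayed trace + anti-Hebbian | $\alpha(\beta q_i(t-\Delta T) - y_i) v_j$ |
| delayed rate + anti-Hebbian | $\alpha(\beta y_i(t-\Delta T) - y_i) v_j$ |
| current trace + anti-Hebbian | $\alpha(\beta q_i - y_i) v_j$ |
| delayed trace only | $\alpha\, q_i(t-\Delta T) v_j$ |

Tuned defaults: $\Delta T = 50$ ms, $\beta = 2.2$ for the delayed-trace
anti-Hebbian rule; $\Delta T = 500$ ms, $\beta = 2.4$ for the delayed-rate
rule; $\beta = 2.2$ for the current-trace rule; $\Delta T = 30$ ms for the
pure delayed-trace rule.  The learning rate (0.05 by default for every
rule) is expressed in s$^{-1}$: an Euler step of $\Delta t$ ms adds
`rate * factor * v_j * dt/1000` to a weight before renormalisation.  The
time constants are quoted in ms, so this convention is the only place where
a unit choice had to be made; it makes one 300 ms fixation move a fully
active synapse by about 0.015 weight units, which is what gradual
self-organisation over tens of epochs requires.

Two further numerical choices: anti-Hebbian terms can push weights
negative, and we clip them at zero before renormalising (synapses stay
excitatory, consistent with Dale's law); and the logistic exponents are
clamped at $\pm 700$ so saturated rates stay finite.

### Training and testing protocols

Training emulates natural gaze behaviour: a visual target sits still in
head-centred space while the eyes saccade.  Each epoch presents $M = 8$
head-centred locations ($-63°$ to $63°$); during each presentation the eyes
make $P = 15$ fixations of 300 ms at uniformly random positions in
$[-24°, 24°]$, joined by 400°/s constant-velocity saccades ("14 saccades
interleaved with 15 fixations"), so an epoch lasts about 40 s of simulated
time.  Trajectories are generated at 1 kHz and linearly interpolated onto
the solver grid — exact, because fixations are constant and saccades linear.
Learning stays on throughout, including during saccades; the target change
between presentations is instantaneous, and the first fixation of a
presentation starts at a freshly drawn eye position.  Dynamic state carries
over between epochs.

Testing holds each of $E = 4$ eye positions ($-18°, -6°, 6°, 18°$) fixed
while the target steps through $T = 80$ head-centred locations
($[-79°, 79°]$ in 2° increments, 330 ms per location, learning off); the
rate vector at the end of each dwell fills each neuron's $E \times T$
response matrix.  State is reset at the start of each eye-position sweep
(330 ms is long against $\tau_h = 100$ ms, so carry-over within a sweep is
marginal; resetting between sweeps removes presentation-order artefacts).

The whole coupled system is integrated by Forward Euler at
$\Delta t = \tau_h/10$.  The delay buffers store the last
$\Delta T/\Delta t$ trace and rate vectors; all delays used are integer
multiples of $\Delta t$, so delayed reads index the buffer exactly.  A
first-order convergence check (halving $\Delta t$ halves the deviation) is
part of the test suite.

## Reference-frame analysis

For each output neuron with response matrix $R[i, j]$ (rows: ascending eye
positions, columns: ascending head-centred targets):

* **Head-centredness** $\Pi$: the mean Pearson correlation between full
  rows over all eye-position pairs.  A perfectly head-centred neuron's rows
  are identical, $\Pi = 1$.
* **Eye-centredness** $\Omega$: the same pairwise correlation computed on
  windowed row segments that cover exactly the *intersection* of the
  retinal ranges sampled at each eye position.  With target spacing
  $\Delta h$ and eye spacing $\Delta e$, the window for eye position $i$
  starts at column $f_i = (\Delta e/\Delta h)(i-1) + 1$ and has length
  $V = T - (\Delta e/\Delta h)(E-1)$, which makes the alignment identities
  $t_{f_i} - e_i = t_1 - e_1$ and $t_{f_i+V-1} - e_i = t_T - e_E$ hold for
  every $i$ (asserted programmatically for every generated window).  A
  shorter window, $V = T - (\Delta e/\Delta h)(E+1)$, appears in some
  derivations of this analysis; it violates the second alignment identity,
  and we provide it only behind the `printed` flag of `window_indices()`.
  Under the standard test geometry the windows are $f = (1, 7, 13, 19)$
  with $V = 62$, covering retinal locations $[-61°, 61°]$.

A neuron is *head-centred* if $\Pi > 0$ and $\Pi > \Omega$, *eye-centred*
if $\Omega > 0$ and $\Omega > \Pi$, otherwise unclassified.  Neurons must
respond within the windowed retinal range at **every** eye position to be
analysed: logistic rates never reach exactly zero, so "no response" is
defined as a within-window response range below `eps = 0.01`
(configurable), and a neuron failing this at any eye position is excluded.
Rows (or windowed rows) with zero variance have no defined correlation and
drop out of the pair averages; if no pair survives, the metric is
undefined and the neuron stays unclassified.

Population summaries report the head-centredness *rate* (head-centred
fraction of all output neurons), the mean $\Pi$ among head-centred neurons
(undefined when none exist), and the mean $\Omega$ among all analysed
neurons.

## Covariance analysis and the prewired network

Competitive Hebbian learning drives weight vectors toward the covariance
structure of the inputs, so `covariance_map()` computes the covariance
between a reference input neuron and the whole population over the
discretised stimulus space ($[-90°, 90°] \times [-30°, 30°]$ at 1° by
default, count-normalised Riemann sum).  Because every response factorises
into a retinal and an eye-position component, each covariance entry reduces
to products of marginal cross-moments; the implementation exploits this and
is checked against a brute-force double loop in the tests.  Peaked
populations give compact, response-function-shaped maps; sigmoidal
populations give maps elongated along the eye-preference axis — exactly the
input clusters that pull learning toward eye-centred solutions.

The manually prewired network (`prewire()`) demonstrates that a
head-centred solution *exists* for sigmoidal inputs: each output neuron is
assigned one of nine head-centred locations ($-68°$ to $68°$, balanced
100-per-location assignment at $N = 900$; the split is our choice — only
"one among nine" is prescribed), and a sampled synapse is elevated (weight
10 before renormalisation, versus 1) exactly when the presynaptic
preferences satisfy the closed-interval membership rule
$h - \beta \le \alpha \le h + W/2$ (positive gain) or
$h - W/2 \le \alpha \le h - \beta$ (negative gain), $W = 60°$.  These are
the two right-triangle regions of the preference space from which a neuron
assigned location $h$ can receive strong, eye-position-consistent drive.

## What the simulations show

The experiment recipes (`gf_recipe()` / `run_recipe()`) reproduce the
canonical findings; the package's tests and the acceptance script compute
all quantitative outcomes at run time rather than this vignette asserting
them:

* peaked gain + standard trace rule: training converts a minority of
  untrained-classified head-centred neurons into a clear majority;
* sigmoidal gain + standard trace rule: training makes the population
  almost perfectly eye-centred instead — the covariance analysis explains
  why;
* the prewired model starts head-centred, and a single epoch of standard
  trace (or Hebbian) plasticity destroys the representation;
* mixed populations tolerate sigmoid modulation rates up to roughly 20%;
* the modified rules (delayed trace/rate with anti-Hebbian terms, or the
  pure delayed trace with a 50:50 mixed population) restore head-centred
  self-organisation under monotonic gain.

## Problem sizes, randomness, and what the synthetic protocols do not show

Everything here is synthetic by design — the model's "data" are the
internally generated gaze trajectories and gain-field responses, and the
canonical parameter tables are the default configuration.  The generator
emulates the *statistics* the mechanism needs (targets stationary in
head-centred space across many eye movements) and none of the texture of
real gaze data: no main-sequence saccade kinematics, no fixational eye
movements, no head-free gaze shifts, no response noise or adaptation in
the input neurons.  Passing tests therefore validate the mechanism under
its stated assumptions, not its quantitative fit to physiology.

Full-scale runs (900 output neurons, 20 epochs) take a few minutes each
on one CPU; the test suite instead uses reduced configurations (down to
~200-neuron input grids and 50-neuron output layers, 200-neuron outputs
and 5 epochs for directional replications) that preserve every rate
equation and protocol shape while shrinking only population sizes and
epoch counts.  The acceptance script states its own scales: full scale
with 2–3 random seeds for untrained, prewired and trained-peaked
statistics, and single full-scale runs for the slowest (sigmoidal)
training arms.  All randomness — connectivity, initial weights, mixed-gain
conversion, fixation draws, prewiring assignment — flows through named
integer seeds, and identical seeds reproduce runs bit for bit.

## Known limitations

* The competition percentile makes each neuron's rate depend on the whole
  population; simulating subpopulations independently is therefore not
  equivalent to one joint run.
* The learning-rate unit convention (per second, with ms time constants)
  is a modelling choice; only the product of rate and step enters the
  updates.
* With randomly sampled sparse connectivity the prewired model's
  elevated-triangle coverage is noisy; individual neurons can land on
  either side of the $\Pi$/$\Omega$ classification boundary, so the
  prewired head-centred rate is sensitive to connectivity draws even
  though the canonical (fully connected) weight structure is robustly
  head-centred.
* Planar (non-saturating) gain fields, spiking dynamics and explicit
  inhibitory interneurons are out of scope.
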