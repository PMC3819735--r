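---
title: "Degree-correlated cortical networks: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degree-correlated cortical networks: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(degcornet)
```

# The scientific question

Cortical networks at rest fire sparsely (about 1 Hz), yet activating a
handful of neurons — or even a single one — can be detected behaviourally.
These two observations pull in opposite directions: a network sensitive
enough to amplify a few extra spikes is also prone to amplifying its own
spontaneous fluctuations into runaway activity.  `degcornet` implements a
model family in which the tension is resolved by the *correlation between
a neuron's in-degree and its out-degree*: if neurons with many outgoing
connections (the amplifiers) receive few inputs, they are rarely recruited
by spontaneous activity but remain available to broadcast a stimulus.
The package generates such networks, simulates their dynamics, and
quantifies stability, sensitivity, and the motif signatures by which the
degree correlation could be detected experimentally.

# The model

## Dynamics

The network holds $N$ binary excitatory neurons.  In each time bin
(width $\Delta t = 10$ ms) neuron $i$ fires with probability

$$\nu_{i,t+1} = \frac{1}{1+\exp\!\big(h_0 - \tfrac{J}{Np_c}\sum_j w_{ij}x_{j,t}\big)},$$

where $w_{ij}=1$ denotes a connection from $j$ to $i$, $x_{j,t}$ is $j$'s
binary state, and the coupling $J$ is normalized by the expected
in-degree $Np_c$ so that its meaning is size-independent.  The field
$h_0$ sets the baseline rate through $r_0 = \frac{1}{\Delta t}
\frac{1}{1+e^{h_0}}$ (`h0_from_rate()`); $r_0 = 1$ Hz gives
$h_0=\ln 99 \approx 4.595$.  A deterministic counterpart iterates the
same map on real-valued rates, isolating the effect of degree
heterogeneity from stochastic spiking.  In the homogeneous limit the
per-neuron equations collapse to the scalar map
$v \mapsto 1/(1+e^{h_0-Jv})$, whose fixed points
(`mean_field_fixed_points()`) define the low-firing state (LFS), an
unstable separatrix, and the high-firing state (HFS).

## Connectivity

Erdős–Rényi graphs have binomial degrees with relative spread
$\sqrt{(1-p)/(Np)}$ — too tight to study degree correlations at
$N = 2000$.  The package therefore samples each neuron's
$(d^{in}, d^{out})$ from a truncated bivariate Gaussian centred at
$(\mu,\mu)$, $\mu = Np_c$: an axis-aligned Gaussian with short axis
$\sigma_x$ and long axis $\sigma_y$ is rotated by 45° anticlockwise
(long axis along the anti-diagonal, *anti-correlated*) or clockwise
(*positively correlated*); the *uncorrelated* control uses equal per-axis
spread $\sqrt{(\sigma_x^2+\sigma_y^2)/2}$ so all three ensembles share
the same marginals.  Values are rejection-sampled into $[1, 2\mu]$
(no zero-degree nodes; symmetric about the mean) and rounded.  The
standard setting is $\sigma_y=\mu/3$ and dispersion
$\sigma_x/\sigma_y = 0.3$, which yields $|\rho(d^{in},d^{out})| \approx
0.82$–$0.83$ at $N=2000$.

Degrees are realized by the configuration model: out-stubs and in-stubs
are matched through a random permutation.  Self-pairings
(≈ 0.05 % of pairings at $\mu=100$, essentially $1/N$) and duplicate
pairings (≈ 2.7 %, $\approx \tfrac{1}{2}\mathbb E[d^2]^2/(N\mu^2)$
relative to all pairings) are removed; both rates are recorded in the
network's metadata.  Because sampling leaves
$\sum_i d^{in}_i \ne \sum_i d^{out}_i$ by an $O(\sqrt{N}\sigma)$ amount,
`balance_totals()` repairs the totals by unit adjustments at uniformly
random nodes inside the truncation interval — each unit of imbalance
costs exactly one adjustment, so marginal means move by at most
$|\Delta|/N$ (a fraction of a percent of $\mu$).

# Stability analyses

Three nested notions of the critical coupling $J_c$ are implemented:

* **mean-field** (`meanfield_Jc()`): bisection on the existence of a
  stable low root of the scalar map (tolerance $10^{-4}$);
* **deterministic finite-size** (`deterministic_Jc()`): bisection (default
  tolerance 0.05) on the attractor reached by the rate map from the
  uniform LFS-matched initial vector, within 400 steps;
* **stochastic** (`stability_curve()`): the fraction of stochastic trials
  (default 100 per coupling, 500 steps, first 100 discarded) that reach
  the HFS, fitted with $p(J) = 1/(1+e^{-(J-J_h)/\sigma_J})$; $J_h$ is the
  transition midpoint and $\sigma_J$ the width.

Trials start from a uniformly random set of $\lfloor N v_{LFS}\rceil$
active neurons, matching the mean-field LFS occupancy at that coupling.
A trial is classified HFS when its mean population activity over the
last ten bins exceeds 0.5; since the two attractors sit near 0.01 and
1.0, any mid-range threshold gives identical classifications (this is
tested).  The compiled trial runner terminates early once activity has
stayed above 0.9 for ten consecutive bins — at these parameters the HFS
is dynamically absorbing, so this is an optimization, not an
approximation.  By default a fresh network realization is drawn per
trial, so the fitted transition reflects both stochastic escape and
realization-to-realization variability; passing a fixed
`directed_network` isolates the former.

The basin of attraction of the LFS is profiled by `boa_profile()`:
initial states of varying active-neuron count are summarized by the
out-degree-weighted effective count
$N_{\text{eff}} = N\sum_{i\in\text{active}} d^{out}_i / \sum_i d^{out}_i$,
binned at unit width; $N_{\text{eff},90}$ is the lowest bin (with at
least 20 trials) in which ≥ 90 % of trials escape to the HFS.

## Rates versus in-degree

In the LFS a neuron's stationary rate grows with its in-degree.  Under
the deterministic map the relation is nearly perfect
($R^2 \approx 0.99$); under stochastic spiking it is jittered by
counting noise.  The package measures the stochastic relation from each
neuron's mean activity over a long window (`rate_indegree_r2()`,
default 2000 steps with 100 discarded).  The window length matters in a
way worth spelling out: at ~2 Hz the across-neuron rate spread in the
LFS is only a few tenths of a Hz, while the standard error of a
single-neuron rate estimate over $T$ bins is
$\sqrt{\bar p(1-\bar p)/T}/\Delta t \approx 0.7$ Hz for $T=400$.  With a
400-bin window the squared correlation with in-degree is therefore
bounded near 0.18 *regardless of implementation*; resolving the
relation at the strength the model actually produces requires
$T \approx 2000$ bins, which is the default.  Runs that escape to the
HFS are redrawn, as the relation is a property of the low-firing state.

# Sensitivity analyses

Stimulation clamps $n_p$ neurons (default 8) to the active state for
$T_{\text{stim}}$ bins (default 6, bins 10–15), emulating
nanostimulation.  Clamping is applied after each update, so stimulated
cells fire in every window bin regardless of their inputs; whether the
underlying experiment clamps or injects a strong field is an
interpretation, and clamping is the stronger, simpler reading.  All
read-outs exclude the stimulated cells: detection must rely on the
downstream population.

`run_detection_ensemble()` produces paired stimulated/spontaneous trials
across network realizations (default 50) and records per-bin population
rates over non-stimulated cells.  `auc_timecourse()` gives the per-bin
Mann–Whitney AUC: ≈ 0.5 before the stimulus and rising through the
window.  `detection_auc()` summarizes a trial either by a single bin's
rate or by its rate response averaged over the post-onset window bins
(the default; the onset bin itself carries no downstream signal yet,
because stimulated spikes need one bin to propagate).  The window
statistic integrates out per-bin counting noise, and at
$J=18$, $r_0=1$ Hz reaches an AUC near 0.75, whereas per-bin AUCs
plateau in the mid-0.6s — the single-bin statistic is noise-limited by
the same counting argument as above.  AUC is computed by threshold sweep and
equals the Mann–Whitney statistic with ties counted one half (tested to
$10^{-12}$ against an independent implementation); errors come from
bootstrap resampling of trials.

Two refinements mirror how a decision circuit could do better than the
population rate.  First, consecutive-rate pairs $(r_t, r_{t+1})$ form a
return map whose kernel density (`return_map_density()`, Silverman
bandwidth $\hat\sigma n^{-1/6}$ per axis) shifts along the diagonal
under stimulation; fuzzy c-means (`fcm()`, 2 clusters, fuzzifier 2) on
these 2-D points yields membership values whose ROC slightly beats the
single-bin rate.  Second, a classical perceptron
(`perceptron_train()`: learning rate 1, zero-initialized weights,
per-epoch shuffling, 500-epoch cap) learns per-neuron read-out weights
from binary state vectors.  The learned weights correlate most strongly
with the number of direct synaptic inputs a neuron receives from the
stimulated set (`weight_feature_correlations()`), weakly with in-degree
and with inputs from the relay population, and negligibly with
out-degree.  The magnitude of the direct-input correlation depends on
the training-sample count and on how the cycling (non-separable)
training run is terminated; with the package defaults
(`perceptron_weight_analysis()`, 800 paired trials, 200 epochs) it
averages near 0.28 with a spread of a few hundredths across
repetitions; an ideal discriminant built from the true per-neuron rate
shifts would correlate far more strongly, so the perceptron estimate is
training-noise-diluted by construction and its exact magnitude depends
on the training protocol.

# Motif statistics

The 13 weakly connected directed 3-node motif classes are labeled by a
canonical id: the induced $3\times 3$ adjacency (entry $[i,j]$ = edge
$i\to j$) is read as a 9-bit integer (row-major, $a_{11}$ most
significant) and minimized over the six node permutations.  The directed
3-cycle ("ring") is id 98, the five-edge class id 110, the complete
triad id 238.  `count_triads()` runs a neighbour-based census
($O(\sum d^2)$, compiled) over *induced* subgraphs; an exhaustive
$O(N^3)$ enumeration and igraph's census serve as independent oracles in
the tests, and the 16-class counts always sum to $\binom{N}{3}$.

Counts are normalized by $\lambda N^3 (k/N)^e$ with $e$ the class edge
count, $k$ the realized mean degree of the counted (sub)network, and
$\lambda = 1/|\mathrm{Aut}|$ the symmetry factor, so sparse-ER
expectations are near 1 and counts are comparable across motifs and
sizes.  Using the realized $k$ (not the nominal $\mu$) avoids bias from
removed edges and sub-sampling; any fixed per-motif constant would only
rescale the counts, leaving AUCs and scaling exponents unchanged.

Ensembles (`ensemble_counts()`; $N=200$, $\mu=10$, 1000 realizations,
one uniformly sampled induced sub-network per realization and size)
show: the normalized means converge for sub-networks above ~50–100
nodes; their spread falls as $N_{\text{sub}}^{-3/2}$ (the count is a
sum over $\sim N_{\text{sub}}^3$ weakly dependent indicators); and the
ring motif is scarcer in anti-correlated networks — closing a 3-cycle
requires each neuron to pass activity on, which is exactly what
anti-correlation suppresses.  Pooling counts over $N_{av}$ realizations
(`pool_counts()`, disjoint groups or resampling) shrinks the spread by
$\sqrt{N_{av}}$; with $N_{av}=50$ the anti- and positively correlated
ensembles become essentially perfectly separable by motif 98 at
$N_{\text{sub}} = 50$ (`motif_auc()`, AUC ≈ 1), and two-motif fuzzy
clustering (`pair_fcm_auc()`) only helps once counts are pooled.

# Numerical and design choices

* Exponents in the logistic are clipped at ±700; irrelevant at model
  scales, it only guards against overflow for extreme parameters.
* Root finding: $10^4$-point sign-change scan plus bracketed polishing;
  residuals below $10^{-12}$.
* All randomness flows through R's global RNG (compiled code uses
  `unif_rand`), so a single `set.seed()` reproduces any analysis
  bit-for-bit; `run_experiment()` records its seed and resolved
  parameters in a manifest.
* The sub-network census uses induced subgraph classification; at the
  sparsity studied ($p_c = 0.05$) the distinction from non-induced
  ("appearance") counting is within the realization noise.
* Sigmoid transition fits use Levenberg–Marquardt least squares with
  $\sigma_J$ bounded positive; $R^2$ is reported as explained variance.
  Fitted parameters are recovered exactly on noiseless data and without
  bias under binomial trial noise (both tested).
* Degenerate inputs are signalled, not silently absorbed: zero-variance
  degree marginals, empty ROC samples, all-identical FCM points,
  single-class perceptron labels, stimulation windows outside the
  simulated range.

# What the synthetic conditions do and do not show

Everything in the package is synthetic by design — the study conditions
are parameter specifications, not recordings.  The generator reproduces
the joint degree statistics, sparsity and size of the modelled circuit,
but real cortical networks have structure the model deliberately omits:
inhibitory populations, spatial connectivity fall-off, synaptic
dynamics, weighted synapses and assortative (cross-node) degree
correlations.  Passing tests therefore validate the implementation of
this model family and the internal consistency of its analyses; they do
not by themselves establish how strongly the motif signatures or
stability margins transfer to biological recordings.

Problem sizes in the tests are chosen to keep a full run at desk scale
(large-network analyses at $N = 2000$ with tens to thousands of trials,
motif ensembles at $N = 200$ with up to 1000 realizations); the
acceptance script re-runs the full pipeline at the standard conditions
in roughly a quarter of an hour.

# Known limitations

* Under enumeration-based counting the humble 2-edge chain motif
  (id 12) is at least as good a degree-correlation discriminator as the
  ring: its count is essentially $\sum_j d^{in}_j d^{out}_j$, an almost
  noise-free read-out of the very moment the correlation shifts,
  whereas the ring count carries that moment cubed plus Poisson noise
  around a small mean.  The ring motif remains the most sensitive
  *cycle-closing* signature and the package's pooled-AUC results focus
  on it, but analyses ranking motifs should be aware that the chain
  ranks first in this implementation.

* The stochastic transition width $\sigma_J$ is a rare-event quantity:
  it is set by the slope of the log escape rate with respect to $J$.
  The implementation reproduces the sigmoid's form, location and
  ensemble ordering robustly, but the fitted width at the standard
  conditions is ≈ 0.24, noticeably sharper than the ≈ 0.39 such models
  have been reported to show; the width is insensitive to trial length
  and fit protocol (both checked), so this should be read as genuine
  sensitivity of extreme-value statistics to unstated protocol details.
* Perceptron weight correlations depend on training minutiae
  (sample count, termination); see above.
* The motif census assumes binary adjacency; multi-edges are removed at
  generation, so weighted variants are out of scope.
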