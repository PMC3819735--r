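# degcornet

Model cortical networks with correlated in- and out-degrees:
generation, stochastic binary dynamics, stability, sensitivity, and
triad-motif statistics.

## The problem

Cortex fires sparsely (~1 Hz) yet reliably detects the activation of a
handful of neurons.  Sensitivity and stability compete: a network that
amplifies a few stimulated spikes also amplifies its own fluctuations.
`degcornet` implements a model family in which the two are reconciled by
**anti-correlation between a neuron's in-degree and its out-degree**:
high-out-degree neurons (the amplifiers) receive few inputs, so
spontaneous activity rarely recruits them while a targeted stimulus
still can.  The package is for computational neuroscientists and
network scientists who want to generate such networks, simulate their
dynamics, and measure the statistics that make the connectivity
structure experimentally detectable.

## The model in brief

* **Dynamics** — N binary neurons; per 10 ms bin, neuron *i* fires with
  probability `1/(1 + exp(h0 − (J/Npc) Σ_j w_ij x_j))`.  The field `h0`
  sets the baseline rate `r0 = (1/Δt)/(1+exp(h0))`; the network is
  bistable between a low-firing state (LFS, ~1 Hz) and a high-firing
  state (HFS, saturated).
* **Connectivity** — per-node degree pairs `(d_in, d_out)` drawn from a
  truncated bivariate Gaussian centred at `μ = N p_c`, rotated ±45° for
  anti-/positively correlated ensembles (uncorrelated and Erdős–Rényi
  controls included), realized by the configuration model with self- and
  duplicate-stub pairings removed.
* **Analyses** — mean-field, deterministic and stochastic critical
  couplings; sigmoid transition fits `p(J) = 1/(1+exp(−(J−J_h)/σ_J))`;
  basin-of-attraction profiles via the out-degree-weighted active count
  `N_eff`; stimulation-detection ROC/AUC (Mann–Whitney), fuzzy-c-means
  and perceptron read-outs; a census of the 13 connected directed triad
  motifs with the ring motif (id 98) as the key degree-correlation
  signature.

## Worked example

```r
library(degcornet)
set.seed(42)

spec <- degree_spec(2000, 0.05, kind = "anti")   # mu = 100, dispersion 0.3
net  <- generate_network(spec)
print(net)
#> <directed_network> 2000 nodes, 194191 edges [anti]
#>   mean degree 97.10; in-degree sd 23.92; out-degree sd 24.00
#>   in/out degree correlation rho = -0.839

h0 <- h0_from_rate(1)          # 1 Hz baseline in 10 ms bins
meanfield_Jc(h0)
#> [1] 37.43

params <- dynamics_params(J = 30, norm = 100, r0 = 1)
sim <- simulate_network(net, params, steps = 500, burn = 100,
                        record_raster = FALSE)
print(sim)
#> <activity_raster> stochastic run, 501 bins, mean activity 0.0182 (1.82 Hz)
classify_attractor(sim)
#> [1] "LFS"

sub <- sample_subnetwork(net, 50)
tab <- normalize_counts(count_triads(sub), 50, k = sub$edge_count / 50)
tab[tab$motif_id %in% c(98, 110, 238), ]
#>    motif_id n_edges count normalized
#> 9        98       3     1  0.2465686
#> 12      110       5     0  0.0000000
#> 13      238       6     0  0.0000000
```

Reading the output: the generated network realizes the prescribed
anti-correlation (ρ ≈ −0.84; its magnitude exceeds 0.82 before the
~2.8 % artifact-edge removal).  At coupling `J = 30` — below the
mean-field critical coupling 37.4 — the stochastic run stays in the
low-firing state at 1.8 Hz.  In a 50-node sampled sub-network the
normalized ring-motif count (0.25) sits far below its sparse-random
expectation of ~1: the depletion of 3-cycles is the fingerprint of
anti-correlated degrees.

A thin command-line wrapper for network generation, simulation and
motif counting is installed at `inst/cli/degcornet-cli.R`;
`run_experiment()` drives the standard analyses from named,
seed-recording configurations.

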