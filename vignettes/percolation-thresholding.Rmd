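---
title: "Percolation-based sparsification thresholds: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Percolation-based sparsification thresholds: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`perconet` studies one question: when a weighted connectivity network —
typically a resting-state functional connectivity matrix — is sparsified
by removing edges below a weight threshold, which threshold preserves the
most information about the network's community structure? The package
implements the percolation-analysis answer together with the synthetic
machinery needed to validate it against a known ground truth. This
vignette records the models, the tunable parameters, and the design
decisions taken where the method description leaves room.

## The percolation threshold

For a threshold $t$ the sparsified graph retains exactly the edges with
weight $\ge t$ (closed convention, so every observed edge weight is an
attainable grid point and the threshold grid can be the sorted unique
weights). The giant component size as a function of $t$ is a
non-increasing step function; the percolation threshold

$$t^\* = \max\{t : \text{the giant component at } t \text{ still contains
every node of the unthresholded giant component}\}$$

is the highest threshold that preserves connectedness. Above $t^\*$ the
network starts breaking apart. `percolation_profile()` computes the whole
curve; an alternative reading of "starts breaking apart" — the threshold
with the largest single drop in giant size — is available as
`tstar_rule = "maxdrop"`. For networks that are already disconnected the
profile is computed with respect to the giant component and a warning
lists the excluded nodes. The default grid is exact (all unique weights);
`grid = "quantile:K"` bounds the sweep on dense matrices (the pipeline's
scaled preset uses `K = 40`).

The hypothesis the validation pipeline tests is that $t^\*$ balances two
error modes: below it, spurious weak edges blur the modular structure;
above it, genuine connectivity is destroyed. On synthetic data this shows
as a rise-then-fall of NMI versus threshold with its maximum near $t^\*$.

## The weighted LFR benchmark

`generate_lfr()` builds networks with planted communities and the
heavy-tailed degree/community-size distributions seen in brain graphs.
Reference configuration (the package default): $N = 600$ nodes, degree
exponent $\tau_d = 2$, mean degree $\langle k \rangle = 12$, maximum
degree 50, community sizes 5–50 from a power law with $\tau_c = 1$, and
mixing $\mu_t = \mu_w = 0.2$ — each node shares a fraction $1-\mu_t$ of
its edges (and $1-\mu_w$ of its strength) with its own community.

Construction details the method description leaves open, fixed as
follows:

- Degrees are drawn from a continuous truncated power law whose lower
  bound is solved so the distribution mean equals $\langle k \rangle$; a
  sampled sequence is accepted when its mean is within 2% of the target
  (resampled up to 100 times).
- Each node's external degree is $\mu_t k_i$ with *stochastic* rounding
  (floor plus a Bernoulli draw on the fractional part). Deterministic
  nearest-integer rounding biases the mean per-node mixing at small
  degrees; stochastic rounding makes the expected per-node external
  fraction exactly $\mu_t$.
- Nodes are assigned to communities in decreasing internal-degree order,
  randomly among communities with free slots large enough to host the
  internal degree (a node's internal degree cannot exceed its community
  size minus one).
- Intra-community graphs are realized per community from the internal
  degree sequence (Viger–Latapy sampling when feasible, stub pairing
  with double-edge-swap repair otherwise); the inter-community graph is
  realized from the external stubs with swaps that forbid intra-community
  pairs. Irreparable stubs are dropped, which is why realized mean degree
  is checked to a $\pm 1$ tolerance.
- Weights target node strengths $s_i = k_i^\beta$ (default
  $\beta = 1.5$, exposed as `strength_exponent`) split
  $(1-\mu_w)/\mu_w$ between intra- and inter-community edges; each edge
  starts from the mean of its endpoints' per-edge shares and a few
  multiplicative balancing iterations pull per-node intra/inter strengths
  toward their targets. Realized mixing lands well within the 0.05
  acceptance tolerance.
- The generator prefers a fully connected realization (retrying the
  construction); it falls back to a giant component covering $\ge 95\%$
  of nodes only if none is found, with a warning. With $\mu_t = 0$
  communities are mutually disconnected by design and the connectivity
  filter is skipped — the zero-mixing limit is a legitimate degenerate
  benchmark.
- Community labels are assigned in decreasing size order so identical
  groupings always serialize identically.

## From adjacency to synthetic cohorts

`generate_cohort()` turns a benchmark network into multi-subject
time-series panels:

1. **Conditioning.** The zero-diagonal adjacency is projected to the
   closest positive-definite matrix $C$ by eigenvalue clipping at a small
   floor (`eig_floor`, default $10^{-8}$). The diagonal is left free, so
   node signal variances inherit the heterogeneous connectivity strengths
   of the network — hubs fluctuate more. This is a deliberate design
   choice: normalizing $C$ to unit diagonal (the alternative, available
   as `correlation_target(..., unit_diagonal = TRUE)`, implemented by
   Higham-style alternating projections in
   `nearest_positive_definite()`) forces unit-variance signals, and at
   the simulation's noise levels (SNR 35, noise s.d.
   $\sigma_N = 100/35 \approx 2.86$ against unit signal s.d.) the
   planted correlations would be attenuated by
   $\approx 1/(1+\sigma_N^2) \approx 0.11$, burying the community
   structure below the spurious-correlation floor at any realistic
   cohort size. With the free-diagonal projection the implied node
   variances exceed 1 and the same noise leaves the structure
   recoverable — the regime in which the percolation analysis is
   meaningful.
2. **Cholesky coloring.** $C = LL^\top$; node series are
   $Y = LX + \text{baseline}$ with $X$ i.i.d. standard Gaussian white
   noise per node and timepoint ($m = 150$ timepoints, baseline 100 by
   default). The population covariance of $Y$ is exactly $C$. Temporal
   autocorrelation of resting-state signals is *not* modeled; see
   limitations.
3. **Rician noise.** Each sample $y$ becomes
   $\sqrt{(y+g_1)^2 + g_2^2}$ with $g_1, g_2 \sim N(0, \sigma_N^2)$ —
   the magnitude of a complex Gaussian perturbation, the standard MR
   noise model. The scale is set once per cohort from
   $\mathrm{SNR} = \bar S / \sigma_N$ with $\bar S$ the mean signal
   magnitude ($\approx$ baseline). The simulations use SNR 35 and 70.
4. **Reproducibility.** Subject $k$ draws its series and noise from
   sub-seeds derived deterministically from the master seed by a fixed
   linear-congruential mix, so a panel is a pure function of
   (network, subjects, timepoints, snr, baseline, seed).

Subject connectivity is the Pearson matrix of the noisy series; the group
matrix averages subjects on the Fisher $z$ scale (correlations clipped at
$\pm(1-10^{-7})$, `atanh`, mean, `tanh` back — the back-transform keeps
the group matrix on the correlation scale). Negative group correlations
are discarded when converting to a weighted network: percolation and all
three community methods operate on non-negative weights, and at the
simulated noise levels negative entries are overwhelmingly spurious.

## Community detection and scoring

Three methods, chosen for their different principles:

- **Newman modularity / Louvain** (`louvain_communities()`): modularity
  $Q = \frac{1}{2W}\sum_{ij}(w_{ij} - s_i s_j / 2W)\,\delta(c_i,c_j)$ at
  resolution 1, optimized by igraph's Louvain implementation under
  seeded random vertex orders with `n_restarts` restarts (default 16),
  keeping the best $Q$.
- **Asymptotical Surprise / PACO** (`paco_communities()`):
  $\mathrm{AS} = W \cdot \mathrm{KL}(q \,\|\, \langle q \rangle)$, where
  $q$ is the observed intracluster weight fraction and
  $\langle q \rangle$ the intracluster *pair* fraction expected under an
  Erdős–Rényi null. The statistic is the asymptotic form of minus the
  log upper-tail probability of the observed intracluster density, hence
  one-sided: partitions with $q \le \langle q \rangle$ score 0. (The
  two-sided KL would be maximized by meaningless depletion
  partitions — anti-communities with $q \approx 0$ — which exhaustive
  enumeration on small graphs confirms.) The optimizer starts from
  singletons and sweeps edges in decreasing weight order, applying for
  each cross-community edge the best AS-improving operation among
  moving either endpoint or merging the two communities; randomized
  node-move refinement and whole-community merges then run to a
  fixpoint. Trials beyond the first use weight-biased random edge orders
  for diversity (`n_trials`, default 16). On exhaustive enumerations
  ($N \le 7$) this attains the global maximum in $\ge 90\%$ of random
  graphs.
- **InfoMap** (`infomap_communities()`): adapter only — the map-equation
  optimizer itself is igraph's built-in implementation (the tooling this
  method is normally run with), with an optional external-command
  backend; a missing backend raises a configuration error and the
  pipeline proceeds with the remaining methods.

Retrieved partitions are scored against the planted one by NMI evaluated
on the community overlap table (log base cancels; the doubly-degenerate
both-single-community case is defined as 1), and by sensitivity
$TP/(TP+FN)$ and specificity $TN/(TN+FP)$ after biggest-overlap matching
(many-to-one allowed, ties to the smaller retrieved label, unweighted
average over planted communities; a specificity denominator of zero is
scored 0).

## Pipeline and problem sizes

`run_simulation1()` applies the three methods directly to benchmark
weights (noiseless); `run_simulation2()` runs the full chain
benchmark → cohort → Pearson → Fisher group average → threshold sweep.
Nodes detached by thresholding are scored as singleton communities
(detection runs on all non-isolated components — the methods handle
disconnected graphs, and this keeps the degenerate fixtures exact).
Every sweep includes $t = 0$ and $t^\*$ as grid points.

Two presets ship with the package. `sim_preset("paper")` is the
full-scale configuration ($N = 600$, cohorts of 20/40/60 subjects,
SNR 35/70, 5 replicates, exact grid). `sim_preset("scaled")` is the
routine-validation size used by the test suite — $N = 150$, 10 subjects,
SNR 35, 3 replicates, a 40-point quantile grid and 4 optimizer restarts
— chosen as the smallest configuration at which the phenomena of
interest (rise-then-fall of NMI, $t^\*$ near the optimum) are stable
across seeds. The exhaustive-maximum checks of the optimizers run at
$N = 8$ (modularity, Bell number 4140) and $N = 7$ (surprise, 877);
union-find cross-checks of the percolation sweep use 100 random graphs
up to $N = 50$.

## What the synthetic data does and does not emulate

The generator reproduces heavy-tailed degrees and community sizes,
controlled mixing, inter-subject variability (independent realizations
sharing one correlation target), magnitude-domain MR noise at controlled
SNR, and the group-averaging workflow. It does **not** emulate temporal
autocorrelation or hemodynamic filtering of BOLD signals, physiological
or motion artifacts, spatial smoothing, inter-subject differences in the
*true* connectivity (all subjects share one target matrix), or negative
functional couplings. Passing tests therefore demonstrate the method's
behavior under controlled, favorable-but-noisy conditions; they do not
certify performance on empirical resting-state data, where the optimal
threshold must still be judged per network.

## Numerical choices

- Nearest-PD: eigen floor $10^{-8}$; the unit-diagonal variant iterates
  alternating projections (with Dykstra correction) to a $10^{-10}$
  Frobenius tolerance, 200-iteration cap.
- Fisher averaging clips correlations at $\pm(1-10^{-7})$ before
  `atanh`.
- NMI groups its log terms so the identity and no-information cases
  evaluate to exactly 1 and 0 in floating point.
- Optimizer ties: move gains must exceed $10^{-12}$; Louvain keeps the
  first-found best across restarts; biggest-overlap ties go to the
  smaller retrieved label.
- Degenerate inputs: edgeless networks are an error for modularity,
  surprise and the percolation profile; zero-variance series are an
  error naming the offending node; empty subject lists and empty sweep
  results are errors.
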