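---
title: "Generative network modeling of in-vitro neuronal networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative network modeling of in-vitro neuronal networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`gnmea` implements an end-to-end analysis of how developing neuronal
cultures, recorded at single-cell resolution on planar high-density
microelectrode arrays, wire themselves into networks. The pipeline has three
scientific stages — functional connectivity inference from spike trains,
economic generative modeling of the resulting graphs, and objective
functions that score how well a wiring rule explains an observed network —
plus a seeded synthetic-data generator so that every stage is testable
without recorded data. This vignette explains the models, the parameters
that matter, the numerical choices, and what the synthetic generator does
and does not emulate.

```{r setup}
library(gnmea)
```

## Functional connectivity from spike trains

Pairwise synchrony is measured with the spike time tiling coefficient
(STTC),

$$STTC = \frac{1}{2}\left(\frac{P_A - T_B}{1 - P_A T_B} +
\frac{P_B - T_A}{1 - P_B T_A}\right),$$

where $T_A$ is the fraction of the recording tiled by the union of
$\pm\Delta t$ windows around A's spikes and $P_A$ is the proportion of A's
spikes falling within $\pm\Delta t$ of any spike of B. The STTC is robust
to firing-rate differences between units, which matters in developing
cultures where rates span orders of magnitude. The only free parameter is
the synchronicity window; the default is $\Delta t = 10$ ms.

Tiling is computed by exact merged-interval arithmetic (windows clipped to
the recording, overlaps merged), not by the $2 n \Delta t / T$
approximation: overlap between windows is common at in-vitro rates and the
approximation would bias $T$ upward. The degenerate case $1 - P\,T = 0$
(a train tiling the entire recording with full overlap) raises an error
with the four intermediate quantities rather than returning a 0/0.

Significance of each pair is established against jittered surrogates: each
unit's spikes are displaced by zero-mean Gaussian noise (SD 10 ms by
default), 1000 times, and the pair's surrogate STTC at permutation $s$
pairs surrogate $s$ of one unit with surrogate $s$ of the other — both
trains are jittered, so the null destroys fine timing while preserving each
train's slow rate envelope. The one-sided add-one p-value
$(1 + \#\{\mathrm{surrogate} \ge \mathrm{empirical}\})/(n_{surr}+1)$ is
binarized at $p \le 0.001$; only positive-synchrony edges are retained by
default (a `two_sided` switch exists), because the downstream topology
analysis consumes significant couplings, not anti-correlations. Units
firing below 0.01 Hz are removed from the node set before pairing.
Surrogate banks are generated per unit in fixed unit order from one seeded
stream, so inference is reproducible for a given seed and independent of
pair iteration order.

## Nodal and global topology

Statistics are computed on the binary undirected graph: degree, local
clustering $2t_i/(k_i(k_i-1))$, betweenness (unnormalized fractional
shortest-path counts — only distributions and correlations are consumed
downstream, so the normalization constant is irrelevant but fixed),
per-node total Euclidean edge length, nodal efficiency (mean inverse
shortest path length, with unreachable pairs contributing 0 so that
fragmented cultures stay finite), the matching index
$M_{ij} = |N_{i/j} \cap N_{j/i}| / |N_{i/j} \cup N_{j/i}|$, and the
participation coefficient over a Louvain partition. Globally: density,
characteristic path length (averaged over reachable pairs), global and
local efficiency, modularity $Q$, and small-worldness
$\sigma = (c/c_{rand})/(l/l_{rand})$. The $\sigma$ null is the mean over
$n$ (default 1000) uniformly random Erdős–Rényi graphs of identical size
and density — not degree-preserving rewiring — matching the convention of
comparing against random networks of the same size and density. Louvain is
stochastic, so $Q$ is reported as the maximum over seeded restarts
(default 100); trajectory analyses use fewer restarts (10–20) since they
evaluate many partial graphs and only directions of change are consumed.

## The generative model

Networks are grown from an empty seed graph, one undirected edge per step,
with wiring probability score

$$P_{ij} \propto D_{ij}^{\,\eta}\,(K_{ij}+\epsilon)^{\,\gamma}$$

over the currently unconnected pairs. $D$ is the fixed Euclidean distance
matrix (connection cost); $K$ is the topology value term, recomputed after
every addition; $\eta$ and $\gamma$ calibrate the cost/value trade-off.
Thirteen rules define $K$: `spatial` (all ones — pure cost), two homophily
rules (`neighbors`: common-neighbor count; `matching`: matching index), and
five combinations each (average, min, max, absolute difference, product) of
nodal clustering (`clu_*`) and nodal degree (`deg_*`).

Numerical choices:

- $\epsilon$ (default $10^{-6}$) is added to $K$ before exponentiation.
  With $\gamma > 0$ every topology rule has $K \equiv 0$ on the empty
  graph, and without the offset growth could never start. $\eta$ applies
  to raw $D$, which the position generators keep strictly positive
  (minimum spacing one electrode pitch, 17.5 µm).
- Growth adds exactly one edge per iteration and stops at the observed
  edge count $m$; the edge formation order is recorded, so any
  intermediate graph can be reconstructed exactly.
- $K$ is updated incrementally: adding edge $(u,v)$ only changes rows of
  nodes whose degree, neighborhood, or clustering changed ($\{u, v\}$ for
  degree/homophily rules, plus the common neighbors of $u$ and $v$ for
  clustering rules). This makes a 100-node, 400-edge growth run in
  milliseconds, which the parameter search relies on.
- If every candidate score is zero or non-finite (e.g. an overflowing
  exponent), growth aborts with an error naming the offending
  exponentiation rather than sampling from garbage.
- Probability-score snapshots over unconnected pairs are recorded in 1%
  intervals of completion (configurable), for the distribution analyses
  below.

## Model-fit objectives

The **energy** of a simulated network against the observed one is the
maximum of four two-sample Kolmogorov–Smirnov distances — degree,
clustering, betweenness, and connection length distributions — so no
component is worse than the energy. The length component uses the
distribution of per-edge Euclidean lengths (one value per existing
connection); the per-node total incident length is used in the fingerprint
below. The text sources for these conventions frame edge length nodally in
one place and distributionally in another; both are implemented and
switchable (`edge_length_on`), with per-edge the default for the energy.

The **topological fingerprint** (TF) is the 6×6 Pearson correlation matrix
of six nodal statistics (degree, clustering, betweenness, total edge
length, nodal efficiency, node-wise mean matching); "efficiency" here is
nodal efficiency rather than a global scalar, since the fingerprint needs a
per-node vector. TF dissimilarity is the Frobenius norm of the difference.
A statistic that is constant across nodes has undefined correlations; such
entries are recorded as `NA` and imputed as 0 in the difference, with a
message, so degenerate fixtures do not silently bias comparisons.

The **p_rank** Monte-Carlo diagnostic asks whether the observed
distribution of a nodal statistic is exchangeable with the distributions
produced by the top-performing simulations (conventionally 99). The base
statistic is the KS distance between the observed values and the pooled
simulated values; the null swaps each simulation in turn into the observed
role. p_rank is the two-sided midrank position of the base statistic,
$\min(1,\, 2\min(r, 101-r)/100)$. This construction is exactly
exchangeable under the null (hence uniformly distributed), reaches
$\le 2/100$ for far-outlying observations, and returns 1 under complete
degeneracy — the three behaviors a calibrated middle-of-the-null rank must
have. The center-distance alternative (rank of $|s - \mathrm{median}|$)
fails exact exchangeability because the median is computed from the null
alone.

**Trajectory decomposition** replays a growth trace at fractions of
completion and computes modularity and global efficiency at each point,
mapping culture age linearly onto percentage completion. **Probability
score distributions** pool the 1%-interval snapshots, normalize each to
its maximum, and summarize the averaged histogram, the pooled median, and
a flatness measure (`uniform_excess`: the sup distance of the pooled
normalized scores from the uniform CDF — 0 for a perfectly flat score
distribution, large for a lognormal-like one). Increased synchrony is
expected to flatten this distribution, i.e. lower the excess: wiring
becomes less specific and the grown topology more random.

## Parameter search

Each rule's $(\eta, \gamma)$ plane — default range $[-10, 10]^2$ — is
searched by Voronoi-tessellation preferential sampling: an initial uniform
draw (4000 points at full scale), then rounds (4 at full scale, 4000
points each, 20,000 evaluations total) in which every evaluated point is
the site of a Voronoi cell, cells are drawn with probability
$\propto (1/\mathrm{energy})^{\alpha}$ ($\alpha = 2$), and a point is
proposed uniformly within the chosen cell. The within-cell proposal is
rejection sampling in a box centred on the site (half-width the distance
to the nearest other site, clipped to the ranges), accepted when the
nearest evaluated site is the chosen one; the box halves on failure, so
the proposal converges to the site, which is always in its own cell. Cell
fitness uses the site's own energy (each cell contains exactly one
evaluated point); mean-of-cell and min-of-cell variants collapse to the
same thing under this tessellation. One network is grown per sample by
default (`n_replicates` exposes averaging, since growth is stochastic).
Energies of the observed network's statistics are cached across the
thousands of evaluations.

## The synthetic-data generator

`generate_culture()` emulates the statistical structure the analysis
assumes, not the biophysics. Defaults describe a sparse culture late in
development: 120 units uniform on a 3.85×2.10 mm array (minimum spacing
17.5 µm, one electrode pitch), 30-minute recordings, lognormal baseline
rates (median 1 Hz, $\sigma_{\log} = 1$), network-burst events as a
Poisson process at 0.2 Hz in which each unit participates with probability
0.6 (boosted to $p + (1-p)/2$ for units of the burst's lead module; 4
planted modules), within-burst spike jitter 50 ms, and planted coupled
pairs that co-spike by copying a fraction of the source unit's spikes with
3 ms jitter — well inside the 10 ms synchronicity window, so planted
couplings are visible to the STTC by construction. Coupling probability
decays exponentially with distance (length scale 800 µm), module structure
makes co-activity homophilic, and a `high_synchrony` mode (participation
pushed toward 1, burst jitter shrunk to 30%) emulates disinhibited
cultures. The developmental stage parameter scales baseline and burst
rates multiplicatively, so a development series shows rising rates and
rising mean STTC with shared unit positions, mirroring longitudinal
tracking of the same units.

Burst shape parameters of real cultures are not quantitatively
characterized in the source material; the defaults above are chosen as
field-plausible values (burst rates of a few per minute, burst widths of
order 100 ms) and are deliberately config-exposed rather than calibrated
to any dataset. What passing tests on synthetic data show is that the
*pipeline* is correct and sensitive in a world satisfying its assumptions
— Poissonian baselines, Gaussian burst jitter, stationary rates. They do
not show that real cultures satisfy those assumptions: real bursts have
structured onset dynamics, refractoriness, and non-stationary development
within a recording, none of which are emulated. No waveforms or
spike-sorting artifacts are simulated.

## Spike-train summary statistics

Firing rate is spikes per second over the whole recording; network-level
means use units above 0.01 Hz. Burst detection uses the $ISI_N$ method
(default $N = 10$): the histogram of $\log_{10}(t_{k+N} - t_k)$ in
developing cultures is bimodal, and the threshold is the local trough
between the two dominant peaks of the smoothed histogram (100 bins over
the observed range, 3-bin moving average — the method's source names the
procedure but not the binning, so both are exposed). Windows of $N$
consecutive intervals under the threshold are merged, burst edges snap to
the first/last spike of the run, and a unimodal histogram returns zero
bursts with a warning rather than an arbitrary threshold. The
inter-burst-interval CV uses onset-to-onset intervals. The population
autocorrelogram pools all units, bins at 1 ms, correlates over lags ±500
ms, zeroes the ±1 ms refractory lags, and normalizes to the maximum.

## Problem sizes used in tests and the acceptance script

The deposited recordings behind the full-scale analysis are not shipped;
all tests run on synthetic data. Sizes were chosen as the smallest that
exercise each property with comfortable statistical margins: inference
tests use 8–30 units at 2 Hz over 120–360 s with the full 1000-surrogate
default where the false-positive rate itself is under test; graph-statistic
oracles enumerate all shortest paths on ≤7-node graphs (500 random draws);
recovery experiments grow 100-node, 400-edge fixtures under the matching
rule and search 250 + 3×250 points per rule over the four rule-group
representatives across 10 seeds; trajectory analyses use 100-node/600-edge
growths. The synchrony-flattening analysis compares 40-unit, 600 s
cultures with strengthened planted coupling (within-module scale 0.6),
which brings control networks to the ~9% density regime of late-stage
recordings: at the generator's default coupling, control networks carry
only a handful of significant edges and their fitted wiring parameters
are too noisy for a powered paired comparison. The
full-scale search bookkeeping (4000 + 4×4000 = 20,000 evaluations) is
verified with a stubbed evaluator, so the count is checked without 20,000
network growths.

## Known limitations

- The generator's burst model is phenomenological; parameter recovery
  results on synthetic cultures bound what the pipeline can do under its
  own assumptions, not on real recordings.
- Only binary undirected graphs are modeled; weighted generative variants
  and directed growth are out of scope.
- The Voronoi proposal kernel (uniform-in-cell via rejection) is one of
  several reasonable choices; the search contract (preferential
  concentration, range clipping, determinism) is tested, the kernel itself
  is a design choice.
- Louvain-based quantities ($Q$, participation) inherit restart
  variability; maxima over seeded restarts make them reproducible but
  still lower bounds on the true maximum modularity.
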