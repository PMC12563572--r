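# gnmea — generative network models for in-vitro neuronal networks

`gnmea` is an R package for asking *how developing neuronal cultures wire
themselves*. Given spike-sorted activity of tens to hundreds of units
recorded on a planar high-density microelectrode array (unit ids, spike
times, 2-D positions), it:

1. **infers functional connectivity** with the spike time tiling
   coefficient (STTC) and jittered-surrogate significance testing,

   $$STTC = \tfrac{1}{2}\left(\tfrac{P_A - T_B}{1 - P_A T_B} +
   \tfrac{P_B - T_A}{1 - P_B T_A}\right),$$

   binarized at p ≤ 0.001 against 1000 surrogates (both trains jittered,
   Gaussian SD 10 ms), with a Δt = 10 ms synchronicity window;

2. **fits thirteen economic generative wiring rules** to the observed
   binary graph. Networks grow one edge at a time from an empty seed with
   probability score

   $$P_{ij} \propto D_{ij}^{\,\eta}\,K_{ij}^{\,\gamma},$$

   trading the cost of a connection (Euclidean distance $D$) against its
   topological value $K$ — all-ones (spatial), common neighbours or
   matching index (homophily), and five combinations each of nodal
   clustering and degree. The $(\eta, \gamma)$ plane is searched by
   Voronoi-tessellation preferential sampling (4000 + 4×4000 evaluations
   per rule at full scale);

3. **scores model fits** with the energy objective
   $E = \max(KS_k, KS_c, KS_b, KS_d)$ (maximum Kolmogorov–Smirnov distance
   over degree, clustering, betweenness and edge-length distributions), the
   topological-fingerprint dissimilarity (Frobenius distance between 6×6
   nodal-statistic correlation matrices), a leave-one-out Monte-Carlo
   `p_rank` diagnostic, growth-trajectory decomposition (modularity and
   global efficiency versus percentage completion), and wiring
   probability-score distribution summaries.

A seeded synthetic-data generator (`generate_culture()`) emulates
developing cultures — lognormal firing rates, network bursts with modular
participation, distance-decaying planted couplings, a developmental rate
ramp, and a high-synchrony (disinhibited) mode — so the entire pipeline is
testable without any recorded data. See `vignettes/methods.Rmd` for the
models, assumptions and design decisions.

## Worked example

```r
library(gnmea)

params <- culture_params(n_units = 40, duration_s = 600,
                         coupling_within = 0.6, coupling_between = 0.1,
                         n_modules = 3, seed = 42)
culture <- generate_culture(params)
culture$set
#> <spike_train_set> 40 units, 600.0 s, 61745 spikes (2.573 Hz/unit mean)

net <- infer_network(culture$set, sttc_config(seed = 1))
net
#> <functional_network> 40 nodes, 68 edges (density 0.087)

global_statistics(net, n_null = 100, seed = 1, n_louvain = 20)
#> <global_stats> n=40 m=68 density=0.087 C=0.393 L=2.923 Eglob=0.214 Q=0.547 sigma=5.65

fits <- fit_rules(net, c("matching", "spatial", "deg_avg", "clu_avg"),
                  search_config(n_initial = 150, n_rounds = 2,
                                samples_per_round = 150, seed = 7))
fits
#> <rule_fits> best energies by rule:
#>   rule_id      group        eta      gamma    energy
#>   deg_avg     degree -2.4042982  1.7047817 0.2058824
#>   clu_avg clustering -2.6873941  1.9178361 0.2250000
#>  matching  homophily -0.9416965  0.2110815 0.2500000
#>   spatial    spatial -2.5465969 -8.8350653 0.2500000
```

The 600 s synthetic culture yields a sparse functional network (density
0.087) with strong community structure (Q = 0.547) and a clearly
small-world topology (σ = 5.65 against 100 same-size, same-density random
graphs). All four fitted rule-group representatives reach energies of
0.21–0.25: every negative `eta` says short connections are strongly
preferred, and this particular culture (whose planted couplings are
modular, not homophilic) is approximated about equally well by
degree/clustering value terms. Replaying the best fit's growth shows the
canonical segregation-to-integration trade-off:

```r
b <- fits$fits$matching$best
tr <- grow_network(net$distance_um,
                   gnm_config("matching", b$eta, b$gamma,
                              network_edge_count(net), seed = 9))
trajectory_decomposition(tr, fractions = c(0.25, 0.5, 0.75, 1),
                         n_louvain = 10, seed = 1)
#>   fraction n_edges modularity global_efficiency
#> 1     0.25      17  0.6626298        0.04960623
#> 2     0.50      34  0.5912630        0.14534239
#> 3     0.75      51  0.4957709        0.25258852
#> 4     1.00      68  0.4656142        0.30844017
```

Modularity falls and global efficiency rises as simulated wiring
completes, mirroring longitudinal observations in developing cultures.

`run_pipeline(pipeline_config(...))` chains all stages (synthesis or file
input → spike metrics → inference → per-rule search → evaluation) and
writes delimited tables, JSON reports and a manifest; a thin command-line
wrapper with the same stages lives at `inst/scripts/gnmea-cli.R`.

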