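#' Parameters of a synthetic developing culture
#'
#' Describes the statistical structure of a simulated in-vitro neuronal
#' network on a planar high-density array: lognormally distributed baseline
#' firing rates, Poisson network-burst events with partial unit
#' participation, planted module structure that boosts same-module burst
#' participation, distance-decaying pairwise co-spiking for planted coupled
#' pairs, and a high-synchrony mode emulating disinhibited (GABA-A blocked)
#' cultures. Defaults emulate a sparse primary culture at a late
#' developmental stage: ~120 active units on a 3.85 x 2.10 mm array,
#' median baseline rate 1 Hz, network bursts every ~5 s.
#'
#' @param n_units number of units (>= 2).
#' @param array_width_um,array_height_um array dimensions in micrometres
#'   (defaults 3850 x 2100).
#' @param duration_s recording duration in seconds (default 1800, a
#'   30-minute recording).
#' @param base_rate_lognorm_mu,base_rate_lognorm_sigma log-rate parameters of
#'   the lognormal baseline firing-rate distribution (defaults give a median
#'   of 1 Hz with sigma 1).
#' @param burst_rate_hz network-burst event rate (default 0.2 Hz).
#' @param burst_jitter_ms within-burst spike-time spread (SD, default 50 ms).
#' @param participation_base probability that a unit joins a burst
#'   (default 0.6).
#' @param module_bonus boost of burst participation for units of the burst's
#'   lead module: `p + (1 - p) * module_bonus` (default 0.5).
#' @param n_modules number of planted modules (default 4).
#' @param coupling_within,coupling_between co-spiking probability scale for
#'   planted coupled pairs within / between modules (defaults 0.3 / 0.05).
#' @param distance_decay_um length scale of the exponential decay of
#'   coupling with distance (default 800; `Inf` disables decay).
#' @param synchrony_mode `"control"` or `"high_synchrony"`; the latter raises
#'   burst participation towards 1 and shrinks the burst jitter, emulating
#'   pharmacologically increased synchrony.
#' @param dev_stage developmental stage in `(0, 1]`, scaling baseline and
#'   burst rates multiplicatively.
#' @param min_distance_um minimum inter-unit distance (one electrode pitch,
#'   17.5 um); coincident draws are resampled.
#' @param seed integer seed; identical parameters including the seed give
#'   bit-identical output.
#' @return A list of class `culture_params`.
#' @export
culture_params <- function(n_units = 120, array_width_um = 3850,
                           array_height_um = 2100, duration_s = 1800,
                           base_rate_lognorm_mu = 0,
                           base_rate_lognorm_sigma = 1,
                           burst_rate_hz = 0.2, burst_jitter_ms = 50,
                           participation_base = 0.6, module_bonus = 0.5,
                           n_modules = 4, coupling_within = 0.3,
                           coupling_between = 0.05,
                           distance_decay_um = 800,
                           synchrony_mode = c("control", "high_synchrony"),
                           dev_stage = 1, min_distance_um = 17.5,
                           seed = 1L) {
  synchrony_mode <- match.arg(synchrony_mode)
  fields <- as.list(environment())
  if (n_units < 2) stop("n_units must be at least 2")
  if (duration_s <= 0) stop("duration_s must be positive")
  probs <- c(participation_base, module_bonus, coupling_within,
             coupling_between)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (array_width_um <= 0 || array_height_um <= 0)
    stop("array dimensions must be positive")
  if (burst_rate_hz < 0 || burst_jitter_ms < 0)
    stop("rates and jitters must be nonnegative")
  if (dev_stage <= 0 || dev_stage > 1) stop("dev_stage must be in (0, 1]")
  structure(fields, class = "culture_params")
}

# Positions uniform on the array with a minimum pairwise spacing of one
# electrode pitch; offending draws are resampled.
sample_positions <- function(n, width, height, min_dist) {
  pos <- cbind(runif(n, 0, width), runif(n, 0, height))
  repeat {
    d <- as.matrix(stats::dist(pos))
    diag(d) <- Inf
    bad <- unique(which(apply(d < min_dist, 1, any)))
    if (length(bad) == 0) break
    pos[bad, ] <- cbind(runif(length(bad), 0, width),
                        runif(length(bad), 0, height))
  }
  colnames(pos) <- c("x_um", "y_um")
  pos
}

# Layout draws (positions, rates, modules, coupled pairs) are seeded with
# params$seed alone so that all developmental stages of one culture share
# them; spike draws are seeded from (seed, dev_stage).
culture_layout <- function(params) {
  set.seed(params$seed)
  pos <- sample_positions(params$n_units, params$array_width_um,
                          params$array_height_um, params$min_distance_um)
  rates <- rlnorm(params$n_units, params$base_rate_lognorm_mu,
                  params$base_rate_lognorm_sigma)
  modules <- sample.int(params$n_modules, params$n_units, replace = TRUE)
  D <- position_distances(pos)
  n <- params$n_units
  cg <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      base <- if (modules[i] == modules[j]) params$coupling_within
              else params$coupling_between
      pr <- base * exp(-D[i, j] / params$distance_decay_um)
      if (runif(1) < pr) cg[i, j] <- cg[j, i] <- 1L
    }
  }
  list(positions = pos, rates = rates, modules = modules,
       coupling_graph = cg, distance_um = D)
}

spike_seed <- function(seed, dev_stage) {
  as.integer((seed + round(dev_stage * 997)) %% .Machine$integer.max)
}

culture_spikes <- function(params, layout, dev_stage) {
  set.seed(spike_seed(params$seed, dev_stage))
  n <- params$n_units
  dur <- params$duration_s
  high <- params$synchrony_mode == "high_synchrony"
  p_base <- params$participation_base
  if (high) p_base <- 1 - 0.2 * (1 - p_base)
  jit_s <- params$burst_jitter_ms / 1000 * (if (high) 0.3 else 1)

  # baseline Poisson spikes at the unit's (stage-scaled) lognormal rate
  spikes <- lapply(seq_len(n), function(i) {
    lam <- layout$rates[i] * dev_stage * dur
    sort(runif(rpois(1, lam), 0, dur))
  })

  # network-burst events: Poisson process, each with a lead module; units
  # participate with boosted probability when they belong to that module
  n_ev <- rpois(1, params$burst_rate_hz * dev_stage * dur)
  if (n_ev > 0) {
    ev_times <- sort(runif(n_ev, 0, dur))
    ev_module <- sample.int(params$n_modules, n_ev, replace = TRUE)
    for (e in seq_len(n_ev)) {
      p_i <- ifelse(layout$modules == ev_module[e],
                    p_base + (1 - p_base) * params$module_bonus, p_base)
      joins <- runif(n) < p_i
      for (i in which(joins)) {
        k <- 1 + rpois(1, 2)
        spikes[[i]] <- c(spikes[[i]], ev_times[e] + rnorm(k, sd = jit_s))
      }
    }
  }

  # planted coupled pairs co-spike: a fraction of the lower-index unit's
  # spikes is copied to the partner with 3 ms jitter (well inside the 10 ms
  # synchronicity window)
  cg <- layout$coupling_graph
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (cg[i, j] == 0) next
      base <- if (layout$modules[i] == layout$modules[j])
        params$coupling_within else params$coupling_between
      q <- base * exp(-layout$distance_um[i, j] / params$distance_decay_um)
      src <- spikes[[i]]
      take <- runif(length(src)) < q
      if (any(take))
        spikes[[j]] <- c(spikes[[j]], src[take] + rnorm(sum(take), sd = 0.003))
    }
  }

  lapply(spikes, function(t) sort(pmin(pmax(t, 0), dur)))
}

#' Generate a synthetic culture
#'
#' Draws unit positions, baseline rates, module labels and planted coupled
#' pairs, then synthesises each unit's spike train as baseline Poisson
#' spikes plus network-burst spikes plus coupled-pair co-spikes (see
#' [culture_params()] for the model). Identical parameters (including the
#' seed) give bit-identical output.
#'
#' @param params a [culture_params()].
#' @return A list with `set` (a [spike_train_set()]) and `ground_truth`
#'   (list with `module_assignment` and the symmetric binary
#'   `coupling_graph`).
#' @export
generate_culture <- function(params) {
  stopifnot(inherits(params, "culture_params"))
  layout <- culture_layout(params)
  spikes <- culture_spikes(params, layout, params$dev_stage)
  names(spikes) <- paste0("u", seq_len(params$n_units))
  set <- spike_train_set(spikes, params$duration_s, layout$positions,
                         metadata = list(condition = params$synchrony_mode,
                                         dev_stage = params$dev_stage))
  list(set = set,
       ground_truth = list(module_assignment = layout$modules,
                           coupling_graph = layout$coupling_graph))
}

#' Generate a developmental series of recordings
#'
#' One spike-train set per developmental stage, with positions, baseline
#' rates, modules and coupled pairs shared across stages (the same tracked
#' units) and rates scaled by each stage fraction.
#'
#' @param params a [culture_params()]; its `dev_stage` is ignored.
#' @param stages strictly increasing fractions in `(0, 1]`.
#' @return A list with `sets` (list of [spike_train_set()], one per stage)
#'   and `ground_truth` (shared across stages).
#' @export
generate_development_series <- function(params, stages) {
  stopifnot(inherits(params, "culture_params"))
  if (length(stages) == 0) stop("stages must be non-empty")
  if (any(stages <= 0 | stages > 1)) stop("stages must lie in (0, 1]")
  if (is.unsorted(stages, strictly = TRUE))
    stop("stages must be strictly increasing")
  layout <- culture_layout(params)
  sets <- lapply(stages, function(s) {
    spikes <- culture_spikes(params, layout, s)
    names(spikes) <- paste0("u", seq_len(params$n_units))
    spike_train_set(spikes, params$duration_s, layout$positions,
                    metadata = list(condition = params$synchrony_mode,
                                    dev_stage = s))
  })
  list(sets = sets,
       ground_truth = list(module_assignment = layout$modules,
                           coupling_graph = layout$coupling_graph))
}

#' Grow a fixture network under a known rule
#'
#' Convenience wrapper for parameter-recovery experiments: places `n_units`
#' uniformly at random on the array (minimum spacing one electrode pitch),
#' grows a network under the named wiring rule, and wraps it as a
#' [functional_network()] that can stand in for an observed one.
#'
#' @param rule_id one of [gnm_rules()].
#' @param eta,gamma wiring exponents.
#' @param n_units number of nodes.
#' @param m number of edges.
#' @param seed integer seed.
#' @param array_width_um,array_height_um array dimensions.
#' @return A [functional_network()] with attribute `"trace"` holding the
#'   growth trace.
#' @export
grow_fixture_network <- function(rule_id, eta, gamma, n_units, m, seed = 1L,
                                 array_width_um = 3850,
                                 array_height_um = 2100) {
  set.seed(seed)
  pos <- sample_positions(n_units, array_width_um, array_height_um, 17.5)
  D <- position_distances(pos)
  cfg <- gnm_config(rule_id, eta, gamma, m, seed = seed + 1L)
  tr <- grow_network(D, cfg, record_trace = FALSE)
  net <- functional_network(tr$adjacency, pos,
                            metadata = list(rule_id = rule_id, eta = eta,
                                            gamma = gamma))
  attr(net, "trace") <- tr
  net
}
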