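#' Parameter-search configuration
#'
#' Controls the Voronoi-tessellation preferential search over the
#' \eqn{(\eta, \gamma)} plane. Defaults follow the full-scale protocol: an
#' initial uniform draw of 4000 parameter pairs in \eqn{[-10, 10]^2}
#' followed by four preferential rounds of 4000 samples each (20,000
#' evaluations per rule), with cell-selection severity \eqn{\alpha = 2}.
#'
#' @param eta_range,gamma_range numeric length-2 intervals.
#' @param n_initial uniform samples in round 0.
#' @param n_rounds preferential rounds after the initial draw.
#' @param samples_per_round samples per preferential round (defaults to
#'   `n_initial`).
#' @param alpha_severity exponent of the inverse-energy cell weights.
#' @param n_replicates grown networks per parameter sample; energies are
#'   averaged (default 1).
#' @param seed integer seed.
#' @return A list of class `search_config`.
#' @export
search_config <- function(eta_range = c(-10, 10), gamma_range = c(-10, 10),
                          n_initial = 4000, n_rounds = 4,
                          samples_per_round = n_initial, alpha_severity = 2,
                          n_replicates = 1, seed = 1L) {
  stopifnot(length(eta_range) == 2, length(gamma_range) == 2,
            diff(eta_range) > 0, diff(gamma_range) > 0,
            n_initial >= 1, n_rounds >= 0, samples_per_round >= 1,
            alpha_severity >= 0, n_replicates >= 1)
  structure(list(eta_range = eta_range, gamma_range = gamma_range,
                 n_initial = as.integer(n_initial),
                 n_rounds = as.integer(n_rounds),
                 samples_per_round = as.integer(samples_per_round),
                 alpha_severity = alpha_severity,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "search_config")
}

search_seed <- function(seed, i, salt) {
  as.integer((as.double(seed) + as.double(salt) * i) %%
               (.Machine$integer.max - 1L) + 1L)
}

default_evaluator <- function(observed, rule_id, cfg) {
  D <- observed$distance_um
  m <- network_edge_count(observed)
  obs_stats <- energy_stats(observed$adjacency, D)
  force(rule_id)
  function(eta, gamma, seed) {
    es <- lapply(seq_len(cfg$n_replicates), function(r) {
      gcfg <- gnm_config(rule_id, eta, gamma, m,
                         seed = search_seed(seed, r, 13L))
      tr <- grow_network(D, gcfg, record_trace = FALSE)
      energy(observed, tr$adjacency, D, observed_stats = obs_stats)
    })
    out <- es[[1]]
    if (length(es) > 1)
      for (f in names(out)) out[[f]] <- mean(vapply(es, `[[`, 0, f))
    out
  }
}

#' Voronoi-tessellation search over the wiring parameter plane
#'
#' Fits one wiring rule to an observed network. Round 0 draws
#' \eqn{(\eta, \gamma)} uniformly; each subsequent round treats every
#' evaluated point as the site of a Voronoi cell, weights cells by
#' \eqn{(1/\mathrm{energy})^{\alpha}} (normalized), draws cells by weight
#' and proposes points uniformly within the chosen cell (rejection sampling
#' against the nearest-site relation, clipped to the ranges). Every sampled
#' point grows one simulated network with the target edge count of the
#' observed network and is scored by the energy objective.
#'
#' @param observed a [functional_network()] with at least one edge.
#' @param rule_id one of [gnm_rules()].
#' @param cfg a [search_config()].
#' @param evaluator optional `function(eta, gamma, seed)` returning a list
#'   with fields `energy`, `ks_degree`, `ks_clustering`, `ks_betweenness`,
#'   `ks_edge_length`; defaults to growing a network under `rule_id` and
#'   scoring it against `observed`. Injectable for testing and for
#'   alternative objectives.
#' @return A list of class `param_search_result`: `samples` (data frame
#'   with `round`, `eta`, `gamma`, `energy`, `ks_degree`, `ks_clustering`,
#'   `ks_betweenness`, `ks_edge_length`), `best` (minimum-energy row),
#'   `rule_id`, `config`.
#' @export
voronoi_search <- function(observed, rule_id, cfg = search_config(),
                           evaluator = NULL) {
  rule_id <- match.arg(rule_id, gnm_rules())
  stopifnot(inherits(cfg, "search_config"))
  if (is.null(evaluator)) {
    if (network_edge_count(observed) < 1)
      stop("observed network must have at least one edge")
    evaluator <- default_evaluator(observed, rule_id, cfg)
  }

  n_total <- cfg$n_initial + cfg$n_rounds * cfg$samples_per_round
  pts <- matrix(NA_real_, n_total, 2)
  res <- matrix(NA_real_, n_total, 5,
                dimnames = list(NULL, c("energy", "ks_degree",
                                        "ks_clustering", "ks_betweenness",
                                        "ks_edge_length")))
  round_id <- integer(n_total)
  n_done <- 0

  eval_batch <- function(prop) {
    for (k in seq_len(nrow(prop))) {
      i <- n_done + k
      ev <- evaluator(prop[k, 1], prop[k, 2],
                      search_seed(cfg$seed, i, 7919L))
      res[i, ] <<- c(ev$energy, ev$ks_degree, ev$ks_clustering,
                     ev$ks_betweenness, ev$ks_edge_length)
    }
    pts[n_done + seq_len(nrow(prop)), ] <<- prop
    n_done <<- n_done + nrow(prop)
  }

  # round 0: uniform
  set.seed(search_seed(cfg$seed, 0L, 104729L))
  prop0 <- cbind(runif(cfg$n_initial, cfg$eta_range[1], cfg$eta_range[2]),
                 runif(cfg$n_initial, cfg$gamma_range[1], cfg$gamma_range[2]))
  round_id[seq_len(cfg$n_initial)] <- 0L
  eval_batch(prop0)

  for (r in seq_len(cfg$n_rounds)) {
    sites <- pts[seq_len(n_done), , drop = FALSE]
    if (anyDuplicated(sites)) {
      warning("duplicate sampled points deduplicated for tessellation")
    }
    keep <- !duplicated(sites)
    sites_u <- sites[keep, , drop = FALSE]
    e_u <- res[seq_len(n_done), "energy"][keep]
    wts <- (1 / pmax(e_u, 1e-6))^cfg$alpha_severity
    wts <- wts / sum(wts)
    set.seed(search_seed(cfg$seed, r, 104729L))
    prop <- matrix(NA_real_, cfg$samples_per_round, 2)
    chosen <- sample.int(nrow(sites_u), cfg$samples_per_round, replace = TRUE,
                         prob = wts)
    for (k in seq_len(cfg$samples_per_round)) {
      s <- chosen[k]
      prop[k, ] <- propose_in_cell(sites_u, s, cfg$eta_range, cfg$gamma_range)
    }
    round_id[n_done + seq_len(cfg$samples_per_round)] <- r
    eval_batch(prop)
  }

  samples <- data.frame(round = round_id, eta = pts[, 1], gamma = pts[, 2],
                        res)
  out <- structure(list(samples = samples, rule_id = rule_id, config = cfg),
                   class = "param_search_result")
  out$best <- top_n(out, 1)
  out
}

# Uniform proposal inside the Voronoi cell of site s: draw in a box centred
# on the site (half-width = distance to the nearest other site, clipped to
# the ranges) and accept when the nearest site is s; the box shrinks on
# failure, so the proposal converges to the site, which lies in its own
# cell.
propose_in_cell <- function(sites, s, eta_range, gamma_range,
                            max_tries = 25) {
  site <- sites[s, ]
  if (nrow(sites) == 1) {
    return(c(runif(1, eta_range[1], eta_range[2]),
             runif(1, gamma_range[1], gamma_range[2])))
  }
  d2 <- (sites[, 1] - site[1])^2 + (sites[, 2] - site[2])^2
  d2[s] <- Inf
  r <- sqrt(min(d2))
  for (try in seq_len(max_tries)) {
    p <- c(max(eta_range[1], min(eta_range[2], runif(1, site[1] - r, site[1] + r))),
           max(gamma_range[1], min(gamma_range[2], runif(1, site[2] - r, site[2] + r))))
    dd <- (sites[, 1] - p[1])^2 + (sites[, 2] - p[2])^2
    if (which.min(dd) == s) return(p)
    r <- r / 2
  }
  site + runif(2, -1e-9, 1e-9)
}

#' Top-n samples of a parameter search
#'
#' @param result a `param_search_result`.
#' @param n number of lowest-energy samples (>= 1, at most the number of
#'   samples). Ties are broken by the four KS components
#'   (degree, clustering, betweenness, edge length) lexicographically, then
#'   by sample index.
#' @return Data frame of `n` rows, sorted best-first.
#' @export
top_n <- function(result, n) {
  s <- result$samples
  if (n <= 0) stop("n must be positive")
  if (n > nrow(s)) stop("n exceeds the number of samples")
  ord <- order(s$energy, s$ks_degree, s$ks_clustering, s$ks_betweenness,
               s$ks_edge_length, seq_len(nrow(s)))
  s[ord[seq_len(n)], , drop = FALSE]
}

#' @export
print.param_search_result <- function(x, ...) {
  cat(sprintf("<param_search_result> rule=%s, %d samples, best E=%.4f at eta=%.2f gamma=%.2f\n",
              x$rule_id, nrow(x$samples), x$best$energy, x$best$eta,
              x$best$gamma))
  invisible(x)
}

#' Fit several wiring rules to one observed network
#'
#' Runs [voronoi_search()] per rule and tabulates the best fit of each.
#'
#' @param observed a [functional_network()].
#' @param rules character vector of rule ids (default all 13).
#' @param cfg a [search_config()].
#' @return A list of class `rule_fits`: `fits` (named list of
#'   `param_search_result`), `summary` (data frame with rule, group, best
#'   eta/gamma/energy, sorted by energy).
#' @export
fit_rules <- function(observed, rules = gnm_rules(), cfg = search_config()) {
  fits <- lapply(rules, function(r) voronoi_search(observed, r, cfg))
  names(fits) <- rules
  summ <- do.call(rbind, lapply(rules, function(r) {
    b <- fits[[r]]$best
    data.frame(rule_id = r, group = gnm_rule_group(r), eta = b$eta,
               gamma = b$gamma, energy = b$energy)
  }))
  summ <- summ[order(summ$energy), ]
  rownames(summ) <- NULL
  structure(list(fits = fits, summary = summ), class = "rule_fits")
}

#' @export
print.rule_fits <- function(x, ...) {
  cat("<rule_fits> best energies by rule:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
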