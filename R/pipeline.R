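#' Pipeline configuration
#'
#' Bundles the stage configurations of an end-to-end run: synthetic culture
#' parameters (or file inputs), STTC inference settings, the wiring rules to
#' fit, the parameter-search settings, and the output directory.
#'
#' @param culture a [culture_params()] for a synthetic run, or `NULL` when
#'   reading spike/position files.
#' @param spike_file,position_file input tables (used when `culture` is
#'   `NULL`).
#' @param duration_s recording duration when reading files.
#' @param sttc an [sttc_config()].
#' @param rules character vector of wiring rules to fit (subset of
#'   [gnm_rules()]).
#' @param search a [search_config()].
#' @param out_dir output directory (created if missing).
#' @param seed global seed; fanned out to per-stage sub-seeds by fixed
#'   derivation.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(culture = NULL, spike_file = NULL,
                            position_file = NULL, duration_s = NULL,
                            sttc = sttc_config(),
                            rules = c("matching", "spatial", "deg_avg",
                                      "clu_avg"),
                            search = search_config(n_initial = 100,
                                                   n_rounds = 2,
                                                   samples_per_round = 100),
                            out_dir = tempfile("gnmea_run_"), seed = 1L) {
  rules <- vapply(rules, function(r) match.arg(r, gnm_rules()), "")
  if (is.null(culture) && (is.null(spike_file) || is.null(position_file)))
    stop("either a culture_params or spike/position files must be given")
  if (!is.null(culture)) stopifnot(inherits(culture, "culture_params"))
  structure(list(culture = culture, spike_file = spike_file,
                 position_file = position_file, duration_s = duration_s,
                 sttc = sttc, rules = unname(rules), search = search,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: (1) synthesise or load spike trains; (2) per-unit spike metrics;
#' (3) STTC functional-network inference; (4) per-rule Voronoi parameter
#' search; (5) evaluation (best fits, trajectory of the overall best rule).
#' All artifacts are written under `cfg$out_dir` together with a manifest
#' recording the configuration and seeds, from which every number in the
#' report can be reproduced.
#'
#' @param cfg a [pipeline_config()].
#' @param verbose log stage boundaries (default `TRUE`).
#' @return A list of class `pipeline_report`: `set`, `network`,
#'   `spike_summary`, `global_stats`, `fits` (a `rule_fits`), `trajectory`,
#'   `manifest`, `out_dir`.
#' @export
run_pipeline <- function(cfg, verbose = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  log_ <- function(...) if (verbose) message(sprintf(...))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  # stage 1: spikes
  if (!is.null(cfg$culture)) {
    culture <- cfg$culture
    culture$seed <- as.integer(cfg$seed + 11L)
    gen <- generate_culture(culture)
    set <- gen$set
    write_json_report(gen$ground_truth,
                      file.path(cfg$out_dir, "ground_truth.json"))
  } else {
    set <- read_spike_tables(cfg$spike_file, cfg$position_file,
                             duration_s = cfg$duration_s)
  }
  write_spike_tables(set, file.path(cfg$out_dir, "spikes.csv"),
                     file.path(cfg$out_dir, "positions.csv"))
  log_("stage spikes: %d units, %.0f s", length(set$unit_ids),
       set$duration_s)

  # stage 2: spike metrics
  rates <- firing_rate_table(set, cfg$sttc$min_rate_hz)
  utils::write.csv(rates, file.path(cfg$out_dir, "unit_rates.csv"),
                   row.names = FALSE)

  # stage 3: connectivity
  sttc_cfg <- cfg$sttc
  sttc_cfg$seed <- as.integer(cfg$seed + 23L)
  net <- infer_network(set, sttc_cfg)
  n <- nrow(net$adjacency)
  m <- network_edge_count(net)
  log_("stage connectivity: n=%d m=%d density=%.3f", n, m,
       if (n > 1) 2 * m / (n * (n - 1)) else NA)
  write_matrix(net$adjacency, file.path(cfg$out_dir, "adjacency.csv"))
  write_matrix(net$sttc_weights, file.path(cfg$out_dir, "sttc_weights.csv"))
  write_matrix(net$p_values, file.path(cfg$out_dir, "p_values.csv"))

  gs <- global_statistics(net, n_null = 100,
                          seed = as.integer(cfg$seed + 31L), n_louvain = 20)
  write_json_report(unclass(gs), file.path(cfg$out_dir, "global_stats.json"))

  # stage 4: per-rule parameter search
  fits <- NULL
  trajectory <- NULL
  if (m >= 1 && length(cfg$rules) > 0) {
    search_cfg <- cfg$search
    search_cfg$seed <- as.integer(cfg$seed + 47L)
    fits <- fit_rules(net, cfg$rules, search_cfg)
    utils::write.csv(fits$summary, file.path(cfg$out_dir, "fit_summary.csv"),
                     row.names = FALSE)
    for (r in names(fits$fits))
      utils::write.csv(fits$fits[[r]]$samples,
                       file.path(cfg$out_dir, paste0("landscape_", r, ".csv")),
                       row.names = FALSE)
    log_("stage fits: best rule %s (E=%.4f)", fits$summary$rule_id[1],
         fits$summary$energy[1])

    # stage 5: trajectory of the overall best fit
    best <- fits$summary[1, ]
    gcfg <- gnm_config(best$rule_id, best$eta, best$gamma, m,
                       seed = as.integer(cfg$seed + 59L))
    tr <- grow_network(net$distance_um, gcfg, record_trace = TRUE)
    trajectory <- trajectory_decomposition(tr, net$distance_um,
                                           fractions = seq(0.1, 1, by = 0.1),
                                           n_louvain = 10,
                                           seed = as.integer(cfg$seed + 61L))
    utils::write.csv(trajectory, file.path(cfg$out_dir, "trajectory.csv"),
                     row.names = FALSE)
  } else {
    log_("stage fits skipped: empty network or no rules requested")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("gnmea")),
    seed = cfg$seed,
    synthetic = !is.null(cfg$culture),
    culture = if (!is.null(cfg$culture)) unclass(cfg$culture),
    sttc = unclass(cfg$sttc), rules = cfg$rules,
    search = unclass(cfg$search),
    n_nodes = n, n_edges = m)
  write_json_report(manifest, file.path(cfg$out_dir, "manifest.json"))

  structure(list(set = set, network = net, spike_summary = rates,
                 global_stats = gs, fits = fits, trajectory = trajectory,
                 manifest = manifest, out_dir = cfg$out_dir),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> n=%d m=%d; artifacts in %s\n",
              x$manifest$n_nodes, x$manifest$n_edges, x$out_dir))
  if (!is.null(x$fits)) {
    cat("best fits:\n")
    print(utils::head(x$fits$summary, 4), row.names = FALSE)
  }
  invisible(x)
}
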