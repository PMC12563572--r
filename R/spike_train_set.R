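#' Construct a spike-train set
#'
#' The raw input of the whole pipeline: per-unit spike times recorded over a
#' common duration, together with the 2-D position of every unit on the array.
#'
#' @param spikes named list of numeric vectors, one sorted vector of spike
#'   times (seconds) per unit. Names are taken as unit ids; unnamed lists get
#'   ids `u1, u2, ...`.
#' @param duration_s recording duration in seconds; all spike times must lie
#'   in `[0, duration_s]`.
#' @param positions two-column matrix or data frame of unit positions
#'   (x, y in micrometres), one row per unit, same order as `spikes`.
#' @param metadata optional named list of free-form labels (condition, stage).
#'
#' @return An object of class `spike_train_set` with elements `unit_ids`,
#'   `spikes`, `duration_s`, `positions` (matrix with columns `x_um`, `y_um`)
#'   and `metadata`.
#' @export
spike_train_set <- function(spikes, duration_s, positions, metadata = list()) {
  stopifnot(is.list(spikes), length(spikes) >= 1)
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0)
    stop("duration_s must be a single positive number")
  ids <- names(spikes)
  if (is.null(ids)) ids <- paste0("u", seq_along(spikes))
  positions <- as.matrix(positions)
  if (nrow(positions) != length(spikes))
    stop("positions must have one row per unit")
  if (!all(is.finite(positions)))
    stop("positions must be finite")
  colnames(positions) <- c("x_um", "y_um")
  rownames(positions) <- ids
  spikes <- lapply(spikes, function(t) {
    t <- as.numeric(t)
    if (is.unsorted(t)) stop("per-unit spike times must be non-decreasing")
    if (length(t) && (t[1] < 0 || t[length(t)] > duration_s))
      stop("spike times must lie in [0, duration_s]")
    t
  })
  names(spikes) <- ids
  structure(
    list(unit_ids = ids, spikes = spikes, duration_s = duration_s,
         positions = positions, metadata = metadata),
    class = "spike_train_set"
  )
}

#' @export
print.spike_train_set <- function(x, ...) {
  n_sp <- sum(lengths(x$spikes))
  cat(sprintf("<spike_train_set> %d units, %.1f s, %d spikes (%.3f Hz/unit mean)\n",
              length(x$unit_ids), x$duration_s, n_sp,
              n_sp / length(x$unit_ids) / x$duration_s))
  invisible(x)
}

#' Euclidean distance matrix from unit positions
#'
#' @param positions matrix with columns `x_um`, `y_um`.
#' @return Symmetric matrix of pairwise distances in micrometres.
#' @export
position_distances <- function(positions) {
  as.matrix(stats::dist(positions[, 1:2, drop = FALSE]))
}
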