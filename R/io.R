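#' Read and write spike-time and position tables
#'
#' Spike tables are delimited files with columns `unit_id`, `spike_time_s`;
#' position tables have columns `unit_id`, `x_um`, `y_um`. Writing then
#' reading reproduces values to full precision.
#'
#' @param set a [spike_train_set()].
#' @param spike_file,position_file file paths.
#' @name spike_io
NULL

#' @rdname spike_io
#' @export
write_spike_tables <- function(set, spike_file, position_file) {
  stopifnot(inherits(set, "spike_train_set"))
  sp <- data.frame(
    unit_id = rep(set$unit_ids, lengths(set$spikes)),
    spike_time_s = sprintf("%.17g", unlist(set$spikes, use.names = FALSE)))
  write.csv(sp, spike_file, row.names = FALSE, quote = FALSE)
  pos <- data.frame(unit_id = set$unit_ids,
                    x_um = sprintf("%.17g", set$positions[, 1]),
                    y_um = sprintf("%.17g", set$positions[, 2]))
  write.csv(pos, position_file, row.names = FALSE, quote = FALSE)
  invisible(c(spike_file, position_file))
}

#' @rdname spike_io
#' @param duration_s recording duration; defaults to the latest spike time.
#' @param metadata free-form labels attached to the returned set.
#' @return `read_spike_tables()` returns a [spike_train_set()].
#' @export
read_spike_tables <- function(spike_file, position_file, duration_s = NULL,
                              metadata = list()) {
  sp <- read.csv(spike_file, stringsAsFactors = FALSE)
  need <- c("unit_id", "spike_time_s")
  if (!all(need %in% names(sp)))
    stop("spike table must have columns unit_id, spike_time_s")
  pos <- read.csv(position_file, stringsAsFactors = FALSE)
  if (!all(c("unit_id", "x_um", "y_um") %in% names(pos)))
    stop("position table must have columns unit_id, x_um, y_um")
  ids <- as.character(pos$unit_id)
  if (nrow(sp) == 0) {
    warning("header-only spike table: empty spike trains")
    spikes <- stats::setNames(rep(list(numeric(0)), length(ids)), ids)
  } else {
    sp$unit_id <- as.character(sp$unit_id)
    unknown <- setdiff(unique(sp$unit_id), ids)
    if (length(unknown))
      stop("spike table references units absent from the position table: ",
           paste(unknown, collapse = ", "))
    spikes <- lapply(ids, function(u) {
      t <- sp$spike_time_s[sp$unit_id == u]
      if (is.unsorted(t)) {
        bad <- which(diff(t) < 0)[1]
        stop(sprintf("non-monotone spike times for unit %s near row %d", u,
                     bad))
      }
      t
    })
    names(spikes) <- ids
  }
  if (is.null(duration_s))
    duration_s <- max(c(unlist(spikes), 0)) + .Machine$double.eps
  spike_train_set(spikes, duration_s,
                  cbind(x_um = pos$x_um, y_um = pos$y_um), metadata)
}

#' Read and write numeric matrices
#'
#' Adjacency, weight and distance matrices are stored as headerless
#' delimited numeric matrices. `read_adjacency()` validates symmetry.
#'
#' @param mat numeric matrix.
#' @param file file path.
#' @name matrix_io
NULL

#' @rdname matrix_io
#' @export
write_matrix <- function(mat, file) {
  utils::write.table(format(unname(as.matrix(mat)), digits = 17,
                            trim = TRUE, scientific = TRUE),
                     file, row.names = FALSE, col.names = FALSE,
                     quote = FALSE, sep = ",")
  invisible(file)
}

#' @rdname matrix_io
#' @export
read_matrix <- function(file) {
  as.matrix(utils::read.table(file, sep = ",", header = FALSE))
}

#' @rdname matrix_io
#' @return `read_adjacency()` returns a validated symmetric binary matrix.
#' @export
read_adjacency <- function(file) {
  check_adjacency(read_matrix(file))
}

#' Write ground truth or result objects as JSON
#'
#' @param x a list (ground truth, global statistics, fit summary, ...).
#' @param file file path.
#' @export
write_json_report <- function(x, file) {
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(file)
}
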