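#' Firing rate of a spike train
#'
#' Total number of spikes per unit time over the entire recording.
#'
#' @param train numeric vector of spike times (seconds); may be empty.
#' @param duration_s recording duration (> 0).
#' @return Rate in Hz (0 for an empty train).
#' @export
firing_rate <- function(train, duration_s) {
  stopifnot(duration_s > 0)
  length(train) / duration_s
}

#' Per-unit firing-rate table
#'
#' @param set a [spike_train_set()].
#' @param min_rate_hz threshold below which a unit is flagged inactive;
#'   network-level means should be taken over active units only.
#' @return Data frame with `unit_id`, `rate_hz`, `active`.
#' @export
firing_rate_table <- function(set, min_rate_hz = 0.01) {
  r <- vapply(set$spikes, firing_rate, 0, duration_s = set$duration_s)
  data.frame(unit_id = set$unit_ids, rate_hz = unname(r),
             active = unname(r > min_rate_hz), row.names = NULL)
}

# Threshold for ISI_N burst detection: local minimum of the smoothed
# log10(ISI_N) histogram between its two dominant peaks. Returns NA when the
# histogram is effectively unimodal (no interior trough between two peaks).
isi_n_threshold <- function(isi_n, n_bins = 100, smooth_bins = 3) {
  lg <- log10(isi_n[isi_n > 0])
  if (length(unique(lg)) < 3) return(NA_real_)
  rng <- range(lg)
  if (diff(rng) == 0) return(NA_real_)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(lg, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = n_bins)
  # moving-average smoothing
  kern <- rep(1 / smooth_bins, smooth_bins)
  hs <- as.numeric(stats::filter(h, kern, sides = 2))
  hs[is.na(hs)] <- h[is.na(hs)]
  nb <- length(hs)
  peaks <- which(diff(sign(diff(c(-Inf, hs, -Inf)))) < 0)
  peaks <- peaks[hs[peaks] > 0]
  if (length(peaks) < 2) return(NA_real_)
  # two dominant peaks
  ord <- order(hs[peaks], decreasing = TRUE)
  p1 <- min(peaks[ord[1]], peaks[ord[2]])
  p2 <- max(peaks[ord[1]], peaks[ord[2]])
  if (p2 - p1 < 2) return(NA_real_)
  trough <- p1 + which.min(hs[(p1 + 1):(p2 - 1)])
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  10^mids[trough]
}

#' Detect bursts with the ISI_N method
#'
#' The N-spike interval `ISI_N(k) = t[k+N] - t[k]` is computed along the
#' train; its log10 histogram in developing cultures is bimodal (a
#' short-interval bursting peak and a long-interval tonic peak), and the
#' burst threshold is set at the local trough between the two dominant
#' peaks. Every window of N consecutive inter-spike intervals shorter than
#' the threshold marks burst membership; overlapping windows are merged and
#' burst edges snap to the first/last spike of the run. When the histogram is
#' unimodal no threshold exists and zero bursts are returned with a warning.
#'
#' @param train sorted spike times (seconds); needs at least `n_for_isi + 1`
#'   spikes.
#' @param n_for_isi the N of ISI_N (default 10).
#' @param duration_s recording duration, used for the burst rate.
#' @param n_bins,smooth_bins histogram resolution and moving-average width
#'   for the trough search.
#' @return A list of class `burst_profile`: `onsets`, `offsets` (seconds),
#'   `isi_n_threshold_s`, `n_for_isi`, `burst_rate` (bursts/min),
#'   `fraction_spikes_in_bursts`, `cv_ibi` (SD/mean of onset-to-onset
#'   inter-burst intervals; `NA` with fewer than 3 bursts).
#' @export
detect_bursts <- function(train, n_for_isi = 10, duration_s = max(train),
                          n_bins = 100, smooth_bins = 3) {
  n <- length(train)
  if (n < n_for_isi + 1) stop("train must have at least n_for_isi + 1 spikes")
  empty <- function(thr) {
    structure(list(onsets = numeric(0), offsets = numeric(0),
                   isi_n_threshold_s = thr, n_for_isi = n_for_isi,
                   burst_rate = 0, fraction_spikes_in_bursts = 0,
                   cv_ibi = NA_real_),
              class = "burst_profile")
  }
  isi_n <- train[(n_for_isi + 1):n] - train[1:(n - n_for_isi)]
  thr <- isi_n_threshold(isi_n, n_bins = n_bins, smooth_bins = smooth_bins)
  if (is.na(thr)) {
    warning("log10(ISI_N) histogram is unimodal; no burst threshold found")
    return(empty(NA_real_))
  }
  qual <- which(isi_n <= thr)  # window k spans spikes k .. k + N
  if (length(qual) == 0) return(empty(thr))
  # merge overlapping windows [k, k + N] into runs
  starts <- c(TRUE, diff(qual) > n_for_isi)
  run_id <- cumsum(starts)
  onsets <- train[vapply(split(qual, run_id), min, 0L)]
  offsets <- train[vapply(split(qual, run_id), max, 0L) + n_for_isi]
  nb <- length(onsets)
  in_burst <- logical(n)
  for (b in seq_len(nb))
    in_burst[train >= onsets[b] & train <= offsets[b]] <- TRUE
  cv <- if (nb >= 3) {
    ibi <- diff(onsets)
    sd(ibi) / mean(ibi)
  } else NA_real_
  structure(list(onsets = onsets, offsets = offsets,
                 isi_n_threshold_s = thr, n_for_isi = n_for_isi,
                 burst_rate = nb / (duration_s / 60),
                 fraction_spikes_in_bursts = mean(in_burst),
                 cv_ibi = cv),
            class = "burst_profile")
}

#' @export
print.burst_profile <- function(x, ...) {
  cat(sprintf("<burst_profile> %d bursts (%.2f/min), %.0f%% of spikes in bursts, CV(IBI)=%s\n",
              length(x$onsets), x$burst_rate,
              100 * x$fraction_spikes_in_bursts,
              ifelse(is.na(x$cv_ibi), "NA", sprintf("%.2f", x$cv_ibi))))
  invisible(x)
}

#' Population autocorrelogram
#'
#' Pools all units' spikes into one train, bins it at 1 ms, and correlates
#' the binned vector with lagged copies of itself over lags -500..500 ms.
#' Lags in -1..1 ms are zeroed to impose a refractory period, and the vector
#' is normalized to its maximum.
#'
#' @param set a [spike_train_set()] with at least one spike.
#' @param max_lag_ms window half-width in milliseconds.
#' @param bin_ms bin width in milliseconds.
#' @param refractory_ms lags in `[-refractory_ms, refractory_ms]` are zeroed.
#' @return Named numeric vector indexed by lag (ms), maximum value 1.
#' @export
population_autocorrelogram <- function(set, max_lag_ms = 500, bin_ms = 1,
                                       refractory_ms = 1) {
  all_sp <- sort(unlist(set$spikes, use.names = FALSE))
  if (length(all_sp) == 0) stop("spike-train set contains no spikes")
  nbin <- ceiling(set$duration_s * 1000 / bin_ms)
  v <- tabulate(pmin(floor(all_sp * 1000 / bin_ms) + 1, nbin), nbins = nbin)
  lags <- seq(-max_lag_ms, max_lag_ms, by = bin_ms)
  nlag <- max_lag_ms / bin_ms
  # FFT-based autocorrelation (convolve reverses its second argument)
  ac_full <- stats::convolve(v, v, type = "open")
  centre <- nbin  # zero-lag index in the length 2*nbin-1 result
  ac <- ac_full[(centre - nlag):(centre + nlag)]
  ac[abs(lags) <= refractory_ms] <- 0
  mx <- max(ac)
  if (mx > 0) ac <- ac / mx
  names(ac) <- lags
  ac
}
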