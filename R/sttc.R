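#' Spike time tiling coefficient
#'
#' Firing-rate-robust pairwise synchrony between two spike trains:
#' \deqn{STTC = \frac{1}{2}\left(\frac{P_A - T_B}{1 - P_A T_B} +
#'   \frac{P_B - T_A}{1 - P_B T_A}\right)}
#' where \eqn{T_A} is the fraction of the recording tiled by the union of
#' \eqn{\pm\Delta t} windows around A's spikes (windows clipped to the
#' recording, overlaps merged exactly) and \eqn{P_A} is the proportion of A's
#' spikes falling within \eqn{\pm\Delta t} of any spike of B.
#'
#' @param a,b sorted numeric vectors of spike times in seconds; both
#'   non-empty.
#' @param duration_s recording duration in seconds.
#' @param delta_t_s half-width of the synchronicity window in seconds
#'   (default 0.010 s).
#' @return STTC value in `[-1, 1]`.
#' @examples
#' sttc(c(1, 2, 3), c(1, 2, 3), duration_s = 10)     # identical trains: 1
#' sttc(c(1, 2), c(6, 7), duration_s = 10)           # no coincidences: < 0
#' @export
sttc <- function(a, b, duration_s, delta_t_s = 0.010) {
  if (length(a) == 0 || length(b) == 0)
    stop("STTC is undefined for empty spike trains")
  stopifnot(duration_s > 0, delta_t_s > 0)
  sttc_cpp(as.numeric(a), as.numeric(b), duration_s, delta_t_s)
}

#' Jitter a spike train with Gaussian noise
#'
#' Displaces every spike independently by a zero-mean Gaussian, re-sorts, and
#' clips to `[0, duration_s]`. Used to build the surrogate null for STTC
#' significance testing; draws come from the R random number stream, so wrap
#' with `set.seed()` for reproducibility.
#'
#' @param train sorted numeric vector of spike times (seconds).
#' @param jitter_sd_s jitter standard deviation in seconds.
#' @param duration_s recording duration for clipping.
#' @return Jittered, sorted, clipped spike-time vector of the same length.
#' @export
jitter_train <- function(train, jitter_sd_s, duration_s) {
  if (length(train) == 0) return(train)
  if (jitter_sd_s == 0) return(train)
  t <- train + rnorm(length(train), sd = jitter_sd_s)
  sort(pmin(pmax(t, 0), duration_s))
}
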