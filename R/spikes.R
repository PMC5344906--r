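#' Detect spikes as upward threshold crossings
#'
#' A spike occurs each time the voltage crosses the threshold (default -15 mV)
#' from below; crossing times are linearly interpolated between samples. For a
#' simulated `hb_trajectory` whose threshold matches the one monitored during
#' integration, the full-resolution crossing times recorded by the integrator
#' are used, so the result does not depend on the recording stride. For any
#' other threshold, or for a plain data frame with columns `t` and `V`,
#' crossings are computed from the sampled trace.
#'
#' @param x an `hb_trajectory` or a data frame with numeric columns `t` (ms)
#'   and `V` (mV).
#' @param threshold crossing level in mV; `NULL` uses the trajectory's own
#'   spike threshold.
#' @return An `hb_spike_train`: list with `times` (ms, measured from the start
#'   of the recorded window), `threshold` and `duration` (ms).
#' @examples
#' wave <- data.frame(t = seq(0, 1000, by = 0.1))
#' wave$V <- -40 + 30 * sin(2 * pi * wave$t / 100)
#' detect_spikes(wave, threshold = -15)
#' @export
detect_spikes <- function(x, threshold = NULL) UseMethod("detect_spikes")

#' @export
detect_spikes.hb_trajectory <- function(x, threshold = NULL) {
  if (is.null(threshold) || isTRUE(threshold == x$threshold)) {
    new_spike_train(x$spike_times, x$threshold, x$duration)
  } else {
    tt <- upward_crossings(x$trace$t, x$trace$V, threshold)
    new_spike_train(tt - x$equilibration, threshold, x$duration)
  }
}

#' @export
detect_spikes.data.frame <- function(x, threshold = NULL) {
  stopifnot(all(c("t", "V") %in% names(x)))
  if (is.null(threshold)) threshold <- -15
  tt <- upward_crossings(x$t, x$V, threshold)
  new_spike_train(tt - x$t[1], threshold, diff(range(x$t)))
}

new_spike_train <- function(times, threshold, duration) {
  structure(list(times = as.numeric(times), threshold = threshold,
                 duration = duration),
            class = "hb_spike_train")
}

#' @export
print.hb_spike_train <- function(x, ...) {
  cat(sprintf("<hb_spike_train> %d spikes in %g ms (threshold %g mV, rate %.2f /s)\n",
              length(x$times), x$duration, x$threshold, firing_rate(x)))
  invisible(x)
}

# interpolated upward crossings of a sampled series
upward_crossings <- function(t, v, threshold) {
  n <- length(v)
  if (n < 2) return(numeric(0))
  below <- v[-n] < threshold & v[-1] >= threshold
  i <- which(below)
  t[i] + (t[i + 1] - t[i]) * (threshold - v[i]) / (v[i + 1] - v[i])
}

#' Inter-spike intervals
#'
#' Successive differences of the spike times, in ms. A train with fewer than
#' two spikes yields an empty series.
#'
#' @param train an `hb_spike_train`, or a numeric vector of spike times.
#' @return Numeric vector of positive intervals (length `n_spikes - 1`).
#' @export
isi <- function(train) {
  times <- if (inherits(train, "hb_spike_train")) train$times else as.numeric(train)
  if (length(times) < 2) return(numeric(0))
  diff(times)
}

#' Mean firing rate in spikes per second
#'
#' @param train an `hb_spike_train`.
#' @return Spikes per second over the train's source duration.
#' @export
firing_rate <- function(train) {
  stopifnot(inherits(train, "hb_spike_train"))
  if (train$duration <= 0) return(NA_real_)
  1000 * length(train$times) / train$duration
}

#' Classify the firing pattern of a simulated trajectory
#'
#' Assigns one of seven integer codes describing the firing regime:
#' \describe{
#'   \item{0}{silent, no oscillations (peak-to-peak V of the last 10 s < 2 mV)}
#'   \item{1}{sub-threshold oscillations without (sustained) spikes}
#'   \item{2}{oscillations and spikes with skipping / polymodal firing}
#'   \item{3}{regular tonic spiking (ISI coefficient of variation < 0.05)}
#'   \item{4}{burst firing; `spikes_per_burst` reports the modal burst size}
#'   \item{5}{tonic with firing rate in (20, 50] spikes/s}
#'   \item{6}{firing rate above 50 spikes/s}
#' }
#' The rate cutoffs for codes 5 and 6 are exact. Among slower trains, tonic
#' firing is a near-constant ISI; otherwise intervals are split at the
#' geometric mean of the extreme ISIs into intra-burst intervals and long
#' gaps. The train is called bursting when the intra-burst intervals are short
#' (median < 100 ms), bursts carry at least two spikes on average, and the
#' spikes-per-burst count is near-constant (>= 90% of bursts within +/- 1 of
#' the mode); irregular structure is classified as skipping (code 2).
#'
#' @param trajectory an `hb_trajectory` covering at least 30 s of recorded
#'   activity.
#' @param train optional pre-computed spike train (defaults to
#'   [detect_spikes()] on the trajectory).
#' @return One-row tibble with `code` (integer), `spikes_per_burst` (modal
#'   count, `NA` unless code 4) and `rate` (spikes/s).
#' @export
classify_pattern <- function(trajectory, train = NULL) {
  stopifnot(inherits(trajectory, "hb_trajectory"))
  if (trajectory$duration < 30000)
    stop("pattern classification needs at least 30 s of recorded activity",
         call. = FALSE)
  if (is.null(train)) train <- detect_spikes(trajectory)
  rate <- firing_rate(train)
  out <- function(code, spb = NA_integer_)
    tibble::tibble(code = as.integer(code), spikes_per_burst = as.integer(spb),
                   rate = rate)

  if (length(train$times) < 3) {
    tr <- trajectory$trace
    last10 <- tr$V[tr$t >= max(tr$t) - 10000]
    return(out(if (diff(range(last10)) < 2) 0L else 1L))
  }
  if (rate > 50) return(out(6L))
  if (rate > 20) return(out(5L))

  iv <- isi(train)
  if (stats::sd(iv) / mean(iv) < 0.05) return(out(3L))

  gap <- sqrt(max(iv) * min(iv))
  long <- iv > gap
  if (!any(long)) return(out(2L))  # irregular but unimodal-spread intervals
  if (all(long)) return(out(2L))

  # bursts: runs of spikes separated by long intervals
  spb <- diff(c(0, which(long), length(iv) + 1))  # spike counts per burst
  mode_spb <- as.integer(names(which.max(table(spb))))
  regular <- mean(abs(spb - mode_spb) <= 1) >= 0.9
  short_ok <- stats::median(iv[!long]) < 100
  bursty <- mean(spb) >= 2
  if (short_ok && bursty && regular) out(4L, mode_spb) else out(2L)
}
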