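# Continuous recordings: container, band-pass filtering, artifact rejection.

#' Construct a raw recording
#'
#' A raw recording is a single continuous signal in nanovolts sampled at a
#' fixed rate, optionally split into acquisition periods (the instrument
#' records several periods of roughly 30 s with rests in between; filtering
#' and artifact rejection operate per period).
#'
#' @param samples Numeric vector of samples in nV; must be finite.
#' @param sampling_rate Sampling rate in Hz.
#' @param period_starts Integer vector of 1-based sample indices starting
#'   each acquisition period; defaults to a single period covering the whole
#'   signal. Must begin at 1 and be strictly increasing.
#'
#' @return An object of class `"raw_recording"`: a list with elements
#'   `samples`, `sampling_rate`, `period_starts`.
#' @export
raw_recording <- function(samples, sampling_rate, period_starts = 1L) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L || any(!is.finite(samples))) {
    stop("`samples` must be a non-empty finite numeric vector.", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("`sampling_rate` must be positive.", call. = FALSE)
  }
  period_starts <- as.integer(period_starts)
  if (period_starts[1] != 1L || is.unsorted(period_starts, strictly = TRUE) ||
      any(period_starts > length(samples))) {
    stop("`period_starts` must start at 1, be strictly increasing and lie ",
         "within the signal.", call. = FALSE)
  }
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 period_starts = period_starts),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat("raw recording:", length(x$samples), "samples @", x$sampling_rate, "Hz |",
      length(x$period_starts), "acquisition period(s)\n")
  invisible(x)
}

.period_index <- function(rec) {
  bounds <- c(rec$period_starts, length(rec$samples) + 1L)
  rep(seq_along(rec$period_starts), diff(bounds))
}

#' Band-pass filter a recording
#'
#' Applies a Butterworth band-pass (default 3-100 Hz, order 2) to each
#' acquisition period independently, by default as a zero-phase
#' forward-backward pass so that the trough latency of the response is not
#' shifted by the filter's phase delay. Filtering per period avoids boundary
#' transients bleeding across the rests between periods.
#'
#' @param rec A [raw_recording()].
#' @param low_cut,high_cut Band edges in Hz; must satisfy
#'   `0 < low_cut < high_cut < sampling_rate / 2`.
#' @param order Butterworth prototype order (default 2).
#' @param zero_phase Use forward-backward (`signal::filtfilt`) filtering;
#'   if `FALSE` a single causal pass is used.
#'
#' @return A new `"raw_recording"` with the same length and sampling rate.
#' @export
bandpass_filter <- function(rec, low_cut = 3, high_cut = 100, order = 2L,
                            zero_phase = TRUE) {
  stopifnot(inherits(rec, "raw_recording"))
  ny <- rec$sampling_rate / 2
  if (!(low_cut > 0 && low_cut < high_cut && high_cut < ny)) {
    stop("Need 0 < low_cut < high_cut < sampling_rate/2 (Nyquist); got band ",
         low_cut, "-", high_cut, " Hz at ", rec$sampling_rate, " Hz.",
         call. = FALSE)
  }
  bf <- signal::butter(order, c(low_cut, high_cut) / ny, type = "pass")
  # pad long enough for the slow low-cut transient (time constant
  # ~ fs / (2 pi low_cut)) to die out inside the padding
  pad <- ceiling(5 * rec$sampling_rate / low_cut)
  idx <- .period_index(rec)
  filtered <- unlist(lapply(split(rec$samples, idx), function(x) {
    if (zero_phase) .zero_phase_filter(bf, x, pad) else signal::filter(bf, x)
  }), use.names = FALSE)
  raw_recording(filtered, rec$sampling_rate, rec$period_starts)
}

# Zero-phase filtering with odd-reflection padding at both ends, which
# suppresses the start-up transients of a plain forward-backward pass (DC
# and slow trends are continued anti-symmetrically, so a constant input
# yields an essentially zero output everywhere).
.zero_phase_filter <- function(bf, x, pad) {
  n <- length(x)
  p <- min(n - 1L, pad)
  if (p < 1L) return(signal::filtfilt(bf, x))
  front <- 2 * x[1] - x[(p + 1L):2L]
  back <- 2 * x[n] - x[(n - 1L):(n - p)]
  y <- signal::filtfilt(bf, c(front, x, back))
  y[(p + 1L):(p + n)]
}

#' Reject artifact-contaminated acquisition periods
#'
#' Any acquisition period containing a sample whose absolute value exceeds
#' `threshold` is dropped in full; the remaining periods are concatenated and
#' re-indexed. The default threshold of 1000 nV is an order of magnitude
#' above the physiological signal on the synthetic scale.
#'
#' @param rec A [raw_recording()].
#' @param threshold Absolute rejection threshold in nV (> 0).
#'
#' @return A list of class `"artifact_rejection"` with elements
#'   `recording` (the cleaned [raw_recording()]) and `report` (a tibble with
#'   one row per original period: `period`, `n_samples`, `max_abs`,
#'   `rejected`).
#' @export
reject_artifacts <- function(rec, threshold = 1000) {
  stopifnot(inherits(rec, "raw_recording"))
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("`threshold` must be a positive voltage in nV.", call. = FALSE)
  }
  idx <- .period_index(rec)
  pieces <- unname(split(rec$samples, idx))
  max_abs <- vapply(pieces, function(x) max(abs(x)), numeric(1))
  rejected <- max_abs > threshold
  report <- tibble::tibble(
    period = seq_along(pieces),
    n_samples = lengths(pieces),
    max_abs = max_abs,
    rejected = rejected
  )
  if (all(rejected)) {
    stop("All ", length(pieces), " acquisition periods exceed the ",
         threshold, " nV artifact threshold; no data left.", call. = FALSE)
  }
  kept <- pieces[!rejected]
  starts <- cumsum(c(1L, utils::head(lengths(kept), -1L)))
  structure(
    list(recording = raw_recording(unlist(kept, use.names = FALSE),
                                   rec$sampling_rate, starts),
         report = report),
    class = "artifact_rejection"
  )
}

#' @export
print.artifact_rejection <- function(x, ...) {
  n_rej <- sum(x$report$rejected)
  cat("artifact rejection:", n_rej, "of", nrow(x$report),
      "acquisition period(s) dropped\n")
  invisible(x)
}
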