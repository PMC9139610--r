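# First-order kernel extraction by m-sequence cross-correlation, and the
# inverse operation: forward synthesis of a continuous recording from known
# per-segment kernels.

# A kernel set is a numeric matrix with one column per segment and one row
# per epoch sample, in nV/deg^2, with attributes `time_ms` (epoch time base,
# ms relative to local stimulus onset) and `sampling_rate` (Hz).
.kernel_set <- function(values, time_ms, sampling_rate) {
  dimnames(values) <- list(NULL, paste0("seg", formatC(seq_len(ncol(values)) - 1L,
                                                       width = 2, flag = "0")))
  structure(values, time_ms = time_ms, sampling_rate = sampling_rate,
            class = c("kernel_set", "matrix", "array"))
}

#' @export
print.kernel_set <- function(x, ...) {
  t <- attr(x, "time_ms")
  cat("kernel set:", ncol(x), "segments |", nrow(x), "samples @",
      attr(x, "sampling_rate"), "Hz | epoch", t[1], "to", t[length(t)], "ms\n")
  invisible(x)
}

#' Epoch time base for a kernel set
#'
#' @param epoch_ms Length-2 epoch window in ms relative to stimulus onset.
#' @param sampling_rate Sampling rate in Hz.
#' @return Numeric vector of sample times in ms.
#' @export
kernel_time_base <- function(epoch_ms = c(-20, 120), sampling_rate = 1000) {
  if (length(epoch_ms) != 2L || epoch_ms[1] >= epoch_ms[2]) {
    stop("`epoch_ms` must be an increasing length-2 window.", call. = FALSE)
  }
  if (epoch_ms[1] > 0 || epoch_ms[2] < 90) {
    stop("The kernel epoch must cover at least 0-90 ms so the trough search ",
         "window fits.", call. = FALSE)
  }
  step <- 1000 / sampling_rate
  seq(epoch_ms[1], epoch_ms[2], by = step)
}

#' Tidy a kernel set into a long tibble
#'
#' @param kernels A kernel-set matrix.
#' @return Tibble with columns `segment_id`, `time_ms`, `amplitude`.
#' @export
kernel_tidy <- function(kernels) {
  time_ms <- attr(kernels, "time_ms")
  tibble::tibble(
    segment_id = rep(seq_len(ncol(kernels)) - 1L, each = nrow(kernels)),
    time_ms = rep(time_ms, ncol(kernels)),
    amplitude = as.vector(unclass(kernels))
  )
}

# Frame onset sample indices (0-based) for M frames at `spf` samples/frame.
.frame_onsets <- function(n_frames, spf) round((seq_len(n_frames) - 1L) * spf)

#' Synthesize a continuous recording from per-segment kernels
#'
#' Builds the forward model of multifocal stimulation: every segment
#' contributes its kernel waveform, scaled by its area (so the continuous
#' signal is in nV while kernels are densities in nV/deg^2), at every frame
#' onset, signed by its +/-1 stimulation schedule. The recording spans an
#' integer number of m-sequence cycles and is circular: contributions beyond
#' the end wrap to the beginning, which makes the noise-free
#' synthesis-extraction round trip exact up to the m-sequence's residual
#' autocorrelation.
#'
#' @param kernels Kernel-set matrix (see [extract_first_order_kernels()] for
#'   the layout), one column per segment, in nV/deg^2.
#' @param sequences Schedule matrix from [derive_segment_sequences()] with
#'   the same number of columns.
#' @param segment_areas Segment areas in deg^2 (one per column).
#' @param base_rate Stimulation frame rate in Hz (default 7).
#' @param sampling_rate Output sampling rate in Hz; defaults to the kernels'.
#' @param n_cycles Number of m-sequence cycles to synthesize.
#' @param noise_sd Optional additive white-noise SD in nV (0 for noise-free).
#'
#' @return A [raw_recording()] of `round(cycles * L * sampling_rate /
#'   base_rate)` samples, a single acquisition period.
#' @export
synthesize_raw_recording <- function(kernels, sequences, segment_areas,
                                     base_rate = 7, sampling_rate = NULL,
                                     n_cycles = 1L, noise_sd = 0) {
  if (ncol(kernels) != ncol(sequences)) {
    stop("`kernels` has ", ncol(kernels), " segments but `sequences` has ",
         ncol(sequences), ".", call. = FALSE)
  }
  if (length(segment_areas) != ncol(kernels)) {
    stop("`segment_areas` must have one area per segment.", call. = FALSE)
  }
  if (is.null(sampling_rate)) sampling_rate <- attr(kernels, "sampling_rate")
  time_ms <- attr(kernels, "time_ms")
  lag_samples <- round(time_ms * sampling_rate / 1000)
  spf <- sampling_rate / base_rate
  L <- nrow(sequences)
  M <- L * n_cycles
  N <- round(M * spf)
  onsets <- .frame_onsets(M, spf)
  sched_idx <- ((seq_len(M) - 1L) %% L) + 1L

  rec <- numeric(N)
  for (k in seq_len(ncol(kernels))) {
    s <- sequences[sched_idx, k] * segment_areas[k]
    pos <- (rep(onsets, each = length(lag_samples)) +
              rep(lag_samples, times = M)) %% N + 1L
    vals <- rep(s, each = length(lag_samples)) * rep(kernels[, k], times = M)
    rec[pos] <- rec[pos] + vals
  }
  if (noise_sd > 0) rec <- rec + stats::rnorm(N, sd = noise_sd)
  raw_recording(rec, sampling_rate)
}

#' Extract first-order kernels by cross-correlation
#'
#' For each segment, the first-order kernel at lag `t` is the average of the
#' recording over all frame onsets, signed by that segment's +/-1 schedule:
#' `kernel(t) = (1/M) * sum_j s(j) * r(t_j + t)`. Because distinct segments
#' follow circular shifts of one m-sequence, each segment's cross-correlation
#' isolates its own response up to the sequence's residual off-peak
#' autocorrelation of `-1/L` (`L` the sequence length), which leaks a scaled
#' copy of the summed response of all segments into every kernel. That bias
#' has a closed form -- every shifted m-sequence sums to +1, so the plain
#' average of the recording over frame onsets estimates the summed response
#' divided by `L` -- and is removed exactly:
#' `kernel_a = (raw_a + mean_response) / (1 + 1/L)`. The result is scaled to
#' response amplitude density (nV/deg^2) by dividing each segment's kernel
#' by its stimulated area.
#'
#' The recording is treated circularly over whole m-sequence cycles; it must
#' contain at least one full cycle at `base_rate`.
#'
#' @param rec A [raw_recording()] (typically filtered and artifact-cleaned).
#' @param sequences Schedule matrix from [derive_segment_sequences()].
#' @param segment_areas Segment areas in deg^2, one per schedule column.
#' @param base_rate Stimulation frame rate in Hz (default 7).
#' @param epoch_ms Kernel epoch window in ms (default `c(-20, 120)`; the
#'   pre-onset 20 ms provides the baseline estimate for the
#'   baseline-to-trough measure).
#'
#' @return A kernel-set matrix (`epoch samples x segments`, class
#'   `"kernel_set"`) in nV/deg^2 with attributes `time_ms` and
#'   `sampling_rate`.
#' @export
extract_first_order_kernels <- function(rec, sequences, segment_areas,
                                        base_rate = 7, epoch_ms = c(-20, 120)) {
  stopifnot(inherits(rec, "raw_recording"))
  if (length(segment_areas) != ncol(sequences)) {
    stop("`segment_areas` must have one area per segment.", call. = FALSE)
  }
  spf <- rec$sampling_rate / base_rate
  L <- nrow(sequences)
  n_cycles <- floor(length(rec$samples) / (L * spf) + 1e-9)
  if (n_cycles < 1L) {
    stop("Recording (", length(rec$samples), " samples) is shorter than one ",
         "full m-sequence cycle (", round(L * spf), " samples).", call. = FALSE)
  }
  M <- L * n_cycles
  N <- round(M * spf)
  r <- rec$samples[seq_len(N)]
  time_ms <- kernel_time_base(epoch_ms, rec$sampling_rate)
  lag_samples <- round(time_ms * rec$sampling_rate / 1000)
  onsets <- .frame_onsets(M, spf)
  sched_idx <- ((seq_len(M) - 1L) %% L) + 1L

  # R_lag[j, l] = r at frame onset j shifted by lag l (circular)
  R_lag <- vapply(lag_samples,
                  function(l) r[(onsets + l) %% N + 1L],
                  numeric(M))
  K <- crossprod(R_lag, sequences[sched_idx, , drop = FALSE]) / M
  # exact removal of the -1/L autocorrelation bias (see Details)
  mean_response <- colMeans(R_lag)
  K <- (K + mean_response) / (1 + 1 / L)
  K <- sweep(K, 2L, segment_areas, "/")
  .kernel_set(K, time_ms, rec$sampling_rate)
}
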