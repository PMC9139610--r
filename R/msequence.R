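# Maximum-length (m-)sequence generation and the per-segment stimulation
# schedule used for multifocal decorrelation.

#' Generate a maximal-length binary (m-)sequence
#'
#' Runs a Fibonacci linear-feedback shift register (LFSR) over GF(2) with the
#' given feedback taps and returns the +/-1-valued sequence of one full
#' period, `2^order - 1` steps. The default taps `{12, 6, 4, 1}` correspond
#' to a primitive polynomial of degree 12, giving the 4095-step sequence of a
#' 12-bit stimulation protocol.
#'
#' An m-sequence is balanced (counts of +1 and -1 differ by exactly one) and
#' has circular autocorrelation -1 at every nonzero lag, which is what makes
#' circularly shifted copies of one sequence effectively orthogonal
#' stimulation schedules for the 60 dartboard segments.
#'
#' @param order LFSR register length (sequence length is `2^order - 1`).
#' @param taps Integer feedback tap positions in `1..order`; must include
#'   `order` and correspond to a primitive polynomial. Non-primitive taps are
#'   detected at run time by their shortened period and rejected.
#' @param init Initial register state, a 0/1 vector of length `order`,
#'   not all zero. Defaults to `c(1, 0, 0, ...)`.
#'
#' @return An object of class `"msequence"`: a list with elements `order`,
#'   `taps`, `length` and `values` (integer vector of +1/-1).
#'
#' @examples
#' m <- generate_msequence(12)
#' m$length           # 4095
#' table(m$values)    # 2048 of one sign, 2047 of the other
#' @export
generate_msequence <- function(order = 12L, taps = NULL, init = NULL) {
  order <- as.integer(order)
  if (order < 2L) stop("`order` must be at least 2.", call. = FALSE)
  if (is.null(taps)) {
    taps <- switch(as.character(order),
      "2" = c(2L, 1L), "3" = c(3L, 2L), "4" = c(4L, 3L), "5" = c(5L, 3L),
      "6" = c(6L, 5L), "7" = c(7L, 6L), "8" = c(8L, 6L, 5L, 4L),
      "9" = c(9L, 5L), "10" = c(10L, 7L), "11" = c(11L, 9L),
      "12" = c(12L, 6L, 4L, 1L),
      stop("No default taps for order ", order, "; supply `taps`.", call. = FALSE))
  }
  taps <- sort(unique(as.integer(taps)), decreasing = TRUE)
  if (any(taps < 1L | taps > order)) {
    stop("Tap positions must lie in 1..order.", call. = FALSE)
  }
  if (taps[1] != order) {
    stop("Taps must include the register length `order`.", call. = FALSE)
  }
  if (is.null(init)) init <- c(1L, integer(order - 1L))
  init <- as.integer(init)
  if (length(init) != order || any(!init %in% c(0L, 1L)) || all(init == 0L)) {
    stop("`init` must be a nonzero 0/1 vector of length `order`.", call. = FALSE)
  }

  len <- 2L^order - 1L
  state <- init
  bits <- integer(len)
  pow2 <- 2^(seq_len(order) - 1L)
  init_id <- sum(init * pow2)
  for (i in seq_len(len)) {
    bits[i] <- state[order]
    fb <- sum(state[taps]) %% 2L
    state <- c(fb, state[-order])
    if (i < len && sum(state * pow2) == init_id) {
      stop("Taps are not primitive: register state repeated after ", i,
           " steps (period < 2^order - 1).", call. = FALSE)
    }
  }
  if (sum(state * pow2) != init_id) {
    stop("LFSR failed to return to its initial state; invalid taps.", call. = FALSE)
  }
  structure(
    list(order = order, taps = taps, length = len,
         values = ifelse(bits == 1L, 1L, -1L)),
    class = "msequence"
  )
}

#' @export
print.msequence <- function(x, ...) {
  cat("m-sequence: order", x$order, "| length", x$length,
      "| taps {", paste(x$taps, collapse = ", "), "}\n")
  invisible(x)
}

#' Circular autocorrelation of a +/-1 sequence
#'
#' Plain sum of elementwise products between the sequence and its circular
#' shift; for an m-sequence this equals the sequence length at lag 0 and -1
#' at every other lag.
#'
#' @param values Integer +/-1 vector.
#' @param lag Circular lag (any integer).
#' @return The autocorrelation sum (not normalised).
#' @export
circular_autocorrelation <- function(values, lag) {
  n <- length(values)
  lag <- lag %% n
  sum(values * values[((seq_len(n) - 1L + lag) %% n) + 1L])
}

#' Derive the per-segment stimulation schedule
#'
#' Each dartboard segment follows the same base m-sequence, circularly
#' shifted by a distinct multiple of `shift_step`. Because the base sequence
#' has two-valued autocorrelation, any two distinct shifts are mutually
#' near-orthogonal, so the first-order kernels of all segments can be pulled
#' apart from a single recording by cross-correlation.
#'
#' `shift_step` must exceed the kernel epoch length expressed in m-steps
#' (`epoch_steps`): otherwise the response evoked by one segment would leak
#' into the cross-correlation window of the next (cross-contamination).
#'
#' @param mseq An [generate_msequence()] object.
#' @param n_segments Number of segments (default 60).
#' @param shift_step Circular shift between consecutive segments, in m-steps.
#' @param epoch_steps Kernel epoch length in m-steps, i.e.
#'   `ceiling(epoch span / frame duration)`; with the default 140 ms epoch
#'   and the 7 Hz frame this is 1.
#'
#' @return An integer matrix of dimension `mseq$length x n_segments`; column
#'   `k` holds segment `k-1`'s +/-1 schedule. The shift of each column is in
#'   `attr(x, "shifts")`.
#'
#' @examples
#' m <- generate_msequence(12)
#' sched <- derive_segment_sequences(m, 60, 68)
#' attr(sched, "shifts")[1:4]
#' @export
derive_segment_sequences <- function(mseq, n_segments = 60L, shift_step = 68L,
                                     epoch_steps = 1L) {
  stopifnot(inherits(mseq, "msequence"))
  n_segments <- as.integer(n_segments)
  shift_step <- as.integer(shift_step)
  if (n_segments < 1L || shift_step < 1L) {
    stop("`n_segments` and `shift_step` must be positive.", call. = FALSE)
  }
  if (n_segments * shift_step > mseq$length) {
    stop("n_segments * shift_step exceeds the sequence length ", mseq$length,
         "; shifts would collide.", call. = FALSE)
  }
  if (shift_step <= epoch_steps) {
    stop("`shift_step` (", shift_step, ") must exceed the kernel epoch ",
         "length of ", epoch_steps, " m-step(s): responses of neighbouring ",
         "segments would cross-contaminate.", call. = FALSE)
  }
  n <- mseq$length
  shifts <- (seq_len(n_segments) - 1L) * shift_step
  idx0 <- seq_len(n) - 1L
  out <- vapply(shifts, function(s) mseq$values[((idx0 + s) %% n) + 1L],
                integer(n))
  dimnames(out) <- list(NULL, paste0("seg", formatC(seq_len(n_segments) - 1L,
                                                    width = 2, flag = "0")))
  attr(out, "shifts") <- shifts
  attr(out, "order") <- mseq$order
  out
}
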