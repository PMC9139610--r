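# Region-averaged response traces and the baseline-to-trough (BT) response
# amplitude density measure.

#' Measurement windows for the baseline-to-trough amplitude
#'
#' @param trough_window Trough search window in ms after stimulus onset
#'   (default 50-90 ms, the PhNR implicit-time range).
#' @param baseline_window Pre-stimulus window in ms whose mean defines the
#'   baseline (default -20-0 ms).
#' @return An object of class `"measurement_spec"`.
#' @export
measurement_spec <- function(trough_window = c(50, 90),
                             baseline_window = c(-20, 0)) {
  ok <- function(w) length(w) == 2L && w[1] < w[2]
  if (!ok(trough_window) || !ok(baseline_window)) {
    stop("Windows must be increasing length-2 intervals.", call. = FALSE)
  }
  if (baseline_window[2] > trough_window[1]) {
    stop("The baseline window must precede the trough window.", call. = FALSE)
  }
  structure(list(trough_window = trough_window,
                 baseline_window = baseline_window),
            class = "measurement_spec")
}

#' Area-weighted average trace of one region
#'
#' The regional response amplitude density is the area-weighted mean of the
#' member-segment density traces, `sum(area_i * k_i(t)) / sum(area_i)` --
#' equivalently the region's total response divided by its total stimulated
#' area, which keeps the density interpretation exact.
#'
#' @param kernels Kernel-set matrix (one column per segment).
#' @param map Region map from [assign_regions()], matching the kernel columns
#'   by `segment_id`.
#' @param region_label Region to average.
#' @return Numeric trace in nV/deg^2 on the kernels' time base.
#' @export
average_region_trace <- function(kernels, map, region_label) {
  members <- map$segment_id[!is.na(map$region_label) &
                              map$region_label == region_label]
  if (length(members) == 0L) {
    stop("Region ", region_label, " is empty or unknown.", call. = FALSE)
  }
  areas <- map$area[match(members, map$segment_id)]
  k <- unclass(kernels)[, members + 1L, drop = FALSE]
  as.vector(k %*% areas) / sum(areas)
}

#' Baseline-to-trough measurement of a density trace
#'
#' The response amplitude density (RAD) is the difference between the
#' pre-stimulus baseline (mean over the baseline window) and the most
#' negative point within the trough search window; it is positive when a
#' genuine trough exists. The trough is the sample minimum (no
#' interpolation); on ties the earliest sample wins.
#'
#' @param trace Numeric density trace in nV/deg^2.
#' @param time_ms Time base of `trace` in ms.
#' @param spec A [measurement_spec()].
#' @return One-row tibble with `rad` (nV/deg^2), `trough_time` (ms) and
#'   `baseline` (nV/deg^2).
#' @examples
#' t <- kernel_time_base()
#' w <- phnr_template(waveform_model(), t)
#' measure_baseline_to_trough(w, t)
#' @export
measure_baseline_to_trough <- function(trace, time_ms,
                                       spec = measurement_spec()) {
  stopifnot(length(trace) == length(time_ms))
  in_b <- time_ms >= spec$baseline_window[1] & time_ms <= spec$baseline_window[2]
  in_t <- time_ms >= spec$trough_window[1] & time_ms <= spec$trough_window[2]
  if (!any(in_b) || !any(in_t)) {
    stop("The trace's epoch does not cover the baseline and trough windows.",
         call. = FALSE)
  }
  baseline <- mean(trace[in_b])
  trough_idx <- which(in_t)[which.min(trace[in_t])]
  tibble::tibble(rad = baseline - trace[trough_idx],
                 trough_time = time_ms[trough_idx],
                 baseline = baseline)
}

#' Per-eye, per-region RAD table over the analysis topographies
#'
#' For every eye of the cohort and every region of every requested
#' topography, averages the member kernels (area-weighted) and measures the
#' baseline-to-trough RAD. Region maps respect each eye's laterality.
#'
#' @param cohort A [generate_cohort()] tibble (or any tibble with `eye_id`,
#'   `group`, `laterality` and a `kernels` list-column of kernel sets on a
#'   common time base).
#' @param schemes Topographies to measure (default all three).
#' @param segments Dartboard geometry; defaults to the cohort's.
#' @param measurement A [measurement_spec()].
#'
#' @return A tibble with columns `eye_id`, `group`, `scheme`, `region_label`,
#'   `rad` (nV/deg^2) and `trough_time` (ms): one row per eye x region
#'   (5 rings + 5 sectors + 9 ETDRS regions for the default schemes).
#' @export
build_rad_table <- function(cohort,
                            schemes = c("rings", "sectors", "etdrs"),
                            segments = NULL,
                            measurement = measurement_spec()) {
  if (nrow(cohort) == 0L) stop("The cohort is empty.", call. = FALSE)
  schemes <- match.arg(schemes, several.ok = TRUE)
  if (is.null(segments)) segments <- attr(cohort, "segments")
  if (is.null(segments)) segments <- build_dartboard()

  bases <- unique(lapply(cohort$kernels, function(k) attr(k, "time_ms")))
  if (length(bases) != 1L) {
    stop("All eyes must share one kernel time base.", call. = FALSE)
  }
  time_ms <- bases[[1]]
  in_b <- time_ms >= measurement$baseline_window[1] &
    time_ms <= measurement$baseline_window[2]
  in_t <- time_ms >= measurement$trough_window[1] &
    time_ms <= measurement$trough_window[2]
  if (!any(in_b) || !any(in_t)) {
    stop("Kernel epoch does not cover the measurement windows.", call. = FALSE)
  }
  t_idx <- which(in_t)

  maps <- list()
  for (sch in schemes) for (eye in unique(cohort$laterality)) {
    m <- assign_regions(segments, sch, eye)
    keep <- !is.na(m$region_label)
    # area-weight matrix: segments x regions, columns normalised
    labs <- sort(unique(m$region_label[keep]))
    W <- vapply(labs, function(l) {
      w <- ifelse(keep & m$region_label == l, m$area, 0)
      w / sum(w)
    }, numeric(nrow(m)))[order(m$segment_id), , drop = FALSE]
    maps[[paste(sch, eye)]] <- W
  }

  rows <- purrr::pmap(
    list(cohort$eye_id, cohort$group, cohort$laterality, cohort$kernels),
    function(eye_id, group, laterality, kernels) {
      purrr::map(schemes, function(sch) {
        W <- maps[[paste(sch, laterality)]]
        traces <- unclass(kernels) %*% W
        baseline <- colMeans(traces[in_b, , drop = FALSE])
        mins <- apply(traces[t_idx, , drop = FALSE], 2L, which.min)
        tibble::tibble(
          eye_id = eye_id, group = group, scheme = sch,
          region_label = colnames(W),
          rad = unname(baseline - traces[cbind(t_idx[mins], seq_along(mins))]),
          trough_time = unname(time_ms[t_idx[mins]])
        )
      }) |> dplyr::bind_rows()
    }
  )
  dplyr::bind_rows(rows)
}
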