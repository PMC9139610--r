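# Seeded synthetic cohort generator: two groups of eyes whose ring-averaged
# RADs are calibrated to published control and MS-ON group summaries.

# Published ring summaries of the reference cohort (25 control eyes, 20 eyes
# of multiple-sclerosis patients with prior optic neuritis), used as the
# default calibration of the generator. Means and SDs in nV/deg^2.
.ring_labels <- paste0("R", 1:5)
.control_ring_means <- stats::setNames(c(32.252, 14.928, 9.448, 5.840, 4.372), .ring_labels)
.control_ring_sds   <- stats::setNames(c(5.487, 3.734, 2.698, 1.941, 1.120), .ring_labels)
.mson_ring_means    <- stats::setNames(c(21.515, 9.63, 7.02, 4.31, 3.19), .ring_labels)
.mson_ring_sds      <- stats::setNames(c(5.402, 3.587, 2.233, 1.694, 0.865), .ring_labels)

#' Specification of a synthetic two-group cohort
#'
#' Defaults reproduce the reference study's conditions: 25 control eyes and
#' 20 case (MS with optic neuritis) eyes; control ring means equal to the
#' published control summaries; the case effect modelled as per-ring
#' multiplicative attenuation of the control profile (default: the published
#' case/control mean ratios); between-eye variability as per-ring additive
#' amplitude offsets with the published per-group SDs; and a small
#' band-limited trace noise on every kernel.
#'
#' @param n_control,n_case Eyes per group (each >= 2).
#' @param control_targets Named per-ring control mean RADs (nV/deg^2, > 0).
#' @param case_attenuation Named per-ring multiplicative factors in (0, 1].
#' @param control_between_sd,case_between_sd Named per-ring SDs (nV/deg^2,
#'   >= 0) of the additive between-eye amplitude offsets.
#' @param trace_noise_sd SD (nV/deg^2) of the band-limited noise added to
#'   each segment kernel (>= 0).
#' @param seed Integer seed; the full cohort is reproducible from it.
#' @param model A [waveform_model()].
#' @param sampling_rate Kernel sampling rate in Hz.
#' @param epoch_ms Kernel epoch window in ms.
#'
#' @return An object of class `"cohort_spec"` (named list).
#' @export
cohort_spec <- function(n_control = 25L, n_case = 20L,
                        control_targets = .control_ring_means,
                        case_attenuation = .mson_ring_means / .control_ring_means,
                        control_between_sd = .control_ring_sds,
                        case_between_sd = .mson_ring_sds,
                        trace_noise_sd = 0.5, seed = 1L,
                        model = waveform_model(),
                        sampling_rate = 1000, epoch_ms = c(-20, 120)) {
  if (n_control < 2L || n_case < 2L) {
    stop("Each group needs at least 2 eyes (group statistics are undefined ",
         "otherwise).", call. = FALSE)
  }
  if (any(control_targets <= 0)) stop("Control targets must be positive.", call. = FALSE)
  if (any(case_attenuation <= 0 | case_attenuation > 1)) {
    stop("`case_attenuation` factors must lie in (0, 1].", call. = FALSE)
  }
  if (any(control_between_sd < 0) || any(case_between_sd < 0) || trace_noise_sd < 0) {
    stop("Standard deviations must be non-negative.", call. = FALSE)
  }
  structure(
    list(n_control = as.integer(n_control), n_case = as.integer(n_case),
         control_targets = control_targets, case_attenuation = case_attenuation,
         control_between_sd = control_between_sd,
         case_between_sd = case_between_sd,
         trace_noise_sd = trace_noise_sd, seed = as.integer(seed),
         model = model, sampling_rate = sampling_rate, epoch_ms = epoch_ms),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("cohort spec:", x$n_control, "control +", x$n_case, "case eyes | seed",
      x$seed, "| trace noise", x$trace_noise_sd, "nV/deg2\n")
  invisible(x)
}

# Cached RMS gain of the zero-phase band-pass applied to unit white noise on
# an n-sample window, so generated trace noise has the requested post-filter
# SD. Computed exactly (and without touching the RNG) from the filter's
# action on the n unit basis vectors: for white input the expected mean
# square of the output is the mean row norm^2 of the linear operator.
.noise_gain_cache <- new.env(parent = emptyenv())
.bandlimited_gain <- function(sampling_rate, n, low = 3, high = 100) {
  key <- paste(sampling_rate, n, low, high)
  if (is.null(.noise_gain_cache[[key]])) {
    bf <- signal::butter(2, c(low, high) / (sampling_rate / 2), type = "pass")
    A <- vapply(seq_len(n), function(j) {
      e <- numeric(n); e[j] <- 1
      signal::filtfilt(bf, e)
    }, numeric(n))
    .noise_gain_cache[[key]] <- sqrt(mean(rowSums(A^2)))
  }
  .noise_gain_cache[[key]]
}

# Band-limited Gaussian noise matrix (n x k) with post-filter SD `sd`.
.bandlimited_noise <- function(n, k, sd, sampling_rate) {
  if (sd == 0) return(matrix(0, n, k))
  bf <- signal::butter(2, c(3, 100) / (sampling_rate / 2), type = "pass")
  gain <- .bandlimited_gain(sampling_rate, n)
  raw <- matrix(stats::rnorm(n * k), n, k)
  apply(raw, 2L, function(x) signal::filtfilt(bf, x)) * (sd / gain)
}

#' Generate one synthetic eye
#'
#' Each segment's kernel is the waveform template scaled by its ring's
#' calibrated factor -- shifted by the eye's per-ring amplitude offset --
#' plus band-limited (3-100 Hz) Gaussian trace noise. Uses R's global random
#' number generator; seed externally (or via [generate_cohort()]) for
#' reproducibility.
#'
#' @param profile An [calibrate_profile()] eccentricity profile.
#' @param model A [waveform_model()].
#' @param trace_noise_sd Post-filter noise SD in nV/deg^2 (>= 0).
#' @param eye_offsets Named per-ring additive RAD offsets in nV/deg^2
#'   (default all zero).
#' @param ring_map Ring region map matching `profile`.
#' @param time_ms Epoch time base.
#'
#' @return A kernel-set matrix (one column per segment).
#' @export
generate_eye <- function(profile, model = waveform_model(),
                         trace_noise_sd = 0,
                         eye_offsets = NULL,
                         ring_map = assign_regions(build_dartboard(), "rings"),
                         time_ms = kernel_time_base()) {
  stopifnot(inherits(profile, "ecc_profile"))
  if (trace_noise_sd < 0) stop("`trace_noise_sd` must be >= 0.", call. = FALSE)
  if (is.null(eye_offsets)) {
    eye_offsets <- stats::setNames(numeric(nrow(profile)), profile$region_label)
  }
  template <- phnr_template(model, time_ms)
  unit_bt <- attr(profile, "unit_bt")
  seg_ring <- ring_map$region_label[order(ring_map$segment_id)]
  effective <- (profile$target[match(seg_ring, profile$region_label)] +
                  eye_offsets[seg_ring]) / unit_bt
  sampling_rate <- round(1000 / diff(time_ms[1:2]))
  K <- outer(template, unname(effective)) +
    .bandlimited_noise(length(time_ms), length(seg_ring), trace_noise_sd,
                       sampling_rate)
  .kernel_set(K, time_ms, sampling_rate)
}

#' Generate a seeded two-group cohort of synthetic eyes
#'
#' Control eyes follow the calibrated control eccentricity profile; case
#' eyes follow the control profile attenuated ring-wise. Per-eye amplitude
#' offsets are drawn from centred normals with the group's per-ring SDs,
#' and every kernel receives band-limited trace noise. The whole cohort is a
#' deterministic function of `spec` (including its seed).
#'
#' @param spec A [cohort_spec()].
#' @param segments Dartboard from [build_dartboard()].
#'
#' @return A tibble of class `"phnr_cohort"`: columns `eye_id`, `group`
#'   (`"control"`/`"case"`), `laterality` (`"right"`/`"left"`, alternating)
#'   and `kernels` (list-column of kernel-set matrices). Attributes: `spec`,
#'   `segments`, `time_ms`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_control = 3, n_case = 2))
#' nrow(cohort)
#' @export
generate_cohort <- function(spec = cohort_spec(), segments = build_dartboard()) {
  stopifnot(inherits(spec, "cohort_spec"))
  time_ms <- kernel_time_base(spec$epoch_ms, spec$sampling_rate)
  ring_map <- assign_regions(segments, "rings")
  control_profile <- calibrate_profile(spec$control_targets, spec$model,
                                       ring_map, time_ms)
  case_targets <- spec$control_targets *
    spec$case_attenuation[names(spec$control_targets)]
  case_profile <- calibrate_profile(case_targets, spec$model, ring_map, time_ms)

  n_total <- spec$n_control + spec$n_case
  group <- rep(c("control", "case"), c(spec$n_control, spec$n_case))
  rings <- names(spec$control_targets)

  kernels <- withr::with_seed(spec$seed, {
    lapply(seq_len(n_total), function(i) {
      ctl <- group[i] == "control"
      sds <- if (ctl) spec$control_between_sd else spec$case_between_sd
      offsets <- stats::setNames(stats::rnorm(length(rings), 0, sds[rings]), rings)
      generate_eye(if (ctl) control_profile else case_profile,
                   model = spec$model, trace_noise_sd = spec$trace_noise_sd,
                   eye_offsets = offsets, ring_map = ring_map,
                   time_ms = time_ms)
    })
  })

  out <- tibble::tibble(
    eye_id = sprintf("%s%02d", ifelse(group == "control", "C", "M"),
                     c(seq_len(spec$n_control), seq_len(spec$n_case))),
    group = group,
    laterality = rep_len(c("right", "left"), n_total),
    kernels = kernels
  )
  attr(out, "spec") <- spec
  attr(out, "segments") <- segments
  attr(out, "time_ms") <- time_ms
  class(out) <- c("phnr_cohort", class(out))
  out
}
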