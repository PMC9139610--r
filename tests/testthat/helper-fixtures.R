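# Shared fixtures built in code.

default_segments <- build_dartboard()
default_time <- kernel_time_base()

# a small single-eye cohort tibble around one kernel set
one_eye_cohort <- function(kernels, group = "control", laterality = "right",
                           segments = default_segments) {
  out <- tibble::tibble(eye_id = "E01", group = group,
                        laterality = laterality, kernels = list(kernels))
  attr(out, "segments") <- segments
  class(out) <- c("phnr_cohort", class(out))
  out
}

# noise-free eye calibrated to the published control ring means
control_targets <- c(R1 = 32.252, R2 = 14.928, R3 = 9.448, R4 = 5.840,
                     R5 = 4.372)
calibrated_profile <- calibrate_profile(control_targets)

# small stimulation fixture: order-8 m-sequence, 12 segments
small_mseq <- generate_msequence(8)
small_sched <- derive_segment_sequences(small_mseq, 12, 20)
small_areas <- seq(2, 24, by = 2)

as_kernel_set <- function(values, time_ms = default_time, rate = 1000) {
  mfphnr:::.kernel_set(values, time_ms, rate)
}
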