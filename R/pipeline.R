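# End-to-end study workflow and plain-text I/O for kernels and cohorts.

#' Full study configuration
#'
#' Bundles the cohort, stimulation, filtering and measurement parameters of
#' one simulated study run.
#'
#' @param cohort A [cohort_spec()].
#' @param schemes Topographies to analyse.
#' @param use_raw_synthesis If `TRUE`, each eye's kernels are additionally
#'   pushed through the full forward model: a continuous recording is
#'   synthesized from the eye's kernels and the m-sequence schedule, and the
#'   kernels are re-extracted by cross-correlation before measurement. This
#'   exercises the whole acquisition chain; the default (`FALSE`) measures
#'   the generated kernels directly.
#' @param msequence_order,shift_step m-sequence stimulation parameters used
#'   when `use_raw_synthesis = TRUE`.
#' @param base_rate Stimulation frame rate in Hz.
#' @param measurement A [measurement_spec()].
#' @param out_dir Optional output directory: when given, [run_study()]
#'   writes the RAD table and the comparison tables as CSV plus a JSON
#'   report there.
#' @return An object of class `"study_config"`.
#' @export
study_config <- function(cohort = cohort_spec(),
                         schemes = c("rings", "sectors", "etdrs"),
                         use_raw_synthesis = FALSE,
                         msequence_order = 12L, shift_step = 68L,
                         base_rate = 7,
                         measurement = measurement_spec(),
                         out_dir = NULL) {
  schemes <- match.arg(schemes, several.ok = TRUE)
  structure(list(cohort = cohort, schemes = schemes,
                 use_raw_synthesis = use_raw_synthesis,
                 msequence_order = as.integer(msequence_order),
                 shift_step = as.integer(shift_step),
                 base_rate = base_rate, measurement = measurement,
                 out_dir = out_dir),
            class = "study_config")
}

#' Run a complete simulated mfPhNR study
#'
#' Generates the seeded cohort, (optionally) round-trips every eye through
#' raw-recording synthesis and kernel re-extraction, measures the per-eye
#' per-region RAD table, and produces the between-group and within-group
#' comparison tables and the eccentricity fits for each requested
#' topography. Identical configurations (including the seed) give identical
#' results.
#'
#' @param config A [study_config()].
#' @return A list of class `"phnr_study"`: `config`, `cohort` (eye metadata
#'   only), `rad_table`, `between` (named list of tibbles per scheme),
#'   `within` (nested per scheme and group), `fits` (per scheme/group), and
#'   `timings` (stage wall-clock seconds).
#' @examples
#' \donttest{
#' res <- run_study(study_config(cohort_spec(n_control = 4, n_case = 4)))
#' res$between$rings
#' }
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  timings <- c()
  tic <- function() Sys.time()
  toc <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))

  t0 <- tic()
  segments <- build_dartboard()
  cohort <- generate_cohort(config$cohort, segments)
  timings["simulate"] <- toc(t0)

  if (config$use_raw_synthesis) {
    t0 <- tic()
    mseq <- generate_msequence(config$msequence_order)
    sched <- derive_segment_sequences(mseq, nrow(segments), config$shift_step)
    cohort$kernels <- lapply(cohort$kernels, function(k) {
      rec <- synthesize_raw_recording(k, sched, segments$area,
                                      base_rate = config$base_rate,
                                      sampling_rate = attr(k, "sampling_rate"))
      time_ms <- attr(k, "time_ms")
      extract_first_order_kernels(rec, sched, segments$area,
                                  base_rate = config$base_rate,
                                  epoch_ms = range(time_ms))
    })
    timings["raw_roundtrip"] <- toc(t0)
  }

  t0 <- tic()
  rad <- build_rad_table(cohort, config$schemes, segments, config$measurement)
  timings["measure"] <- toc(t0)

  t0 <- tic()
  between <- lapply(stats::setNames(config$schemes, config$schemes),
                    function(s) between_group_table(rad, s))
  within <- lapply(stats::setNames(config$schemes, config$schemes), function(s) {
    lapply(c(control = "control", case = "case"),
           function(g) within_group_table(rad, s, g))
  })
  fits <- lapply(stats::setNames(config$schemes, config$schemes), function(s) {
    summ <- .rad_to_summaries(rad, s)
    lapply(c(control = "control", case = "case"), function(g) {
      if (s == "rings") {
        list(exponential = exponential_fit_r2(region_means(summ, s, g)))
      } else if (s == "sectors") {
        list(linear = linear_fit_r2(region_means(summ, s, g)))
      } else {
        list(`linear 5-10` = linear_fit_r2(region_means(summ, s, g, "5-10")),
             `linear 10-20` = linear_fit_r2(region_means(summ, s, g, "10-20")))
      }
    })
  })
  timings["stats"] <- toc(t0)

  out <- structure(
    list(config = config,
         cohort = dplyr::select(tibble::as_tibble(cohort), -"kernels"),
         rad_table = rad, between = between, within = within, fits = fits,
         timings = timings),
    class = "phnr_study"
  )
  if (!is.null(config$out_dir)) .write_study(out, config$out_dir)
  out
}

.write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(study$rad_table, file.path(out_dir, "rad_table.csv"))
  for (s in names(study$between)) {
    readr::write_csv(study$between[[s]],
                     file.path(out_dir, paste0("between_", s, ".csv")))
    for (g in names(study$within[[s]])) {
      readr::write_csv(study$within[[s]][[g]],
                       file.path(out_dir, paste0("within_", s, "_", g, ".csv")))
    }
  }
  report <- list(
    seed = study$config$cohort$seed,
    n_control = study$config$cohort$n_control,
    n_case = study$config$cohort$n_case,
    schemes = study$config$schemes,
    use_raw_synthesis = study$config$use_raw_synthesis,
    timings_sec = as.list(round(study$timings, 3)),
    fits = lapply(study$fits, function(by_group) {
      lapply(by_group, function(fl) {
        lapply(fl, function(f) list(kind = f$kind, r_squared = f$r_squared,
                                    params = as.list(f$params)))
      })
    })
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.phnr_study <- function(x, ...) {
  cat("mfPhNR study:", nrow(x$cohort), "eyes |",
      paste(x$config$schemes, collapse = "/"), "|",
      if (x$config$use_raw_synthesis) "raw-synthesis path" else "kernels-direct path",
      "| seed", x$config$cohort$seed, "\n")
  invisible(x)
}

# ---- kernel CSV dialect ----------------------------------------------------
# Header comment lines `# key=value` (sampling_rate_hz, units, eye metadata),
# then a CSV table: time_ms plus one column per segment (seg00..seg59).

#' Write / read an eye's kernel set in the documented CSV dialect
#'
#' The file starts with `# key=value` header lines (at least
#' `sampling_rate_hz` and `units`; eye metadata when available), followed by
#' a plain CSV table with a `time_ms` column and one `segNN` column per
#' segment. Values are written with 9 significant digits, so a write/read
#' round trip reproduces the kernels to ~1e-9 relative.
#'
#' @param kernels A kernel-set matrix.
#' @param path File path.
#' @param eye_id,group,laterality Optional eye metadata stored in the header.
#' @return `write_kernel_csv()` returns `path` invisibly; `read_kernel_csv()`
#'   returns the kernel-set matrix with metadata in attributes.
#' @export
write_kernel_csv <- function(kernels, path, eye_id = NULL, group = NULL,
                             laterality = NULL) {
  header <- c(
    paste0("# sampling_rate_hz=", attr(kernels, "sampling_rate")),
    "# units=nV/deg2",
    if (!is.null(eye_id)) paste0("# eye_id=", eye_id),
    if (!is.null(group)) paste0("# group=", group),
    if (!is.null(laterality)) paste0("# laterality=", laterality)
  )
  df <- cbind(time_ms = attr(kernels, "time_ms"),
              as.data.frame(unclass(kernels)))
  body <- c(paste(colnames(df), collapse = ","),
            apply(format(df, digits = 9, scientific = FALSE, trim = TRUE),
                  1L, paste, collapse = ","))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_kernel_csv
#' @param n_segments Expected number of segment columns (default 60).
#' @export
read_kernel_csv <- function(path, n_segments = 60L) {
  lines <- readLines(path)
  is_header <- grepl("^#", lines)
  header <- lines[is_header]
  kv <- sub("^#\\s*", "", header)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  meta <- stats::setNames(as.list(vals), keys)
  if (!"sampling_rate_hz" %in% keys) {
    stop("Kernel CSV header lacks `sampling_rate_hz` (line ",
         sum(is_header) + 1L, " starts the table).", call. = FALSE)
  }
  body <- utils::read.csv(text = lines[!is_header], check.names = FALSE)
  if (!"time_ms" %in% names(body)) {
    stop("Kernel CSV table lacks the `time_ms` column.", call. = FALSE)
  }
  seg_cols <- setdiff(names(body), "time_ms")
  expected <- paste0("seg", formatC(seq_len(n_segments) - 1L, width = 2, flag = "0"))
  missing <- setdiff(expected, seg_cols)
  if (length(missing) > 0L) {
    stop("Kernel CSV is missing segment column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  k <- as.matrix(body[expected])
  out <- .kernel_set(k, body$time_ms, as.numeric(meta$sampling_rate_hz))
  for (key in setdiff(keys, c("sampling_rate_hz", "units"))) {
    attr(out, key) <- meta[[key]]
  }
  out
}

#' Write / read a whole cohort as a directory of kernel CSVs
#'
#' One kernel CSV per eye plus a `manifest.json` echoing the cohort
#' specification, the seed and the file list.
#'
#' @param cohort A [generate_cohort()] tibble.
#' @param dir Directory (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` returns
#'   a cohort tibble (without the generating spec attached).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("%s.csv", cohort$eye_id)
  purrr::pwalk(list(cohort$eye_id, cohort$group, cohort$laterality,
                    cohort$kernels, files),
               function(eye_id, group, laterality, kernels, file) {
                 write_kernel_csv(kernels, file.path(dir, file),
                                  eye_id = eye_id, group = group,
                                  laterality = laterality)
               })
  spec <- attr(cohort, "spec")
  manifest <- list(
    n_control = spec$n_control, n_case = spec$n_case, seed = spec$seed,
    trace_noise_sd = spec$trace_noise_sd,
    control_targets = as.list(spec$control_targets),
    case_attenuation = as.list(spec$case_attenuation),
    control_between_sd = as.list(spec$control_between_sd),
    case_between_sd = as.list(spec$case_between_sd),
    files = files
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  kernels <- lapply(manifest$files, function(f) read_kernel_csv(file.path(dir, f)))
  out <- tibble::tibble(
    eye_id = vapply(kernels, attr, "", "eye_id"),
    group = vapply(kernels, attr, "", "group"),
    laterality = vapply(kernels, attr, "", "laterality"),
    kernels = kernels
  )
  attr(out, "time_ms") <- attr(kernels[[1]], "time_ms")
  class(out) <- c("phnr_cohort", class(out))
  out
}
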