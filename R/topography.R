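# Stimulus geometry: the scaled dartboard and its three analysis topographies.

#' Build the scaled dartboard stimulus geometry
#'
#' Constructs the 60-segment "scaled dart pattern" used for multifocal
#' stimulation: five concentric annular bands whose segment counts grow with
#' eccentricity, so that segment areas scale roughly with retinal
#' magnification. Within each band all segments have equal angular width, and
#' the first angular edge of every band lies on the 45-degree meridian, so
#' that the four diagonal meridians (45/135/225/315 degrees) coincide with
#' segment edges in every band. Quadrant-based region maps built with
#' [assign_regions()] therefore never straddle a segment.
#'
#' Angles are polar screen coordinates, counter-clockwise, with 0 degrees to
#' the right of fixation; eccentricities are degrees of visual angle.
#'
#' @param band_counts Integer vector of segments per band, innermost first.
#'   Must sum to 60 and each count must be divisible by 4 (otherwise quadrant
#'   boundaries would cut through segments).
#' @param band_edges Numeric vector of band boundary eccentricities in
#'   degrees, length `length(band_counts) + 1`, strictly increasing from 0.
#'
#' @return A tibble with one row per segment and columns `segment_id` (0-59),
#'   `band`, `inner_ecc`, `outer_ecc`, `start_angle`, `end_angle`,
#'   `mid_angle` (angular centroid, in `[0, 360)`) and `area` (deg^2).
#'
#' @examples
#' segs <- build_dartboard()
#' sum(segs$area)    # pi * 25^2, the full 25-degree disc
#' @export
build_dartboard <- function(band_counts = c(4L, 8L, 12L, 16L, 20L),
                            band_edges = c(0, 5, 10, 15, 20, 25)) {
  if (length(band_edges) != length(band_counts) + 1L) {
    stop("`band_edges` must have one more element than `band_counts`.", call. = FALSE)
  }
  if (band_edges[1] != 0 || any(diff(band_edges) <= 0)) {
    stop("`band_edges` must start at 0 and be strictly increasing.", call. = FALSE)
  }
  if (sum(band_counts) != 60L) {
    stop("`band_counts` must sum to 60 segments.", call. = FALSE)
  }
  if (any(band_counts %% 4L != 0L)) {
    stop("Each band count must be divisible by 4: quadrant boundaries would ",
         "straddle segments otherwise.", call. = FALSE)
  }

  bands <- purrr::map(seq_along(band_counts), function(b) {
    n <- band_counts[b]
    width <- 360 / n
    start <- 45 + width * (seq_len(n) - 1L)
    tibble::tibble(
      band = b,
      inner_ecc = band_edges[b],
      outer_ecc = band_edges[b + 1L],
      start_angle = start %% 360,
      end_angle = (start + width) %% 360,
      mid_angle = (start + width / 2) %% 360,
      area = (width * pi / 180) / 2 * (band_edges[b + 1L]^2 - band_edges[b]^2)
    )
  })
  out <- dplyr::bind_rows(bands)
  out$segment_id <- seq_len(nrow(out)) - 1L
  dplyr::relocate(out, "segment_id")
}

# Anatomical label of a screen-polar direction. Image inversion through the
# eye's optics: screen-superior stimuli fall on inferior retina and
# vice versa; for a right eye a screen-right (temporal visual field) stimulus
# falls on nasal retina, mirrored for the left eye.
.vertical_label <- function(screen_up) ifelse(screen_up, "I", "S")
.horizontal_label <- function(screen_right, eye) {
  if (eye == "right") ifelse(screen_right, "N", "T") else ifelse(screen_right, "T", "N")
}

#' Assign dartboard segments to the regions of an analysis topography
#'
#' Three topographies are supported, all centred on the fovea:
#' \describe{
#'   \item{`"rings"`}{five concentric annuli R1-R5 with boundaries at
#'     5/10/15/20/25 degrees; covers all 60 segments.}
#'   \item{`"sectors"`}{the central 5-degree disc S1 (identical to R1) plus
#'     four quarter-annuli over 5-20 degrees labelled by the oblique retinal
#'     quadrants: superior-temporal (ST), superior-nasal (SN), inferior-nasal
#'     (IN) and inferior-temporal (IT). Quadrant boundaries are the vertical
#'     and horizontal meridians.}
#'   \item{`"etdrs"`}{nine regions in the style of the ETDRS macular grid:
#'     the central disc plus temporal (T), superior (S), nasal (N) and
#'     inferior (I) quadrants at 5-10 and 10-20 degrees. Quadrant boundaries
#'     are the diagonal meridians, so each region is centred on a cardinal
#'     retinal direction.}
#' }
#' Segments beyond 20 degrees are left unassigned (`NA`) under `"sectors"`
#' and `"etdrs"`.
#'
#' Region labels are *retinal* (not visual-field) labels: the screen position
#' is inverted vertically and horizontally through the eye's optics before
#' labelling, and left-eye maps are the horizontal mirror image of right-eye
#' maps. Ring labels are laterality-invariant. A segment is assigned to the
#' quadrant containing its angular centroid; centroids falling exactly on a
#' boundary meridian (which happens for the vertical/horizontal meridians in
#' bands whose count is not divisible by 8) are assigned counter-clockwise,
#' i.e. to the quadrant that starts at that meridian.
#'
#' @param segments Tibble from [build_dartboard()].
#' @param scheme One of `"rings"`, `"sectors"`, `"etdrs"`.
#' @param eye Eye laterality, `"right"` or `"left"`.
#'
#' @return The `segments` tibble with an added `region_label` character
#'   column (`NA` for unassigned segments), carrying attributes `scheme` and
#'   `eye`.
#'
#' @examples
#' rings <- assign_regions(build_dartboard(), "rings")
#' table(rings$region_label)
#' @export
assign_regions <- function(segments,
                           scheme = c("rings", "sectors", "etdrs"),
                           eye = c("right", "left")) {
  scheme <- match.arg(scheme)
  eye <- match.arg(eye)
  req <- c("segment_id", "band", "inner_ecc", "outer_ecc", "mid_angle", "area")
  if (!all(req %in% names(segments))) {
    stop("`segments` must come from build_dartboard() (missing columns).", call. = FALSE)
  }
  edges <- sort(unique(c(segments$inner_ecc, segments$outer_ecc)))
  if (!isTRUE(all.equal(edges, c(0, 5, 10, 15, 20, 25)))) {
    stop("Segments are not aligned to the 5/10/15/20/25-degree band edges ",
         "required by the analysis topographies.", call. = FALSE)
  }

  mid <- segments$mid_angle %% 360
  label <- switch(
    scheme,
    rings = paste0("R", segments$band),
    sectors = {
      # Oblique quadrants bounded by the vertical and horizontal meridians.
      # Half-open [0, 90) etc.: a centroid exactly on a meridian joins the
      # quadrant starting there (counter-clockwise assignment).
      up <- mid >= 0 & mid < 180
      right <- mid < 90 | mid >= 270
      lab <- paste0(.vertical_label(up), .horizontal_label(right, eye))
      ifelse(segments$outer_ecc <= 20 & segments$band > 1L, lab, NA_character_)
    },
    etdrs = {
      # Cardinal quadrants bounded by the diagonal meridians.
      quadrant <- cut((mid + 45) %% 360, breaks = c(0, 90, 180, 270, 360),
                      labels = c("right", "up", "left", "down"),
                      include.lowest = TRUE, right = FALSE)
      lab <- switch(eye,
        right = c(right = "N", up = "I", left = "T", down = "S"),
        left  = c(right = "T", up = "I", left = "N", down = "S"))[as.character(quadrant)]
      ecc <- ifelse(segments$band == 2L, "5-10", "10-20")
      ifelse(segments$outer_ecc <= 20 & segments$band > 1L,
             paste0(lab, " ", ecc), NA_character_)
    }
  )
  if (scheme != "rings") {
    label[segments$band == 1L] <- if (scheme == "sectors") "S1" else "C"
  }

  out <- segments
  out$region_label <- label
  attr(out, "scheme") <- scheme
  attr(out, "eye") <- eye
  class(out) <- c("region_map", class(out))
  out
}

#' Total area of one region of a region map
#'
#' @param map A region map from [assign_regions()].
#' @param region_label Region label present in the map.
#' @return Summed member-segment area in deg^2.
#' @examples
#' region_area(assign_regions(build_dartboard(), "rings"), "R1")  # pi * 25
#' @export
region_area <- function(map, region_label) {
  stopifnot(is.data.frame(map), "region_label" %in% names(map))
  keep <- !is.na(map$region_label) & map$region_label == region_label
  if (!any(keep)) {
    stop("Unknown region label: ", region_label, call. = FALSE)
  }
  sum(map$area[keep])
}

#' Summarise a region map
#'
#' One row per region with member counts and total areas.
#'
#' @param map A region map from [assign_regions()].
#' @return Tibble with columns `region_label`, `n_segments`, `area`.
#' @export
region_map_summary <- function(map) {
  stopifnot(is.data.frame(map), "region_label" %in% names(map))
  map |>
    dplyr::filter(!is.na(.data$region_label)) |>
    dplyr::group_by(.data$region_label) |>
    dplyr::summarise(n_segments = dplyr::n(), area = sum(.data$area),
                     .groups = "drop")
}

#' Write / read a region map as a plain tabular file
#'
#' The on-disk format is a plain CSV with columns `segment_id`, `inner_ecc`,
#' `outer_ecc`, `start_angle`, `end_angle`, `scheme`, `region_label` (plus
#' the remaining geometry columns), or an equivalent JSON document.
#'
#' @param map A region map from [assign_regions()].
#' @param path Output file; format chosen by extension (`.csv` or `.json`).
#' @return `write_region_map()` returns `path` invisibly; `read_region_map()`
#'   returns the region map tibble.
#' @export
write_region_map <- function(map, path) {
  out <- tibble::as_tibble(map)
  out$scheme <- attr(map, "scheme")
  out$eye <- attr(map, "eye")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, digits = NA, na = "null")
  } else {
    readr::write_csv(out, path)
  }
  invisible(path)
}

#' @rdname write_region_map
#' @export
read_region_map <- function(path) {
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE)
  }
  scheme <- unique(df$scheme)
  eye <- unique(df$eye)
  df$scheme <- NULL
  df$eye <- NULL
  df$segment_id <- as.integer(df$segment_id)
  df$band <- as.integer(df$band)
  attr(df, "scheme") <- scheme
  attr(df, "eye") <- eye
  class(df) <- c("region_map", class(df))
  df
}
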