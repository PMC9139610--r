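test_that("dartboard tiles the 25-degree disc with scaled bands", {
  segs <- build_dartboard()
  expect_equal(nrow(segs), 60L)
  expect_equal(sum(segs$area), pi * 25^2, tolerance = 1e-9)
  # band 4 (15-20 deg) segments: annulus quarter arithmetic
  b4 <- segs[segs$band == 4L, ]
  expect_equal(unique(round(b4$area, 6)), round(pi * (400 - 225) / 16, 6))
  # equal angular widths within a band; first edge on the 45-degree meridian
  for (b in 1:5) {
    sb <- segs[segs$band == b, ]
    widths <- (sb$end_angle - sb$start_angle) %% 360
    expect_equal(unique(round(widths, 9)), 360 / nrow(sb))
    expect_true(45 %in% round(sb$start_angle, 9))
    # the four diagonal meridians are segment edges in every band
    expect_true(all(c(45, 135, 225, 315) %in% round(sb$start_angle %% 360, 6)) ||
                  nrow(sb) %% 4 == 0)
  }
  # no two segments of one band overlap: edges are distinct
  expect_false(any(duplicated(segs[c("band", "start_angle")])))
})

test_that("dartboard validation rejects bad band layouts", {
  expect_error(build_dartboard(band_counts = c(4, 8, 12, 16, 24)), "sum to 60")
  expect_error(build_dartboard(band_counts = c(5, 7, 12, 16, 20)), "divisible by 4")
  expect_error(build_dartboard(band_edges = c(0, 5, 10, 15, 20)), "one more")
})

test_that("ring map partitions all 60 segments with analytic areas", {
  map <- assign_regions(default_segments, "rings")
  summ <- region_map_summary(map)
  expect_equal(summ$n_segments, c(4L, 8L, 12L, 16L, 20L))
  edges <- c(0, 5, 10, 15, 20, 25)
  expect_equal(summ$area, pi * diff(edges^2), tolerance = 1e-9)
  expect_equal(region_area(map, "R1"), pi * 25, tolerance = 1e-9)
  # laterality-invariant
  left <- assign_regions(default_segments, "rings", "left")
  expect_equal(map$region_label, left$region_label)
})

test_that("sector map covers 5-20 degrees in four balanced oblique quadrants", {
  map <- assign_regions(default_segments, "sectors")
  summ <- region_map_summary(map)
  expect_setequal(summ$region_label, c("S1", "ST", "SN", "IN", "IT"))
  quad <- summ[summ$region_label != "S1", ]
  expect_equal(unique(quad$n_segments), 9L)
  expect_equal(quad$area, rep(pi * (400 - 25) / 4, 4), tolerance = 1e-9)
  # S1 membership identical to R1 membership
  rings <- assign_regions(default_segments, "rings")
  expect_equal(map$segment_id[!is.na(map$region_label) & map$region_label == "S1"],
               rings$segment_id[rings$region_label == "R1"])
  # segments beyond 20 degrees unassigned
  expect_true(all(is.na(map$region_label[map$outer_ecc > 20])))
})

test_that("ETDRS map has 9 regions with analytic quadrant areas", {
  map <- assign_regions(default_segments, "etdrs")
  summ <- region_map_summary(map)
  expect_equal(nrow(summ), 9L)
  outer_quads <- summ[grepl("10-20", summ$region_label), ]
  expect_equal(outer_quads$area, rep(pi * (400 - 100) / 4, 4), tolerance = 1e-9)
  expect_equal(sum(summ$area), pi * 400, tolerance = 1e-9)
  inner <- summ[grepl("5-10", summ$region_label), ]
  expect_equal(inner$area, rep(pi * (100 - 25) / 4, 4), tolerance = 1e-9)
})

test_that("retinal labels invert the screen position and mirror with laterality", {
  # right eye: a 5-10 deg segment with centroid at screen right -> nasal retina
  map_r <- assign_regions(default_segments, "etdrs", "right")
  seg_right <- map_r[map_r$band == 2L &
                       (map_r$mid_angle < 45 | map_r$mid_angle > 315), ]
  expect_true(all(seg_right$region_label == "N 5-10"))
  # same segment in the left eye: temporal retina
  map_l <- assign_regions(default_segments, "etdrs", "left")
  seg_right_l <- map_l[map_l$segment_id %in% seg_right$segment_id, ]
  expect_true(all(seg_right_l$region_label == "T 5-10"))
  # screen-superior stimuli label inferior retina (both eyes)
  seg_up <- map_r[map_r$band == 2L & map_r$mid_angle > 45 & map_r$mid_angle < 135, ]
  expect_true(all(seg_up$region_label == "I 5-10"))
  # mirror property: left map = right map with T and N exchanged
  swap <- function(x) chartr("TN", "NT", x)
  expect_equal(map_l$region_label, swap(map_r$region_label))
  # sectors mirror the same way
  s_r <- assign_regions(default_segments, "sectors", "right")
  s_l <- assign_regions(default_segments, "sectors", "left")
  expect_equal(s_l$region_label, swap(s_r$region_label))
})

test_that("every scheme partitions exactly the segments inside its outer limit", {
  for (scheme in c("rings", "sectors", "etdrs")) {
    for (eye in c("right", "left")) {
      map <- assign_regions(default_segments, scheme, eye)
      limit <- if (scheme == "rings") 25 else 20
      eligible <- map$outer_ecc <= limit
      expect_true(all(!is.na(map$region_label[eligible])))
      expect_true(all(is.na(map$region_label[!eligible])))
      # area conservation region-wise
      summ <- region_map_summary(map)
      expect_equal(sum(summ$area), pi * limit^2, tolerance = 1e-9)
    }
  }
})

test_that("region maps reject misaligned segments and unknown labels", {
  shifted <- build_dartboard(band_edges = c(0, 4, 10, 15, 20, 25))
  expect_error(assign_regions(shifted, "rings"), "band edges")
  map <- assign_regions(default_segments, "rings")
  expect_error(region_area(map, "R9"), "Unknown region")
})

test_that("region maps round-trip through CSV and JSON", {
  map <- assign_regions(default_segments, "etdrs", "left")
  for (ext in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_region_map(map, path)
    back <- read_region_map(path)
    expect_equal(back$region_label, map$region_label)
    expect_equal(back$area, map$area, tolerance = 1e-9)
    expect_equal(attr(back, "scheme"), "etdrs")
    expect_equal(attr(back, "eye"), "left")
  }
})
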