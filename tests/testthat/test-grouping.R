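mkdet <- function(times, rec, ind) {
  pingnet:::as_detections(data.frame(
    time = EPOCH + times, receiver_id = rec, individual_id = ind,
    stringsAsFactors = FALSE))
}

test_that("filter_window is half-open [start, end)", {
  w <- study_window(EPOCH, EPOCH + 3600)
  det <- mkdet(c(0, 1800, 3600), "R1", c("A", "B", "C"))
  out <- filter_window(det, w)
  expect_equal(out$individual_id, c("A", "B"))   # end excluded, start included
  expect_equal(filter_window(mkdet(c(10, 20), "R1", c("A", "B")), w)$individual_id,
               c("A", "B"))                       # all inside -> identity
})

test_that("bin_detections forms clock-aligned per-receiver groups", {
  # A at 09:03 and B at 09:07, same receiver -> one group {A,B} in bin 09:00
  det <- mkdet(9 * 3600 + c(180, 420), "R1", c("A", "B"))
  g <- bin_detections(det)
  expect_equal(nrow(g), 1)
  expect_equal(g$members[[1]], c("A", "B"))
  expect_equal(as.numeric(g$bin_start - EPOCH, units = "hours"), 9)

  # same times at different receivers -> two singleton groups
  g2 <- bin_detections(mkdet(9 * 3600 + c(180, 420), c("R1", "R2"), c("A", "B")))
  expect_equal(nrow(g2), 2)
  expect_equal(lengths(g2$members), c(1, 1))

  # 09:09:59 vs 09:10:00 fall in different bins
  g3 <- bin_detections(mkdet(9 * 3600 + c(599, 600), "R1", "A"))
  expect_equal(nrow(g3), 2)

  expect_error(bin_detections(det, bin_width = 0), "bin_width")
})

test_that("binning partitions detections, deduplicates, ignores row order", {
  set.seed(11)
  det <- mkdet(sample(0:7200, 300, TRUE), sample(c("R1", "R2"), 300, TRUE),
               sample(LETTERS[1:6], 300, TRUE))
  g <- bin_detections(det)
  # every detection maps to exactly one (receiver, bin) group
  key_det <- unique(paste(det$receiver_id, floor(as.numeric(det$time) / 600)))
  key_grp <- paste(g$receiver_id, floor(as.numeric(g$bin_start) / 600))
  expect_setequal(key_det, key_grp)
  expect_false(anyDuplicated(key_grp) > 0)
  # total members <= total detections (dedup only removes)
  expect_lte(sum(lengths(g$members)), nrow(det))
  # shuffled input gives the identical result
  shuf <- det[sample(nrow(det)), ]
  g_s <- bin_detections(pingnet:::as_detections(shuf))
  expect_identical(g$members, g_s$members)
})

test_that("bin_capacity matches the tag-delay arithmetic", {
  expect_identical(bin_capacity(600, 90), 6L)    # six detection occasions
  expect_identical(bin_capacity(90, 90), 1L)
  expect_identical(bin_capacity(600, 120), 5L)
  expect_error(bin_capacity(0, 90), "positive")
  expect_error(bin_capacity(600, -1), "positive")
})

test_that("collapse_to_periods aligns hourly and validates widths", {
  det <- mkdet(c(9 * 3600, 9 * 3600 + 3000, 10 * 3600), "R1", c("A", "B", "C"))
  p <- collapse_to_periods(bin_detections(det), 3600)
  hrs <- as.numeric(p$period_start - EPOCH, units = "hours")
  expect_equal(hrs, c(9, 9, 10))                 # 09:50 bin same period, 10:00 next
  expect_error(collapse_to_periods(bin_detections(det), 1000), "multiple")
  empty <- bin_detections(mkdet(numeric(0), character(0), character(0)))
  expect_equal(nrow(collapse_to_periods(empty, 3600)), 0)
})

test_that("restrict_proximity_groups keeps groups covered by the reference", {
  g <- group_table("PROX", EPOCH + 9 * 3600, list(c("A", "B")), bin_width = 600)
  ref_hit <- mkdet(9 * 3600 + 240, "V1", "A")       # A at 09:04
  expect_equal(nrow(restrict_proximity_groups(g, ref_hit)), 1)
  ref_miss <- mkdet(14 * 3600, "V1", "C")
  expect_equal(nrow(restrict_proximity_groups(g, ref_miss)), 0)
  # tolerance 0: a reference detection inside the same bin still counts
  expect_equal(nrow(restrict_proximity_groups(g, ref_hit, tolerance = 0)), 1)
  # member_rule = "all" requires every member
  expect_equal(nrow(restrict_proximity_groups(g, ref_hit, member_rule = "all")), 0)
  both <- mkdet(9 * 3600 + c(240, 250), "V1", c("A", "B"))
  expect_equal(nrow(restrict_proximity_groups(g, both, member_rule = "all")), 1)
  # empty reference stream: everything dropped, with a warning
  empty <- mkdet(numeric(0), character(0), character(0))
  expect_warning(out <- restrict_proximity_groups(g, empty), "dropped")
  expect_equal(nrow(out), 0)
  # reference must be a single receiver
  two <- mkdet(c(1, 2), c("V1", "V2"), c("A", "A"))
  expect_error(restrict_proximity_groups(g, two), "single receiver")
})

test_that("exclude_individual removes the host and drops emptied groups", {
  g <- group_table("P", EPOCH + c(0, 600), list(c("H", "A"), "H"), bin_width = 600)
  out <- exclude_individual(g, "H")
  expect_equal(nrow(out), 1)
  expect_equal(out$members[[1]], "A")
  # absent individual -> identity
  expect_equal(exclude_individual(g, "Z")$members, g$members)
  # all groups are {H} -> empty output
  gh <- group_table("P", EPOCH, list("H"), bin_width = 600)
  expect_equal(nrow(exclude_individual(gh, "H")), 0)
})

test_that("group tables round-trip through CSV", {
  g <- group_table(c("P", "Q"), EPOCH + c(0, 600),
                   list(c("A", "B"), "C"), bin_width = 600)
  f <- withr::local_tempfile(fileext = ".csv")
  write_groups(g, f)
  back <- read_groups(f, bin_width = 600)
  expect_identical(back$members, g$members)
  expect_identical(back$receiver_id, g$receiver_id)
  expect_equal(as.numeric(back$bin_start), as.numeric(g$bin_start))
})
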