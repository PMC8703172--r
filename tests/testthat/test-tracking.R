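test_that("a static cell yields a single full-length track", {
  det <- det_df(frame = 0:9, x = rep(20, 10), y = rep(20, 10))
  tr <- link_detections(det, tracking_params())
  expect_equal(length(tr$tracks), 1L)
  expect_equal(length(tr$tracks[[1]]), 10L)
})

test_that("links above max displacement are rejected (no identity swaps)", {
  # two distant cells; a would-be swap needs a jump beyond max_displacement
  frames <- rep(0:5, each = 2)
  xs <- rep(c(10, 60), 6)
  det <- det_df(frames, xs, rep(10, 12))
  tr <- link_detections(det, tracking_params(max_displacement = 10))
  expect_equal(length(tr$tracks), 2L)
  xs_by_track <- lapply(tr$tracks, function(t) unique(det$x[t]))
  expect_true(all(lengths(xs_by_track) == 1L))
})

test_that("gap closing bridges dropouts up to max_gap frames", {
  keep <- c(0:4, 7:11) # 2 missed frames
  det <- det_df(keep, x = 30 + 0.3 * keep, y = rep(15, length(keep)))
  tr <- link_detections(det, tracking_params(max_gap = 4))
  expect_equal(length(tr$tracks), 1L)
  trace <- extract_trace(tr, 1L, 0.5)
  expect_equal(sum(trace$interpolated), 2L)
  # interpolated intensity equals the neighbour mean on a linear gap
  expect_equal(trace$venus[trace$interpolated][1], 100)

  far <- c(0:4, 12:16) # 7 missed frames > max_gap
  det2 <- det_df(far, x = rep(30, 10), y = rep(15, 10))
  tr2 <- link_detections(det2, tracking_params(max_gap = 4))
  expect_equal(length(tr2$tracks), 2L)
})

test_that("a vanishing blob followed by two flanking starts is a division", {
  # parent at (40, 40) frames 0..9, daughters appear at frame 10
  f_p <- 0:9; f_d <- 10:19
  det <- rbind(det_df(f_p, rep(40, 10), rep(40, 10)),
               det_df(f_d, rep(34, 10), rep(40, 10)),
               det_df(f_d, rep(46, 10), rep(40, 10)))
  tr <- detect_divisions(link_detections(det, tracking_params(
    max_displacement = 5, division_radius = 12)))
  expect_equal(length(tr$tracks), 3L)
  kids <- which(!is.na(tr$parent))
  expect_equal(length(kids), 2L)
  expect_equal(unique(tr$parent[kids]), 1L)
  # a track that simply ends at the movie end has no children
  expect_equal(sum(tr$parent %in% 2L), 0L)
})

test_that("three appearances near one ended track: best two adopted", {
  f_p <- 0:9; f_d <- 10:19
  det <- rbind(det_df(f_p, rep(40, 10), rep(40, 10)),
               det_df(f_d, rep(35, 10), rep(40, 10)),
               det_df(f_d, rep(45, 10), rep(40, 10)),
               det_df(f_d, rep(40, 10), rep(49, 10)))
  tr <- detect_divisions(link_detections(det, tracking_params(
    max_displacement = 4, division_radius = 12)))
  expect_equal(length(tr$tracks), 4L)
  expect_equal(sum(!is.na(tr$parent)), 2L)
  kids <- which(!is.na(tr$parent))
  # the two nearest starts (5 px) win over the 9 px one
  kid_x <- vapply(kids, function(k) det$x[tr$tracks[[k]][1]], numeric(1))
  expect_setequal(kid_x, c(35, 45))
})

test_that("a parent tracked through the division is split at the birth", {
  # linker follows the parent into daughter 1 (same position); daughter 2
  # appears 8 px away at frame 10
  det <- rbind(det_df(0:19, rep(40, 20), rep(40, 20)),
               det_df(10:19, rep(48, 10), rep(40, 10)))
  tr <- detect_divisions(link_detections(det, tracking_params(
    max_displacement = 5, division_radius = 12)))
  expect_equal(length(tr$tracks), 3L)
  expect_equal(sum(!is.na(tr$parent)), 2L)
  parent_track <- unique(stats::na.omit(tr$parent))
  expect_equal(length(parent_track), 1L)
  # the parent's own remaining frames end right before the birth frame
  pf <- tr$detections$frame_index[tr$tracks[[parent_track]]]
  expect_equal(max(pf), 9L)
})

test_that("tracking fidelity on the low-motility imaging fixture", {
  fix <- small_imaging_fixture()
  la <- link_accuracy(fix$result, fix$lineage)
  expect_gte(la$link_accuracy, 0.99)
  dr <- division_recovery(fix$result, fix$lineage)
  expect_gte(dr$division_recovery, 0.95)
  # conservation: each detection belongs to at most one track
  all_rows <- unlist(fix$result$tracks$tracks)
  expect_equal(anyDuplicated(all_rows), 0L)
  # children counts are 0 or 2 and lineage is acyclic
  par <- fix$result$tracks$parent
  kid_counts <- table(par[!is.na(par)])
  expect_true(all(kid_counts == 2L))
  for (i in seq_along(par)) {
    seen <- integer(0); j <- i
    while (!is.na(par[j])) {
      expect_false(j %in% seen)
      seen <- c(seen, j); j <- par[j]
    }
  }
})

test_that("trace extraction handles single-sample tracks and errors", {
  det <- det_df(5L, 10, 10)
  tr <- link_detections(det, tracking_params())
  trace <- extract_trace(tr, 1L, 0.5)
  expect_equal(nrow(trace), 1L)
  expect_false(any(trace$interpolated))
  expect_error(extract_trace(structure(list(tracks = list(integer(0)),
                                            parent = NA_integer_,
                                            detections = det,
                                            params = tracking_params()),
                                       class = "cell_tracks"), 1L),
               "empty track")
})
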