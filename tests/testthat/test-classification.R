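test_that("binarization handles flat, stepped and ramped series", {
  cfg <- classifier_config()
  times <- seq(0, 30, by = 0.5)
  zero <- binarize_channel(rep(0, length(times)), times, cfg)
  expect_false(any(zero$on))

  step <- ifelse(times >= 10, 1, 0)
  b <- binarize_channel(step, times, cfg)
  first_on <- times[which(b$on)[1]]
  expect_lte(abs(first_on - 10), 2 * 0.5) # within smoothing reach of t0

  # rise over 4 h, plateau, fall over 3 h: a single on-run whose off
  # switch happens during the fall, within the fall duration of its start
  v <- pmin(1, pmax(0, (times - 5) / 4))
  v <- pmin(v, pmax(0, 1 - (times - 20) / 3))
  b2 <- binarize_channel(v, times, cfg)
  runs <- rle(b2$on)
  expect_equal(sum(runs$values), 1L)
  off_t <- times[which(b2$on)[sum(b2$on)] + 1L]
  expect_gte(off_t, 20)
  expect_lte(off_t, 23 + 0.5)

  # traces shorter than 3 samples are rejected as unclassifiable
  expect_null(binarize_channel(c(0, 1), c(0, 0.5), cfg))
  short_call <- classify_trace(make_trace(c(0, 1), c(0, 1)))
  expect_false(short_call$classifiable)
  expect_equal(short_call$reason, "too_short")
})

test_that("state segmentation recovers generator state boundaries", {
  fix <- trace_oracle_fixture("pc3_hotel", 40, seed = 6)
  cells <- fix$lineage$cells
  cfg <- classifier_config(min_signal = 0.05)
  checked <- 0L
  for (tr in fix$traces) {
    id <- attr(tr, "track_id")
    rec <- cells[match(id, cells$cell_id), ]
    if (is.na(rec$parent_id) || rec$fate != "TRANSIENT_G0_TO_G1") next
    if (is.na(rec$cherry_off_h)) next
    segs <- segment_states(tr, cfg)
    st <- as.character(segs$segments$state)
    expect_equal(st, c("DN", "V_ONLY", "DP", "C_ONLY", "DN"))
    # boundaries within one frame of the half-rise / half-fall times
    p <- fix$profile
    expected <- c(rec$venus_on_h + p$venus_rise_h / 4,
                  rec$cherry_on_h + p$cherry_rise_h / 4)
    got <- segs$segments$start_h[2:3]
    expect_true(all(abs(got - expected) <= 1))
    checked <- checked + 1L
    if (checked >= 8L) break
  }
  expect_gte(checked, 3L)

  # all-zero trace is one DN segment
  z <- make_trace(rep(0, 40), rep(0, 40))
  segs <- segment_states(z, cfg)
  expect_equal(nrow(segs$segments), 1L)
  expect_equal(as.character(segs$segments$state), "DN")

  # serum-starvation-like trace: both rise, never fall -> terminal DP
  sf <- record_trace(venus_on = 4, cherry_on = 8, end_h = 48)
  segs2 <- segment_states(sf, cfg)
  last <- segs2$segments[nrow(segs2$segments), ]
  expect_equal(as.character(last$state), "DP")
  expect_equal(last$end_h, 48)
  expect_equal(segs2$final_state, "DP")
})

test_that("quiescence calls honor the strict 14 h boundary", {
  cfg <- classifier_config(min_signal = 0.05)
  # DP dwell exactly 15 h: cherry on 4, venus off 19
  c15 <- classify_trace(record_trace(2, 4, 19, 29, end_h = 48), cfg)
  expect_true(c15$classifiable)
  expect_equal(c15$dp_duration_h, 15, tolerance = 1e-6)
  expect_true(c15$spontaneous_g0)
  expect_false(c15$transient_g0)
  # exactly 14.0 h is not beyond the threshold
  c14 <- classify_trace(record_trace(2, 4, 18, 28, end_h = 48), cfg)
  expect_equal(c14$dp_duration_h, 14, tolerance = 1e-6)
  expect_false(c14$spontaneous_g0)
  expect_true(c14$transient_g0)
  # 6 h dwell then G1 entry: transient G0, entry at the DP end
  c6 <- classify_trace(record_trace(2, 4, 10, 20, end_h = 48), cfg)
  expect_false(c6$spontaneous_g0)
  expect_true(c6$transient_g0)
  expect_equal(c6$g1_entry_h, 10, tolerance = 1e-6)
  expect_equal(c6$g1_exit_h, 20, tolerance = 1e-6)
  # 3 h dwell: direct G1 entry, neither spontaneous nor transient
  c3 <- classify_trace(record_trace(2, 4, 7, 17, end_h = 48), cfg)
  expect_false(c3$spontaneous_g0)
  expect_false(c3$transient_g0)
})

test_that("censored DP windows are spontaneous only beyond threshold", {
  cfg <- classifier_config(min_signal = 0.05)
  # still double positive at the movie end with > 14 h observed
  long <- classify_trace(record_trace(2, 4, NA, NA, end_h = 30), cfg)
  expect_true(long$classifiable)
  expect_true(long$censored_dp)
  expect_true(long$spontaneous_g0)
  expect_true(is.na(long$g1_entry_h))
  # censored with only ~8 h observed: undetermined, excluded
  short <- classify_trace(record_trace(2, 4, NA, NA, end_h = 12), cfg)
  expect_false(short$classifiable)
  expect_equal(short$reason, "censored_dp_undetermined")
  expect_true(short$censored_dp)
})

test_that("order violations and mid-cycle starts are withheld, not fixed", {
  cfg <- classifier_config(min_signal = 0.05)
  # cherry before venus (G0 re-entry shape)
  n <- 80
  t <- seq(0, 39.5, by = 0.5)
  cherry <- rep(1, n)
  venus <- pmin(1, pmax(0, (t - 10) / 2))
  cl <- classify_trace(make_trace(venus, cherry), cfg)
  expect_false(cl$classifiable)
  expect_equal(cl$reason, "order_violation")
  expect_equal(cl$final_state, "DP")
  # already double positive at the first sample (mid-cycle founder)
  founder <- classify_trace(make_trace(rep(1, n), rep(1, n)), cfg)
  expect_false(founder$classifiable)
  expect_equal(founder$final_state, "DP")
})

test_that("spontaneous counts are monotone in the threshold", {
  fix <- trace_oracle_fixture("pc3_hotel", 60, seed = 8)
  lin <- fix$lineage
  traces <- simulate_traces(lin, noise_sd = 0.04, seed = 99)
  counts <- vapply(c(8, 11, 14, 17, 22), function(thr) {
    cfg <- classifier_config(spontaneous_threshold_h = thr,
                             min_signal = 0.05)
    calls <- classify_traces(traces, cfg)
    sum(calls$spontaneous_g0 %in% TRUE)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[1], 0)
})

test_that("classification of noiseless generator traces matches fates", {
  for (nm in c("pc3_hotel", "t3t3_fullserum")) {
    fix <- trace_oracle_fixture(nm)
    calls <- fix$calls
    cells <- fix$lineage$cells
    idx <- match(calls$track_id, cells$cell_id)
    eligible <- !is.na(calls$parent_track_id) &
      calls$start_h <= fix$spec$duration_h - 24 &
      calls$classifiable %in% TRUE
    expect_gt(sum(eligible), 50)
    truth <- cells$fate[idx][eligible]
    expect_equal(mean((calls$spontaneous_g0[eligible] %in% TRUE) ==
                        (truth == "SPONT_G0")), 1)
    expect_equal(mean((calls$transient_g0[eligible] %in% TRUE) ==
                        (truth == "TRANSIENT_G0_TO_G1")), 1)
    # measured dwell equals the generated dwell exactly for exiters
    ex <- eligible & !calls$censored_dp & !is.na(cells$dp_dwell_h[idx])
    expect_lt(max(abs(calls$dp_duration_h[ex] -
                        cells$dp_dwell_h[idx][ex])), 1e-6)
  }
})

test_that("classification is a pure function of trace and config", {
  fix <- trace_oracle_fixture("pc3_hotel", 20, seed = 13)
  cfg <- classifier_config(min_signal = 0.05)
  a <- classify_traces(fix$traces, cfg)
  b <- classify_traces(fix$traces, cfg)
  expect_identical(a, b)
})
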