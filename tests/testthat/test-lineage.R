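mk_call <- function(parent = 1, start_h = 10, g1_entry = NA,
                    spont = FALSE, classifiable = TRUE,
                    reason = "ok", dp_start = start_h + 4,
                    censored = FALSE) {
  structure(list(track_id = sample.int(1000, 1), parent_track_id = parent,
                 start_h = start_h, end_h = 72, classifiable = classifiable,
                 reason = reason, dp_start_h = dp_start,
                 dp_duration_h = if (is.na(g1_entry)) 30 else
                   g1_entry - dp_start,
                 censored_dp = censored, spontaneous_g0 = spont,
                 transient_g0 = FALSE, g1_entry_h = g1_entry,
                 g1_exit_h = NA, final_state = "DP",
                 order_violation = FALSE),
            class = "cell_cycle_call")
}

test_that("daughter-pair categories follow the decision taxonomy", {
  cfg <- classifier_config()
  # one daughter enters G1 at 6 h post-division, the other stays in G0
  a <- classify_daughter_pair(mk_call(g1_entry = 16), mk_call(spont = TRUE),
                              cfg)
  expect_equal(a$category, "ASYNC")
  expect_true(a$censored_delta || is.na(a$delta_g1_entry_h))
  # both enter within tolerance
  s <- classify_daughter_pair(mk_call(g1_entry = 18.0),
                              mk_call(g1_entry = 18.4), cfg)
  expect_equal(s$category, "SYNC_G1")
  expect_equal(s$delta_g1_entry_h, 0.4, tolerance = 1e-9)
  # both enter far apart
  a2 <- classify_daughter_pair(mk_call(g1_entry = 18),
                               mk_call(g1_entry = 25), cfg)
  expect_equal(a2$category, "ASYNC")
  expect_equal(a2$delta_g1_entry_h, 7)
  expect_equal(asynchrony_delta(a2), 7)
  # both spontaneous G0: synchronous quiescence, no delta
  g0 <- classify_daughter_pair(mk_call(spont = TRUE), mk_call(spont = TRUE),
                               cfg)
  expect_equal(g0$category, "SYNC_G0")
  expect_true(is.na(g0$delta_g1_entry_h))
  expect_true(is.na(asynchrony_delta(g0)))
  # unclassifiable sibling: undetermined
  u <- classify_daughter_pair(mk_call(g1_entry = 18),
                              mk_call(classifiable = FALSE,
                                      reason = "too_short"), cfg)
  expect_equal(u$category, "UNDETERMINED")
  # censored sibling that had dwelt in DP long enough: asynchrony
  cens <- mk_call(classifiable = FALSE,
                  reason = "censored_dp_undetermined", dp_start = 12,
                  censored = TRUE)
  ac <- classify_daughter_pair(mk_call(g1_entry = 20), cens, cfg,
                               observation_h = 72)
  expect_equal(ac$category, "ASYNC")
  expect_true(ac$censored_delta)
  expect_true(is.na(asynchrony_delta(ac)))
  # ... but a sibling track lost mid-movie is not asynchrony evidence
  lost <- cens
  lost$end_h <- 50
  al <- classify_daughter_pair(mk_call(g1_entry = 20), lost, cfg,
                               observation_h = 72)
  expect_equal(al$category, "UNDETERMINED")
  # non-siblings are an argument error
  expect_error(classify_daughter_pair(mk_call(parent = 1),
                                      mk_call(parent = 2), cfg),
               "parent")
})

test_that("population summary arithmetic and conservation", {
  cfg <- classifier_config()
  calls <- do.call(rbind, lapply(1:10, function(i) {
    cl <- mk_call(parent = i, start_h = 10,
                  g1_entry = if (i <= 7) 20 else NA,
                  spont = i > 7)
    as.data.frame(unclass(cl)[names(unclass(cl)) != "track_id"],
                  stringsAsFactors = FALSE)
  }))
  calls$track_id <- seq_len(nrow(calls)) + 100
  s <- summarize_population(calls, pairs = NULL, cfg, observation_h = 72)
  expect_equal(s$n_classifiable_postmitotic, 10L)
  expect_equal(s$percent_spontaneous_g0, 30)
  expect_true(s$percent_spontaneous_g0 >= 0 &&
                s$percent_spontaneous_g0 <= 100)

  # all pairs synchronous G1 -> zero percent asynchronous, counts conserve
  pairs <- data.frame(parent_track_id = 1:4, category = "SYNC_G1",
                      delta_g1_entry_h = 0.2, censored_delta = FALSE,
                      division_time_h = 10)
  s2 <- summarize_population(calls, pairs, cfg, observation_h = 72)
  expect_equal(s2$percent_async_pairs, 0)
  expect_equal(sum(s2$pair_counts), nrow(pairs))

  # empty input gives the empty-summary sentinel
  s0 <- summarize_population(classify_traces(list()), config = cfg,
                             observation_h = 72)
  expect_equal(s0$n_tracked, 0L)
  expect_true(is.na(s0$percent_spontaneous_g0))
})

test_that("Mann-Whitney comparison matches exact enumeration", {
  # independent oracle: enumerate all choose(4, 2) label assignments
  pool <- c(1, 2, 3, 4)
  combs <- utils::combn(4, 2)
  u_obs <- sum(outer(c(1, 2), c(3, 4), ">"))
  u_all <- apply(combs, 2, function(ix) {
    sum(outer(pool[ix], pool[-ix], ">"))
  })
  p_exact <- mean(u_all <= u_obs) * 2 # two-sided by symmetry
  res <- compare_duration_distributions(c(1, 2), c(3, 4))
  expect_equal(unname(res$U), 0)
  expect_equal(res$p_value, p_exact)
  expect_equal(res$p_value, 1 / 3)
  # identical samples are maximally compatible: p of 1
  res2 <- compare_duration_distributions(c(1.5, 2.5, 3.5),
                                         c(1.5, 2.5, 3.5))
  expect_equal(res2$p_value, 1)
  expect_error(compare_duration_distributions(numeric(0), 1:3),
               "non-empty")
  # symmetry up to U <-> n1 n2 - U
  ra <- compare_duration_distributions(c(1, 5, 9), c(2, 3, 11))
  rb <- compare_duration_distributions(c(2, 3, 11), c(1, 5, 9))
  expect_equal(unname(ra$U), 9 - unname(rb$U))
  expect_equal(ra$p_value, rb$p_value)
})

test_that("fibroblast DP dwells exceed prostate-cancer dwells (U test)", {
  set.seed(31)
  t3 <- quiescence_profile("t3t3_fullserum")
  pc <- quiescence_profile("pc3_hotel")
  dwell_sample <- function(p, n) {
    spont <- stats::runif(n) < p$p_spontaneous_g0
    ifelse(spont, dist_sample(p$dp_dwell_prolonged, n),
           dist_sample(p$dp_dwell_transient, n))
  }
  a <- dwell_sample(t3, 50)
  b <- dwell_sample(pc, 50)
  res <- compare_duration_distributions(a, b)
  expect_lt(res$p_value, 0.01)
  expect_gt(mean(a), mean(b))
})

test_that("division timing histogram counts and orderings", {
  h0 <- division_timing_profile(numeric(0), 24, 72)
  expect_equal(h0$count, c(0L, 0L, 0L))
  expect_error(division_timing_profile(c(1, 2), 7, 72), "divide")
  set.seed(5)
  tt <- stats::runif(900, 0, 72)
  h <- division_timing_profile(tt, 24, 72)
  expect_equal(sum(h$count), 900L)
  gof <- stats::chisq.test(h$count, p = rep(1 / 3, 3))
  expect_gt(gof$p.value, 0.001)

  # dormancy-signal preset concentrates divisions in the first 24 h
  spec <- movie_spec()
  frac24 <- function(nm, seed) {
    lin <- simulate_population(quiescence_profile(nm), 150, spec,
                               seed = seed, with_positions = FALSE)
    div <- lin$cells$division_h
    div <- div[!is.na(div) & div >= 0]
    mean(div <= 24)
  }
  expect_gt(frac24("pc3_gas6", 17), frac24("pc3_hotel", 17))
})
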