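test_that("empty and degenerate populations are handled", {
  spec <- movie_spec()
  p <- quiescence_profile("pc3_hotel")
  lin0 <- simulate_population(p, 0, spec, seed = 1)
  expect_equal(nrow(lin0$cells), 0L)
  expect_equal(nrow(lin0$positions), 0L)
  expect_error(simulate_population(p, -3, spec, seed = 1), "non-negative")

  # all-synchronous-G0 fate law: no daughter ever exits G0 or divides
  pf <- quiescence_profile("pc3_hotel", pair_fate_probs = c(1, 0, 0),
                           p_spontaneous_g0 = NULL)
  lin <- simulate_population(pf, 25, spec, seed = 2,
                             with_positions = FALSE)
  d <- lin$cells[!is.na(lin$cells$parent_id), ]
  expect_gt(nrow(d), 0)
  expect_true(all(is.na(d$venus_off_h)))
  expect_true(all(is.na(d$division_h)))
  expect_true(all(d$fate == "SPONT_G0"))
})

test_that("event order and censoring invariants hold across profiles", {
  spec <- movie_spec()
  for (nm in c("pc3_hotel", "t3t3_fullserum", "pc3_gas6",
               "serumfree_from_sgm", "serumfree_from_g1")) {
    lin <- simulate_population(quiescence_profile(nm), 40, spec,
                               seed = 7, with_positions = FALSE)
    cells <- lin$cells
    ns <- cells[!cells$silent & !cells$reentry, ]
    on_ok <- is.na(ns$venus_on_h) | is.na(ns$cherry_on_h) |
      ns$venus_on_h < ns$cherry_on_h
    expect_true(all(on_ok), info = nm)
    expect_true(all(is.na(ns$venus_off_h) | is.na(ns$cherry_on_h) |
                      ns$venus_off_h > ns$cherry_on_h), info = nm)
    expect_true(all(is.na(ns$cherry_off_h) | is.na(ns$venus_off_h) |
                      ns$cherry_off_h > ns$venus_off_h), info = nm)
    expect_true(all(is.na(ns$division_h) | is.na(ns$cherry_off_h) |
                      ns$division_h > ns$cherry_off_h), info = nm)
    # censoring conservation: division XOR censored end
    expect_true(all(xor(is.na(cells$division_h),
                        is.na(cells$censored_end_h))), info = nm)
    expect_true(all(stats::na.omit(cells$censored_end_h) ==
                      spec$duration_h), info = nm)
    # every division produces exactly two daughters born at the division
    for (pid in cells$cell_id[!is.na(cells$division_h)]) {
      kids <- cells[cells$parent_id %in% pid, ]
      expect_equal(nrow(kids), 2L, info = nm)
      expect_equal(kids$birth_h,
                   rep(cells$division_h[cells$cell_id == pid], 2),
                   info = nm)
    }
    # the G0-reentry cohort is the only one allowed to invert onset order
    if (nm == "serumfree_from_g1") {
      re <- cells[cells$reentry, ]
      expect_true(all(re$venus_on_h > re$cherry_on_h))
    }
  }
})

test_that("identical seeds reproduce lineages bit for bit", {
  spec <- movie_spec()
  p <- quiescence_profile("t3t3_fullserum")
  a <- simulate_population(p, 8, spec, seed = 42)
  b <- simulate_population(p, 8, spec, seed = 42)
  expect_identical(a$cells, b$cells)
  expect_identical(a$positions, b$positions)
  c2 <- simulate_population(p, 8, spec, seed = 43)
  expect_false(identical(a$cells, c2$cells))
})

test_that("pair-fate frequencies and asynchrony deltas follow the law", {
  p <- quiescence_profile("t3t3_fullserum")
  set.seed(2)
  n <- 10000
  draws <- replicate(n, assign_daughter_fates(p), simplify = FALSE)
  cats <- vapply(draws, `[[`, character(1), "category")
  freq <- table(factor(cats, c("SYNC_G0", "SYNC_G1", "ASYNC"))) / n
  for (k in names(freq)) {
    pk <- p$pair_fate_probs[[tolower(k)]]
    se <- sqrt(pk * (1 - pk) / n)
    expect_lt(abs(freq[[k]] - pk), 4 * se)
  }
  # mean asynchrony delta of the uniform 1-15 h law is 8 h
  deltas <- vapply(draws[cats == "ASYNC"], `[[`, numeric(1), "delta_h")
  expect_lt(abs(mean(deltas) - 8), 3 * stats::sd(deltas) / sqrt(length(deltas)))
  expect_true(all(deltas >= 1 & deltas <= 15))

  # degenerate law: every pair asynchronous with a fixed 3 h delta
  pd <- quiescence_profile("pc3_hotel", p_spontaneous_g0 = NULL,
                           pair_fate_probs = c(0, 0, 1),
                           async_delta = hours_const(3))
  set.seed(3)
  for (i in 1:20) {
    f <- assign_daughter_fates(pd)
    expect_equal(f$category, "ASYNC")
    expect_equal(f$delta_h, 3)
    expect_equal(abs(diff(f$dwells)), 3)
  }

  # dwell assignments respect the thresholds per category
  set.seed(4)
  for (i in 1:300) {
    f <- assign_daughter_fates(p)
    if (f$category == "SYNC_G0") {
      expect_true(all(f$dwells > p$spontaneous_threshold_h))
      expect_false(any(f$exits))
    }
    if (f$category == "SYNC_G1") {
      expect_true(all(f$dwells <= p$spontaneous_threshold_h))
      expect_lte(abs(diff(f$dwells)), p$sync_jitter_h)
    }
  }
})

test_that("realized dwell fractions match the profile marginal", {
  spec <- movie_spec()
  p <- quiescence_profile("pc3_hotel")
  lin <- simulate_population(p, 500, spec, seed = 1,
                             with_positions = FALSE)
  d <- lin$cells[!is.na(lin$cells$parent_id) & !lin$cells$silent, ]
  # truth dwell-exceedance: non-exiting daughters are prolonged by design
  over <- is.na(d$dp_dwell_h) | d$dp_dwell_h > p$spontaneous_threshold_h
  ci <- binom_ci_pct(sum(over), nrow(d))
  expect_gt(100 * p$p_spontaneous_g0, ci[1])
  expect_lt(100 * p$p_spontaneous_g0, ci[2])
})

test_that("volume exclusion keeps concurrent cells separated", {
  fix <- small_imaging_fixture()
  pos <- fix$lineage$positions
  min_d <- Inf
  for (f in unique(pos$frame)) {
    sub <- pos[pos$frame == f, ]
    if (nrow(sub) < 2) next
    dm <- as.matrix(stats::dist(sub[, c("x", "y")]))
    diag(dm) <- Inf
    min_d <- min(min_d, min(dm))
  }
  expect_gt(min_d, 2.5 * fix$spec$psf_sigma)
})
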