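test_that("noiseless rendering puts the spot peak at the cell centroid", {
  spec <- movie_spec(width = 96, height = 96, duration_h = 4)
  p <- quiescence_profile("pc3_hotel", p_divide = 0, motility_sigma = 0)
  lin <- simulate_population(p, 1, spec, seed = 3)
  mov <- render_movie(lin, spec, seed = 1, noise = FALSE)
  for (f in seq_len(dim(mov$venus)[3])) {
    tru <- lin$positions[lin$positions$frame == f - 1L, ]
    m <- mov$venus[, , f]
    peak <- which(m == max(m), arr.ind = TRUE)[1, ]
    expect_equal(unname(peak["col"]) - 1L, round(tru$x))
    expect_equal(unname(peak["row"]) - 1L, round(tru$y))
  }
})

test_that("rendered spot intensity tracks the reporter level over time", {
  spec <- movie_spec(width = 96, height = 96, duration_h = 36)
  # a founder that divides early gives daughters with full ramp dynamics
  p <- quiescence_profile("pc3_hotel", p_divide = 1,
                          founder_div_window_h = 2, motility_sigma = 0.1)
  lin <- simulate_population(p, 1, spec, seed = 4)
  mov <- render_movie(lin, spec, seed = 5)
  kid <- lin$cells$cell_id[!is.na(lin$cells$parent_id)][1]
  rec <- lin$cells[match(kid, lin$cells$cell_id), ]
  tru <- lin$positions[lin$positions$cell_id == kid, ]
  sigma <- spec$psf_sigma
  lv <- obs <- numeric(nrow(tru))
  for (k in seq_len(nrow(tru))) {
    f <- tru$frame[k] + 1L
    t_h <- (f - 1L) * spec$frame_interval_h
    lv[k] <- reporter_level(rec, t_h, "venus", lin$profile)
    xs <- intersect(round(tru$x[k]) + (-9:9), 0:(spec$width - 1))
    ys <- intersect(round(tru$y[k]) + (-9:9), 0:(spec$height - 1))
    patch <- mov$venus[ys + 1L, xs + 1L, f]
    dmask <- outer(ys - tru$y[k], xs - tru$x[k],
                   function(a, b) sqrt(a^2 + b^2)) <= 3 * sigma
    obs[k] <- mean(patch[dmask])
  }
  expect_gt(stats::sd(lv), 0)
  expect_gt(stats::cor(lv, obs), 0.95)
})

test_that("an empty lineage renders pure background noise", {
  spec <- movie_spec(width = 64, height = 64, duration_h = 2)
  p <- quiescence_profile("pc3_hotel")
  lin <- simulate_population(p, 0, spec, seed = 1)
  mov <- render_movie(lin, spec, seed = 2)
  expect_equal(mean(mov$venus), spec$background, tolerance = 0.05)
  det <- segment_movie(mov)
  expect_equal(nrow(det), 0L)
})

test_that("rendering is bit-identical under a fixed seed", {
  spec <- movie_spec(width = 64, height = 64, duration_h = 6)
  p <- quiescence_profile("pc3_hotel")
  lin <- simulate_population(p, 3, spec, seed = 8)
  a <- render_movie(lin, spec, seed = 9)
  b <- render_movie(lin, spec, seed = 9)
  expect_identical(a$venus, b$venus)
  expect_identical(a$cherry, b$cherry)
  expect_false(identical(a$venus, render_movie(lin, spec, seed = 10)$venus))
})

test_that("TIFF round trip preserves stack, page order and metadata", {
  spec <- movie_spec(width = 48, height = 40, duration_h = 2)
  p <- quiescence_profile("pc3_hotel")
  lin <- simulate_population(p, 2, spec, seed = 5)
  mov <- render_movie(lin, spec, seed = 6)
  path <- tempfile(fileext = ".tiff")
  write_movie_tiff(mov, path)
  back <- read_movie_tiff(path)
  expect_equal(dim(back$venus), dim(mov$venus))
  expect_equal(back$venus, mov$venus)
  expect_equal(back$cherry, mov$cherry)
  expect_equal(back$spec$frame_interval_h, spec$frame_interval_h)
  # pages are frame-major, channel-minor
  pages <- tiff::readTIFF(path, all = TRUE)
  expect_equal(length(pages), 2L * spec$n_frames)
  expect_equal(round(pages[[1]] * 65535), mov$venus[, , 1])
  expect_equal(round(pages[[2]] * 65535), mov$cherry[, , 1])
  # a missing sidecar is a hard error naming the remedy
  path2 <- tempfile(fileext = ".tiff")
  file.copy(path, path2)
  expect_error(read_movie_tiff(path2), "sidecar")
})

test_that("ground-truth export writes the documented CSV schema", {
  spec <- movie_spec(width = 64, height = 64, duration_h = 4)
  lin <- simulate_population(quiescence_profile("pc3_hotel"), 3, spec,
                             seed = 12)
  dir <- tempfile()
  write_ground_truth(lin, dir)
  cells <- utils::read.csv(file.path(dir, "cells.csv"))
  pos <- utils::read.csv(file.path(dir, "positions.csv"))
  expect_true(all(c("cell_id", "parent_id", "birth_h", "venus_on_h",
                    "cherry_on_h", "venus_off_h", "cherry_off_h",
                    "division_h", "fate") %in% names(cells)))
  expect_equal(names(pos), c("frame", "cell_id", "x", "y"))
  expect_equal(nrow(pos), nrow(lin$positions))
})
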