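#' Render a simulated lineage into a two-channel movie
#'
#' Each live cell is drawn as an isotropic Gaussian spot (width
#' `spec$psf_sigma`) whose amplitude is `basal + reporter_level * peak` in
#' each channel; the basal term keeps double-negative cells visible so the
#' pipeline can track cells without a constitutive nuclear marker. A
#' uniform background is added, then signal-dependent shot noise plus
#' Gaussian read noise (drawn jointly as Gaussian noise with variance
#' `signal + read_sd^2`; at the background levels used the
#' Poisson-to-Gaussian approximation is exact for practical purposes), and
#' the result is quantized and clipped to the camera bit depth. Identical
#' `(lineage, spec, seed)` give a bit-identical stack.
#'
#' @param lineage A `cell_lineage` from [simulate_population()].
#' @param spec A [movie_spec()] (defaults to the lineage's own).
#' @param seed Integer seed for the rendering noise.
#' @param noise Set `FALSE` to render a noiseless, unquantized stack.
#' @return An object of class `reporter_movie`: list with `venus` and
#'   `cherry` (`height x width x n_frames` arrays, counts), `spec`, and
#'   `truth` (the per-frame ground-truth centroid table
#'   `frame`, `cell_id`, `x`, `y`).
#' @export
render_movie <- function(lineage, spec = lineage$spec, seed = 0,
                         noise = TRUE) {
  stopifnot(inherits(lineage, "cell_lineage"), inherits(spec, "movie_spec"))
  if (spec$width <= 0 || spec$height <= 0) {
    stop("movie_spec with non-positive dimensions", call. = FALSE)
  }
  with_local_seed(seed, {
    nf <- spec$n_frames
    h <- spec$height; w <- spec$width
    venus <- array(spec$background, dim = c(h, w, nf))
    cherry <- array(spec$background, dim = c(h, w, nf))
    times <- frame_times(spec)
    pos <- lineage$positions
    cells <- lineage$cells
    profile <- lineage$profile
    if (nrow(pos)) {
      # per-cell reporter levels on that cell's frames
      lv_v <- numeric(nrow(pos)); lv_c <- numeric(nrow(pos))
      for (id in unique(pos$cell_id)) {
        sel <- which(pos$cell_id == id)
        rec <- cells[match(id, cells$cell_id), ]
        tt <- times[pos$frame[sel] + 1L]
        lv_v[sel] <- reporter_level(rec, tt, "venus", profile)
        lv_c[sel] <- reporter_level(rec, tt, "cherry", profile)
      }
      basal_v <- spec$basal_frac * spec$peak_venus
      basal_c <- spec$basal_frac * spec$peak_cherry
      silent <- cells$silent[match(pos$cell_id, cells$cell_id)]
      amp_v <- ifelse(silent, 0, basal_v) + lv_v * spec$peak_venus
      amp_c <- ifelse(silent, 0, basal_c) + lv_c * spec$peak_cherry
      # silent cells keep a basal spot in the cherry channel only when they
      # retain cherry (reentry cohort); modelled simply: silent cells are
      # rendered at background (invisible), matching lost-reporter clones,
      # unless an onset time exists.
      has_cherry <- !is.na(cells$cherry_on_h[match(pos$cell_id,
                                                   cells$cell_id)])
      amp_c <- ifelse(silent & has_cherry, basal_c + lv_c * spec$peak_cherry,
                      amp_c)
      by_frame <- split(seq_len(nrow(pos)), pos$frame)
      for (fr_name in names(by_frame)) {
        f <- as.integer(fr_name) + 1L
        mv <- venus[, , f]; mc <- cherry[, , f]
        for (k in by_frame[[fr_name]]) {
          mv <- add_spot(mv, pos$x[k], pos$y[k], amp_v[k], spec$psf_sigma)
          mc <- add_spot(mc, pos$x[k], pos$y[k], amp_c[k], spec$psf_sigma)
        }
        venus[, , f] <- mv; cherry[, , f] <- mc
      }
    }
    if (noise) {
      venus <- add_camera_noise(venus, spec)
      cherry <- add_camera_noise(cherry, spec)
    }
    structure(list(venus = venus, cherry = cherry, spec = spec,
                   truth = lineage$positions),
              class = "reporter_movie")
  })
}

# add one Gaussian spot to a frame matrix (rows = y, cols = x, 0-based
# coordinates) and return the updated matrix
add_spot <- function(m, x, y, amp, sigma) {
  if (amp <= 0) return(m)
  h <- nrow(m); w <- ncol(m)
  r <- ceiling(4 * sigma)
  cx <- round(x); cy <- round(y)
  if (cx + r < 0 || cx - r > w - 1 || cy + r < 0 || cy - r > h - 1) return(m)
  ix <- max(0, cx - r):min(w - 1, cx + r)
  iy <- max(0, cy - r):min(h - 1, cy + r)
  gx <- exp(-((ix - x)^2) / (2 * sigma^2))
  gy <- exp(-((iy - y)^2) / (2 * sigma^2))
  m[iy + 1L, ix + 1L] <- m[iy + 1L, ix + 1L] + amp * outer(gy, gx)
  m
}

add_camera_noise <- function(arr, spec) {
  rs2 <- spec$read_noise_sd^2
  if (spec$shot_noise) {
    arr <- arr + stats::rnorm(length(arr)) * sqrt(arr + rs2)
  } else if (spec$read_noise_sd > 0) {
    arr <- arr + stats::rnorm(length(arr)) * spec$read_noise_sd
  }
  arr <- round(arr)
  neg <- arr < 0
  if (any(neg)) arr[neg] <- 0
  top <- 2^spec$bit_depth - 1
  over <- arr > top
  if (any(over)) arr[over] <- top
  arr
}

#' @export
print.reporter_movie <- function(x, ...) {
  d <- dim(x$venus)
  cat(sprintf("Reporter movie: %d x %d px, %d frames, 2 channels\n",
              d[2], d[1], d[3]))
  invisible(x)
}

#' Write / read a two-channel movie as multi-page TIFF with sidecar
#'
#' Pages are ordered frame-major, channel-minor (frame 0 Venus, frame 0
#' Cherry, frame 1 Venus, ...), 16-bit unsigned; acquisition metadata
#' (frame interval, channel names) goes to a YAML sidecar next to the
#' stack.
#'
#' @param movie A `reporter_movie`.
#' @param path Output TIFF path; the sidecar is written to
#'   `<path>.meta.yaml` unless `meta_path` is given.
#' @param meta_path Optional explicit sidecar path.
#' @return `write_movie_tiff()` the TIFF path, invisibly;
#'   `read_movie_tiff()` a `reporter_movie` (without ground truth).
#' @export
write_movie_tiff <- function(movie, path, meta_path = NULL) {
  stopifnot(inherits(movie, "reporter_movie"))
  if (is.null(meta_path)) meta_path <- paste0(path, ".meta.yaml")
  top <- 2^movie$spec$bit_depth - 1
  nf <- dim(movie$venus)[3]
  pages <- vector("list", 2L * nf)
  for (f in seq_len(nf)) {
    pages[[2L * f - 1L]] <- pmin(pmax(movie$venus[, , f], 0), top) / top
    pages[[2L * f]] <- pmin(pmax(movie$cherry[, , f], 0), top) / top
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = "none", reduce = FALSE)
  yaml::write_yaml(list(frame_interval_h = movie$spec$frame_interval_h,
                        duration_h = movie$spec$duration_h,
                        channels = c("venus", "cherry"),
                        width = movie$spec$width,
                        height = movie$spec$height,
                        bit_depth = movie$spec$bit_depth),
                   meta_path)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path, meta_path = NULL) {
  if (is.null(meta_path)) meta_path <- paste0(path, ".meta.yaml")
  if (!file.exists(meta_path)) {
    stop("missing metadata sidecar '", meta_path,
         "'; a frame interval is required -- provide a YAML sidecar with ",
         "at least `frame_interval_h`", call. = FALSE)
  }
  meta <- yaml::read_yaml(meta_path)
  if (is.null(meta$frame_interval_h)) {
    stop("metadata sidecar lacks frame_interval_h", call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) %% 2L != 0L) {
    stop("expected an even number of pages (two channels per frame)",
         call. = FALSE)
  }
  nf <- length(pages) / 2L
  bit_depth <- if (!is.null(meta$bit_depth)) meta$bit_depth else 16L
  top <- 2^bit_depth - 1
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  venus <- array(0, c(h, w, nf)); cherry <- array(0, c(h, w, nf))
  for (f in seq_len(nf)) {
    venus[, , f] <- round(pages[[2L * f - 1L]] * top)
    cherry[, , f] <- round(pages[[2L * f]] * top)
  }
  spec <- movie_spec(frame_interval_h = meta$frame_interval_h,
                     duration_h = if (!is.null(meta$duration_h))
                       meta$duration_h else nf * meta$frame_interval_h,
                     width = w, height = h, bit_depth = bit_depth)
  structure(list(venus = venus, cherry = cherry, spec = spec,
                 truth = NULL),
            class = "reporter_movie")
}

#' Export ground truth of a simulated lineage as CSV
#'
#' Writes `cells.csv` (event times and fates, one row per cell) and
#' `positions.csv` (per-frame centroids) into a directory.
#'
#' @param lineage A `cell_lineage`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_ground_truth <- function(lineage, dir) {
  stopifnot(inherits(lineage, "cell_lineage"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(lineage$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE)
  utils::write.csv(lineage$positions, file.path(dir, "positions.csv"),
                   row.names = FALSE)
  invisible(dir)
}
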