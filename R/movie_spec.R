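#' Acquisition geometry and optics of a simulated two-channel movie
#'
#' @param frame_interval_h Imaging interval in hours (typical live-imaging
#'   practice is 20--30 min; default 0.5).
#' @param duration_h Total imaging period in hours (default 72); must be a
#'   multiple of `frame_interval_h`.
#' @param width,height Frame size in pixels.
#' @param psf_sigma Isotropic Gaussian spot width (pixels) used to render a
#'   cell.
#' @param peak_venus,peak_cherry Full-expression spot amplitude per channel
#'   (camera counts above background).
#' @param basal_frac Basal (reporter-independent) spot amplitude as a
#'   fraction of the channel peak; keeps double-negative cells visible to
#'   segmentation and tracking without a constitutive nuclear marker.
#' @param background Uniform background level (counts).
#' @param read_noise_sd Gaussian read-noise standard deviation (counts).
#' @param shot_noise Add signal-dependent shot noise?
#' @param bit_depth Output bit depth (16-bit unsigned).
#' @return An object of class `movie_spec`.
#' @export
movie_spec <- function(frame_interval_h = 0.5, duration_h = 72,
                       width = 256, height = 256, psf_sigma = 3,
                       peak_venus = 8000, peak_cherry = 8000,
                       basal_frac = 0.03, background = 100,
                       read_noise_sd = 5, shot_noise = TRUE,
                       bit_depth = 16L) {
  stopifnot(is.numeric(frame_interval_h), frame_interval_h > 0,
            is.numeric(duration_h), duration_h > 0)
  if (width < 8 || height < 8) {
    stop("movie_spec(): width/height must be at least 8 pixels",
         call. = FALSE)
  }
  n_frames <- duration_h / frame_interval_h
  if (abs(n_frames - round(n_frames)) > 1e-9) {
    stop("duration_h must be a multiple of frame_interval_h", call. = FALSE)
  }
  stopifnot(psf_sigma > 0, peak_venus > 0, peak_cherry > 0,
            basal_frac >= 0, background >= 0, read_noise_sd >= 0,
            bit_depth %in% c(8L, 16L))
  structure(list(frame_interval_h = frame_interval_h,
                 duration_h = duration_h,
                 width = as.integer(width), height = as.integer(height),
                 psf_sigma = psf_sigma,
                 peak_venus = peak_venus, peak_cherry = peak_cherry,
                 basal_frac = basal_frac, background = background,
                 read_noise_sd = read_noise_sd,
                 shot_noise = isTRUE(shot_noise),
                 bit_depth = as.integer(bit_depth),
                 n_frames = as.integer(round(n_frames))),
            class = "movie_spec")
}

#' @export
print.movie_spec <- function(x, ...) {
  cat(sprintf("Movie spec: %d x %d px, %d frames (%g h at %g h/frame), 2 channels\n",
              x$width, x$height, x$n_frames, x$duration_h,
              x$frame_interval_h))
  invisible(x)
}

#' Frame acquisition times of a movie spec
#' @param spec A [movie_spec()].
#' @return Numeric vector of frame times in hours (frame index 0 at 0 h).
#' @export
frame_times <- function(spec) {
  stopifnot(inherits(spec, "movie_spec"))
  seq(0, by = spec$frame_interval_h, length.out = spec$n_frames)
}

# Run code with a locally seeded RNG, restoring the caller's stream.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
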