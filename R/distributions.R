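#' Duration distributions for kinetic profiles
#'
#' Kinetic profiles describe onset delays and dwell times as small
#' distribution objects so that profiles are fully serializable to plain
#' text and every draw is reproducible from the R random number generator.
#' Two families cover everything the shipped profiles need: a uniform
#' distribution over an interval of hours and a point mass.
#'
#' @param min,max Interval bounds in hours, `0 <= min <= max`.
#' @param value Point-mass location in hours, `>= 0`.
#' @return An object of class `duration_dist`.
#' @examples
#' d <- hours_uniform(2, 4)
#' dist_mean(d)
#' @export
hours_uniform <- function(min, max) {
  stopifnot(is.numeric(min), is.numeric(max), length(min) == 1L,
            length(max) == 1L, is.finite(min), is.finite(max))
  if (min < 0 || max < min) {
    stop("hours_uniform() needs 0 <= min <= max", call. = FALSE)
  }
  structure(list(kind = "uniform", min = as.numeric(min),
                 max = as.numeric(max)),
            class = "duration_dist")
}

#' @rdname hours_uniform
#' @export
hours_const <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  if (value < 0) stop("hours_const() needs value >= 0", call. = FALSE)
  structure(list(kind = "const", value = as.numeric(value)),
            class = "duration_dist")
}

is_duration_dist <- function(x) inherits(x, "duration_dist")

#' @export
print.duration_dist <- function(x, ...) {
  if (x$kind == "uniform") {
    cat(sprintf("Uniform(%g, %g) h\n", x$min, x$max))
  } else {
    cat(sprintf("%g h (fixed)\n", x$value))
  }
  invisible(x)
}

#' Draw, summarize or bound a duration distribution
#'
#' @param d A `duration_dist`.
#' @param n Number of draws (uses the current RNG stream).
#' @return `dist_sample()` a numeric vector of length `n`; `dist_mean()`
#'   the expectation; `dist_support()` a length-2 numeric `c(lower, upper)`.
#' @export
dist_sample <- function(d, n = 1L) {
  stopifnot(is_duration_dist(d))
  switch(d$kind,
         uniform = stats::runif(n, d$min, d$max),
         const   = rep.int(d$value, n))
}

#' @rdname dist_sample
#' @export
dist_mean <- function(d) {
  stopifnot(is_duration_dist(d))
  switch(d$kind, uniform = (d$min + d$max) / 2, const = d$value)
}

#' @rdname dist_sample
#' @export
dist_support <- function(d) {
  stopifnot(is_duration_dist(d))
  switch(d$kind, uniform = c(d$min, d$max), const = rep(d$value, 2L))
}

#' Tail probability of a sum of two independent duration distributions
#'
#' Closed-form `P(X + Y > threshold)` for the supported families (the
#' uniform/uniform case is the trapezoid convolution). Used to calibrate
#' pair-fate probabilities against a target marginal quiescence fraction,
#' so the calibration is exact and deterministic rather than Monte Carlo.
#'
#' @param dx,dy `duration_dist` objects.
#' @param threshold Threshold in hours.
#' @return `P(X + Y > threshold)` as a number in `[0, 1]`.
#' @export
dist_sum_tail <- function(dx, dy, threshold) {
  stopifnot(is_duration_dist(dx), is_duration_dist(dy),
            is.numeric(threshold), length(threshold) == 1L)
  if (dx$kind == "const" && dy$kind == "const") {
    return(as.numeric(dx$value + dy$value > threshold))
  }
  if (dx$kind == "const") return(unif_tail(dy, threshold - dx$value))
  if (dy$kind == "const") return(unif_tail(dx, threshold - dy$value))
  # both uniform: integrate P(Y > t - x) over x ~ U(ax, bx)
  ax <- dx$min; bx <- dx$max
  if (bx == ax) return(unif_tail(dy, threshold - ax))
  f <- function(x) unif_tail_vec(dy, threshold - x)
  # piecewise-linear integrand: trapezoid over its breakpoints is exact
  br <- sort(unique(pmin(bx, pmax(ax, c(ax, bx, threshold - dy$min,
                                        threshold - dy$max)))))
  tot <- 0
  for (i in seq_len(length(br) - 1L)) {
    lo <- br[i]; hi <- br[i + 1L]
    if (hi > lo) tot <- tot + (hi - lo) * (f(lo) + f(hi)) / 2
  }
  tot / (bx - ax)
}

unif_tail <- function(d, t) {
  # P(X > t) for X ~ d (uniform or const)
  if (d$kind == "const") return(as.numeric(d$value > t))
  if (t <= d$min) return(1)
  if (t >= d$max) return(0)
  (d$max - t) / (d$max - d$min)
}

unif_tail_vec <- function(d, t) vapply(t, function(ti) unif_tail(d, ti),
                                       numeric(1))
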