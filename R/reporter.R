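#' Deterministic reporter level of a cell at a given time
#'
#' Piecewise-linear (trapezoidal) reporter kinetics: a channel is 0 before
#' its onset, rises linearly to full expression over the profile's rise
#' time, plateaus, and decays linearly to 0 over the fall time starting at
#' the recorded off event. A cell whose off event is absent (prolonged G0)
#' plateaus at 1 until censoring.
#'
#' @param record A single cell record (one row of `lineage$cells`, or a
#'   list with the same fields).
#' @param t_h Time(s) in hours from movie start; must lie within the cell's
#'   life interval `[birth_h, division_h or censored_end_h]`.
#' @param channel `"venus"` or `"cherry"`.
#' @param profile The [kinetic_profile()] providing the ramp durations.
#' @return Intensity fraction(s) in `[0, 1]`.
#' @export
reporter_level <- function(record, t_h, channel = c("venus", "cherry"),
                           profile) {
  channel <- match.arg(channel)
  stopifnot(inherits(profile, "kinetic_profile"))
  record <- as.list(record)
  end_h <- if (!is.na(record$division_h)) record$division_h
           else record$censored_end_h
  if (any(t_h < record$birth_h - 1e-9) || any(t_h > end_h + 1e-9)) {
    stop("t_h outside the cell's life interval", call. = FALSE)
  }
  if (channel == "venus") {
    ramp_level(t_h, record$venus_on_h, record$venus_off_h,
               profile$venus_rise_h, profile$venus_fall_h)
  } else {
    ramp_level(t_h, record$cherry_on_h, record$cherry_off_h,
               profile$cherry_rise_h, profile$cherry_fall_h)
  }
}

ramp_level <- function(t, on, off, rise, fall) {
  if (is.na(on)) return(rep(0, length(t)))
  up <- (t - on) / rise
  lv <- pmin(1, pmax(0, up))
  if (!is.na(off)) lv <- pmin(lv, pmax(0, 1 - (t - off) / fall))
  lv
}

#' Extract per-cell reporter traces directly from a simulated lineage
#'
#' Samples [reporter_level()] on the movie's frame grid for every cell,
#' optionally adding Gaussian measurement noise. This is the image-free
#' route to traces (the imaging route is render + segment + track +
#' [extract_trace()]).
#'
#' @param lineage A `cell_lineage` from [simulate_population()].
#' @param noise_sd Gaussian noise standard deviation on the intensity
#'   fraction scale (0 = noiseless).
#' @param seed Optional seed for the measurement noise.
#' @return A list of `reporter_trace` objects: data frames with columns
#'   `t_h`, `venus`, `cherry`, `interpolated`, carrying attributes
#'   `track_id`, `parent_track_id`, `start_h`.
#' @export
simulate_traces <- function(lineage, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(lineage, "cell_lineage"))
  run <- function() {
    times <- frame_times(lineage$spec)
    cells <- lineage$cells
    out <- vector("list", nrow(cells))
    for (i in seq_len(nrow(cells))) {
      rec <- cells[i, ]
      end_h <- if (!is.na(rec$division_h)) rec$division_h
               else rec$censored_end_h
      sel <- times >= max(rec$birth_h, 0) & times < end_h
      if (!any(sel)) next
      tt <- times[sel]
      v <- reporter_level(rec, tt, "venus", lineage$profile)
      cc <- reporter_level(rec, tt, "cherry", lineage$profile)
      if (noise_sd > 0) {
        v <- pmax(0, v + stats::rnorm(length(tt), 0, noise_sd))
        cc <- pmax(0, cc + stats::rnorm(length(tt), 0, noise_sd))
      }
      out[[i]] <- new_reporter_trace(
        data.frame(t_h = tt, venus = v, cherry = cc,
                   interpolated = FALSE),
        track_id = rec$cell_id,
        parent_track_id = rec$parent_id,
        start_h = tt[1])
    }
    out[!vapply(out, is.null, logical(1))]
  }
  if (!is.null(seed)) with_local_seed(seed, run()) else run()
}

new_reporter_trace <- function(df, track_id, parent_track_id = NA,
                               start_h = df$t_h[1]) {
  structure(df, class = c("reporter_trace", "data.frame"),
            track_id = track_id, parent_track_id = parent_track_id,
            start_h = start_h)
}

#' @export
print.reporter_trace <- function(x, ...) {
  cat(sprintf("Reporter trace, track %s: %d samples over [%.1f, %.1f] h\n",
              as.character(attr(x, "track_id")), nrow(x),
              min(x$t_h), max(x$t_h)))
  invisible(x)
}
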