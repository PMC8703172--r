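#' Classifier configuration
#'
#' Tunable parameters of the trace-to-state classifier.
#'
#' @param smoothing_window_h Moving-median window (hours) applied to each
#'   channel before thresholding.
#' @param theta_on,theta_off Hysteresis on/off thresholds as fractions of
#'   the per-trace robust maximum (95th percentile); a channel switches on
#'   above `theta_on` and off below `theta_off` (`0 < theta_off < theta_on
#'   < 1`). Per-trace normalization absorbs cell-to-cell variation in
#'   reporter expression intensity.
#' @param spontaneous_threshold_h Double-positive dwell beyond which a cell
#'   is called spontaneous G0 (strict `>`; default 14 h).
#' @param transient_threshold_h Dwell above which a G1-entrant is called
#'   transient G0 (strict `>`; default 4 h).
#' @param sync_tolerance_h Daughter G1-entry difference at or below which a
#'   pair is synchronous (default 1 h).
#' @param min_state_dwell_h State runs shorter than this are merged into
#'   their neighbours (noise-chatter guard).
#' @param min_signal Absolute floor on the per-trace robust maximum; a
#'   channel whose 95th-percentile value does not exceed it is called off
#'   throughout (guards basal-only / reporter-silent cells against
#'   normalization blow-up). Same units as the trace values.
#' @param min_classifiable_window_h Post-mitotic cells first observed
#'   later than `movie end - min_classifiable_window_h` are not scored:
#'   with less remaining observation than this, a prolonged-G0 dwell cannot
#'   be distinguished from a still-pending G1 entry, and scoring such cells
#'   would censor the two fates asymmetrically.
#' @param strict_threshold Read "prolonged beyond the threshold" as strict
#'   inequality (default TRUE).
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(smoothing_window_h = 1.5,
                              theta_on = 0.25, theta_off = 0.15,
                              spontaneous_threshold_h = 14,
                              transient_threshold_h = 4,
                              sync_tolerance_h = 1,
                              min_state_dwell_h = 1,
                              min_signal = 0,
                              min_classifiable_window_h = 24,
                              strict_threshold = TRUE) {
  if (!(theta_off > 0 && theta_on > theta_off && theta_on < 1)) {
    stop("need 0 < theta_off < theta_on < 1", call. = FALSE)
  }
  stopifnot(spontaneous_threshold_h > 0, transient_threshold_h > 0,
            sync_tolerance_h >= 0, min_state_dwell_h >= 0,
            smoothing_window_h >= 0, min_signal >= 0,
            min_classifiable_window_h >= 0)
  structure(as.list(environment()), class = "classifier_config")
}

STATE_LEVELS <- c("DN", "V_ONLY", "DP", "C_ONLY")

#' Binarize one reporter channel with smoothing and hysteresis
#'
#' Moving-median smoothing, per-trace normalization by the 95th-percentile
#' value, hysteresis thresholding (`theta_on`/`theta_off`), and merging of
#' runs shorter than `min_state_dwell_h`.
#'
#' @param values Channel intensities (any non-negative scale).
#' @param times Sample times in hours (uniform spacing).
#' @param config A [classifier_config()].
#' @return A list with `on` (logical vector), `z` (smoothed normalized
#'   series used downstream for event-time refinement), or `NULL` when the
#'   trace has fewer than 3 samples (unclassifiable).
#' @export
binarize_channel <- function(values, times, config = classifier_config()) {
  n <- length(values)
  if (n < 3L || length(times) != n) return(NULL)
  dt <- times[2] - times[1]
  k <- max(1L, round(config$smoothing_window_h / dt))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (n %% 2L == 1L) n else n - 1L)
  sm <- if (k >= 3L) as.numeric(stats::runmed(values, k, endrule = "median"))
        else as.numeric(values)
  q <- as.numeric(stats::quantile(sm, 0.95, names = FALSE, type = 7))
  if (!is.finite(q) || q <= config$min_signal || q <= 0) {
    return(list(on = rep(FALSE, n), z = rep(0, n)))
  }
  z <- sm / q
  on <- logical(n)
  state <- FALSE
  for (i in seq_len(n)) {
    if (!state && z[i] > config$theta_on) state <- TRUE
    else if (state && z[i] < config$theta_off) state <- FALSE
    on[i] <- state
  }
  on <- merge_short_runs(on, dt, config$min_state_dwell_h)
  list(on = on, z = z)
}

merge_short_runs <- function(on, dt, min_dwell_h) {
  repeat {
    r <- rle(on)
    if (length(r$lengths) <= 1L) return(on)
    len_h <- r$lengths * dt
    short <- which(len_h < min_dwell_h - 1e-9)
    if (!length(short)) return(on)
    j <- short[which.min(len_h[short])]
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    on[starts[j]:ends[j]] <- !r$values[j]
  }
}

#' Segment a reporter trace into cell-cycle states
#'
#' Combines the binarized Venus and Cherry series into per-sample states
#' (`DN`, `V_ONLY`, `DP`, `C_ONLY`) and contiguous half-open state
#' segments. The canonical post-mitotic progression is
#' `DN -> V_ONLY -> DP -> C_ONLY -> DN`; any observed run sequence that is
#' not an in-order subsequence of that progression is flagged as an order
#' violation (it is reported, never silently fixed).
#'
#' @param trace A `reporter_trace` (data frame with `t_h`, `venus`,
#'   `cherry`).
#' @param config A [classifier_config()].
#' @return An object of class `state_segments`: list with `segments` (data
#'   frame `state`, `start_h`, `end_h`), `states` (per-sample factor),
#'   `order_violation` flag, `final_state`, and the smoothed normalized
#'   channel series used for event refinement. `NULL` if the trace is too
#'   short to classify.
#' @export
segment_states <- function(trace, config = classifier_config()) {
  # min_signal may carry per-channel floors (venus, cherry)
  cfg_v <- config; cfg_v$min_signal <- config$min_signal[[1L]]
  cfg_c <- config
  cfg_c$min_signal <- config$min_signal[[min(2L, length(config$min_signal))]]
  bv <- binarize_channel(trace$venus, trace$t_h, cfg_v)
  bc <- binarize_channel(trace$cherry, trace$t_h, cfg_c)
  if (is.null(bv) || is.null(bc)) return(NULL)
  n <- nrow(trace)
  dt <- if (n > 1L) trace$t_h[2] - trace$t_h[1] else 0.5
  st <- ifelse(bv$on,
               ifelse(bc$on, "DP", "V_ONLY"),
               ifelse(bc$on, "C_ONLY", "DN"))
  r <- rle(st)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segments <- data.frame(
    state = r$values,
    start_h = trace$t_h[starts],
    end_h = c(trace$t_h[starts[-1L]], trace$t_h[n] + dt),
    start_idx = starts, end_idx = ends)
  structure(list(
    segments = segments,
    states = factor(st, levels = STATE_LEVELS),
    order_violation = !is_canonical_order(r$values),
    final_state = st[n],
    times = trace$t_h, z_venus = bv$z, z_cherry = bc$z,
    on_venus = bv$on, on_cherry = bc$on,
    track_id = attr(trace, "track_id"),
    parent_track_id = attr(trace, "parent_track_id")),
    class = "state_segments")
}

is_canonical_order <- function(run_states) {
  template <- c("DN", "V_ONLY", "DP", "C_ONLY", "DN")
  pos <- 1L
  for (s in run_states) {
    while (pos <= length(template) && template[pos] != s) pos <- pos + 1L
    if (pos > length(template)) return(FALSE)
    pos <- pos + 1L
  }
  TRUE
}

#' @export
print.state_segments <- function(x, ...) {
  cat(sprintf("State segments (track %s)%s:\n",
              as.character(x$track_id),
              if (x$order_violation) " [order violation]" else ""))
  print(x$segments[, c("state", "start_h", "end_h")])
  invisible(x)
}

# Sub-frame event refinement ------------------------------------------------
# Boundary times from hysteresis are quantized to the frame grid and biased
# by the ramp shape. Around each switch we locate the interpolated crossing
# times of two levels (0.25 and 0.75 of the local plateau) and extrapolate
# the line through them to level 0 (for an onset) or to the plateau (for a
# fall start). Exact for piecewise-linear kinetics; approximately unbiased
# under noise after smoothing.

crossing_before <- function(times, z, level, idx) {
  # last upward crossing of `level` at or before index idx
  j <- idx
  while (j > 1L && z[j - 1L] > level) j <- j - 1L
  if (j <= 1L) return(NA_real_)
  interp_cross(times[j - 1L], times[j], z[j - 1L], z[j], level)
}

crossing_after <- function(times, z, level, idx) {
  # first downward crossing of `level` at or after index idx
  n <- length(z)
  j <- idx
  while (j < n && z[j + 1L] > level) j <- j + 1L
  if (j >= n) return(NA_real_)
  interp_cross(times[j], times[j + 1L], z[j], z[j + 1L], level)
}

interp_cross <- function(t0, t1, z0, z1, level) {
  if (z1 == z0) return((t0 + t1) / 2)
  t0 + (level - z0) / (z1 - z0) * (t1 - t0)
}

refine_onset <- function(times, z, run_start, run_end) {
  if (run_start <= 1L) return(times[run_start])
  p <- as.numeric(stats::quantile(z[run_start:run_end], 0.9, names = FALSE))
  if (!is.finite(p) || p <= 0) return(times[run_start])
  # index of first sample at/above the upper level
  jb <- run_start
  n <- length(z)
  while (jb < n && z[jb] < 0.75 * p) jb <- jb + 1L
  t_b <- crossing_before(times, z, 0.75 * p, jb)
  t_a <- crossing_before(times, z, 0.25 * p, jb)
  if (is.na(t_a) || is.na(t_b) || t_b <= t_a) return(times[run_start])
  t_a - 0.5 * (t_b - t_a)
}

refine_fall_start <- function(times, z, run_start, run_end) {
  n <- length(z)
  if (run_end >= n) return(NA_real_) # still on at trace end
  p <- as.numeric(stats::quantile(z[run_start:run_end], 0.9, names = FALSE))
  if (!is.finite(p) || p <= 0) return(times[run_end + 1L])
  # last sample at/above the upper level within/after the run
  jb <- run_end
  while (jb > run_start && z[jb] < 0.75 * p) jb <- jb - 1L
  t_b <- crossing_after(times, z, 0.75 * p, jb)
  t_a <- crossing_after(times, z, 0.25 * p, jb)
  if (is.na(t_b)) return(times[run_end + 1L])
  if (is.na(t_a) || t_a <= t_b) return(t_b)
  t_b - 0.5 * (t_a - t_b)
}

#' Derive a quiescence call from classified state segments
#'
#' Locates the post-mitotic double-positive window (the first `DP` episode
#' entered from `V_ONLY` after a trace start in `DN`/`V_ONLY`), measures
#' its duration with sub-frame event refinement, and derives the
#' spontaneous / transient G0 calls. A `DP` window still open at the trace
#' end is censored: it yields a spontaneous call only when the observed
#' dwell already exceeds the spontaneous threshold, and is otherwise
#' undetermined. Traces with order violations, or that start mid-cycle
#' (already expressing at the first sample), are withheld with a reason.
#'
#' @param segs A `state_segments` object from [segment_states()].
#' @param config A [classifier_config()].
#' @param censored_at End of observation in hours (defaults to the trace
#'   end).
#' @return An object of class `cell_cycle_call`: a list with fields
#'   `track_id`, `classifiable`, `reason`, `dp_start_h`, `dp_duration_h`,
#'   `censored_dp`, `spontaneous_g0`, `transient_g0`, `g1_entry_h`,
#'   `g1_exit_h`, `final_state`, `start_h`, `end_h`.
#' @export
call_cell_cycle <- function(segs, config = classifier_config(),
                            censored_at = NULL) {
  stopifnot(inherits(segs, "state_segments"))
  times <- segs$times
  n <- length(times)
  dt <- if (n > 1L) times[2] - times[1] else 0.5
  if (is.null(censored_at)) censored_at <- times[n] + dt
  out <- list(track_id = segs$track_id,
              parent_track_id = segs$parent_track_id,
              start_h = times[1], end_h = censored_at,
              classifiable = FALSE, reason = "",
              dp_start_h = NA_real_, dp_duration_h = NA_real_,
              censored_dp = FALSE, spontaneous_g0 = NA,
              transient_g0 = NA, g1_entry_h = NA_real_,
              g1_exit_h = NA_real_, final_state = segs$final_state,
              order_violation = segs$order_violation)
  class(out) <- "cell_cycle_call"
  fail <- function(reason) { out$reason <- reason; out }

  if (segs$order_violation) return(fail("order_violation"))
  rv <- rle(as.logical(segs$on_venus))
  rc <- rle(as.logical(segs$on_cherry))
  v_on_runs <- run_table(rv)
  c_on_runs <- run_table(rc)
  v_on_runs <- v_on_runs[v_on_runs$value, , drop = FALSE]
  c_on_runs <- c_on_runs[c_on_runs$value, , drop = FALSE]
  if (nrow(v_on_runs) == 0L) return(fail("no_venus_expression"))
  vrun <- v_on_runs[1L, ]
  if (vrun$start == 1L) return(fail("expressing_at_start"))
  if (nrow(c_on_runs) == 0L) {
    out$censored_dp <- vrun$end == n
    return(fail("no_dp_observed"))
  }
  crun <- c_on_runs[1L, ]
  if (crun$start <= vrun$start) return(fail("expressing_at_start"))
  if (crun$start > vrun$end) return(fail("no_dp_observed"))

  dp_start <- refine_onset(times, segs$z_cherry, crun$start, crun$end)
  venus_fall <- refine_fall_start(times, segs$z_venus, vrun$start, vrun$end)
  censored_dp <- vrun$end == n && is.na(venus_fall)
  dp_end <- if (censored_dp) censored_at else venus_fall
  dp_dur <- dp_end - dp_start
  if (!is.finite(dp_dur) || dp_dur < 0) return(fail("degenerate_dp"))

  cmp <- if (config$strict_threshold) `>` else `>=`
  out$classifiable <- TRUE
  out$reason <- "ok"
  out$dp_start_h <- dp_start
  out$dp_duration_h <- dp_dur
  out$censored_dp <- censored_dp
  out$spontaneous_g0 <- cmp(dp_dur, config$spontaneous_threshold_h)
  if (!censored_dp) {
    out$g1_entry_h <- dp_end
    out$g1_exit_h <- refine_fall_start(times, segs$z_cherry, crun$start,
                                       crun$end)
    out$transient_g0 <- !out$spontaneous_g0 &&
      cmp(dp_dur, config$transient_threshold_h)
  } else {
    out$transient_g0 <- FALSE
    if (!out$spontaneous_g0) {
      # censored while <= threshold: undetermined, excluded from fractions
      out$classifiable <- FALSE
      out$reason <- "censored_dp_undetermined"
      out$spontaneous_g0 <- NA
      out$transient_g0 <- NA
    }
  }
  out
}

run_table <- function(r) {
  ends <- cumsum(r$lengths)
  data.frame(value = r$values, start = ends - r$lengths + 1L, end = ends)
}

#' @export
print.cell_cycle_call <- function(x, ...) {
  if (!x$classifiable) {
    cat(sprintf("Cell-cycle call (track %s): not classifiable (%s)\n",
                as.character(x$track_id), x$reason))
  } else {
    cat(sprintf(
      "Cell-cycle call (track %s): DP %.2f h%s | spontaneous G0: %s | G1 entry: %s\n",
      as.character(x$track_id), x$dp_duration_h,
      if (x$censored_dp) " (censored)" else "",
      x$spontaneous_g0,
      if (is.na(x$g1_entry_h)) "none" else sprintf("%.2f h", x$g1_entry_h)))
  }
  invisible(x)
}

#' Classify a reporter trace end to end
#'
#' Convenience wrapper: [segment_states()] then [call_cell_cycle()].
#'
#' @param trace A `reporter_trace`.
#' @param config A [classifier_config()].
#' @return A `cell_cycle_call` (with `classifiable = FALSE` and a reason
#'   when the trace cannot be classified).
#' @export
classify_trace <- function(trace, config = classifier_config()) {
  segs <- segment_states(trace, config)
  if (is.null(segs)) {
    out <- list(track_id = attr(trace, "track_id"),
                parent_track_id = attr(trace, "parent_track_id"),
                start_h = if (nrow(trace)) trace$t_h[1] else NA_real_,
                end_h = if (nrow(trace)) trace$t_h[nrow(trace)] else NA_real_,
                classifiable = FALSE, reason = "too_short",
                dp_start_h = NA_real_, dp_duration_h = NA_real_,
                censored_dp = FALSE, spontaneous_g0 = NA, transient_g0 = NA,
                g1_entry_h = NA_real_, g1_exit_h = NA_real_,
                final_state = NA_character_, order_violation = NA)
    class(out) <- "cell_cycle_call"
    return(out)
  }
  call_cell_cycle(segs, config)
}

#' Classify a list of traces into a calls table
#'
#' @param traces List of `reporter_trace` objects.
#' @param config A [classifier_config()].
#' @return A data frame with one row per trace and the `cell_cycle_call`
#'   fields as columns.
#' @export
classify_traces <- function(traces, config = classifier_config()) {
  if (!length(traces)) {
    return(data.frame(track_id = character(), parent_track_id = character(),
                      start_h = numeric(), end_h = numeric(),
                      classifiable = logical(), reason = character(),
                      dp_start_h = numeric(), dp_duration_h = numeric(),
                      censored_dp = logical(), spontaneous_g0 = logical(),
                      transient_g0 = logical(), g1_entry_h = numeric(),
                      g1_exit_h = numeric(), final_state = character(),
                      order_violation = logical()))
  }
  calls <- lapply(traces, classify_trace, config = config)
  fields <- c("track_id", "parent_track_id", "start_h", "end_h",
              "classifiable", "reason", "dp_start_h", "dp_duration_h",
              "censored_dp", "spontaneous_g0", "transient_g0",
              "g1_entry_h", "g1_exit_h", "final_state", "order_violation")
  as.data.frame(stats::setNames(lapply(fields, function(f) {
    vals <- lapply(calls, function(cl) {
      v <- cl[[f]]
      if (is.null(v) || length(v) != 1L) NA else v
    })
    unlist(vals, use.names = FALSE)
  }), fields), stringsAsFactors = FALSE)
}
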