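#' Classify the proliferation-quiescence decision of a daughter pair
#'
#' Categories follow the decision taxonomy for two daughters born of a
#' single mitosis: `SYNC_G0` (both spontaneous / censored-prolonged G0),
#' `SYNC_G1` (both entered G1 with entry times within the synchrony
#' tolerance), `ASYNC` (exactly one entered G1 while its sibling stayed in
#' prolonged G0, or both entered with a difference beyond tolerance) and
#' `UNDETERMINED` (either daughter unclassifiable). When one daughter
#' entered and the sibling never did, asynchrony is only declared if the
#' sibling was genuinely observed to stay double positive: it must have
#' dwelt in DP at least the transient threshold when its sister entered
#' G1, and (when `observation_h` is known) its trace must reach the end of
#' the observation — a sibling track lost mid-movie says nothing about its
#' fate, and scoring such dropouts would inflate the asynchrony fraction.
#'
#' @param call_d1,call_d2 `cell_cycle_call` objects (or single rows of a
#'   calls table) for the two daughters; both must share a parent.
#' @param config A [classifier_config()].
#' @param division_time_h Division time in hours (defaults to the earliest
#'   daughter track start).
#' @param observation_h Total observation span (movie duration) in hours;
#'   used to distinguish movie-end censoring from track loss.
#' @return A list of class `daughter_pair_call`: `parent_track_id`,
#'   `category`, `delta_g1_entry_h` (present when both entered),
#'   `censored_delta` (TRUE when one daughter never entered within
#'   observation), `division_time_h`.
#' @export
classify_daughter_pair <- function(call_d1, call_d2,
                                   config = classifier_config(),
                                   division_time_h = NULL,
                                   observation_h = NULL) {
  d1 <- as.list(call_d1); d2 <- as.list(call_d2)
  p1 <- d1$parent_track_id; p2 <- d2$parent_track_id
  if (is.null(p1) || is.null(p2) || is.na(p1) || is.na(p2) || p1 != p2) {
    stop("daughter calls do not share a parent track", call. = FALSE)
  }
  if (is.null(division_time_h)) {
    division_time_h <- min(d1$start_h, d2$start_h, na.rm = TRUE)
  }
  out <- list(parent_track_id = p1, category = "UNDETERMINED",
              delta_g1_entry_h = NA_real_, censored_delta = FALSE,
              division_time_h = division_time_h)
  class(out) <- "daughter_pair_call"

  entered <- function(d) isTRUE(d$classifiable) && !is.na(d$g1_entry_h)
  spont <- function(d) isTRUE(d$classifiable) && isTRUE(d$spontaneous_g0)

  if (spont(d1) && spont(d2)) {
    out$category <- "SYNC_G0"
    return(out)
  }
  if (entered(d1) && entered(d2)) {
    delta <- abs(d1$g1_entry_h - d2$g1_entry_h)
    out$delta_g1_entry_h <- delta
    out$category <- if (spont(d1) || spont(d2)) "ASYNC"
                    else if (delta <= config$sync_tolerance_h) "SYNC_G1"
                    else "ASYNC"
    return(out)
  }
  one_in <- if (entered(d1)) d1 else if (entered(d2)) d2 else NULL
  other <- if (entered(d1)) d2 else d1
  observed_to_end <- function(d) {
    is.null(observation_h) ||
      (!is.na(d$end_h) && d$end_h >= observation_h - 1)
  }
  if (!is.null(one_in)) {
    # a sibling with a proven dwell beyond the spontaneous threshold is
    # asynchrony evidence even if its track was lost afterwards
    if (spont(other)) {
      out$category <- "ASYNC"
      out$censored_delta <- TRUE
      return(out)
    }
    # sibling censored without a call: it must have been in DP at least
    # transient_threshold_h when the entering daughter left G0, and its
    # trace must reach the movie end (not a mid-movie track loss)
    if (identical(other$reason, "censored_dp_undetermined") &&
        observed_to_end(other) &&
        !is.na(other$dp_start_h) &&
        one_in$g1_entry_h - other$dp_start_h >= config$transient_threshold_h) {
      out$category <- "ASYNC"
      out$censored_delta <- TRUE
      return(out)
    }
  }
  out
}

#' @export
print.daughter_pair_call <- function(x, ...) {
  cat(sprintf("Daughter pair (parent %s): %s%s\n",
              as.character(x$parent_track_id), x$category,
              if (!is.na(x$delta_g1_entry_h))
                sprintf(", delta G1 entry %.2f h", x$delta_g1_entry_h)
              else ""))
  invisible(x)
}

#' G1-entry time difference of an asynchronous pair
#'
#' @param pair A `daughter_pair_call` (or row of a pairs table).
#' @return The delta in hours for `ASYNC` pairs where both daughters
#'   entered G1; `NA` otherwise (a censored delta — one daughter never
#'   entered within observation — is reported as `NA` with the pair's
#'   `censored_delta` flag set).
#' @export
asynchrony_delta <- function(pair) {
  pair <- as.list(pair)
  if (!identical(pair$category, "ASYNC")) return(NA_real_)
  if (isTRUE(pair$censored_delta)) return(NA_real_)
  pair$delta_g1_entry_h
}

#' Score all daughter pairs in a calls table
#'
#' @param calls Calls data frame from [classify_traces()].
#' @param config A [classifier_config()].
#' @return Data frame of `daughter_pair_call` fields, one row per parent
#'   with exactly two daughter calls.
#' @export
pair_calls <- function(calls, config = classifier_config(),
                       observation_h = NULL) {
  empty <- data.frame(parent_track_id = integer(), category = character(),
                      delta_g1_entry_h = numeric(),
                      censored_delta = logical(),
                      division_time_h = numeric())
  if (!nrow(calls)) return(empty)
  kids <- calls[!is.na(calls$parent_track_id), , drop = FALSE]
  if (!nrow(kids)) return(empty)
  out <- list()
  for (p in sort(unique(kids$parent_track_id))) {
    ds <- kids[kids$parent_track_id == p, , drop = FALSE]
    if (nrow(ds) != 2L) next
    pc <- classify_daughter_pair(ds[1L, ], ds[2L, ], config,
                                 observation_h = observation_h)
    out[[length(out) + 1L]] <- data.frame(
      parent_track_id = pc$parent_track_id, category = pc$category,
      delta_g1_entry_h = pc$delta_g1_entry_h,
      censored_delta = pc$censored_delta,
      division_time_h = pc$division_time_h)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Population-level quiescence summary
#'
#' Aggregates per-cell calls and daughter-pair calls into the headline
#' population statistics. The spontaneous-G0 percentage is computed over
#' classifiable post-mitotic cells (known parent, scorable call, first
#' observed early enough that a prolonged dwell could have been measured;
#' see [classifier_config()]'s `min_classifiable_window_h`); cells still
#' double positive at censoring count as spontaneous only when their
#' observed dwell already exceeds the threshold.
#'
#' @param calls Calls data frame from [classify_traces()].
#' @param pairs Pairs data frame from [pair_calls()] (optional).
#' @param config A [classifier_config()].
#' @param observation_h Total observation span in hours (defaults to the
#'   latest call end).
#' @param min_division_obs_h Minimum observation window for a track to
#'   enter the percent-divided denominator (default 24 h).
#' @return An object of class `population_summary` (a list; see fields in
#'   the examples / vignette).
#' @export
summarize_population <- function(calls, pairs = NULL,
                                 config = classifier_config(),
                                 observation_h = NULL,
                                 min_division_obs_h = 24) {
  if (is.null(pairs)) pairs <- pair_calls(calls, config)
  if (!nrow(calls)) {
    return(structure(list(n_tracked = 0L, n_divided = 0L,
                          percent_divided = NA_real_,
                          n_classifiable_postmitotic = 0L,
                          percent_spontaneous_g0 = NA_real_,
                          percent_transient_g0 = NA_real_,
                          dp_durations_h = numeric(),
                          division_times_h = numeric(),
                          pair_counts = c(SYNC_G0 = 0L, SYNC_G1 = 0L,
                                          ASYNC = 0L, UNDETERMINED = 0L),
                          percent_async_pairs = NA_real_,
                          observation_h = observation_h),
                     class = "population_summary"))
  }
  if (is.null(observation_h)) observation_h <- max(calls$end_h, na.rm = TRUE)
  eligible_start <- observation_h - config$min_classifiable_window_h
  postmitotic <- !is.na(calls$parent_track_id)
  scorable <- postmitotic & calls$classifiable %in% TRUE &
    calls$start_h <= eligible_start
  dp <- calls$dp_duration_h[scorable]
  spont <- calls$spontaneous_g0[scorable]
  trans <- calls$transient_g0[scorable]

  parents <- unique(calls$parent_track_id[postmitotic])
  denom_div <- sum(calls$start_h <= observation_h - min_division_obs_h,
                   na.rm = TRUE)
  n_div <- length(parents)

  cats <- factor(pairs$category,
                 levels = c("SYNC_G0", "SYNC_G1", "ASYNC", "UNDETERMINED"))
  pair_counts <- table(cats)
  scored_pairs <- sum(pair_counts[c("SYNC_G0", "SYNC_G1", "ASYNC")])

  structure(list(
    n_tracked = nrow(calls),
    n_divided = n_div,
    percent_divided = if (denom_div > 0) 100 * n_div / denom_div
                      else NA_real_,
    n_classifiable_postmitotic = sum(scorable),
    percent_spontaneous_g0 = if (sum(scorable) > 0)
      100 * mean(spont %in% TRUE) else NA_real_,
    percent_transient_g0 = if (sum(scorable) > 0)
      100 * mean(trans %in% TRUE) else NA_real_,
    dp_durations_h = as.numeric(dp),
    division_times_h = as.numeric(pairs$division_time_h),
    pair_counts = stats::setNames(as.integer(pair_counts),
                                  names(pair_counts)),
    percent_async_pairs = if (scored_pairs > 0)
      100 * as.integer(pair_counts[["ASYNC"]]) / scored_pairs
      else NA_real_,
    observation_h = observation_h),
    class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat("Population summary\n")
  cat(sprintf("  tracked cells            %d\n", x$n_tracked))
  cat(sprintf("  divisions                %d (%.1f%% of eligible tracks)\n",
              x$n_divided,
              ifelse(is.na(x$percent_divided), NA, x$percent_divided)))
  cat(sprintf("  classifiable post-mitotic %d\n",
              x$n_classifiable_postmitotic))
  cat(sprintf("  spontaneous G0           %.1f%%\n",
              x$percent_spontaneous_g0))
  cat(sprintf("  transient G0             %.1f%%\n",
              x$percent_transient_g0))
  cat(sprintf("  pairs  sync-G0 %d | sync-G1 %d | async %d | undet. %d\n",
              x$pair_counts[["SYNC_G0"]], x$pair_counts[["SYNC_G1"]],
              x$pair_counts[["ASYNC"]], x$pair_counts[["UNDETERMINED"]]))
  cat(sprintf("  asynchronous pairs       %.1f%%\n",
              x$percent_async_pairs))
  invisible(x)
}

#' Compare two dwell-time distributions (Mann-Whitney U)
#'
#' Wilcoxon rank-sum / Mann-Whitney U test: exact two-sided p by
#' enumeration when both samples have at most 20 observations and no ties,
#' otherwise the normal approximation with midrank tie correction and
#' continuity correction (via [stats::wilcox.test()]).
#'
#' @param durations_a,durations_b Numeric samples (hours), each non-empty.
#' @param exact_max Sample-size cutoff for the exact test.
#' @return List with `U` (for sample `a`), `p_value`, `n_a`, `n_b`,
#'   `method`.
#' @export
compare_duration_distributions <- function(durations_a, durations_b,
                                           exact_max = 20) {
  if (!length(durations_a) || !length(durations_b)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(durations_a, durations_b)) > 0L
  use_exact <- length(durations_a) <= exact_max &&
    length(durations_b) <= exact_max && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(durations_a, durations_b, exact = use_exact,
                       correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       n_a = length(durations_a), n_b = length(durations_b),
       method = if (use_exact) "exact" else "normal approximation")
}

#' Histogram of division times
#'
#' @param division_times_h Division times in hours.
#' @param window_h Bin width in hours; must divide the observation span.
#' @param observation_h Observation span (default: ceiling of the data to a
#'   whole window).
#' @return Data frame with `bin_start_h`, `bin_end_h`, `count`.
#' @export
division_timing_profile <- function(division_times_h, window_h,
                                    observation_h = NULL) {
  stopifnot(window_h > 0)
  if (is.null(observation_h)) {
    observation_h <- if (length(division_times_h))
      ceiling(max(division_times_h) / window_h) * window_h else window_h
  }
  if (abs(observation_h / window_h - round(observation_h / window_h)) >
      1e-9) {
    stop("window_h must divide the observation span", call. = FALSE)
  }
  breaks <- seq(0, observation_h, by = window_h)
  cnt <- if (length(division_times_h)) {
    as.integer(table(cut(division_times_h, breaks, right = FALSE,
                         include.lowest = TRUE)))
  } else {
    rep(0L, length(breaks) - 1L)
  }
  data.frame(bin_start_h = breaks[-length(breaks)],
             bin_end_h = breaks[-1L], count = cnt)
}
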