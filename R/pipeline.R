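#' Run the full analysis pipeline on a two-channel movie
#'
#' segment -> track -> divisions -> traces -> classify -> pairs ->
#' summarize. Each stage's output is returned so stages can be inspected
#' or rerun independently; the whole chain is a pure function of the movie
#' and parameters.
#'
#' The classifier's absolute signal floor is set adaptively per channel to
#' `min_signal_frac` of the pooled 99th-percentile trace intensity, so
#' basal-only (double-negative) phases and reporter-silent cells are never
#' scored as "on" however the per-trace normalization scales them.
#'
#' @param movie A `reporter_movie` (from [render_movie()] or
#'   [read_movie_tiff()]).
#' @param seg_params A [segmentation_params()].
#' @param track_params A [tracking_params()] (its `division_radius`
#'   defaults from the movie's `psf_sigma`).
#' @param config A [classifier_config()].
#' @param min_signal_frac Adaptive signal-floor fraction (see above).
#' @return An object of class `pipeline_result`: list with `detections`,
#'   `tracks`, `traces`, `calls`, `pairs`, `summary`, and the parameter
#'   objects used.
#' @export
run_pipeline <- function(movie,
                         seg_params = segmentation_params(),
                         track_params = NULL,
                         config = classifier_config(),
                         min_signal_frac = 0.1) {
  stopifnot(inherits(movie, "reporter_movie"))
  psf <- if (!is.null(movie$spec$psf_sigma)) movie$spec$psf_sigma else 3
  if (is.null(track_params)) track_params <- tracking_params(psf_sigma = psf)
  detections <- segment_movie(movie, seg_params, psf)
  tracks <- detect_divisions(link_detections(detections, track_params))
  traces <- extract_traces(tracks, movie$spec$frame_interval_h)
  config <- adapt_min_signal(config, traces, min_signal_frac)
  calls <- classify_traces(traces, config)
  pairs <- pair_calls(calls, config, observation_h = movie$spec$duration_h)
  summary <- summarize_population(calls, pairs, config,
                                  observation_h = movie$spec$duration_h)
  structure(list(detections = detections, tracks = tracks, traces = traces,
                 calls = calls, pairs = pairs, summary = summary,
                 seg_params = seg_params, track_params = track_params,
                 config = config),
            class = "pipeline_result")
}

adapt_min_signal <- function(config, traces, min_signal_frac) {
  if (min_signal_frac <= 0 || !length(traces)) return(config)
  all_v <- unlist(lapply(traces, function(tr) tr$venus), use.names = FALSE)
  all_c <- unlist(lapply(traces, function(tr) tr$cherry), use.names = FALSE)
  fl <- function(x) {
    if (!length(x)) return(config$min_signal[[1]])
    min_signal_frac * as.numeric(stats::quantile(x, 0.99, names = FALSE))
  }
  config$min_signal <- c(max(config$min_signal[[1]], fl(all_v)),
                         max(config$min_signal[[length(config$min_signal)]],
                             fl(all_c)))
  config
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result: %d detections -> %d tracks -> %d calls\n",
              nrow(x$detections), length(x$tracks$tracks), nrow(x$calls)))
  print(x$summary)
  invisible(x)
}

#' Simulated parameter-recovery experiment
#'
#' Simulates `n_founders` cells under a named condition profile as a set
#' of independent fields of view, renders each field into a noisy
#' two-channel movie, runs the full pipeline on the movies (which never see
#' the ground truth), and pools the per-cell calls and daughter-pair calls.
#'
#' @param profile A [kinetic_profile()] or profile name for
#'   [quiescence_profile()].
#' @param n_founders Total founder cells across all fields.
#' @param seed Integer seed; field f uses sub-seed `seed * 1000 + f`.
#' @param founders_per_movie Founders per field of view.
#' @param spec A [movie_spec()] for each field.
#' @param config,seg_params,track_params Pipeline parameters.
#' @return List with pooled `calls`, `pairs`, `summary`, and `n_movies`.
#' @export
run_recovery_experiment <- function(profile, n_founders, seed = 1,
                                    founders_per_movie = 16,
                                    spec = movie_spec(),
                                    config = classifier_config(),
                                    seg_params = segmentation_params(),
                                    track_params = NULL) {
  if (is.character(profile)) profile <- quiescence_profile(profile)
  n_movies <- ceiling(n_founders / founders_per_movie)
  calls <- list(); pairs <- list()
  left <- n_founders
  for (f in seq_len(n_movies)) {
    nf <- min(founders_per_movie, left); left <- left - nf
    sub_seed <- (seed * 1000 + f) %% .Machine$integer.max
    lin <- simulate_population(profile, nf, spec, seed = sub_seed)
    mov <- render_movie(lin, spec, seed = sub_seed + 1)
    res <- run_pipeline(mov, seg_params, track_params, config)
    if (nrow(res$calls)) {
      res$calls$track_id <- paste0("m", f, "_", res$calls$track_id)
      res$calls$parent_track_id <-
        ifelse(is.na(res$calls$parent_track_id), NA,
               paste0("m", f, "_", res$calls$parent_track_id))
      calls[[f]] <- res$calls
    }
    if (nrow(res$pairs)) {
      res$pairs$parent_track_id <- paste0("m", f, "_",
                                          res$pairs$parent_track_id)
      pairs[[f]] <- res$pairs
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    classify_traces(list())
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    pair_calls(calls, config)
  summary <- summarize_population(calls, pairs, config,
                                  observation_h = spec$duration_h)
  list(calls = calls, pairs = pairs, summary = summary,
       n_movies = n_movies, profile = profile)
}

#' Reporter-state snapshot of a simulated cohort
#'
#' Image-free study: simulates a cohort, samples traces on the frame grid
#' (with optional measurement noise), classifies each trace's state
#' sequence, and reports the percentage of end-of-movie survivors in each
#' state at the final frame.
#'
#' @param profile Profile or profile name.
#' @param n_cells Number of founder cells.
#' @param seed Integer seed.
#' @param spec A [movie_spec()].
#' @param noise_sd Trace measurement noise (intensity-fraction scale).
#' @param config A [classifier_config()]; its `min_signal` should exceed
#'   the noise floor (default 0.05 here).
#' @return List with `percent_by_state` (named percentages over final-frame
#'   survivors), `n` (number of survivors), `calls` (full calls table).
#' @export
snapshot_state_fractions <- function(profile, n_cells, seed = 1,
                                     spec = movie_spec(),
                                     noise_sd = 0.02,
                                     config = classifier_config(
                                       min_signal = 0.05)) {
  if (is.character(profile)) profile <- quiescence_profile(profile)
  lin <- simulate_population(profile, n_cells, spec, seed = seed,
                             with_positions = FALSE)
  traces <- simulate_traces(lin, noise_sd = noise_sd, seed = seed + 1)
  final_t <- max(frame_times(spec))
  at_end <- vapply(traces, function(tr) {
    abs(tr$t_h[nrow(tr)] - final_t) < 1e-9
  }, logical(1))
  traces <- traces[at_end]
  calls <- classify_traces(traces, config)
  st <- factor(calls$final_state, levels = STATE_LEVELS)
  n <- sum(!is.na(st))
  pct <- if (n > 0) 100 * as.numeric(table(st)) / n else rep(NA_real_, 4)
  list(percent_by_state = stats::setNames(pct, STATE_LEVELS), n = n,
       calls = calls)
}

# ---- evaluation against ground truth -------------------------------------

#' Match detections to ground-truth centroids
#'
#' Greedy nearest-neighbour matching per frame within a tolerance radius.
#'
#' @param detections Detections data frame.
#' @param truth Ground-truth per-frame table (`frame`, `cell_id`, `x`,
#'   `y`).
#' @param tol Match radius in pixels.
#' @return Data frame with one row per matched detection: `frame_index`,
#'   detection row (`det_row`), `cell_id`, `dist`.
#' @export
match_detections_to_truth <- function(detections, truth, tol = 3) {
  out <- list()
  for (f in sort(unique(detections$frame_index))) {
    di <- which(detections$frame_index == f)
    ti <- which(truth$frame == f)
    if (!length(di) || !length(ti)) next
    d <- dist_matrix(detections$x[di], detections$y[di],
                     truth$x[ti], truth$y[ti])
    repeat {
      m <- which.min(d)
      if (!length(m) || d[m] > tol) break
      i <- (m - 1L) %% nrow(d) + 1L
      j <- (m - 1L) %/% nrow(d) + 1L
      out[[length(out) + 1L]] <- data.frame(
        frame_index = f, det_row = di[i], cell_id = truth$cell_id[ti[j]],
        dist = d[m])
      d[i, ] <- Inf; d[, j] <- Inf
    }
  }
  if (!length(out)) {
    return(data.frame(frame_index = integer(), det_row = integer(),
                      cell_id = integer(), dist = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detection and tracking fidelity against ground truth
#'
#' `detection_scores()` reports recall and precision of per-frame
#' detections (match = centroid within `tol` pixels).
#' `link_accuracy()` reports the fraction of consecutive within-track
#' links that connect detections matched to the same ground-truth cell.
#' `division_recovery()` reports the fraction of true divisions for which
#' a parent track with exactly its two daughters was recovered.
#'
#' @param result A `pipeline_result`.
#' @param lineage The ground-truth `cell_lineage`.
#' @param tol Match radius in pixels.
#' @return A named list of scores.
#' @export
detection_scores <- function(result, lineage, tol = 3) {
  m <- match_detections_to_truth(result$detections, lineage$positions, tol)
  list(recall = nrow(m) / max(nrow(lineage$positions), 1L),
       precision = nrow(m) / max(nrow(result$detections), 1L),
       mean_localization_error = if (nrow(m)) mean(m$dist) else NA_real_)
}

#' @rdname detection_scores
#' @export
link_accuracy <- function(result, lineage, tol = 3) {
  m <- match_detections_to_truth(result$detections, lineage$positions, tol)
  id_of <- rep(NA_integer_, nrow(result$detections))
  id_of[m$det_row] <- m$cell_id
  good <- 0L; total <- 0L
  det <- result$detections
  for (tr in result$tracks$tracks) {
    if (length(tr) < 2L) next
    ids <- id_of[tr]
    fr <- det$frame_index[tr]
    consec <- which(diff(fr) == 1L)
    for (i in consec) {
      if (is.na(ids[i]) || is.na(ids[i + 1L])) next
      total <- total + 1L
      if (ids[i] == ids[i + 1L]) good <- good + 1L
    }
  }
  list(link_accuracy = if (total) good / total else NA_real_,
       n_links = total)
}

#' @rdname detection_scores
#' @export
division_recovery <- function(result, lineage, tol = 3) {
  m <- match_detections_to_truth(result$detections, lineage$positions, tol)
  id_of <- rep(NA_integer_, nrow(result$detections))
  id_of[m$det_row] <- m$cell_id
  det <- result$detections
  # majority ground-truth identity per track
  maj <- vapply(result$tracks$tracks, function(tr) {
    ids <- id_of[tr]
    ids <- ids[!is.na(ids)]
    if (!length(ids)) return(NA_integer_)
    as.integer(names(sort(table(ids), decreasing = TRUE))[1])
  }, integer(1))
  cells <- lineage$cells
  true_parents <- cells$cell_id[!is.na(cells$division_h)]
  # only divisions whose daughters actually appear in the movie
  recovered <- 0L; scored <- 0L
  parent_of <- result$tracks$parent
  for (p in true_parents) {
    kids <- cells$cell_id[!is.na(cells$parent_id) & cells$parent_id == p]
    if (length(kids) != 2L) next
    if (!all(kids %in% lineage$positions$cell_id)) next
    scored <- scored + 1L
    # find a recovered parent track whose two children map to the true kids
    cand <- which(!is.na(parent_of))
    by_parent <- split(cand, parent_of[cand])
    hit <- any(vapply(by_parent, function(ch) {
      length(ch) == 2L && setequal(stats::na.omit(maj[ch]), kids) &&
        identical(maj[parent_of[ch[1L]]], as.integer(p))
    }, logical(1)))
    if (hit) recovered <- recovered + 1L
  }
  list(division_recovery = if (scored) recovered / scored else NA_real_,
       n_true_divisions = scored)
}
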