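#' Stage input/output in plain-text formats
#'
#' Every pipeline stage reads and writes flat CSV (plus YAML/JSON for
#' summaries), so stages can be rerun independently and inspected with
#' ordinary tools. Writers return the path invisibly.
#'
#' @param detections,tracks,calls,pairs Stage outputs (see
#'   [segment_movie()], [link_detections()], [classify_traces()],
#'   [pair_calls()]).
#' @param path Output file path.
#' @param frame_interval_h Frame interval used to convert frames to hours.
#' @name stage_io
NULL

#' @rdname stage_io
#' @export
write_detections_csv <- function(detections, path) {
  utils::write.csv(detections, path, row.names = FALSE)
  invisible(path)
}

#' @rdname stage_io
#' @export
read_detections_csv <- function(path) {
  utils::read.csv(path)
}

#' @rdname stage_io
#' @export
write_tracks_csv <- function(tracks, path, frame_interval_h = 0.5) {
  stopifnot(inherits(tracks, "cell_tracks"))
  det <- tracks$detections
  rows <- lapply(seq_along(tracks$tracks), function(i) {
    tr <- tracks$tracks[[i]]
    if (!length(tr)) return(NULL)
    data.frame(track_id = i, frame_index = det$frame_index[tr],
               x = det$x[tr], y = det$y[tr],
               mean_venus = det$mean_venus[tr],
               mean_cherry = det$mean_cherry[tr],
               interpolated_flag = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname stage_io
#' @export
write_lineage_csv <- function(tracks, path) {
  stopifnot(inherits(tracks, "cell_tracks"))
  utils::write.csv(data.frame(track_id = seq_along(tracks$tracks),
                              parent_track_id = tracks$parent),
                   path, row.names = FALSE)
  invisible(path)
}

#' Rebuild reporter traces from a tracks CSV (plus optional lineage CSV)
#'
#' @param tracks_df Data frame as written by [write_tracks_csv()] (columns
#'   `track_id`, `frame_index`, `mean_venus`, `mean_cherry`).
#' @param lineage_df Optional data frame with `track_id`,
#'   `parent_track_id`.
#' @param frame_interval_h Frame interval in hours.
#' @return List of `reporter_trace` objects.
#' @export
traces_from_tracks_df <- function(tracks_df, lineage_df = NULL,
                                  frame_interval_h = 0.5) {
  parent_of <- function(id) {
    if (is.null(lineage_df)) return(NA)
    j <- match(id, lineage_df$track_id)
    if (is.na(j)) NA else lineage_df$parent_track_id[j]
  }
  ids <- sort(unique(tracks_df$track_id))
  lapply(ids, function(id) {
    sub <- tracks_df[tracks_df$track_id == id, , drop = FALSE]
    sub <- sub[order(sub$frame_index), , drop = FALSE]
    full <- seq(min(sub$frame_index), max(sub$frame_index))
    if (nrow(sub) > 1L) {
      mv <- stats::approx(sub$frame_index, sub$mean_venus, xout = full)$y
      mc <- stats::approx(sub$frame_index, sub$mean_cherry, xout = full)$y
    } else {
      mv <- sub$mean_venus
      mc <- sub$mean_cherry
    }
    new_reporter_trace(
      data.frame(t_h = full * frame_interval_h, venus = mv, cherry = mc,
                 interpolated = !(full %in% sub$frame_index)),
      track_id = id, parent_track_id = parent_of(id),
      start_h = min(sub$frame_index) * frame_interval_h)
  })
}

#' @rdname stage_io
#' @export
write_calls_csv <- function(calls, path) {
  utils::write.csv(calls, path, row.names = FALSE)
  invisible(path)
}

#' @rdname stage_io
#' @export
write_pairs_csv <- function(pairs, path) {
  utils::write.csv(pairs, path, row.names = FALSE)
  invisible(path)
}

#' Write a population summary as YAML (human) and JSON (machine)
#'
#' @param summary A `population_summary`.
#' @param path_yaml,path_json Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_summary <- function(summary, path_yaml = NULL, path_json = NULL) {
  stopifnot(inherits(summary, "population_summary"))
  x <- unclass(summary)
  x$pair_counts <- as.list(x$pair_counts)
  x$dp_durations_h <- round(as.numeric(x$dp_durations_h), 4)
  x$division_times_h <- round(as.numeric(x$division_times_h), 4)
  if (!is.null(path_yaml)) yaml::write_yaml(x, path_yaml)
  if (!is.null(path_json)) {
    jsonlite::write_json(x, path_json, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(c(path_yaml, path_json))
}
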