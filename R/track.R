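#' Tracking parameters
#'
#' @param max_displacement Maximum centroid displacement per frame (pixels)
#'   for a frame-to-frame link.
#' @param max_gap Maximum number of consecutive missed frames bridged by
#'   gap closing (default 4 frames, about 2 h at 0.5 h/frame — newborn
#'   cells are dim only briefly because Venus rises within a couple of
#'   hours of cytokinesis and a basal signal is present).
#' @param division_radius Maximum distance (pixels) between a parent's last
#'   position and a daughter's first position; default `4 * psf_sigma`.
#' @param min_track_len Tracks shorter than this many frames are excluded
#'   from downstream classification (still returned, flagged).
#' @param method `"hungarian"` (optimal assignment) or `"greedy"` (nearest
#'   neighbour, faster).
#' @param psf_sigma Spot sigma used for the `division_radius` default.
#' @return An object of class `tracking_params`.
#' @export
tracking_params <- function(max_displacement = 10, max_gap = 4,
                            division_radius = NULL, min_track_len = 6,
                            method = c("hungarian", "greedy"),
                            psf_sigma = 3) {
  method <- match.arg(method)
  if (max_displacement <= 0 || max_gap < 0 || min_track_len < 1) {
    stop("invalid tracking parameters", call. = FALSE)
  }
  if (is.null(division_radius)) division_radius <- 4 * psf_sigma
  stopifnot(division_radius > 0)
  structure(list(max_displacement = max_displacement,
                 max_gap = as.integer(max_gap),
                 division_radius = division_radius,
                 min_track_len = as.integer(min_track_len),
                 method = method),
            class = "tracking_params")
}

#' Link detections across frames into tracks
#'
#' Frame-to-frame one-to-one assignment minimizing total centroid distance
#' (Hungarian-style optimal assignment via `clue::solve_LSAP`; ties broken
#' toward lower detection label), with links above `max_displacement`
#' rejected, followed by gap closing: a track end may be joined to a later
#' track start within `max_gap` missed frames and
#' `max_displacement * gap` distance. Deterministic.
#'
#' @param detections Detections data frame from [segment_movie()].
#' @param params A [tracking_params()].
#' @return An object of class `cell_tracks`: list with `tracks` (list of
#'   integer row-index vectors into `detections`, ordered by frame),
#'   `parent` (integer vector of parent track ids, `NA` for roots, filled
#'   by [detect_divisions()]), `detections`, `params`.
#' @export
link_detections <- function(detections, params = tracking_params()) {
  stopifnot(is.data.frame(detections))
  if (!inherits(params, "tracking_params")) {
    stop("params must be tracking_params()", call. = FALSE)
  }
  n <- nrow(detections)
  tracks <- list()
  if (n > 0L) {
    frames <- sort(unique(detections$frame_index))
    open_track <- integer(0)   # track id for each open tail
    open_rows <- integer(0)    # detection row of each tail
    open_frame <- integer(0)
    for (f in frames) {
      rows_f <- which(detections$frame_index == f)
      rows_f <- rows_f[order(detections$label[rows_f])]
      # only tails from the immediately preceding frame participate in
      # frame-to-frame linking; older tails are left for gap closing
      active <- which(open_frame == f - 1L)
      assign_to <- rep(NA_integer_, length(rows_f))
      if (length(active) && length(rows_f)) {
        d <- dist_matrix(detections$x[open_rows[active]],
                         detections$y[open_rows[active]],
                         detections$x[rows_f], detections$y[rows_f])
        pair <- solve_links(d, params$max_displacement, params$method)
        assign_to[pair[, 2L]] <- active[pair[, 1L]]
      }
      for (k in seq_along(rows_f)) {
        r <- rows_f[k]
        if (!is.na(assign_to[k])) {
          ti <- open_track[assign_to[k]]
          tracks[[ti]] <- c(tracks[[ti]], r)
          open_rows[assign_to[k]] <- r
          open_frame[assign_to[k]] <- f
        } else {
          tracks[[length(tracks) + 1L]] <- r
          open_track <- c(open_track, length(tracks))
          open_rows <- c(open_rows, r)
          open_frame <- c(open_frame, f)
        }
      }
    }
    tracks <- close_gaps(tracks, detections, params)
  }
  structure(list(tracks = tracks,
                 parent = rep(NA_integer_, length(tracks)),
                 detections = detections, params = params),
            class = "cell_tracks")
}

dist_matrix <- function(x1, y1, x2, y2) {
  sqrt(outer(x1, x2, "-")^2 + outer(y1, y2, "-")^2)
}

# returns a 2-column matrix (row of d, col of d) of accepted links
solve_links <- function(d, max_disp, method) {
  n1 <- nrow(d); n2 <- ncol(d)
  if (method == "greedy") {
    pairs <- matrix(integer(0), 0, 2)
    dd <- d
    repeat {
      m <- which.min(dd)
      if (!length(m) || dd[m] > max_disp) break
      i <- (m - 1L) %% n1 + 1L
      j <- (m - 1L) %/% n1 + 1L
      pairs <- rbind(pairs, c(i, j))
      dd[i, ] <- Inf; dd[, j] <- Inf
      if (all(!is.finite(dd))) break
    }
    return(pairs)
  }
  big <- 1e6
  nn <- n1 + n2
  C <- matrix(big, nn, nn)
  # tiny label-ordered epsilon makes equal-distance ties deterministic
  eps <- outer(rep(1e-9, n1), seq_len(n2))
  C[seq_len(n1), seq_len(n2)] <- ifelse(d <= max_disp, d + eps, big)
  for (i in seq_len(n1)) C[i, n2 + i] <- max_disp + 1
  for (j in seq_len(n2)) C[n1 + j, j] <- max_disp + 1
  C[(n1 + 1):nn, (n2 + 1):nn] <- 0
  sol <- as.integer(clue::solve_LSAP(C))
  keep <- which(seq_len(n1) <= n1 & sol[seq_len(n1)] <= n2 &
                  d[cbind(seq_len(n1), pmin(sol[seq_len(n1)], n2))] <=
                  max_disp)
  cbind(keep, sol[keep])
}

close_gaps <- function(tracks, detections, params) {
  if (length(tracks) < 2L || params$max_gap < 1L) return(tracks)
  info <- track_endpoints(tracks, detections)
  last_frame <- max(detections$frame_index)
  cand <- list()
  for (e in seq_along(tracks)) {
    if (info$end_frame[e] >= last_frame) next
    for (s in seq_along(tracks)) {
      if (s == e) next
      g <- info$start_frame[s] - info$end_frame[e]
      if (g < 2L || g - 1L > params$max_gap) next
      dd <- sqrt((info$end_x[e] - info$start_x[s])^2 +
                   (info$end_y[e] - info$start_y[s])^2)
      if (dd <= params$max_displacement * g) {
        cand[[length(cand) + 1L]] <- c(e, s, dd)
      }
    }
  }
  if (!length(cand)) return(tracks)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand[, 3L], cand[, 1L], cand[, 2L]), , drop = FALSE]
  used_end <- logical(length(tracks)); used_start <- logical(length(tracks))
  redirect <- seq_along(tracks) # where each track's content now lives
  resolve <- function(x) { while (redirect[x] != x) x <- redirect[x]; x }
  for (k in seq_len(nrow(cand))) {
    e <- cand[k, 1L]; s <- cand[k, 2L]
    if (used_end[e] || used_start[s]) next
    er <- resolve(e)
    if (er == s) next
    tracks[[er]] <- c(tracks[[er]], tracks[[s]])
    tracks[[s]] <- integer(0)
    redirect[s] <- er
    used_end[e] <- TRUE; used_start[s] <- TRUE
  }
  tracks[lengths(tracks) > 0L]
}

track_endpoints <- function(tracks, detections) {
  first <- vapply(tracks, function(tr) tr[1L], integer(1))
  last <- vapply(tracks, function(tr) tr[length(tr)], integer(1))
  list(start_frame = detections$frame_index[first],
       end_frame = detections$frame_index[last],
       start_x = detections$x[first], start_y = detections$y[first],
       end_x = detections$x[last], end_y = detections$y[last])
}

#' Detect cell divisions and annotate lineage
#'
#' Track starts after the first frame are treated as division candidates
#' and processed in chronological order. For each candidate daughter start
#' the nearest childless track holding a detection on the immediately
#' preceding frames (within `max_gap`) and within `division_radius` is the
#' candidate parent. Two situations arise: the parent track ends there
#' (the linker dropped both daughters — the parent adopts up to two such
#' starts), or the parent track continues through the division (the
#' optimal linker followed the parent into one daughter — the track is
#' split at the daughter's first frame and both halves are recorded as
#' daughters). Sequential divisions along one linked track are handled
#' because each split creates fresh childless tracks. A parent left with a
#' single adopted child (an unconfirmed division) is reverted; parents
#' never exceed two children.
#'
#' @param tracks A `cell_tracks` object from [link_detections()].
#' @return The `cell_tracks` object with `parent` filled in (and tracks
#'   possibly split).
#' @export
detect_divisions <- function(tracks) {
  stopifnot(inherits(tracks, "cell_tracks"))
  det <- tracks$detections
  params <- tracks$params
  trs <- tracks$tracks
  parent <- rep(NA_integer_, length(trs))
  if (length(trs) >= 2L) {
    first_frame <- min(det$frame_index)
    n_children <- integer(length(trs))
    start_fr <- function(i) det$frame_index[trs[[i]][1L]]
    end_fr <- function(i) det$frame_index[trs[[i]][length(trs[[i]])]]
    orphans <- which(vapply(seq_along(trs), start_fr, integer(1)) >
                       first_frame)
    orphans <- orphans[order(vapply(orphans, start_fr, integer(1)),
                             orphans)]
    oi <- 1L
    while (oi <= length(orphans)) {
      s <- orphans[oi]; oi <- oi + 1L
      if (!is.na(parent[s])) next
      fs <- start_fr(s)
      r_s <- trs[[s]][1L]
      # candidate parents: childless-or-ended tracks with a detection in
      # the preceding frames, close to the daughter's first position
      best_p <- NA_integer_; best_d <- Inf; best_cont <- FALSE
      for (p in seq_along(trs)) {
        if (p == s || !length(trs[[p]])) next
        if (start_fr(p) >= fs) next
        fr_p <- det$frame_index[trs[[p]]]
        continues <- fr_p[length(fr_p)] >= fs
        if (continues && n_children[p] > 0L) next
        if (n_children[p] >= 2L) next
        # last detection strictly before fs, within the gap window
        i_prev <- findInterval(fs - 1L, fr_p)
        if (i_prev < 1L) next
        fq <- fr_p[i_prev]
        if (fs - fq > params$max_gap) next
        r_prev <- trs[[p]][i_prev]
        dd <- sqrt((det$x[r_prev] - det$x[r_s])^2 +
                     (det$y[r_prev] - det$y[r_s])^2)
        if (dd <= params$division_radius && dd < best_d) {
          best_d <- dd; best_p <- p; best_cont <- continues
        }
      }
      if (is.na(best_p)) next
      if (best_cont) {
        # split the parent track at the daughter's first frame
        fr_p <- det$frame_index[trs[[best_p]]]
        before <- trs[[best_p]][fr_p < fs]
        after <- trs[[best_p]][fr_p >= fs]
        if (!length(before) || !length(after)) next
        trs[[best_p]] <- before
        trs[[length(trs) + 1L]] <- after
        parent <- c(parent, best_p)
        n_children <- c(n_children, 0L)
        parent[s] <- best_p
        n_children[best_p] <- 2L
      } else {
        parent[s] <- best_p
        n_children[best_p] <- n_children[best_p] + 1L
      }
    }
    # revert unconfirmed single-child adoptions of ended tracks
    singles <- which(n_children == 1L)
    for (p in singles) parent[parent %in% p] <- NA_integer_
  }
  # order tracks deterministically and remap parents
  ord <- order(vapply(trs, function(tr) det$frame_index[tr[1L]], numeric(1)),
               vapply(trs, function(tr) det$label[tr[1L]], numeric(1)),
               vapply(trs, function(tr) tr[1L], numeric(1)))
  remap <- integer(length(trs)); remap[ord] <- seq_along(trs)
  tracks$tracks <- trs[ord]
  tracks$parent <- as.integer(ifelse(is.na(parent[ord]), NA,
                                     remap[parent[ord]]))
  tracks
}

#' @export
print.cell_tracks <- function(x, ...) {
  cat(sprintf("Cell tracks: %d tracks, %d detections, %d divisions\n",
              length(x$tracks), nrow(x$detections),
              length(unique(stats::na.omit(x$parent)))))
  invisible(x)
}

#' Extract a reporter trace from a track
#'
#' Time series of per-cell mean intensities; frames missed inside a track
#' (closed gaps) are filled by linear interpolation and flagged.
#'
#' @param tracks A `cell_tracks` object.
#' @param track_id Track index.
#' @param frame_interval_h Frame interval in hours.
#' @return A `reporter_trace` (columns `t_h`, `venus`, `cherry`,
#'   `interpolated`).
#' @export
extract_trace <- function(tracks, track_id, frame_interval_h = 0.5) {
  stopifnot(inherits(tracks, "cell_tracks"))
  tr <- tracks$tracks[[track_id]]
  if (!length(tr)) stop("empty track", call. = FALSE)
  det <- tracks$detections
  fr <- det$frame_index[tr]
  full <- seq(min(fr), max(fr))
  if (length(fr) > 1L) {
    mv <- stats::approx(fr, det$mean_venus[tr], xout = full)$y
    mc <- stats::approx(fr, det$mean_cherry[tr], xout = full)$y
  } else {
    mv <- det$mean_venus[tr]
    mc <- det$mean_cherry[tr]
  }
  new_reporter_trace(
    data.frame(t_h = full * frame_interval_h, venus = mv, cherry = mc,
               interpolated = !(full %in% fr)),
    track_id = track_id,
    parent_track_id = tracks$parent[track_id],
    start_h = min(fr) * frame_interval_h)
}

#' Extract traces for all (sufficiently long) tracks
#'
#' @param tracks A `cell_tracks` object.
#' @param frame_interval_h Frame interval in hours.
#' @param min_len Minimum track length in frames (defaults to the tracking
#'   parameters' `min_track_len`).
#' @return List of `reporter_trace` objects (shorter tracks are skipped).
#' @export
extract_traces <- function(tracks, frame_interval_h = 0.5,
                           min_len = NULL) {
  stopifnot(inherits(tracks, "cell_tracks"))
  if (is.null(min_len)) min_len <- tracks$params$min_track_len
  keep <- which(lengths(tracks$tracks) >= min_len)
  lapply(keep, function(i) extract_trace(tracks, i, frame_interval_h))
}
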