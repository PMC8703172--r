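#' Simulate a single-cell lineage under a kinetic profile
#'
#' Draws a population of founder cells and their descendants over one
#' simulated imaging period. Event times (cytokinesis, Venus/Cherry onset,
#' reporter decay, division) are drawn from the profile's distributions; at
#' every division the joint fate of the two daughters is drawn by
#' [assign_daughter_fates()]. Cells whose double-positive (DP) dwell exceeds
#' the spontaneous threshold are spontaneous-G0 cells; under cycling
#' profiles they may later exit G0, re-enter G1 and divide again, while
#' under serum-free profiles G0 is permanent. All records are censored at
#' the movie end. Per-frame positions follow an isotropic Gaussian random
#' walk (reflected at the frame borders); daughters start one spot radius
#' from the parent on opposite sides.
#'
#' Founders of cycling profiles are sampled from the proliferating
#' subpopulation: with probability `p_divide` a founder divides at a uniform
#' time within `founder_div_window_h` (its earlier event times are
#' reconstructed backwards and may lie before the movie start), otherwise it
#' is a G0-arrested cell that stays double positive throughout. Founder
#' records that begin mid-cycle carry no post-mitotic onset pattern and are
#' excluded from post-mitotic statistics downstream.
#'
#' @param profile A [kinetic_profile()].
#' @param n_founders Number of founder cells (>= 0).
#' @param spec A [movie_spec()].
#' @param seed Integer seed; identical inputs give identical lineages.
#' @param transient_threshold_h Dwell threshold (hours) separating
#'   `DIRECT_G1` from `TRANSIENT_G0_TO_G1` fate labels.
#' @param with_positions Simulate per-frame positions (needed for
#'   rendering; the joint motion model with volume exclusion is quadratic
#'   in the number of concurrent cells, so image-free trace studies of
#'   large cohorts should skip it).
#' @return An object of class `cell_lineage`: a list with elements
#'   `cells` (one row per cell: ids, event times in hours, fate label),
#'   `positions` (per-frame centroid table: `frame`, `cell_id`, `x`, `y`,
#'   0-based pixel coordinates), `profile`, `spec`, `seed`.
#' @examples
#' lin <- simulate_population(quiescence_profile("pc3_hotel"), 5,
#'                            movie_spec(duration_h = 24), seed = 1)
#' table(lin$cells$fate)
#' @export
simulate_population <- function(profile, n_founders, spec, seed,
                                transient_threshold_h = 4,
                                with_positions = TRUE) {
  stopifnot(inherits(profile, "kinetic_profile"),
            inherits(spec, "movie_spec"))
  if (!is.numeric(n_founders) || length(n_founders) != 1L ||
      is.na(n_founders) || n_founders < 0 ||
      n_founders != round(n_founders)) {
    stop("n_founders must be a non-negative integer", call. = FALSE)
  }
  n_founders <- as.integer(n_founders)
  with_local_seed(seed, {
    cells <- simulate_records(profile, n_founders, spec,
                              transient_threshold_h)
    positions <- if (with_positions) {
      simulate_positions(cells, profile, spec)
    } else {
      data.frame(frame = integer(), cell_id = integer(),
                 x = numeric(), y = numeric())
    }
    structure(list(cells = cells, positions = positions,
                   profile = profile, spec = spec, seed = seed),
              class = "cell_lineage")
  })
}

#' @export
print.cell_lineage <- function(x, ...) {
  cat(sprintf("Cell lineage: %d cells (%d founders) over %g h ['%s']\n",
              nrow(x$cells), sum(is.na(x$cells$parent_id)),
              x$spec$duration_h, x$profile$name))
  if (nrow(x$cells)) print(table(fate = x$cells$fate))
  invisible(x)
}

empty_cells_df <- function() {
  data.frame(cell_id = integer(), parent_id = integer(),
             birth_h = numeric(), venus_on_h = numeric(),
             cherry_on_h = numeric(), venus_off_h = numeric(),
             cherry_off_h = numeric(), division_h = numeric(),
             censored_end_h = numeric(), dp_dwell_h = numeric(),
             fate = character(), silent = logical(),
             reentry = logical(), generation = integer())
}

simulate_records <- function(profile, n_founders, spec, transient_thr) {
  T_end <- spec$duration_h
  rows <- list()
  n_rows <- 0L
  next_id <- 1L
  add_row <- function(row) {
    n_rows <<- n_rows + 1L
    rows[[n_rows]] <<- row
  }
  # queue of pending cells: list(parent_id, birth_h, dwell (NA = draw from
  # pair logic already done), silent, generation)
  queue <- list()
  push <- function(x) queue[[length(queue) + 1L]] <<- x

  cens <- function(t) ifelse(!is.na(t) & t < T_end, t, NA_real_)

  make_cell <- function(parent_id, birth_h, venus_on, cherry_on, venus_off,
                        cherry_off, division, dwell, fate, silent,
                        reentry, generation) {
    id <- next_id; next_id <<- next_id + 1L
    divides <- !is.na(division) && division < T_end
    add_row(list(
      cell_id = id, parent_id = as.integer(parent_id), birth_h = birth_h,
      venus_on_h = cens(venus_on), cherry_on_h = cens(cherry_on),
      venus_off_h = cens(venus_off), cherry_off_h = cens(cherry_off),
      division_h = if (divides) division else NA_real_,
      censored_end_h = if (divides) NA_real_ else T_end,
      dp_dwell_h = as.numeric(dwell), fate = fate, silent = silent,
      reentry = reentry, generation = as.integer(generation)))
    if (divides) list(id = id, division_h = division) else NULL
  }

  # grow a post-mitotic daughter given its assigned DP dwell; daughters of
  # a synchronous-G0 decision remain in G0 (no exit within the simulation),
  # all others exit to G1 when their dwell ends
  grow_daughter <- function(parent_id, birth, dwell, exits, silent,
                            generation) {
    if (silent) {
      make_cell(parent_id, birth, NA, NA, NA, NA, NA, NA_real_,
                "SILENT", TRUE, FALSE, generation)
      return(invisible(NULL))
    }
    v_on <- birth + dist_sample(profile$venus_onset_delay)
    c_on <- v_on + dist_sample(profile$cherry_onset_delay)
    spont <- !exits || dwell > profile$spontaneous_threshold_h
    v_off <- if (exits) c_on + dwell else NA_real_
    c_off <- div <- NA_real_
    if (!is.na(v_off)) {
      c_off <- v_off + dist_sample(profile$g1_duration)
      div <- c_off + dist_sample(profile$sgm_duration)
    }
    fate <- if (spont) "SPONT_G0"
            else if (dwell > transient_thr) "TRANSIENT_G0_TO_G1"
            else "DIRECT_G1"
    parent_info <- make_cell(parent_id, birth, v_on, c_on, v_off, c_off,
                             div, if (exits) dwell else NA_real_, fate,
                             FALSE, FALSE, generation)
    if (!is.null(parent_info)) {
      fates <- assign_daughter_fates(profile)
      push(list(parent_id = parent_info$id, birth = parent_info$division_h,
                dwells = fates$dwells, exits = fates$exits, silent = FALSE,
                generation = generation + 1L))
    }
    invisible(NULL)
  }

  for (i in seq_len(n_founders)) {
    silent_clone <- stats::runif(1) < profile$p_reporter_silent
    if (profile$start_state == "g1") {
      # serum-free cohort sorted in G1: Cherry-only at t=0; non-silent
      # cells re-enter G0 during the movie (Venus rises after Cherry --
      # flagged `reentry`, the one condition that inverts onset order).
      c_on <- -stats::runif(1, 1, 6)
      if (silent_clone) {
        make_cell(NA_integer_, c_on, NA, c_on, NA, NA, NA, NA_real_,
                  "SILENT", TRUE, FALSE, 0L)
      } else {
        v_on <- stats::runif(1, 2, 16)
        make_cell(NA_integer_, c_on, v_on, c_on, NA, NA, NA, NA_real_,
                  "SPONT_G0", FALSE, TRUE, 0L)
      }
      next
    }
    if (profile$start_state == "sgm") {
      # serum-free cohort sorted in S/G2/M: double negative at t=0,
      # completes the committed mitosis early, daughters arrest in G0.
      div <- stats::runif(1, 0, max(profile$founder_div_window_h, 1e-6))
      birth <- div - dist_sample(profile$sgm_duration)
      info <- make_cell(NA_integer_, birth, NA, NA, NA, NA, div, NA_real_,
                        if (silent_clone) "SILENT" else "FOUNDER",
                        silent_clone, FALSE, 0L)
      if (!is.null(info)) {
        fates <- assign_daughter_fates(profile)
        push(list(parent_id = info$id, birth = info$division_h,
                  dwells = fates$dwells, exits = fates$exits,
                  silent = silent_clone, generation = 1L))
      }
      next
    }
    # cycling founder
    if (stats::runif(1) < profile$p_divide) {
      div <- stats::runif(1, 0, max(profile$founder_div_window_h, 1e-6))
      sgm <- dist_sample(profile$sgm_duration)
      g1 <- dist_sample(profile$g1_duration)
      dwell <- dist_sample(profile$dp_dwell_transient)
      c_off <- div - sgm
      v_off <- c_off - g1
      c_on <- v_off - dwell
      v_on <- c_on - dist_sample(profile$cherry_onset_delay)
      birth <- v_on - dist_sample(profile$venus_onset_delay)
      info <- make_cell(NA_integer_, birth, v_on, c_on, v_off, c_off, div,
                        dwell, "FOUNDER", silent_clone, FALSE, 0L)
      if (!is.null(info)) {
        fates <- assign_daughter_fates(profile)
        push(list(parent_id = info$id, birth = info$division_h,
                  dwells = fates$dwells, exits = fates$exits,
                  silent = silent_clone, generation = 1L))
      }
    } else {
      # G0-arrested founder: double positive throughout the movie
      c_on <- -stats::runif(1, 2, 8)
      v_on <- c_on - dist_sample(profile$cherry_onset_delay)
      birth <- v_on - dist_sample(profile$venus_onset_delay)
      make_cell(NA_integer_, birth, v_on, c_on, NA, NA, NA,
                T_end - c_on, "SPONT_G0", silent_clone, FALSE, 0L)
    }
  }

  qi <- 1L
  while (qi <= length(queue)) {
    ev <- queue[[qi]]; qi <- qi + 1L
    grow_daughter(ev$parent_id, ev$birth, ev$dwells[1], ev$exits[1],
                  ev$silent, ev$generation)
    grow_daughter(ev$parent_id, ev$birth, ev$dwells[2], ev$exits[2],
                  ev$silent, ev$generation)
  }

  if (n_rows == 0L) return(empty_cells_df())
  rows <- rows[seq_len(n_rows)]
  col <- function(name, mode) {
    vapply(rows, function(r) r[[name]], vector(mode, 1L))
  }
  out <- data.frame(
    cell_id = col("cell_id", "integer"),
    parent_id = col("parent_id", "integer"),
    birth_h = col("birth_h", "numeric"),
    venus_on_h = col("venus_on_h", "numeric"),
    cherry_on_h = col("cherry_on_h", "numeric"),
    venus_off_h = col("venus_off_h", "numeric"),
    cherry_off_h = col("cherry_off_h", "numeric"),
    division_h = col("division_h", "numeric"),
    censored_end_h = col("censored_end_h", "numeric"),
    dp_dwell_h = col("dp_dwell_h", "numeric"),
    fate = col("fate", "character"),
    silent = col("silent", "logical"),
    reentry = col("reentry", "logical"),
    generation = col("generation", "integer"))
  rownames(out) <- NULL
  out
}

#' Draw the joint fate of a daughter-cell pair
#'
#' One of three pair categories is drawn from the profile's
#' `pair_fate_probs`: `SYNC_G0` (both daughters receive prolonged DP dwells
#' beyond the spontaneous threshold), `SYNC_G1` (both receive the same
#' transient dwell up to a small jitter, so their G1 entries differ by less
#' than the synchrony tolerance) or `ASYNC` (one daughter receives a
#' transient dwell, its sibling that dwell plus a G1-entry delay drawn from
#' `async_delta`). Uses the current RNG stream.
#'
#' @param profile A [kinetic_profile()].
#' @return A list with `category` (`"SYNC_G0"`, `"SYNC_G1"`, `"ASYNC"`),
#'   `dwells` (DP dwell hours for the two daughters, in birth order),
#'   `exits` (logical pair: does each daughter leave G0 for G1 when its
#'   dwell ends — `FALSE` for the permanently quiescent daughters of a
#'   synchronous-G0 decision) and `delta_h` (the drawn G1-entry
#'   difference; 0 for synchronous pairs).
#' @examples
#' set.seed(1)
#' assign_daughter_fates(quiescence_profile("t3t3_fullserum"))
#' @export
assign_daughter_fates <- function(profile) {
  stopifnot(inherits(profile, "kinetic_profile"))
  p <- profile$pair_fate_probs
  u <- stats::runif(1)
  if (u < p[["sync_g0"]]) {
    dwells <- dist_sample(profile$dp_dwell_prolonged, 2L)
    return(list(category = "SYNC_G0", dwells = dwells,
                exits = c(FALSE, FALSE), delta_h = 0))
  }
  if (u < p[["sync_g0"]] + p[["sync_g1"]]) {
    d <- dist_sample(profile$dp_dwell_transient)
    jit <- stats::runif(1, -profile$sync_jitter_h, profile$sync_jitter_h)
    d2 <- min(max(d + jit, 0.1), profile$spontaneous_threshold_h - 0.1)
    return(list(category = "SYNC_G1", dwells = c(d, d2),
                exits = c(TRUE, TRUE), delta_h = abs(d2 - d)))
  }
  d <- dist_sample(profile$dp_dwell_transient)
  delta <- dist_sample(profile$async_delta)
  dwells <- if (stats::runif(1) < 0.5) c(d, d + delta) else c(d + delta, d)
  list(category = "ASYNC", dwells = dwells, exits = c(TRUE, TRUE),
       delta_h = delta)
}

# ---- per-frame positions -------------------------------------------------

# Frame-by-frame joint position simulation: isotropic Gaussian random walk
# with pairwise volume exclusion (cell bodies cannot overlap; pairs closer
# than the contact separation are pushed apart symmetrically), reflection
# at a border margin, and daughters starting one spot radius from the
# parent's last position on opposite sides.
simulate_positions <- function(cells, profile, spec) {
  empty <- data.frame(frame = integer(), cell_id = integer(),
                      x = numeric(), y = numeric())
  if (nrow(cells) == 0L) return(empty)
  times <- frame_times(spec)
  nf <- length(times)
  margin <- 2 * spec$psf_sigma
  lo <- margin
  hi_x <- spec$width - 1 - margin
  hi_y <- spec$height - 1 - margin
  if (hi_x <= lo || hi_y <= lo) {
    stop("frame too small for the configured psf_sigma", call. = FALSE)
  }
  contact_sep <- 6 * spec$psf_sigma

  birth <- cells$birth_h
  endt <- ifelse(!is.na(cells$division_h), cells$division_h,
                 cells$censored_end_h)
  first_fr <- vapply(seq_len(nrow(cells)), function(i) {
    w <- which(times >= max(birth[i], 0) & times < endt[i])
    if (length(w)) w[1L] else NA_integer_
  }, integer(1))
  last_fr <- vapply(seq_len(nrow(cells)), function(i) {
    w <- which(times >= max(birth[i], 0) & times < endt[i])
    if (length(w)) w[length(w)] else NA_integer_
  }, integer(1))

  clamp01 <- function(p) c(min(max(p[1], lo), hi_x),
                           min(max(p[2], lo), hi_y))
  pos <- matrix(NA_real_, nrow(cells), 2)       # current position
  final_pos <- matrix(NA_real_, nrow(cells), 2) # last recorded position
  active <- logical(nrow(cells))
  offset_of <- rep(NA_real_, nrow(cells))       # pending daughter angle

  rec_frame <- vector("list", nf)
  for (f in seq_len(nf)) {
    # retire cells that ended before this frame
    gone <- which(active & last_fr < f)
    if (length(gone)) {
      final_pos[gone, ] <- pos[gone, , drop = FALSE]
      active[gone] <- FALSE
    }
    # random-walk step for continuing cells (ordered by row = cell id)
    cont <- which(active)
    if (length(cont) && profile$motility_sigma > 0) {
      pos[cont, 1] <- pos[cont, 1] +
        stats::rnorm(length(cont), 0, profile$motility_sigma)
      pos[cont, 2] <- pos[cont, 2] +
        stats::rnorm(length(cont), 0, profile$motility_sigma)
    }
    # newborns
    born <- which(!active & first_fr == f)
    for (i in born) {
      pid <- cells$parent_id[i]
      if (is.na(pid)) {
        # founder: rejection-sample a separated position
        p <- c(stats::runif(1, lo, hi_x), stats::runif(1, lo, hi_y))
        occ <- which(active)
        for (attempt in seq_len(300L)) {
          if (!length(occ)) break
          dmin <- min(sqrt((pos[occ, 1] - p[1])^2 +
                             (pos[occ, 2] - p[2])^2))
          if (dmin >= contact_sep) break
          p <- c(stats::runif(1, lo, hi_x), stats::runif(1, lo, hi_y))
        }
        pos[i, ] <- p
      } else {
        j <- match(pid, cells$cell_id)
        anchor <- if (active[j]) pos[j, ] else final_pos[j, ]
        if (anyNA(anchor)) {
          anchor <- c(stats::runif(1, lo, hi_x), stats::runif(1, lo, hi_y))
        }
        if (is.na(offset_of[j])) {
          offset_of[j] <- stats::runif(1, 0, 2 * pi)
          theta <- offset_of[j]
        } else {
          theta <- offset_of[j] + pi
        }
        r <- 2 * spec$psf_sigma
        pos[i, ] <- clamp01(anchor + r * c(cos(theta), sin(theta)))
      }
      active[i] <- TRUE
    }
    # volume exclusion: push overlapping pairs apart (deterministic order)
    act <- which(active)
    if (length(act) > 1L) {
      for (iter in seq_len(4L)) {
        moved <- FALSE
        for (ai in seq_along(act)[-length(act)]) {
          i <- act[ai]
          for (bj in (ai + 1L):length(act)) {
            j <- act[bj]
            dx <- pos[j, 1] - pos[i, 1]
            dy <- pos[j, 2] - pos[i, 2]
            d <- sqrt(dx * dx + dy * dy)
            if (d >= contact_sep) next
            if (d < 1e-6) { dx <- 1; dy <- 0; d <- 1 }
            push <- (contact_sep - d) / 2
            ux <- dx / d; uy <- dy / d
            pos[i, ] <- pos[i, ] - push * c(ux, uy)
            pos[j, ] <- pos[j, ] + push * c(ux, uy)
            moved <- TRUE
          }
        }
        if (!moved) break
      }
      for (i in act) pos[i, ] <- clamp01(pos[i, ])
    } else if (length(act) == 1L) {
      pos[act, ] <- clamp01(pos[act, ])
    }
    if (length(act)) {
      rec_frame[[f]] <- data.frame(frame = f - 1L,
                                   cell_id = cells$cell_id[act],
                                   x = pos[act, 1], y = pos[act, 2])
    }
  }
  still <- which(active)
  if (length(still)) final_pos[still, ] <- pos[still, , drop = FALSE]
  rec_frame <- rec_frame[!vapply(rec_frame, is.null, logical(1))]
  if (!length(rec_frame)) return(empty)
  res <- do.call(rbind, rec_frame)
  res <- res[order(res$frame, res$cell_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
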