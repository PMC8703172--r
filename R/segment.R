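#' Segmentation parameters
#'
#' @param smoothing_sigma Gaussian smoothing sigma (pixels) applied to the
#'   summed channel image before thresholding.
#' @param threshold_rule `"otsu_log"` (Otsu's threshold computed on the
#'   log1p-transformed smoothed image, robust when bright reporter-positive
#'   and dim basal-only cells coexist), `"otsu"` (linear-domain Otsu) or
#'   `"floor"` (noise-floor threshold only). All rules are floored at
#'   `k_noise` noise sigmas so near-empty frames yield no detections.
#' @param k_noise Threshold floor in units of the robust noise sigma
#'   (median absolute deviation of the smoothed image).
#' @param min_area,max_area Object area bounds in pixels. Defaults derive
#'   from the spot size: `min_area = round(pi * psf_sigma^2 / 2)`,
#'   `max_area = 50 * min_area`.
#' @param watershed Split touching objects by watershed on the distance
#'   transform?
#' @param watershed_tolerance Minimum object-separation depth passed to the
#'   watershed.
#' @param intensity_split_tol Relative valley depth (fraction of the
#'   object's peak intensity) above which an object is further split by a
#'   watershed on its own intensity profile. Shape-based watershed cannot
#'   separate two spots so close that their union is convex; the intensity
#'   valley between two peaks can. 0 disables.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(smoothing_sigma = 1.5,
                                threshold_rule = c("otsu_log", "otsu",
                                                   "floor"),
                                k_noise = 3,
                                min_area = NULL, max_area = NULL,
                                watershed = TRUE,
                                watershed_tolerance = 1,
                                intensity_split_tol = 0.2) {
  threshold_rule <- match.arg(threshold_rule)
  stopifnot(smoothing_sigma >= 0, k_noise >= 0, watershed_tolerance > 0,
            intensity_split_tol >= 0, intensity_split_tol < 1)
  structure(list(smoothing_sigma = smoothing_sigma,
                 threshold_rule = threshold_rule, k_noise = k_noise,
                 min_area = min_area, max_area = max_area,
                 watershed = isTRUE(watershed),
                 watershed_tolerance = watershed_tolerance,
                 intensity_split_tol = intensity_split_tol),
            class = "segmentation_params")
}

area_bounds <- function(params, psf_sigma) {
  min_area <- params$min_area
  if (is.null(min_area)) min_area <- max(4L, round(pi * psf_sigma^2 / 2))
  max_area <- params$max_area
  if (is.null(max_area)) max_area <- 50L * min_area
  c(min_area, max_area)
}

#' Robust per-channel background level of a frame
#'
#' Median of the pixels at or below the 25th percentile — a low-order
#' statistic that ignores bright spots occupying a minority of the frame.
#'
#' @param frame_pair List with `venus` and `cherry` matrices (equal shape).
#' @return Named numeric vector `c(venus = ..., cherry = ...)`.
#' @export
estimate_background <- function(frame_pair) {
  one <- function(m) {
    if (!length(m)) stop("empty frame", call. = FALSE)
    # robust statistics on a pixel subsample: the estimator targets the
    # smooth background, so a stride-4 subsample loses nothing
    v <- if (length(m) > 16384L) m[seq(1L, length(m), by = 4L)] else m
    q <- stats::quantile(v, 0.25, names = FALSE)
    stats::median(v[v <= q])
  }
  c(venus = one(frame_pair$venus), cherry = one(frame_pair$cherry))
}

#' Segment one two-channel frame into cell detections
#'
#' Pipeline: per-channel background subtraction, pixelwise channel sum,
#' Gaussian smoothing, thresholding (see [segmentation_params()]), hole
#' filling, watershed splitting on the distance transform, area filtering,
#' and per-object intensity-weighted centroids plus per-channel mean/total
#' intensities. A pure function of the frame pixels and the parameters.
#'
#' @param frame_pair List with `venus` and `cherry` matrices
#'   (`rows = y`, `cols = x`).
#' @param params A [segmentation_params()].
#' @param psf_sigma Expected spot sigma in pixels (drives smoothing /
#'   area defaults).
#' @param frame_index 0-based frame index stored in the output.
#' @return A data frame of detections: `frame_index`, `label`, `x`, `y`
#'   (0-based sub-pixel centroids), `area`, `mean_venus`, `mean_cherry`,
#'   `total_venus`, `total_cherry`.
#' @export
segment_frame <- function(frame_pair, params = segmentation_params(),
                          psf_sigma = 3, frame_index = 0L) {
  v <- frame_pair$venus; ch <- frame_pair$cherry
  if (!all(dim(v) == dim(ch))) {
    stop("channel shape mismatch", call. = FALSE)
  }
  bg <- estimate_background(frame_pair)
  sub_v <- pmax(v - bg[["venus"]], 0)
  sub_c <- pmax(ch - bg[["cherry"]], 0)
  total <- sub_v + sub_c
  sm <- if (params$smoothing_sigma > 0) {
    # replicate boundary: circular (FFT) boundaries would wrap bright
    # cells at one edge into ghost objects at the opposite edge
    sz <- 2L * ceiling(3 * params$smoothing_sigma) + 1L
    brush <- EBImage::makeBrush(sz, shape = "Gaussian",
                                sigma = params$smoothing_sigma)
    as.matrix(EBImage::filter2(total, brush, boundary = "replicate"))
  } else total
  smv <- if (length(sm) > 16384L) sm[seq(1L, length(sm), by = 4L)] else sm
  med <- stats::median(smv)
  sigma_n <- stats::mad(smv, center = med)
  # the robust background estimator is a low-order statistic, so the
  # subtracted image keeps a small positive pedestal: floor from its median
  floor_thr <- med + params$k_noise * max(sigma_n, .Machine$double.eps)
  thr <- floor_thr
  mx <- max(sm)
  if (params$threshold_rule != "floor" && mx > floor_thr) {
    if (params$threshold_rule == "otsu_log") {
      lg <- log1p(sm)
      t_log <- EBImage::otsu(EBImage::Image(lg / max(lg)),
                             range = c(0, 1)) * max(lg)
      thr <- max(floor_thr, expm1(t_log))
    } else {
      t_lin <- EBImage::otsu(EBImage::Image(sm / mx), range = c(0, 1)) * mx
      thr <- max(floor_thr, t_lin)
    }
  }
  mask <- sm > thr
  empty <- empty_detections()
  if (!any(mask)) return(empty)
  mask_img <- EBImage::fillHull(EBImage::Image(mask * 1))
  lab <- if (params$watershed) {
    dm <- EBImage::distmap(mask_img)
    EBImage::watershed(dm, tolerance = params$watershed_tolerance, ext = 1)
  } else {
    EBImage::bwlabel(mask_img)
  }
  lab <- as.matrix(EBImage::imageData(lab))
  if (params$watershed && params$intensity_split_tol > 0) {
    lab <- split_by_intensity(lab, sm, params$intensity_split_tol)
  }
  measure_labels(lab, sm, sub_v, sub_c, area_bounds(params, psf_sigma),
                 frame_index)
}

empty_detections <- function() {
  data.frame(frame_index = integer(), label = integer(), x = numeric(),
             y = numeric(), area = integer(), mean_venus = numeric(),
             mean_cherry = numeric(), total_venus = numeric(),
             total_cherry = numeric())
}

measure_labels <- function(lab, weight, sub_v, sub_c, bounds, frame_index) {
  idx <- which(lab > 0)
  if (!length(idx)) return(empty_detections())
  lv <- lab[idx]
  area <- tabulate(lv)
  keep_labels <- which(area >= bounds[1] & area <= bounds[2])
  if (!length(keep_labels)) return(empty_detections())
  sel <- lv %in% keep_labels
  idx <- idx[sel]; lv <- lv[sel]
  h <- nrow(lab)
  row0 <- (idx - 1L) %% h          # 0-based y
  col0 <- (idx - 1L) %/% h         # 0-based x
  w <- pmax(weight[idx], .Machine$double.eps)
  g <- match(lv, keep_labels)
  wsum <- tapply_num(w, g)
  x <- tapply_num(w * col0, g) / wsum
  y <- tapply_num(w * row0, g) / wsum
  mean_v <- tapply_num(sub_v[idx], g) / tabulate(g)
  mean_c <- tapply_num(sub_c[idx], g) / tabulate(g)
  tot_v <- tapply_num(sub_v[idx], g)
  tot_c <- tapply_num(sub_c[idx], g)
  out <- data.frame(frame_index = frame_index,
                    label = seq_along(keep_labels),
                    x = x, y = y, area = area[keep_labels],
                    mean_venus = pmax(mean_v, 0),
                    mean_cherry = pmax(mean_c, 0),
                    total_venus = pmax(tot_v, 0),
                    total_cherry = pmax(tot_c, 0))
  out[order(out$label), , drop = FALSE]
}

tapply_num <- function(x, g) {
  as.numeric(rowsum(x, g, reorder = TRUE))
}

# Re-split labelled objects whose intensity profile has two (or more)
# maxima separated by a valley deeper than `tol` times the object peak.
split_by_intensity <- function(lab, sm, tol) {
  n_lab <- max(lab)
  if (n_lab == 0L) return(lab)
  next_label <- n_lab
  for (l in seq_len(n_lab)) {
    idx <- which(lab == l)
    if (length(idx) < 8L) next
    h <- nrow(lab)
    r0 <- range((idx - 1L) %% h)
    c0 <- range((idx - 1L) %/% h)
    rows <- (r0[1] + 1L):(r0[2] + 1L)
    cols <- (c0[1] + 1L):(c0[2] + 1L)
    sub_lab <- lab[rows, cols, drop = FALSE]
    sub_int <- sm[rows, cols, drop = FALSE]
    obj <- sub_lab == l
    peak <- max(sub_int[obj])
    if (peak <= 0) next
    xin <- (sub_int / peak) * obj
    ws <- as.matrix(EBImage::imageData(
      EBImage::watershed(EBImage::Image(xin), tolerance = tol, ext = 1)))
    parts <- sort(unique(ws[obj]))
    parts <- parts[parts > 0]
    if (length(parts) < 2L) next
    for (k in seq_along(parts)[-1L]) {
      next_label <- next_label + 1L
      sel <- obj & ws == parts[k]
      sub_lab[sel] <- next_label
      lab[rows, cols] <- sub_lab
    }
  }
  lab
}

#' Measure one object mask on a frame pair
#'
#' @param mask Logical matrix selecting the object's pixels.
#' @param frame_pair List with `venus` and `cherry` matrices.
#' @param background Named background levels as from
#'   [estimate_background()].
#' @return List with `mean_venus`, `mean_cherry`, `total_venus`,
#'   `total_cherry` (background-subtracted, clamped at 0).
#' @export
measure_object <- function(mask, frame_pair,
                           background = estimate_background(frame_pair)) {
  if (!any(mask)) stop("empty mask", call. = FALSE)
  sv <- pmax(frame_pair$venus[mask] - background[["venus"]], 0)
  sc <- pmax(frame_pair$cherry[mask] - background[["cherry"]], 0)
  list(mean_venus = mean(sv), mean_cherry = mean(sc),
       total_venus = sum(sv), total_cherry = sum(sc))
}

#' Segment every frame of a movie
#'
#' @param movie A `reporter_movie`.
#' @param params A [segmentation_params()].
#' @param psf_sigma Spot sigma in pixels (defaults to the movie spec's).
#' @return A detections data frame (one row per object over all frames).
#' @export
segment_movie <- function(movie, params = segmentation_params(),
                          psf_sigma = NULL) {
  stopifnot(inherits(movie, "reporter_movie"))
  if (is.null(psf_sigma)) {
    psf_sigma <- if (!is.null(movie$spec$psf_sigma)) movie$spec$psf_sigma
                 else 3
  }
  nf <- dim(movie$venus)[3]
  out <- vector("list", nf)
  for (f in seq_len(nf)) {
    fp <- list(venus = movie$venus[, , f], cherry = movie$cherry[, , f])
    out[[f]] <- segment_frame(fp, params, psf_sigma, frame_index = f - 1L)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
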