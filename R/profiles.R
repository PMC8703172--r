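#' Kinetic profile of a cell-cycle / reporter state machine
#'
#' A kinetic profile collects the stochastic parameters of the dual-reporter
#' cell-cycle state machine under one culture condition: onset delays of the
#' G0 reporter (Venus) and the G0/G1 reporter (Cherry) after cytokinesis,
#' rise/fall times of the reporters, dwell-time distributions of the
#' post-mitotic Venus/Cherry double-positive (DP) window for cells that
#' proceed to G1 versus cells that enter prolonged spontaneous G0, G1 and
#' S/G2/M phase durations, and the joint fate law for the two daughters of a
#' division.
#'
#' Daughter-pair fates are drawn per division from `pair_fate_probs =
#' (p_sync_g0, p_sync_g1, p_async)`. In asynchronous pairs one daughter
#' receives a transient DP dwell and its sibling that dwell plus a delay
#' drawn from `async_delta`; when the sum exceeds the spontaneous threshold
#' the slow sibling is itself a (threshold-crossing) spontaneous-G0 cell that
#' later exits. The population fraction of post-mitotic cells whose DP dwell
#' exceeds the threshold is therefore
#' \deqn{p_{G0} = p_{syncG0} + \tfrac12\, p_{async}\,
#'       P(D_{transient} + \Delta > \theta).}
#' `kinetic_profile()` accepts either an explicit `pair_fate_probs` triple or
#' a target marginal `p_spontaneous_g0` together with `p_async`, in which
#' case `p_sync_g0` is derived from the closed-form tail probability
#' (see [dist_sum_tail()]); the stored `p_spontaneous_g0` is always the
#' implied marginal.
#'
#' @param name Profile label.
#' @param venus_onset_delay,cherry_onset_delay [hours_uniform()] /
#'   [hours_const()] distributions: cytokinesis to Venus rise, and Venus rise
#'   to Cherry rise.
#' @param venus_rise_h,cherry_rise_h,venus_fall_h,cherry_fall_h Ramp
#'   durations of the reporter rise and decay, hours.
#' @param dp_dwell_transient DP dwell distribution for cells that proceed to
#'   G1; support must not exceed `spontaneous_threshold_h`.
#' @param dp_dwell_prolonged DP dwell distribution for spontaneous-G0 cells;
#'   support must exceed `spontaneous_threshold_h`.
#' @param g1_duration,sgm_duration Post-G1-entry phase durations up to the
#'   next division.
#' @param p_spontaneous_g0 Target marginal probability that a post-mitotic
#'   cell's DP dwell exceeds the spontaneous threshold (used to derive
#'   `p_sync_g0` when `pair_fate_probs` is not given).
#' @param p_async Probability that a daughter pair makes an asynchronous
#'   G0/G1 decision (used with `p_spontaneous_g0`).
#' @param pair_fate_probs Optional explicit numeric triple
#'   `(p_sync_g0, p_sync_g1, p_async)` summing to 1.
#' @param async_delta Distribution of the G1-entry time difference in
#'   asynchronous pairs, hours.
#' @param sync_jitter_h Half-width of the small dwell jitter between
#'   synchronous-G1 siblings (realized `|delta|` stays below the pair
#'   synchrony tolerance).
#' @param p_reporter_silent Probability that a cell never expresses either
#'   reporter (serum-free retention profiles).
#' @param p_divide Probability that a founder divides during imaging.
#' @param founder_div_window_h Founder divisions are spread uniformly over
#'   `[0, founder_div_window_h]` (roughly one doubling time).
#' @param motility_sigma Random-walk step scale, pixels per frame.
#' @param start_state Founder starting context: `"cycling"` (asynchronously
#'   proliferating population), `"g1"` (serum-free cohort sorted in G1,
#'   Cherry-only at time zero, G0 re-entry during the movie) or `"sgm"`
#'   (serum-free cohort sorted in S/G2/M, completes mitosis then arrests).
#' @param spontaneous_threshold_h DP dwell threshold defining spontaneous G0
#'   (hours; the classifier default matches).
#' @return An object of class `kinetic_profile`.
#' @seealso [quiescence_profile()] for the shipped condition presets.
#' @export
kinetic_profile <- function(name,
                            venus_onset_delay = hours_uniform(2, 4),
                            cherry_onset_delay = hours_uniform(3, 4),
                            venus_rise_h = 3,
                            cherry_rise_h = 3,
                            venus_fall_h = 3,
                            cherry_fall_h = 3,
                            dp_dwell_transient = hours_uniform(5, 10),
                            dp_dwell_prolonged = hours_uniform(15, 40),
                            g1_duration = hours_uniform(7, 9),
                            sgm_duration = hours_uniform(9, 11),
                            p_spontaneous_g0 = NULL,
                            p_async = 0.3,
                            pair_fate_probs = NULL,
                            async_delta = hours_uniform(1, 15),
                            sync_jitter_h = 0.5,
                            p_reporter_silent = 0,
                            p_divide = 0.9,
                            founder_div_window_h = 24,
                            motility_sigma = 0.4,
                            start_state = c("cycling", "g1", "sgm"),
                            spontaneous_threshold_h = 14) {
  start_state <- match.arg(start_state)
  for (d in list(venus_onset_delay, cherry_onset_delay, dp_dwell_transient,
                 dp_dwell_prolonged, g1_duration, sgm_duration, async_delta)) {
    if (!is_duration_dist(d)) {
      stop("all delay/dwell parameters must be duration_dist objects",
           call. = FALSE)
    }
  }
  thr <- spontaneous_threshold_h
  q_slow <- dist_sum_tail(dp_dwell_transient, async_delta, thr)
  if (is.null(pair_fate_probs)) {
    if (is.null(p_spontaneous_g0)) {
      stop("give either pair_fate_probs or p_spontaneous_g0", call. = FALSE)
    }
    check_prob(p_spontaneous_g0, "p_spontaneous_g0")
    check_prob(p_async, "p_async")
    p_sync_g0 <- p_spontaneous_g0 - 0.5 * p_async * q_slow
    p_sync_g1 <- 1 - p_sync_g0 - p_async
    if (p_sync_g0 < -1e-9 || p_sync_g1 < -1e-9) {
      stop("p_spontaneous_g0/p_async are not jointly attainable with the ",
           "given dwell distributions", call. = FALSE)
    }
    pair_fate_probs <- c(sync_g0 = max(p_sync_g0, 0),
                         sync_g1 = max(p_sync_g1, 0),
                         async = p_async)
  } else {
    if (length(pair_fate_probs) != 3L || anyNA(pair_fate_probs)) {
      stop("pair_fate_probs must be a numeric triple", call. = FALSE)
    }
    pair_fate_probs <- as.numeric(pair_fate_probs)
    names(pair_fate_probs) <- c("sync_g0", "sync_g1", "async")
    if (any(pair_fate_probs < 0 | pair_fate_probs > 1) ||
        abs(sum(pair_fate_probs) - 1) > 1e-9) {
      stop("pair_fate_probs components must lie in [0,1] and sum to 1",
           call. = FALSE)
    }
  }
  implied_marginal <- unname(pair_fate_probs[["sync_g0"]] +
                               0.5 * pair_fate_probs[["async"]] * q_slow)
  check_prob(p_reporter_silent, "p_reporter_silent")
  check_prob(p_divide, "p_divide")
  if (dist_support(dp_dwell_transient)[2] > thr + 1e-9) {
    stop("dp_dwell_transient support must not exceed the spontaneous ",
         "threshold", call. = FALSE)
  }
  if (dist_support(dp_dwell_prolonged)[1] < thr - 1e-9) {
    stop("dp_dwell_prolonged support must exceed the spontaneous threshold",
         call. = FALSE)
  }
  stopifnot(venus_rise_h > 0, cherry_rise_h > 0, venus_fall_h > 0,
            cherry_fall_h > 0, sync_jitter_h >= 0, motility_sigma >= 0,
            founder_div_window_h >= 0)
  structure(list(
    name = name,
    venus_onset_delay = venus_onset_delay,
    cherry_onset_delay = cherry_onset_delay,
    venus_rise_h = venus_rise_h, cherry_rise_h = cherry_rise_h,
    venus_fall_h = venus_fall_h, cherry_fall_h = cherry_fall_h,
    dp_dwell_transient = dp_dwell_transient,
    dp_dwell_prolonged = dp_dwell_prolonged,
    g1_duration = g1_duration, sgm_duration = sgm_duration,
    pair_fate_probs = pair_fate_probs,
    p_spontaneous_g0 = implied_marginal,
    async_delta = async_delta, sync_jitter_h = sync_jitter_h,
    p_reporter_silent = p_reporter_silent,
    p_divide = p_divide, founder_div_window_h = founder_div_window_h,
    motility_sigma = motility_sigma, start_state = start_state,
    spontaneous_threshold_h = thr
  ), class = "kinetic_profile")
}

check_prob <- function(p, what) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop(sprintf("%s must be a probability in [0, 1]", what), call. = FALSE)
  }
  invisible(p)
}

#' @export
print.kinetic_profile <- function(x, ...) {
  cat(sprintf("Kinetic profile '%s' (start state: %s)\n", x$name,
              x$start_state))
  cat(sprintf("  pair fates  sync-G0 %.3f | sync-G1 %.3f | async %.3f\n",
              x$pair_fate_probs[["sync_g0"]], x$pair_fate_probs[["sync_g1"]],
              x$pair_fate_probs[["async"]]))
  cat(sprintf("  marginal P(DP dwell > %g h) = %.3f\n",
              x$spontaneous_threshold_h, x$p_spontaneous_g0))
  cat(sprintf("  p(silent) %.2f  p(founder divides) %.2f  motility %.2g px/frame\n",
              x$p_reporter_silent, x$p_divide, x$motility_sigma))
  invisible(x)
}

#' Shipped condition profiles
#'
#' Named presets of [kinetic_profile()] emulating the reporter kinetics of
#' the conditions studied with the dual G0/G1 reporter system:
#' \describe{
#'   \item{`t3t3_fullserum`}{NIH/3T3 fibroblasts in full serum: Venus onset
#'     2–4 h after cytokinesis, Cherry 3–4 h later, transient DP dwell
#'     5–10 h, Venus decay ~3 h at G1 entry; 64.4% of post-mitotic cells
#'     exceed the 14 h spontaneous-G0 threshold; 30% of daughter pairs decide
#'     asynchronously with G1-entry differences of 1–15 h.}
#'   \item{`t3t3_lowserum`}{3T3 after serum reduction: trajectories collapse
#'     into prolonged G0.}
#'   \item{`pc3_hotel`}{PC3 prostate cancer cells confined in a microfluidic
#'     single-cell chamber array (low motility): Venus onset ~2 h, Cherry
#'     ~2 h later, Venus decay ~4 h; 27.5% spontaneous G0; 30% asynchronous
#'     pairs with deltas of 1–6 h.}
#'   \item{`pc3_plate`}{PC3 in plate imaging (more motile): 20% spontaneous
#'     G0, otherwise PC3 kinetics.}
#'   \item{`serumfree_from_g1`}{Cherry-only (G1-sorted) cells placed in
#'     serum-free medium: Venus rises during the movie and 90% of cells are
#'     double positive at the 72 h snapshot (10% reporter-silent).}
#'   \item{`serumfree_from_sgm`}{Double-negative (S/G2/M-sorted) cells in
#'     serum-free medium: cells complete mitosis early, both daughters
#'     arrest in G0; 85% double positive at 72 h (15% reporter-silent).}
#'   \item{`pc3_gas6`}{PC3 + Gas6: fewer, earlier divisions; more
#'     synchronous G0 pairs; longer transient-G0 dwells; larger asynchrony
#'     deltas.}
#'   \item{`pc3_tgfb2`}{PC3 + TGF-beta-2: fewer, earlier divisions; more
#'     synchronous G0 pairs.}
#'   \item{`pc3_gmcsf`}{PC3 + GM-CSF: fewer divisions overall but more
#'     synchronous G1 entry among the pairs that do divide.}
#' }
#' Treatment-preset magnitudes encode the directional effects only and are
#' fully overridable through `...`.
#'
#' @param name One of the preset names above.
#' @param ... Overrides forwarded to [kinetic_profile()].
#' @return A `kinetic_profile`.
#' @examples
#' quiescence_profile("pc3_hotel")
#' @export
quiescence_profile <- function(name, ...) {
  presets <- quiescence_profile_names()
  if (!is.character(name) || length(name) != 1L || !(name %in% presets)) {
    stop(sprintf("unknown profile '%s' (available: %s)",
                 as.character(name)[1], paste(presets, collapse = ", ")),
         call. = FALSE)
  }
  base <- switch(
    name,
    t3t3_fullserum = list(
      venus_onset_delay = hours_uniform(2, 4),
      cherry_onset_delay = hours_uniform(3, 4),
      venus_rise_h = 3, cherry_rise_h = 3,
      venus_fall_h = 3, cherry_fall_h = 3,
      dp_dwell_transient = hours_uniform(5, 10),
      dp_dwell_prolonged = hours_uniform(15, 40),
      g1_duration = hours_uniform(7, 9),
      sgm_duration = hours_uniform(9, 11),
      p_spontaneous_g0 = 0.644, p_async = 0.30,
      async_delta = hours_uniform(1, 15),
      p_divide = 0.9, founder_div_window_h = 20,
      motility_sigma = 0.4),
    t3t3_lowserum = list(
      venus_onset_delay = hours_uniform(2, 4),
      cherry_onset_delay = hours_uniform(3, 4),
      dp_dwell_transient = hours_uniform(6, 12),
      dp_dwell_prolonged = hours_uniform(20, 60),
      p_spontaneous_g0 = 0.85, p_async = 0.10,
      async_delta = hours_uniform(1, 15),
      p_divide = 0.6, founder_div_window_h = 20,
      motility_sigma = 0.4,
      spontaneous_threshold_h = 14),
    pc3_hotel = pc3_base(),
    pc3_plate = utils::modifyList(pc3_base(), list(
      p_spontaneous_g0 = 0.20, motility_sigma = 1.5)),
    serumfree_from_g1 = utils::modifyList(pc3_base(), list(
      p_reporter_silent = 0.10, p_divide = 0,
      start_state = "g1", motility_sigma = 0.3)),
    serumfree_from_sgm = utils::modifyList(pc3_base(), list(
      p_reporter_silent = 0.15, p_divide = 1,
      pair_fate_probs = c(1, 0, 0), p_spontaneous_g0 = NULL,
      founder_div_window_h = 8,
      start_state = "sgm", motility_sigma = 0.3)),
    pc3_gas6 = utils::modifyList(pc3_base(), list(
      p_spontaneous_g0 = NULL,
      pair_fate_probs = c(0.45, 0.27, 0.28),
      dp_dwell_transient = hours_uniform(4, 13),
      async_delta = hours_uniform(2, 20),
      p_divide = 0.45, founder_div_window_h = 18)),
    pc3_tgfb2 = utils::modifyList(pc3_base(), list(
      p_spontaneous_g0 = NULL,
      pair_fate_probs = c(0.45, 0.25, 0.30),
      p_divide = 0.45, founder_div_window_h = 18)),
    pc3_gmcsf = utils::modifyList(pc3_base(), list(
      p_spontaneous_g0 = NULL,
      pair_fate_probs = c(0.15, 0.60, 0.25),
      p_divide = 0.45, founder_div_window_h = 18))
  )
  base <- base[!vapply(base, is.null, logical(1))]
  args <- utils::modifyList(base, list(...))
  do.call(kinetic_profile, c(list(name = name), args))
}

pc3_base <- function() {
  list(
    venus_onset_delay = hours_uniform(1.5, 2.5),
    cherry_onset_delay = hours_uniform(1.5, 2.5),
    venus_rise_h = 2, cherry_rise_h = 2,
    venus_fall_h = 4, cherry_fall_h = 3,
    dp_dwell_transient = hours_uniform(2, 9),
    dp_dwell_prolonged = hours_uniform(15, 30),
    g1_duration = hours_uniform(9, 11),
    sgm_duration = hours_uniform(11, 13),
    p_spontaneous_g0 = 0.275, p_async = 0.30,
    async_delta = hours_uniform(1, 6),
    p_divide = 0.8, founder_div_window_h = 24,
    motility_sigma = 0.3)
}

#' @rdname quiescence_profile
#' @export
quiescence_profile_names <- function() {
  c("t3t3_fullserum", "t3t3_lowserum", "pc3_hotel", "pc3_plate",
    "serumfree_from_g1", "serumfree_from_sgm", "pc3_gas6", "pc3_tgfb2",
    "pc3_gmcsf")
}
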