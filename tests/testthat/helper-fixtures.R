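# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

# A small rendered imaging run (low-motility confined-cell profile) with
# ground truth and the full pipeline result.
small_imaging_fixture <- function() {
  cache_get("small_imaging", function() {
    spec <- movie_spec(width = 256, height = 256)
    profile <- quiescence_profile("pc3_hotel")
    lineage <- simulate_population(profile, 12, spec, seed = 11)
    movie <- render_movie(lineage, spec, seed = 111)
    result <- run_pipeline(movie)
    list(spec = spec, profile = profile, lineage = lineage,
         movie = movie, result = result)
  })
}

# Pooled imaging-based parameter-recovery run for a profile (scaled down).
recovery_fixture <- function(profile_name, n_founders, seed = 1) {
  key <- paste0("recovery_", profile_name, "_", n_founders, "_", seed)
  cache_get(key, function() {
    run_recovery_experiment(profile_name, n_founders, seed = seed,
                            founders_per_movie = 14)
  })
}

# Noiseless generator traces plus classifier calls for a profile.
trace_oracle_fixture <- function(profile_name, n_founders = 120,
                                 seed = 5) {
  key <- paste0("oracle_", profile_name, "_", n_founders, "_", seed)
  cache_get(key, function() {
    profile <- quiescence_profile(profile_name)
    spec <- movie_spec()
    lineage <- simulate_population(profile, n_founders, spec, seed = seed,
                                   with_positions = FALSE)
    traces <- simulate_traces(lineage, noise_sd = 0)
    calls <- classify_traces(traces, classifier_config(min_signal = 0.05))
    list(profile = profile, spec = spec, lineage = lineage,
         traces = traces, calls = calls)
  })
}

# Build a reporter trace directly from channel vectors.
make_trace <- function(venus, cherry, dt = 0.5, track_id = 1L,
                       parent = NA, start_h = 0) {
  n <- length(venus)
  quietrack:::new_reporter_trace(
    data.frame(t_h = start_h + (seq_len(n) - 1L) * dt,
               venus = venus, cherry = cherry, interpolated = FALSE),
    track_id = track_id, parent_track_id = parent, start_h = start_h)
}

# Trace of a synthetic cell record sampled on a uniform grid.
record_trace <- function(venus_on = NA, cherry_on = NA, venus_off = NA,
                         cherry_off = NA, end_h = 72, birth_h = 0,
                         profile = quiescence_profile("pc3_hotel"),
                         dt = 0.5, track_id = 1L, parent = NA) {
  rec <- list(birth_h = birth_h, venus_on_h = venus_on,
              cherry_on_h = cherry_on, venus_off_h = venus_off,
              cherry_off_h = cherry_off, division_h = NA_real_,
              censored_end_h = end_h)
  tt <- seq(birth_h, end_h - dt, by = dt)
  make_trace(reporter_level(rec, tt, "venus", profile),
             reporter_level(rec, tt, "cherry", profile),
             dt = dt, track_id = track_id, parent = parent,
             start_h = tt[1])
}

# Wilson binomial confidence interval (percent scale).
binom_ci_pct <- function(k, n, conf = 0.95) {
  ci <- stats::prop.test(k, n, conf.level = conf)$conf.int
  100 * as.numeric(ci)
}

# Cluster-robust 95% CI for a proportion (percent scale), ratio estimator
# over clusters. The two daughters of one division share their pair-fate
# draw, so per-cell successes are correlated within sibling pairs; a plain
# binomial CI at the cell-level n would understate the sampling error.
cluster_ci_pct <- function(success, cluster) {
  success <- as.numeric(success)
  n_i <- tapply(rep(1, length(success)), cluster, sum)
  k_i <- tapply(success, cluster, sum)
  n <- sum(n_i)
  p <- sum(k_i) / n
  m <- length(n_i)
  se <- sqrt(m / (m - 1) * sum((k_i - p * n_i)^2)) / n
  100 * c(p - 1.96 * se, p + 1.96 * se)
}

# Spontaneous-G0 CI of a pooled imaging recovery run, clustered by parent.
recovery_spont_ci <- function(run, window_h = 24) {
  calls <- run$calls
  sc <- !is.na(calls$parent_track_id) & calls$classifiable %in% TRUE &
    calls$start_h <= 72 - window_h
  cluster_ci_pct(calls$spontaneous_g0[sc] %in% TRUE,
                 calls$parent_track_id[sc])
}

# Detections table for hand-built tracking scenarios.
det_df <- function(frame, x, y, label = NULL) {
  n <- length(frame)
  if (is.null(label)) {
    label <- stats::ave(seq_len(n), frame, FUN = seq_along)
  }
  data.frame(frame_index = frame, label = label, x = x, y = y,
             area = 20L, mean_venus = 100, mean_cherry = 100,
             total_venus = 2000, total_cherry = 2000)
}
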