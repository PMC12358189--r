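# Shared fixtures for the detection / sorting tests: plant known units in a
# rendered recording and keep the ground-truth spike times.

plant_recording <- function(seed, n_units = 4, duration_s = 30, rate_hz = 8,
                            snr = 8, noise_sd = 5) {
  set.seed(seed)
  geom <- electrode_geometry(n_channels = 3)
  tm <- make_templates(n_units, geom, snr = snr, noise_sd_uV = noise_sd,
                       seed = seed + 100)
  # single channel group: put every footprint on channels 1-3
  tm$channels$ch_low <- 1L
  tm$channels$ch_dom <- 2L
  tm$channels$ch_high <- 3L
  spk <- do.call(rbind, lapply(seq_len(n_units), function(u) {
    tt <- enforce_refractory(
      sort(stats::runif(stats::rpois(1, rate_hz * duration_s),
                        0.01, duration_s - 0.01)))
    data.frame(unit = u, time_s = tt)
  }))
  rec <- render_voltage(spk, tm, 3, duration_s, noise_sd_uV = noise_sd,
                        seed = seed + 200)
  list(spikes = spk, recording = rec, templates = tm)
}

# Label detected events by the nearest planted spike (within 1 ms).
match_planted <- function(event_times_s, planted) {
  vapply(event_times_s, function(t) {
    i <- which.min(abs(planted$time_s - t))
    if (abs(planted$time_s[i] - t) < 0.001) planted$unit[i] else NA_integer_
  }, integer(1))
}

# Synthetic spike events directly in waveform space (no rendering): each
# event is its unit's template plus white noise, as a detect_spikes()-shaped
# tibble. Times are Poisson with a refractory dead time per unit.
waveform_events <- function(templates, n_per_unit, noise_sd = 5,
                            rate_hz = 10, seed = 1) {
  set.seed(seed)
  n_units <- length(templates$templates)
  rows <- list()
  for (u in seq_len(n_units)) {
    tt <- enforce_refractory(sort(stats::runif(n_per_unit, 0,
                                               n_per_unit / rate_hz)))
    for (t in tt) {
      w <- templates$templates[[u]] +
        matrix(stats::rnorm(length(templates$templates[[u]]), 0, noise_sd),
               nrow = 3)
      rows[[length(rows) + 1]] <- tibble::tibble(
        unit = u, time_s = t, waveform = list(w)
      )
    }
  }
  ev <- dplyr::bind_rows(rows)
  ev <- dplyr::arrange(ev, .data$time_s)
  ev$event_id <- seq_len(nrow(ev))
  ev
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
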