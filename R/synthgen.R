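#' Default DC-mediated reduction fractions by condition
#'
#' Ground-truth thinning fractions `r` (fraction of in-window spikes removed
#' during DC) for every modality x treatment-group x amplitude cell, including
#' the sustained thermal window. Cells in which DC produced no significant
#' change carry `r = 0`. These defaults are calibrated to the reductions the
#' method reports on real recordings (lower bound of each reported range) and
#' are configuration, not physiological truth.
#'
#' @return a tibble with columns `modality`, `group`, `amplitude_uA`,
#'   `window`, and `r`.
#' @export
dc_reduction_defaults <- function() {
  grid <- tidyr::expand_grid(
    modality = c("noxious_thermal", "noxious_press", "tactile", "proprioceptive"),
    group = c("naive", "neuropathic", "inflammatory"),
    amplitude_uA = c(500, 1000),
    window = "main"
  )
  sustained <- tidyr::expand_grid(
    modality = "noxious_thermal",
    group = c("naive", "neuropathic", "inflammatory"),
    amplitude_uA = c(500, 1000),
    window = "sustained"
  )
  dplyr::bind_rows(grid, sustained) |>
    dplyr::mutate(r = dplyr::case_when(
      modality == "noxious_thermal" & window == "main" & group == "naive" ~ 0.397,
      modality == "noxious_thermal" & window == "main" ~ 0.705,
      modality == "noxious_thermal" & window == "sustained" & group == "naive" ~ 0,
      modality == "noxious_thermal" & window == "sustained" ~ 0.564,
      modality == "noxious_press" & group == "naive" ~ 0.221,
      modality == "noxious_press" ~ 0.259,
      modality == "tactile" & group == "neuropathic" ~ 0.576,
      modality == "tactile" & group == "inflammatory" & amplitude_uA == 1000 ~ 0.305,
      modality == "proprioceptive" & group == "naive" ~ 0.290,
      TRUE ~ 0
    ))
}

#' Stimulus paradigm description for a modality
#'
#' Encodes the delivery schedule of each natural stimulus: two laser pulses
#' for noxious thermal (long inter-stimulus rest), 50 stimulations at 1 Hz for
#' the mechanical modalities. The trial segment spans -1 s to +4.5 s around
#' the trigger for thermal stimulation (covering the sustained response) and
#' -1 s to +1 s otherwise.
#'
#' @param modality one of `"noxious_thermal"`, `"noxious_press"`,
#'   `"tactile"`, `"proprioceptive"`.
#' @return a one-row tibble: `modality`, `n_stimuli`,
#'   `inter_stimulus_interval_s`, `stimulus_duration_s`, `span_pre_ms`,
#'   `span_post_ms`.
#' @export
stimulus_paradigm <- function(modality = c("noxious_thermal", "noxious_press",
                                           "tactile", "proprioceptive")) {
  modality <- match.arg(modality)
  p <- switch(modality,
    noxious_thermal = list(n = 2L, isi = 300, dur = 1),
    noxious_press = list(n = 50L, isi = 1, dur = 0.3),
    tactile = list(n = 50L, isi = 1, dur = 0.00025),
    proprioceptive = list(n = 50L, isi = 1, dur = 0.4)
  )
  stopifnot(p$isi > p$dur)
  tibble::tibble(
    modality = modality,
    n_stimuli = p$n,
    inter_stimulus_interval_s = p$isi,
    stimulus_duration_s = p$dur,
    span_pre_ms = -1000,
    span_post_ms = if (modality == "noxious_thermal") 4500 else 1000
  )
}

#' DC schedule descriptor
#'
#' @param phase `"pre"`, `"during"`, or `"post"`.
#' @param amplitude_uA 0, 500 or 1000; must be 0 exactly when `phase != "during"`.
#' @param polarity `"none"`, `"cathodic_centre"` or `"anodic_centre"`; `"none"`
#'   exactly when `amplitude_uA` is 0.
#' @param time_since_dc_end_min minutes since DC offset (post phase only).
#' @param ramp_s on/offset ramp duration (s).
#' @param plateau_s total plateau duration (s).
#' @return a one-row tibble.
#' @export
dc_schedule <- function(phase = c("pre", "during", "post"), amplitude_uA = 0,
                        polarity = c("none", "cathodic_centre", "anodic_centre"),
                        time_since_dc_end_min = NA_real_,
                        ramp_s = 10, plateau_s = 105) {
  phase <- match.arg(phase)
  polarity <- match.arg(polarity)
  if (!amplitude_uA %in% c(0, 500, 1000)) {
    stop("amplitude_uA must be 0, 500 or 1000")
  }
  if ((amplitude_uA == 0) != (phase != "during")) {
    stop("amplitude_uA must be 0 exactly when phase is not 'during'")
  }
  if ((polarity == "none") != (amplitude_uA == 0)) {
    stop("polarity must be 'none' exactly when amplitude_uA is 0")
  }
  if (phase == "post" && is.na(time_since_dc_end_min)) {
    stop("post phase requires time_since_dc_end_min")
  }
  tibble::tibble(
    phase = phase, amplitude_uA = amplitude_uA, polarity = polarity,
    time_since_dc_end_min = time_since_dc_end_min,
    ramp_s = ramp_s, plateau_s = plateau_s
  )
}

#' Generator configuration
#'
#' Assembles the parameters of the synthetic-session generator. Defaults
#' encode the study conditions: 30 kHz sampling, per-modality evoked profiles
#' (sustained thermal firing from ~0.85 s, press bursts around 50-150 ms,
#' tactile single/double spikes near 8.31 ms, bimodal proprioceptive bursts
#' across 400 ms), pain-group elevation of evoked counts and a late second
#' tactile latency mode, mild spontaneous-rate elevation during DC, and
#' modality-specific post-DC recovery half-lives.
#'
#' @param modality stimulus modality of the session.
#' @param treatment_group `"naive"`, `"neuropathic"` or `"inflammatory"`.
#' @param sex `"F"` or `"M"` (metadata only; the generator applies no sex
#'   effect).
#' @param n_units number of ground-truth units.
#' @param sampling_rate_hz acquisition rate.
#' @param noise_sd_uV Gaussian noise standard deviation for voltage rendering.
#' @param snr template trough amplitude on the dominant channel, in units of
#'   `noise_sd_uV`.
#' @param spontaneous_rate_hz background firing rate per unit.
#' @param dc_spontaneous_gain multiplicative spontaneous-rate factor (>= 1)
#'   during DC, applied outside the response window.
#' @param dc_reduction tibble of thinning fractions as produced by
#'   [dc_reduction_defaults()].
#' @param recovery_halflife_min named per-modality half-lives (minutes) of the
#'   post-DC block decay.
#' @param post_times_min post-DC recording-set times (minutes after DC end).
#' @param evoked_count_mean expected evoked spikes per stimulus in the main
#'   response window (per-modality, naive baseline).
#' @param sustained_count_mean expected spikes per stimulus in the sustained
#'   thermal tail (1.5-4.5 s). The default keeps the tail's pooled histogram
#'   elevation below the 1.5x-baseline window-derivation threshold, so the
#'   derived main window still closes at 1.5 s.
#' @param pain_gain multiplicative elevation of evoked counts in pain groups.
#' @param tactile_latency_mean_ms naive tactile latency centre.
#' @param tactile_second_mode_ms centre of the late tactile mode recruited in
#'   pain groups.
#' @param tactile_mixture_weight probability that a pain-group tactile unit
#'   belongs to the late mode; defaults solve the printed group means
#'   (10.85 ms neuropathic, 10.41 ms inflammatory).
#' @param seed integer seed.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(modality = "noxious_thermal",
                             treatment_group = c("naive", "neuropathic", "inflammatory"),
                             sex = c("F", "M"),
                             n_units = 40,
                             sampling_rate_hz = 30000,
                             noise_sd_uV = 5,
                             snr = 8,
                             spontaneous_rate_hz = 3,
                             dc_spontaneous_gain = 1.1,
                             dc_reduction = dc_reduction_defaults(),
                             recovery_halflife_min = c(noxious_thermal = 20,
                                                       noxious_press = 8,
                                                       tactile = 2,
                                                       proprioceptive = 5),
                             post_times_min = c(1:5, seq(10, 45, by = 5)),
                             evoked_count_mean = c(noxious_thermal = 15,
                                                   noxious_press = 4,
                                                   tactile = 1.5,
                                                   proprioceptive = 3),
                             sustained_count_mean = 0.9,
                             pain_gain = 1.3,
                             tactile_latency_mean_ms = 8.31,
                             tactile_second_mode_ms = 16,
                             tactile_mixture_weight = NULL,
                             seed = 1L) {
  treatment_group <- match.arg(treatment_group)
  sex <- match.arg(sex)
  stopifnot(
    n_units >= 1, sampling_rate_hz > 0, noise_sd_uV >= 0, snr > 0,
    spontaneous_rate_hz >= 0, dc_spontaneous_gain >= 1,
    all(dc_reduction$r >= 0 & dc_reduction$r <= 1),
    all(recovery_halflife_min > 0)
  )
  if (is.null(tactile_mixture_weight)) {
    shift <- tactile_second_mode_ms - tactile_latency_mean_ms
    tactile_mixture_weight <- switch(treatment_group,
      naive = 0,
      neuropathic = (10.85 - tactile_latency_mean_ms) / shift,
      inflammatory = (10.41 - tactile_latency_mean_ms) / shift
    )
  }
  stopifnot(tactile_mixture_weight >= 0, tactile_mixture_weight <= 1)
  structure(list(
    modality = modality, treatment_group = treatment_group, sex = sex,
    n_units = n_units, sampling_rate_hz = sampling_rate_hz,
    noise_sd_uV = noise_sd_uV, snr = snr,
    spontaneous_rate_hz = spontaneous_rate_hz,
    dc_spontaneous_gain = dc_spontaneous_gain,
    dc_reduction = dc_reduction,
    recovery_halflife_min = recovery_halflife_min,
    post_times_min = sort(post_times_min),
    evoked_count_mean = evoked_count_mean,
    sustained_count_mean = sustained_count_mean,
    pain_gain = pain_gain,
    tactile_latency_mean_ms = tactile_latency_mean_ms,
    tactile_second_mode_ms = tactile_second_mode_ms,
    tactile_mixture_weight = tactile_mixture_weight,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' Electrode geometry
#'
#' A linearised two-column polytrode layout: channels ordered by depth with
#' 50 um spacing; triples of consecutive channels are "spatially adjacent"
#' groups.
#'
#' @param n_channels number of channels (>= 3 for any template placement).
#' @param spacing_um inter-electrode spacing.
#' @return a list with `n_channels` and `spacing_um`.
#' @export
electrode_geometry <- function(n_channels = 32, spacing_um = 50) {
  list(n_channels = as.integer(n_channels), spacing_um = spacing_um)
}

#' Generate biphasic spike templates
#'
#' Each unit's template is a 3-channel footprint of `n_samples` samples
#' (~1.6 ms at 30 kHz): a negative trough followed by a positive rebound, with
#' the trough equal to `snr * noise_sd_uV` on the dominant channel and
#' attenuated by at least 40% on the flanking channels. Shapes are drawn from
#' randomised width/rebound parameters and redrawn until all pairwise
#' normalised cross-correlations (on the concatenated footprint) fall below
#' 0.95.
#'
#' @param n_units number of templates.
#' @param geometry an [electrode_geometry()]; needs >= 3 channels.
#' @param snr,noise_sd_uV trough amplitude specification (uV = snr * noise sd).
#' @param n_samples samples per channel (48 = 1.6 ms at 30 kHz).
#' @param sampling_rate_hz sampling rate.
#' @param seed integer seed.
#' @param max_tries redraw budget for the similarity constraint.
#' @return a list with `templates` (list of 3 x n_samples matrices),
#'   `channels` (tibble: unit, ch_low, ch_dom, ch_high), and `peak_sample`
#'   (index of the trough within the template).
#' @export
make_templates <- function(n_units, geometry = electrode_geometry(),
                           snr = 8, noise_sd_uV = 5, n_samples = 48,
                           sampling_rate_hz = 30000, seed = 1L,
                           max_tries = 200) {
  if (geometry$n_channels < 3) {
    stop("geometry must have at least 3 channels")
  }
  stopifnot(n_units >= 1)
  local_rng(seed)
  peak_sample <- round(0.0006 * sampling_rate_hz) + 1L  # trough at 0.6 ms
  t_ms <- (seq_len(n_samples) - peak_sample) / sampling_rate_hz * 1000

  draw_shape <- function() {
    w1 <- stats::runif(1, 0.1, 0.3)      # trough width (ms)
    w2 <- stats::runif(1, 0.12, 0.35)    # rebound width
    lag <- stats::runif(1, 0.2, 0.55)    # rebound delay
    amp2 <- stats::runif(1, 0.15, 0.55)  # rebound relative amplitude
    amp0 <- stats::runif(1, 0, 0.3)      # pre-trough positivity
    lag0 <- stats::runif(1, 0.15, 0.4)
    s <- -exp(-(t_ms / w1)^2 / 2) + amp2 * exp(-((t_ms - lag) / w2)^2 / 2) +
      amp0 * exp(-((t_ms + lag0) / 0.15)^2 / 2)
    # taper the tail to zero so the truncated template has no step edge
    # (a step would ring through the band-pass filter and retrigger the
    # detector after the lockout)
    n_tap <- 8L
    tap <- (cos(seq(0, pi, length.out = n_tap)) + 1) / 2
    s[(n_samples - n_tap + 1):n_samples] <-
      s[(n_samples - n_tap + 1):n_samples] * tap
    s / max(abs(s))
  }
  xc <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

  shapes <- vector("list", n_units)
  flanks <- matrix(0, n_units, 2)
  for (u in seq_len(n_units)) {
    best_vec <- NULL
    best_worst <- Inf
    for (try in seq_len(max_tries)) {
      cand <- draw_shape()
      fl <- stats::runif(2, 0.1, 0.6)
      vec <- c(cand * fl[1], cand, cand * fl[2])
      worst <- 0
      if (u > 1) {
        for (p in seq_len(u - 1)) {
          prev <- c(shapes[[p]] * flanks[p, 1], shapes[[p]],
                    shapes[[p]] * flanks[p, 2])
          worst <- max(worst, xc(vec, prev))
        }
      }
      if (worst < best_worst) {
        best_worst <- worst
        shapes[[u]] <- cand
        flanks[u, ] <- fl
      }
      if (best_worst < 0.85) break
    }
    if (best_worst >= 0.95) {
      warning("could not separate template ", u,
              " below cross-correlation 0.95 (best ",
              round(best_worst, 3), ")")
    }
  }

  base <- sample.int(geometry$n_channels - 2, n_units, replace = TRUE)
  amp <- snr * noise_sd_uV
  templates <- lapply(seq_len(n_units), function(u) {
    rbind(shapes[[u]] * flanks[u, 1], shapes[[u]], shapes[[u]] * flanks[u, 2]) * amp
  })
  list(
    templates = templates,
    channels = tibble::tibble(
      unit = seq_len(n_units),
      ch_low = base, ch_dom = base + 1L, ch_high = base + 2L
    ),
    peak_sample = peak_sample
  )
}

# Per-unit latency centres (ms). Tactile centres follow the group mixture
# (late mode recruited in pain groups); other modalities get mild unit-to-unit
# jitter around the modality's canonical burst timing.
unit_latency_centres <- function(modality, n_units, config, seed = NULL) {
  if (!is.null(seed)) local_rng(seed)
  switch(modality,
    tactile = {
      late <- stats::runif(n_units) < config$tactile_mixture_weight
      ifelse(late,
             stats::rnorm(n_units, config$tactile_second_mode_ms, 1.2),
             stats::rnorm(n_units, config$tactile_latency_mean_ms, 1.2))
    },
    noxious_thermal = stats::rnorm(n_units, 1150, 50),
    noxious_press = stats::rnorm(n_units, 140, 30),
    proprioceptive = stats::rnorm(n_units, 60, 10)  # first of the two modes
  )
}

#' Sample evoked spike times for one unit
#'
#' Draws trial-aligned evoked spike times (ms after trigger) from the
#' modality's inhomogeneous-Poisson profile: a sustained thermal burst over
#' ~0.85-1.5 s plus a uniform sustained tail to 4.5 s; a wide press burst in
#' 0-500 ms; one or two precisely timed tactile spikes near the unit's latency
#' centre; and a bimodal proprioceptive burst (rotation and counter-rotation)
#' within 0-400 ms.
#'
#' @param modality stimulus modality.
#' @param n_trials number of trials to draw.
#' @param count_mean expected evoked spikes per trial in the main window.
#' @param latency_centre_ms the unit's latency centre (tactile/press/proprio)
#'   or thermal burst centre.
#' @param sustained_mean expected spikes in the sustained thermal tail
#'   (1.5-4.5 s); 0 disables the tail.
#' @param jitter_ms within-unit trial-to-trial latency jitter (tactile).
#' @param seed integer seed.
#' @return tibble with columns `trial`, `time_ms`.
#' @export
sample_evoked_times <- function(modality, n_trials, count_mean,
                                latency_centre_ms = NULL,
                                sustained_mean = 0, jitter_ms = 1,
                                seed = NULL) {
  if (!is.null(seed)) local_rng(seed)
  stopifnot(n_trials >= 1, count_mean >= 0, sustained_mean >= 0)
  counts <- stats::rpois(n_trials, count_mean)
  trial <- rep(seq_len(n_trials), counts)
  n <- length(trial)
  times <- switch(modality,
    noxious_thermal = {
      centre <- latency_centre_ms %||% 1150
      main <- 850 + (centre - 850) * 2 * stats::rbeta(n, 2, 2)
      pmin(pmax(main, 851), 1499)
    },
    noxious_press = {
      tt <- (latency_centre_ms %||% 140) + stats::rnorm(n, 0, 60)
      tt
    },
    tactile = (latency_centre_ms %||% 8.31) + stats::rnorm(n, 0, jitter_ms),
    proprioceptive = {
      mode1 <- latency_centre_ms %||% 60
      ifelse(stats::runif(n) < 0.5, mode1, mode1 + 200) + stats::rnorm(n, 0, 25)
    },
    stop("unknown modality: ", modality)
  )
  lim <- switch(modality,
    noxious_thermal = c(800, 1500),
    noxious_press = c(20, 490),
    tactile = c(0.5, 39),
    proprioceptive = c(0, 395)
  )
  keep <- times >= lim[1] & times < lim[2]
  out <- tibble::tibble(trial = trial[keep], time_ms = times[keep])
  if (modality == "noxious_thermal" && sustained_mean > 0) {
    tc <- stats::rpois(n_trials, sustained_mean)
    out <- dplyr::bind_rows(out, tibble::tibble(
      trial = rep(seq_len(n_trials), tc),
      time_ms = stats::runif(sum(tc), 1500, 4500)
    ))
  }
  dplyr::arrange(out, .data$trial, .data$time_ms)
}

#' Sample spontaneous spike times
#'
#' Homogeneous Poisson background activity over the trial segment.
#'
#' @param rate_hz firing rate.
#' @param n_trials number of trials.
#' @param span_ms two-element trial span (ms relative to trigger).
#' @param seed integer seed.
#' @return tibble with columns `trial`, `time_ms`.
#' @export
sample_spontaneous_times <- function(rate_hz, n_trials, span_ms = c(-1000, 1000),
                                     seed = NULL) {
  if (!is.null(seed)) local_rng(seed)
  stopifnot(rate_hz >= 0, span_ms[2] > span_ms[1])
  dur_s <- diff(span_ms) / 1000
  counts <- stats::rpois(n_trials, rate_hz * dur_s)
  tibble::tibble(
    trial = rep(seq_len(n_trials), counts),
    time_ms = stats::runif(sum(counts), span_ms[1], span_ms[2])
  ) |>
    dplyr::arrange(.data$trial, .data$time_ms)
}

#' Apply the DC conditioning effect to a spike train
#'
#' During DC, every spike inside the response window is independently removed
#' with probability `r`, so the expected windowed count is exactly `(1 - r)`
#' times its pre-DC value; spontaneous activity outside the window is
#' augmented to `dc_spontaneous_gain` times its base rate. After DC, the
#' thinning probability decays as `r * 2^(-t / halflife)` with `t` the time
#' since DC offset.
#'
#' @param spikes tibble with `trial`, `time_ms` (trial-aligned).
#' @param window_ms two-element window `[start, end)` in ms.
#' @param r thinning fraction in `[0, 1]`.
#' @param phase `"during"` or `"post"`.
#' @param time_since_dc_end_min minutes since DC offset (post phase).
#' @param halflife_min block-decay half-life (post phase).
#' @param spont_rate_hz base spontaneous rate (for the outside-window gain).
#' @param spont_gain spontaneous gain (>= 1) while DC is on.
#' @param span_ms trial span over which gained spontaneous spikes are added.
#' @param n_trials number of trials (gained spikes are added per trial).
#' @param seed integer seed.
#' @return tibble with `trial`, `time_ms`.
#' @export
apply_dc_effect <- function(spikes, window_ms, r,
                            phase = c("during", "post"),
                            time_since_dc_end_min = NA_real_,
                            halflife_min = NA_real_,
                            spont_rate_hz = 0, spont_gain = 1,
                            span_ms = c(-1000, 1000),
                            n_trials = max(spikes$trial, 1L),
                            seed = NULL) {
  phase <- match.arg(phase)
  if (r < 0 || r > 1) stop("r must lie in [0, 1]")
  if (!is.null(seed)) local_rng(seed)
  p_block <- if (phase == "during") {
    r
  } else {
    if (is.na(time_since_dc_end_min) || is.na(halflife_min)) {
      stop("post phase requires time_since_dc_end_min and halflife_min")
    }
    r * 2^(-time_since_dc_end_min / halflife_min)
  }
  out <- spikes
  if (p_block > 0 && nrow(spikes)) {
    inside <- spikes$time_ms >= window_ms[1] & spikes$time_ms < window_ms[2]
    drop <- inside & (stats::runif(nrow(spikes)) < p_block)
    out <- spikes[!drop, , drop = FALSE]
  }
  gain_on <- phase == "during" ||
    (phase == "post" && time_since_dc_end_min <= 0)
  if (gain_on && spont_gain > 1 && spont_rate_hz > 0) {
    extra <- sample_spontaneous_times((spont_gain - 1) * spont_rate_hz,
                                      n_trials, span_ms)
    extra <- extra[extra$time_ms < window_ms[1] | extra$time_ms >= window_ms[2], ]
    out <- dplyr::bind_rows(out, extra)
  }
  dplyr::arrange(out, .data$trial, .data$time_ms)
}

# Enforce an absolute refractory dead time within a single unit's train
# (applied on absolute times, seconds).
enforce_refractory <- function(times_s, dead_s = 0.0015) {
  if (length(times_s) < 2) return(times_s)
  times_s <- sort(times_s)
  keep <- logical(length(times_s))
  last <- -Inf
  for (i in seq_along(times_s)) {
    if (times_s[i] - last >= dead_s) {
      keep[i] <- TRUE
      last <- times_s[i]
    }
  }
  times_s[keep]
}

#' Render a voltage matrix from spike times and templates
#'
#' Adds each unit's 3-channel template into a Gaussian-noise background at
#' its spike samples (linear superposition; overlapping spikes simply add).
#'
#' @param spikes tibble with `unit`, `time_s` (absolute time in the set).
#' @param tmpl a template set from [make_templates()].
#' @param n_channels total channel count.
#' @param duration_s recording duration.
#' @param sampling_rate_hz sampling rate.
#' @param noise_sd_uV Gaussian noise sd; 0 gives a noiseless trace.
#' @param triggers_s stimulus trigger times (s), recorded exactly.
#' @param seed integer seed.
#' @return a list of class `recording_set`: `voltage` (channels x samples,
#'   uV), `triggers` (0-based sample indices), `sampling_rate_hz`.
#' @export
render_voltage <- function(spikes, tmpl, n_channels, duration_s,
                           sampling_rate_hz = 30000, noise_sd_uV = 5,
                           triggers_s = numeric(0), seed = NULL) {
  if (!is.null(seed)) local_rng(seed)
  n_samples <- round(duration_s * sampling_rate_hz)
  v <- matrix(stats::rnorm(n_channels * n_samples, 0, noise_sd_uV),
              nrow = n_channels)
  if (nrow(spikes)) {
    n_t <- ncol(tmpl$templates[[1]])
    pre <- tmpl$peak_sample - 1L
    for (i in seq_len(nrow(spikes))) {
      u <- spikes$unit[i]
      s0 <- round(spikes$time_s[i] * sampling_rate_hz) + 1L
      a <- s0 - pre
      b <- a + n_t - 1L
      if (a < 1L || b > n_samples) next
      ch <- unlist(tmpl$channels[u, c("ch_low", "ch_dom", "ch_high")])
      v[ch, a:b] <- v[ch, a:b] + tmpl$templates[[u]]
    }
  }
  structure(list(
    voltage = v,
    triggers = as.integer(round(triggers_s * sampling_rate_hz)),
    sampling_rate_hz = sampling_rate_hz
  ), class = "recording_set")
}

# Expected in-window counts for one unit, used for ground-truth bookkeeping.
expected_window_count <- function(modality, count_mean, sustained_mean,
                                  window) {
  if (window == "sustained") sustained_mean else count_mean
}

#' Generate a full synthetic session
#'
#' Produces the recording-set manifest of one experimental session: pre-DC
#' sets, the four during-DC permutations of amplitude (500, 1000 uA) and
#' centre polarity (cathodic, anodic) in pseudorandom order, and post-DC sets
#' at the configured times since DC offset. Spike trains are generated at the
#' spike level (fast path); voltage can be rendered per set with
#' [render_voltage()] where needed.
#'
#' @param config a [generator_config()].
#' @param n_pre_sets number of pre-DC sets.
#' @param recovery logical: if `TRUE` the during-DC thinning is complete
#'   (`r = 1`, full conduction block) and post-DC sets decay with the
#'   modality's half-life, the regime of the recovery-time analysis; if
#'   `FALSE` the during-DC thinning uses the configured reduction table and
#'   no post sets are generated.
#' @return a list of class `synthetic_session` with elements `sets` (tibble:
#'   set metadata plus a `spikes` list-column of per-unit trial-aligned spike
#'   tables), `ground_truth` (per-unit tibble), `windows` (the window table
#'   used), and `config`.
#' @export
generate_session <- function(config, n_pre_sets = 1, recovery = FALSE) {
  stopifnot(inherits(config, "generator_config"))
  local_rng(config$seed)
  modality <- config$modality
  par <- stimulus_paradigm(modality)
  span <- c(par$span_pre_ms, par$span_post_ms)
  wins <- default_windows()
  win <- wins[wins$modality == modality & wins$window == "main", ]
  win_ms <- c(win$post_start, win$post_end)

  gain <- if (config$treatment_group == "naive") 1 else config$pain_gain
  count_mean <- config$evoked_count_mean[[modality]] * gain
  sustained_mean <- if (modality == "noxious_thermal") {
    config$sustained_count_mean * gain
  } else {
    0
  }
  centres <- unit_latency_centres(modality, config$n_units, config)
  unit_scale <- stats::rlnorm(config$n_units, 0, 0.3)

  # during-DC permutations in pseudorandom order
  perms <- tidyr::expand_grid(amplitude_uA = c(500, 1000),
                              polarity = c("cathodic_centre", "anodic_centre"))
  perms <- perms[sample.int(nrow(perms)), ]

  halflife <- config$recovery_halflife_min[[modality]]
  rtab <- config$dc_reduction
  r_for <- function(amp) {
    if (recovery) return(1)
    rtab$r[rtab$modality == modality & rtab$group == config$treatment_group &
             rtab$amplitude_uA == amp & rtab$window == "main"]
  }

  sets <- tibble::tibble(
    set_id = character(), phase = character(), amplitude_uA = numeric(),
    polarity = character(), time_since_dc_end_min = numeric(), r_true = numeric()
  )
  add_set <- function(sets, id, phase, amp, pol, t_post, r) {
    dplyr::bind_rows(sets, tibble::tibble(
      set_id = id, phase = phase, amplitude_uA = amp, polarity = pol,
      time_since_dc_end_min = t_post, r_true = r
    ))
  }
  for (i in seq_len(n_pre_sets)) {
    sets <- add_set(sets, sprintf("pre_%02d", i), "pre", 0, "none", NA, 0)
  }
  for (i in seq_len(nrow(perms))) {
    sets <- add_set(sets, sprintf("dc_%02d", i), "during",
                    perms$amplitude_uA[i], perms$polarity[i], NA,
                    r_for(perms$amplitude_uA[i]))
  }
  if (recovery) {
    for (i in seq_along(config$post_times_min)) {
      t_post <- config$post_times_min[i]
      sets <- add_set(sets, sprintf("post_%02d", i), "post", 0, "none",
                      t_post, 2^(-t_post / halflife))
    }
  }

  gen_set <- function(phase, r_eff) {
    lapply(seq_len(config$n_units), function(u) {
      ev <- sample_evoked_times(modality, par$n_stimuli,
                                count_mean * unit_scale[u],
                                latency_centre_ms = centres[u],
                                sustained_mean = sustained_mean * unit_scale[u])
      sp <- sample_spontaneous_times(config$spontaneous_rate_hz,
                                     par$n_stimuli, span)
      all <- dplyr::bind_rows(ev, sp)
      if (phase != "pre" && r_eff > 0) {
        inside <- all$time_ms >= win_ms[1] & all$time_ms < win_ms[2]
        drop <- inside & (stats::runif(nrow(all)) < r_eff)
        all <- all[!drop, , drop = FALSE]
      }
      if (phase == "during" && config$dc_spontaneous_gain > 1) {
        extra <- sample_spontaneous_times(
          (config$dc_spontaneous_gain - 1) * config$spontaneous_rate_hz,
          par$n_stimuli, span)
        extra <- extra[extra$time_ms < win_ms[1] | extra$time_ms >= win_ms[2], ]
        all <- dplyr::bind_rows(all, extra)
      }
      dplyr::arrange(all, .data$trial, .data$time_ms)
    })
  }

  sets$spikes <- lapply(seq_len(nrow(sets)), function(i) {
    gen_set(sets$phase[i], sets$r_true[i])
  })

  e_pre <- count_mean * unit_scale +
    config$spontaneous_rate_hz * diff(win_ms) / 1000
  ground_truth <- tibble::tibble(
    unit = seq_len(config$n_units),
    modality = modality,
    latency_centre_ms = centres,
    evoked_scale = unit_scale,
    expected_window_pre = e_pre
  )

  structure(list(sets = sets, ground_truth = ground_truth,
                 windows = wins, config = config),
            class = "synthetic_session")
}
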