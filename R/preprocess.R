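#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass (default 300-5000 Hz) applied
#' forward-backward (`signal::filtfilt`) for zero phase distortion.
#'
#' @param voltage numeric vector, or channels x samples matrix.
#' @param sampling_rate_hz sampling rate.
#' @param low_hz,high_hz band edges; `high_hz` must be below Nyquist.
#' @param order filter order (per band edge).
#' @return filtered data with the input's shape.
#' @export
bandpass_filter <- function(voltage, sampling_rate_hz,
                            low_hz = 300, high_hz = 5000, order = 4) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < sampling_rate_hz / 2)) {
    stop("band edges must satisfy 0 < low < high < Nyquist")
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / (sampling_rate_hz / 2),
                       type = "pass")
  # odd-reflection padding keeps the forward-backward pass free of start-up
  # transients (the filter state starts at zero); the pad must outlast the
  # low-edge impulse response
  apply_filter <- function(x) {
    n <- length(x)
    np <- min(n - 1, ceiling(3 * sampling_rate_hz / low_hz))
    left <- 2 * x[1] - x[(np + 1):2]
    right <- 2 * x[n] - x[(n - 1):(n - np)]
    y <- as.numeric(signal::filtfilt(bf, c(left, x, right)))
    y[(np + 1):(np + n)]
  }
  if (is.matrix(voltage)) {
    t(apply(voltage, 1, apply_filter))
  } else {
    apply_filter(voltage)
  }
}

#' Segment a recording into trigger-aligned trials
#'
#' @param voltage channels x samples matrix.
#' @param triggers 0-based trigger sample indices.
#' @param sampling_rate_hz sampling rate.
#' @param pre_s,post_s segment extent around each trigger (s).
#' @return a list of channels x samples matrices, one per retained trigger;
#'   triggers too close to the recording edges are dropped with a warning.
#'   Attribute `trigger_sample` gives the within-segment sample index (1-based)
#'   of the trigger, i.e. `pre_s * rate + 1`.
#' @export
segment_trials <- function(voltage, triggers, sampling_rate_hz,
                           pre_s = 1, post_s = 1) {
  if (!is.matrix(voltage)) voltage <- matrix(voltage, nrow = 1)
  n <- ncol(voltage)
  pre_n <- round(pre_s * sampling_rate_hz)
  post_n <- round(post_s * sampling_rate_hz)
  keep <- (triggers - pre_n) >= 0 & (triggers + post_n) < n
  if (any(!keep)) {
    warning(sum(!keep), " trigger(s) too close to the recording edge; dropped")
  }
  segs <- lapply(triggers[keep], function(tr) {
    voltage[, (tr - pre_n + 1):(tr + post_n), drop = FALSE]
  })
  structure(segs, trigger_sample = pre_n + 1L)
}

#' Trial-align spike times
#'
#' Fast-path companion to [segment_trials()]: assigns absolute spike times to
#' trials and re-references them to the trigger (ms).
#'
#' @param times_s absolute spike times (s).
#' @param triggers_s trigger times (s).
#' @param span_ms trial span (ms relative to trigger).
#' @return tibble with `trial`, `time_ms`; spikes outside every span are
#'   dropped.
#' @export
align_spike_times <- function(times_s, triggers_s, span_ms = c(-1000, 1000)) {
  out <- lapply(seq_along(triggers_s), function(i) {
    rel <- (times_s - triggers_s[i]) * 1000
    sel <- rel >= span_ms[1] & rel < span_ms[2]
    tibble::tibble(trial = i, time_ms = rel[sel])
  })
  dplyr::bind_rows(out)
}

#' Select channel groups by evoked energy
#'
#' Scores every triple of spatially adjacent channels by its evoked energy -
#' post-trigger RMS minus pre-trigger RMS, averaged over triggers and summed
#' over the triple - and returns the top non-overlapping triples. Automates
#' the by-eye selection of channel groups showing clear evoked activity.
#'
#' @param voltage channels x samples matrix (filtered).
#' @param triggers 0-based trigger sample indices.
#' @param sampling_rate_hz sampling rate.
#' @param k_groups number of groups to return.
#' @param pre_s,post_s RMS comparison windows around each trigger (s).
#' @return tibble with `group_id`, `ch_low`, `ch_mid`, `ch_high`, `score`,
#'   `low_score` (flag for scores indistinguishable from noise).
#' @export
select_channel_groups <- function(voltage, triggers, sampling_rate_hz,
                                  k_groups = 1, pre_s = 0.5, post_s = 0.5) {
  n_ch <- nrow(voltage)
  if (n_ch < 3) stop("need at least 3 channels to form a group")
  pre_n <- round(pre_s * sampling_rate_hz)
  post_n <- round(post_s * sampling_rate_hz)
  rms <- function(x) sqrt(mean(x^2))
  ch_score <- vapply(seq_len(n_ch), function(ch) {
    deltas <- vapply(triggers, function(tr) {
      a <- max(1, tr - pre_n + 1)
      b <- min(ncol(voltage), tr + post_n)
      rms(voltage[ch, (tr + 1):b]) - rms(voltage[ch, a:tr])
    }, numeric(1))
    mean(deltas)
  }, numeric(1))
  triples <- tibble::tibble(
    ch_low = seq_len(n_ch - 2),
    ch_mid = seq_len(n_ch - 2) + 1L,
    ch_high = seq_len(n_ch - 2) + 2L
  )
  triples$score <- ch_score[triples$ch_low] + ch_score[triples$ch_mid] +
    ch_score[triples$ch_high]
  triples <- dplyr::arrange(triples, dplyr::desc(.data$score))
  taken <- logical(n_ch)
  picked <- list()
  for (i in seq_len(nrow(triples))) {
    chs <- unlist(triples[i, c("ch_low", "ch_mid", "ch_high")])
    if (!any(taken[chs])) {
      taken[chs] <- TRUE
      picked[[length(picked) + 1]] <- triples[i, ]
      if (length(picked) == k_groups) break
    }
  }
  out <- dplyr::bind_rows(picked)
  out$group_id <- seq_len(nrow(out))
  noise_floor <- stats::sd(ch_score) * 2
  out$low_score <- out$score < max(noise_floor, 1e-12)
  dplyr::select(out, "group_id", "ch_low", "ch_mid", "ch_high",
                "score", "low_score")
}

#' Detect spikes on a channel group
#'
#' Negative-threshold detector: a spike event occurs where any channel of
#' the group crosses `-theta` with `theta = multiplier * median(|v|) / 0.6745`
#' per channel (a robust noise-sd estimate). Events are aligned to the
#' negative peak across the group, with a lockout after each event, and a
#' waveform snippet spanning `snip_pre_ms` before to `snip_post_ms` after the
#' peak is cut out.
#'
#' @param voltage 3 x samples matrix (one filtered channel group).
#' @param sampling_rate_hz sampling rate.
#' @param multiplier threshold in robust-noise-sd units.
#' @param lockout_ms dead time after each detected event.
#' @param snip_pre_ms,snip_post_ms snippet extent around the aligned peak.
#' @return tibble with `event_id`, `sample` (1-based peak sample), `time_s`,
#'   `peak_channel`, `amplitude_uV`, and a `waveform` list-column of
#'   3 x n_snippet matrices. Events whose snippet would cross the recording
#'   edge are discarded. A flat (zero-variance) input yields zero events with
#'   a warning.
#' @export
detect_spikes <- function(voltage, sampling_rate_hz, multiplier = 4.5,
                          lockout_ms = 1, snip_pre_ms = 0.6,
                          snip_post_ms = 1.0) {
  if (!is.matrix(voltage)) voltage <- matrix(voltage, nrow = 1)
  n <- ncol(voltage)
  theta <- apply(voltage, 1, function(x) {
    multiplier * stats::median(abs(x)) / 0.6745
  })
  if (all(theta == 0)) {
    warning("flat (zero-variance) trace: no spikes detected")
    return(empty_events(sampling_rate_hz, snip_pre_ms, snip_post_ms))
  }
  below <- sweep(voltage, 1, -theta, `<`)
  cand <- which(colSums(below) > 0)
  if (!length(cand)) {
    return(empty_events(sampling_rate_hz, snip_pre_ms, snip_post_ms))
  }
  lock_n <- round(lockout_ms / 1000 * sampling_rate_hz)
  align_n <- round(0.5 / 1000 * sampling_rate_hz)
  pre_n <- round(snip_pre_ms / 1000 * sampling_rate_hz)
  post_n <- round(snip_post_ms / 1000 * sampling_rate_hz)

  events <- list()
  next_ok <- 1
  for (s in cand) {
    if (s < next_ok) next
    b <- min(n, s + align_n)
    seg <- voltage[, s:b, drop = FALSE]
    peak_rel <- which(seg == min(seg), arr.ind = TRUE)[1, ]
    peak_sample <- s + as.integer(peak_rel[2]) - 1L
    peak_channel <- as.integer(peak_rel[1])
    a <- peak_sample - pre_n
    z <- peak_sample + post_n - 1L
    if (a >= 2 && z <= n - 1) {
      # sub-sample alignment: parabolic interpolation of the trough, then
      # cubic resampling of the snippet at the fractional offset, so that
      # +/- 1 sample jitter does not masquerade as a shape difference
      y <- voltage[peak_channel, (peak_sample - 1):(peak_sample + 1)]
      denom <- y[1] - 2 * y[2] + y[3]
      delta <- if (denom > 0) 0.5 * (y[1] - y[3]) / denom else 0
      delta <- max(-0.5, min(0.5, delta))
      wav <- t(vapply(seq_len(nrow(voltage)), function(ch) {
        stats::spline(x = (a - 1):(z + 1),
                      y = voltage[ch, (a - 1):(z + 1)],
                      xout = (a:z) + delta, method = "fmm")$y
      }, numeric(z - a + 1L)))
      events[[length(events) + 1]] <- list(
        sample = peak_sample,
        time_s = (peak_sample - 1 + delta) / sampling_rate_hz,
        peak_channel = peak_channel,
        amplitude_uV = voltage[peak_channel, peak_sample],
        waveform = wav
      )
    }
    next_ok <- peak_sample + lock_n
  }
  if (!length(events)) {
    return(empty_events(sampling_rate_hz, snip_pre_ms, snip_post_ms))
  }
  tibble::tibble(
    event_id = seq_along(events),
    sample = vapply(events, `[[`, integer(1), "sample"),
    time_s = vapply(events, `[[`, numeric(1), "time_s"),
    peak_channel = vapply(events, `[[`, integer(1), "peak_channel"),
    amplitude_uV = vapply(events, `[[`, numeric(1), "amplitude_uV"),
    waveform = lapply(events, `[[`, "waveform")
  )
}

empty_events <- function(rate, pre_ms, post_ms) {
  tibble::tibble(
    event_id = integer(0), sample = integer(0), time_s = numeric(0),
    peak_channel = integer(0), amplitude_uV = numeric(0),
    waveform = list()
  )
}
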