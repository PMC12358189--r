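#' Simulate a percent-reduction study on the spike-level fast path
#'
#' Generates per-trial windowed counts for a population of units of one
#' modality under pre-DC and during-DC conditions, with the during-DC
#' response thinned by the ground-truth fraction `r` (all spikes inside the
#' analysed window are thinned; spontaneous activity outside the window is
#' elevated by the DC gain). This is the generative regime under which
#' [estimate_reduction()] should recover `r` as the EMM-based percent
#' reduction.
#'
#' @param modality stimulus modality.
#' @param group treatment group.
#' @param n_units number of units.
#' @param n_sets_per_phase recording sets per phase (trials per set follow
#'   the paradigm: 2 for thermal, 50 otherwise).
#' @param amplitude_uA DC amplitude (selects the reduction-table row when `r`
#'   is not given).
#' @param window `"main"` or `"sustained"` (thermal only).
#' @param r ground-truth thinning fraction; defaults to the configured
#'   reduction table value for the condition.
#' @param config a [generator_config()] supplying rates, gains and latency
#'   structure.
#' @param seed integer seed.
#' @return a list with `counts` (tibble: unit, phase, set, trial, pre_count,
#'   post_count), `r_true`, and `window` (the window row used).
#' @export
simulate_reduction_study <- function(modality, group, n_units = 60,
                                     n_sets_per_phase = 1,
                                     amplitude_uA = 1000,
                                     window = c("main", "sustained"),
                                     r = NULL,
                                     config = NULL,
                                     seed = 1L) {
  window <- match.arg(window)
  config <- config %||% generator_config(modality = modality,
                                         treatment_group = group,
                                         n_units = n_units, seed = seed)
  local_rng(seed)
  par <- stimulus_paradigm(modality)
  span <- c(par$span_pre_ms, par$span_post_ms)
  wins <- default_windows()
  win <- wins[wins$modality == modality & wins$window == window, ]
  if (!nrow(win)) stop("no ", window, " window for modality ", modality)
  win_ms <- c(win$post_start, win$post_end)
  if (is.null(r)) {
    rt <- config$dc_reduction
    r <- rt$r[rt$modality == modality & rt$group == group &
                rt$amplitude_uA == amplitude_uA & rt$window == window]
  }
  stopifnot(length(r) == 1, r >= 0, r <= 1)

  gain <- if (group == "naive") 1 else config$pain_gain
  count_mean <- config$evoked_count_mean[[modality]] * gain
  sustained_mean <- if (modality == "noxious_thermal") {
    config$sustained_count_mean * gain
  } else {
    0
  }
  centres <- unit_latency_centres(modality, n_units, config)
  unit_scale <- stats::rlnorm(n_units, 0, 0.3)

  rows <- list()
  for (u in seq_len(n_units)) {
    for (phase in c("pre", "during")) {
      for (s in seq_len(n_sets_per_phase)) {
        ev <- sample_evoked_times(modality, par$n_stimuli,
                                  count_mean * unit_scale[u],
                                  latency_centre_ms = centres[u],
                                  sustained_mean = sustained_mean * unit_scale[u])
        sp <- sample_spontaneous_times(config$spontaneous_rate_hz,
                                       par$n_stimuli, span)
        spikes <- dplyr::bind_rows(ev, sp)
        if (phase == "during") {
          spikes <- apply_dc_effect(
            spikes, win_ms, r, phase = "during",
            spont_rate_hz = config$spontaneous_rate_hz,
            spont_gain = config$dc_spontaneous_gain,
            span_ms = span, n_trials = par$n_stimuli
          )
        }
        cc <- windowed_counts(spikes, win, par$n_stimuli, span_ms = span)
        cc$unit <- u
        cc$phase <- phase
        cc$set <- s
        rows[[length(rows) + 1]] <- cc
      }
    }
  }
  counts <- dplyr::bind_rows(rows) |>
    dplyr::select("unit", "phase", "set", "trial", "pre_count", "post_count")
  list(counts = counts, r_true = r, window = win)
}

#' Simulate a post-DC recovery study
#'
#' Generates, for each modality, a population of units that are completely
#' blocked during DC (thinning `r = 1`) and whose block decays after DC
#' offset with the modality's half-life. Each post-DC recording set is then
#' scored with the evoked criterion and recovery times extracted.
#'
#' @param modalities modalities to simulate.
#' @param n_units units per modality.
#' @param seed integer seed.
#' @param horizon_min censoring horizon.
#' @return tibble: `modality`, `unit`, `blocked_during_dc`, `recovery_min`,
#'   `censored`.
#' @export
simulate_recovery_study <- function(modalities = c("tactile", "noxious_press",
                                                   "noxious_thermal"),
                                    n_units = 30, seed = 1L,
                                    horizon_min = 45) {
  out <- list()
  for (m in modalities) {
    cfg <- generator_config(modality = m, treatment_group = "naive",
                            n_units = n_units,
                            seed = derive_seed(seed, paste0("recovery_", m)))
    ses <- generate_session(cfg, recovery = TRUE)
    win <- ses$windows[ses$windows$modality == m &
                         ses$windows$window == "main", ]
    par <- stimulus_paradigm(m)
    span <- c(par$span_pre_ms, par$span_post_ms)
    for (u in seq_len(n_units)) {
      per_set <- lapply(seq_len(nrow(ses$sets)), function(i) {
        sp <- ses$sets$spikes[[i]][[u]]
        cc <- windowed_counts(sp, win, par$n_stimuli, span_ms = span)
        ev <- classify_evoked(cc)
        tibble::tibble(
          phase = ses$sets$phase[i],
          time_since_dc_end_min = ses$sets$time_since_dc_end_min[i],
          evoked = ev$evoked
        )
      })
      rec <- recovery_time(dplyr::bind_rows(per_set), horizon_min = horizon_min)
      rec$modality <- m
      rec$unit <- u
      out[[length(out) + 1]] <- rec
    }
  }
  dplyr::bind_rows(out) |>
    dplyr::select("modality", "unit", "blocked_during_dc",
                  "recovery_min", "censored")
}
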