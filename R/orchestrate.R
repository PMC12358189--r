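#' Pipeline configuration
#'
#' Bundles the stage parameters of the end-to-end analysis. Every stochastic
#' stage consumes a seed derived deterministically from the global seed and
#' the stage name, so a fixed global seed makes the whole pipeline
#' reproducible.
#'
#' @param modality,treatment_group,n_units passed to [generator_config()].
#' @param amplitude_uA during-DC amplitude analysed for the reduction table.
#' @param window_mode `"fixed"` uses the canonical window table
#'   ([default_windows()]); `"derived"` re-derives the post window from the
#'   session's pooled latency histogram.
#' @param n_pre_sets number of pre-DC recording sets; derived-window mode
#'   pools the latency histogram across all of them, so thermal sessions
#'   (2 trials per set) need several for a stable baseline.
#' @param alpha evoked-test level.
#' @param horizon_min recovery censoring horizon.
#' @param recovery include the post-DC recovery stage (complete block during
#'   DC).
#' @param seed global seed.
#' @param ... further arguments forwarded to [generator_config()].
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(modality = "noxious_thermal",
                            treatment_group = "naive",
                            n_units = 20,
                            amplitude_uA = 1000,
                            window_mode = c("fixed", "derived"),
                            n_pre_sets = 1,
                            alpha = 0.05,
                            horizon_min = 45,
                            recovery = FALSE,
                            seed = 1L, ...) {
  window_mode <- match.arg(window_mode)
  structure(list(
    modality = modality, treatment_group = treatment_group,
    n_units = n_units, amplitude_uA = amplitude_uA,
    window_mode = window_mode, n_pre_sets = n_pre_sets,
    alpha = alpha, horizon_min = horizon_min,
    recovery = recovery, seed = as.integer(seed),
    generator_args = list(...)
  ), class = "pipeline_config")
}

#' Run the end-to-end analysis pipeline on a synthetic session
#'
#' Generates a session (spike-level fast path), derives or loads the
#' response windows, computes per-trial windowed counts, classifies evoked
#' responses, estimates the DC-mediated percent reduction with the
#' mixed-model EMMs, extracts spontaneous rates, and (optionally) the
#' post-DC recovery distribution.
#'
#' @param config a [pipeline_config()].
#' @return a list of class `spikedc_report`: `unit_inventory`, `counts`,
#'   `evoked`, `reduction`, `spontaneous`, `recovery` (NULL unless
#'   requested), `windows`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  gc_args <- c(list(modality = config$modality,
                    treatment_group = config$treatment_group,
                    n_units = config$n_units,
                    seed = derive_seed(config$seed, "generate")),
               config$generator_args)
  gen <- do.call(generator_config, gc_args)
  session <- generate_session(gen, n_pre_sets = config$n_pre_sets,
                              recovery = config$recovery)
  par <- stimulus_paradigm(config$modality)
  span <- c(par$span_pre_ms, par$span_post_ms)

  win <- session$windows[session$windows$modality == config$modality &
                           session$windows$window == "main", ]
  derived <- NULL
  if (config$window_mode == "derived") {
    pre_spikes <- dplyr::bind_rows(lapply(
      which(session$sets$phase == "pre"),
      function(i) dplyr::bind_rows(session$sets$spikes[[i]])
    ))
    hist <- build_latency_histogram(pre_spikes$time_ms, win$bin_width,
                                    span_ms = span,
                                    modality = config$modality)
    derived <- derive_window(hist)
    win$post_start <- derived$start
    win$post_end <- derived$end
  }

  # per unit x set counts and evoked classification
  counts <- list()
  evoked <- list()
  for (i in seq_len(nrow(session$sets))) {
    for (u in seq_len(config$n_units)) {
      cc <- windowed_counts(session$sets$spikes[[i]][[u]], win,
                            par$n_stimuli, span_ms = span)
      cc$unit <- u
      cc$set_id <- session$sets$set_id[i]
      cc$phase <- session$sets$phase[i]
      cc$amplitude_uA <- session$sets$amplitude_uA[i]
      cc$polarity <- session$sets$polarity[i]
      cc$time_since_dc_end_min <- session$sets$time_since_dc_end_min[i]
      counts[[length(counts) + 1]] <- cc
      ev <- classify_evoked(cc, alpha = config$alpha)
      ev$unit <- u
      ev$set_id <- session$sets$set_id[i]
      ev$phase <- session$sets$phase[i]
      ev$time_since_dc_end_min <- session$sets$time_since_dc_end_min[i]
      evoked[[length(evoked) + 1]] <- ev
    }
  }
  counts <- dplyr::bind_rows(counts)
  evoked <- dplyr::bind_rows(evoked)

  red_data <- counts[counts$phase %in% c("pre", "during"), ]
  reduction <- tryCatch(
    estimate_reduction(red_data),
    error = function(e) {
      warning("reduction stage failed: ", conditionMessage(e))
      NULL
    }
  )

  spont <- dplyr::bind_rows(lapply(seq_len(nrow(session$sets)), function(i) {
    rates <- vapply(seq_len(config$n_units), function(u) {
      sp <- session$sets$spikes[[i]][[u]]
      spontaneous_rates(sp, "single_unit",
                        pre_window_ms = c(win$pre_start, win$pre_end),
                        n_trials = par$n_stimuli)$rate_hz
    }, numeric(1))
    tibble::tibble(set_id = session$sets$set_id[i],
                   phase = session$sets$phase[i],
                   unit = seq_len(config$n_units),
                   rate_hz = rates)
  }))

  recovery <- NULL
  if (config$recovery) {
    recovery <- dplyr::bind_rows(lapply(seq_len(config$n_units), function(u) {
      per <- evoked[evoked$unit == u & evoked$phase %in% c("during", "post"), ]
      rec <- recovery_time(per, horizon_min = config$horizon_min)
      rec$unit <- u
      rec
    }))
  }

  inventory <- dplyr::count(
    dplyr::left_join(
      session$ground_truth,
      dplyr::summarise(
        dplyr::group_by(evoked[evoked$phase == "pre", ], .data$unit),
        evoked_pre = any(.data$evoked), .groups = "drop"
      ),
      by = "unit"
    ),
    .data$modality, .data$evoked_pre
  )

  structure(list(
    unit_inventory = inventory,
    counts = counts,
    evoked = evoked,
    reduction = reduction,
    spontaneous = spont,
    recovery = recovery,
    windows = win,
    derived_window = derived,
    manifest = tibble::tibble(
      seed = config$seed,
      config_hash = rlang::hash(config),
      n_units = config$n_units,
      modality = config$modality,
      treatment_group = config$treatment_group,
      window_mode = config$window_mode
    )
  ), class = "spikedc_report")
}

#' @export
print.spikedc_report <- function(x, ...) {
  cat("<spikedc_report>", x$manifest$modality, "/",
      x$manifest$treatment_group, "\n")
  cat("  units:", x$manifest$n_units,
      " window:", x$windows$post_start, "-", x$windows$post_end, "ms\n")
  if (!is.null(x$reduction)) {
    cat(sprintf("  percent reduction (EMM): %.1f%% (p = %.3g)\n",
                x$reduction$pct_reduction, x$reduction$p_value))
  }
  invisible(x)
}
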