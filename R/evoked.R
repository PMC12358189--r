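#' Classify an evoked response
#'
#' Tests whether a unit's post-stimulus windowed spike count significantly
#' exceeds its pre-stimulus count (alpha = .05 by default). The default test
#' is a paired one-sided t-test on the per-trial (post - pre) differences;
#' an unpaired two-sample variant is available. Zero-variance differences
#' are handled as degenerate cases: a constant positive difference is evoked
#' (p = 0), a constant zero or negative difference is not (p = 1).
#'
#' @param counts tibble with `pre_count`, `post_count` (one row per trial).
#' @param alpha significance level.
#' @param paired paired (default) or two-sample t-test.
#' @return one-row tibble: `n_trials`, `t`, `p_value`, `evoked`.
#' @export
classify_evoked <- function(counts, alpha = 0.05, paired = TRUE) {
  n <- nrow(counts)
  if (n < 2) stop("cannot test an evoked response with fewer than 2 trials")
  d <- counts$post_count - counts$pre_count
  if (paired) {
    if (stats::sd(d) == 0) {
      p <- if (mean(d) > 0) 0 else 1
      tt <- NA_real_
    } else {
      ht <- stats::t.test(d, alternative = "greater")
      p <- ht$p.value
      tt <- unname(ht$statistic)
    }
  } else {
    if (stats::sd(counts$post_count) == 0 && stats::sd(counts$pre_count) == 0) {
      p <- if (mean(d) > 0) 0 else 1
      tt <- NA_real_
    } else {
      ht <- stats::t.test(counts$post_count, counts$pre_count,
                          alternative = "greater")
      p <- ht$p.value
      tt <- unname(ht$statistic)
    }
  }
  tibble::tibble(
    n_trials = n,
    t = tt,
    p_value = p,
    evoked = mean(d) > 0 && p < alpha
  )
}

#' Percent reduction from baseline
#'
#' `100 * (1 - emm_dc / emm_pre)`. Increases come out negative (an increase
#' is reported as a negative reduction, never clamped at zero).
#'
#' @param emm_pre baseline estimated marginal mean (> 0).
#' @param emm_dc during-DC estimated marginal mean.
#' @return percent reduction.
#' @export
percent_reduction <- function(emm_pre, emm_dc) {
  if (any(emm_pre <= 0)) stop("emm_pre must be positive")
  100 * (1 - emm_dc / emm_pre)
}

#' Post-DC recovery time of a unit
#'
#' A unit is blocked during DC when its evoked criterion fails in every
#' during-DC recording set. For blocked units, the recovery time is the time
#' since DC cessation of the first post-DC set that passes the evoked
#' criterion; units that never re-pass within the observation horizon are
#' censored.
#'
#' @param evoked_by_set tibble with one row per recording set: `phase`
#'   (`"during"` / `"post"`), `time_since_dc_end_min`, `evoked` (logical).
#'   Must contain at least one post-DC set.
#' @param horizon_min observation horizon (minutes).
#' @return one-row tibble: `blocked_during_dc`, `recovery_min`, `censored`.
#' @export
recovery_time <- function(evoked_by_set, horizon_min = 45) {
  during <- evoked_by_set[evoked_by_set$phase == "during", ]
  post <- evoked_by_set[evoked_by_set$phase == "post", ]
  if (!nrow(post)) stop("no post-DC sets: recovery time is undefined")
  post <- dplyr::arrange(post, .data$time_since_dc_end_min)
  blocked <- nrow(during) > 0 && !any(during$evoked)
  if (!blocked) {
    return(tibble::tibble(blocked_during_dc = FALSE,
                          recovery_min = NA_real_, censored = NA))
  }
  hit <- which(post$evoked & post$time_since_dc_end_min <= horizon_min)
  tibble::tibble(
    blocked_during_dc = TRUE,
    recovery_min = if (length(hit)) post$time_since_dc_end_min[hit[1]] else NA_real_,
    censored = !length(hit)
  )
}

#' Spontaneous firing rates
#'
#' Two levels of analysis: multi-unit rates are computed from unsorted
#' detector events per channel over the pre-stimulus period of a recording
#' block (before any stimulus); single-unit rates are computed from a sorted
#' unit's spikes inside the per-trial pre-stimulus windows.
#'
#' @param x for `mode = "multi_unit"`: a tibble of detector events with
#'   `channel` and `time_s`; for `mode = "single_unit"`: a tibble of
#'   trial-aligned unit spikes with `trial`, `time_ms`.
#' @param mode analysis level.
#' @param period_s duration of the pre-stimulus period (multi-unit mode);
#'   must be at least 1 s.
#' @param pre_window_ms pre-stimulus window (single-unit mode).
#' @param n_trials number of trials (single-unit mode).
#' @param channels channels to report (multi-unit mode; defaults to those
#'   present).
#' @return tibble with `id` (channel or `"unit"`), `level`, `rate_hz`.
#' @export
spontaneous_rates <- function(x, mode = c("multi_unit", "single_unit"),
                              period_s = NULL, pre_window_ms = c(-1000, 0),
                              n_trials = NULL, channels = NULL) {
  mode <- match.arg(mode)
  if (mode == "multi_unit") {
    if (is.null(period_s) || period_s < 1) {
      stop("multi-unit mode needs a pre-stimulus period of at least 1 s")
    }
    channels <- channels %||% sort(unique(x$channel))
    counts <- tabulate(factor(x$channel, levels = channels), length(channels))
    tibble::tibble(
      id = as.character(channels),
      level = "multi_unit_per_channel",
      rate_hz = counts / period_s
    )
  } else {
    if (is.null(n_trials)) stop("single-unit mode needs n_trials")
    total_s <- n_trials * diff(pre_window_ms) / 1000
    if (total_s <= 0) stop("no pre-stimulus period")
    n_sp <- sum(x$time_ms >= pre_window_ms[1] & x$time_ms < pre_window_ms[2])
    tibble::tibble(
      id = "unit",
      level = "single_unit",
      rate_hz = n_sp / total_s
    )
  }
}

#' Peak response latency
#'
#' The centre of the post-stimulus histogram bin holding the maximum spike
#' count. Ties break toward the earlier bin.
#'
#' @param times_ms trial-aligned spike times (ms); only `t >= 0` contribute.
#' @param bin_width_ms histogram bin width.
#' @return peak latency (ms, bin centre).
#' @export
peak_latency <- function(times_ms, bin_width_ms = 1) {
  post <- times_ms[times_ms >= 0]
  if (!length(post)) stop("no post-stimulus spikes: peak latency undefined")
  idx <- floor(post / bin_width_ms)
  counts <- table(idx)
  top <- as.numeric(names(counts))[counts == max(counts)]
  (min(top) + 0.5) * bin_width_ms
}
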