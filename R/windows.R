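#' Canonical response-window table
#'
#' Pre- and post-stimulus counting windows (ms relative to the trigger) for
#' each stimulus modality, with the sustained thermal window as a separate
#' row. The sustained row carries a pre-count multiplier of 3 because its 3 s
#' post window is compared against a 1 s pre window. Bin widths are the ones
#' used for that modality's latency histograms (50 ms thermal, 10 ms press
#' and proprioceptive, 1 ms tactile).
#'
#' @return a tibble with columns `modality`, `window`, `pre_start`,
#'   `pre_end`, `post_start`, `post_end`, `multiplier`, `bin_width`.
#' @export
default_windows <- function() {
  tibble::tribble(
    ~modality,          ~window,     ~pre_start, ~pre_end, ~post_start, ~post_end, ~multiplier, ~bin_width,
    "noxious_thermal",  "main",      -700,       0,        800,         1500,      1,           50,
    "noxious_thermal",  "sustained", -1000,      0,        1500,        4500,      3,           50,
    "noxious_press",    "main",      -500,       0,        0,           500,       1,           10,
    "tactile",          "main",      -40,        0,        0,           40,        1,           1,
    "proprioceptive",   "main",      -400,       0,        0,           400,       1,           10
  )
}

#' Pooled latency histogram
#'
#' Builds the relative-frequency histogram of trial-aligned spike times used
#' for response-window derivation. Bins tile the trial span with an edge at
#' t = 0; the baseline frequency is the mean per-bin frequency over the
#' pre-stimulus span.
#'
#' @param times_ms pooled trial-aligned spike times (ms after trigger).
#' @param bin_width_ms histogram bin width (1, 10 or 50 ms by modality
#'   convention, but any positive width is accepted).
#' @param span_ms two-element trial span; defaults to the range implied by
#'   the data, snapped outward to bin edges.
#' @param modality optional modality label carried in the result.
#' @return an object of class `latency_histogram`: a tibble with `bin_start`,
#'   `bin_end`, `freq`, and attributes `bin_width`, `baseline`, `n`,
#'   `modality`.
#' @export
build_latency_histogram <- function(times_ms, bin_width_ms,
                                    span_ms = NULL, modality = NA_character_) {
  if (length(times_ms) == 0) stop("empty spike pool: cannot build histogram")
  stopifnot(bin_width_ms > 0)
  if (is.null(span_ms)) span_ms <- range(times_ms)
  lo <- floor(span_ms[1] / bin_width_ms) * bin_width_ms
  hi <- ceiling(span_ms[2] / bin_width_ms) * bin_width_ms
  if (hi <= lo) hi <- lo + bin_width_ms
  edges <- seq(lo, hi, by = bin_width_ms)
  counts <- tabulate(
    findInterval(times_ms, edges, rightmost.closed = FALSE, left.open = FALSE),
    nbins = length(edges) - 1
  )
  # spikes exactly at the top edge would fall outside; they are rare and
  # excluded by the half-open convention
  freq <- counts / sum(counts)
  out <- tibble::tibble(
    bin_start = edges[-length(edges)],
    bin_end = edges[-1],
    freq = freq
  )
  pre <- out$bin_end <= 0
  baseline <- if (any(pre)) mean(out$freq[pre]) else 0
  structure(out, class = c("latency_histogram", class(out)),
            bin_width = bin_width_ms, baseline = baseline,
            n = length(times_ms), modality = modality)
}

# Round a window edge outward from the peak. The rounding step is one
# significant figure of the raw window width, so 2 -> 0 and 38 -> 40 for a
# 36 ms-wide tactile crossing, and 820 -> 800, 1480 -> 1500 for a 660 ms-wide
# thermal crossing. Zero-magnitude edges stay 0.
round_edge_outward <- function(edge, peak, width) {
  if (edge == 0) return(0)
  step <- 10^floor(log10(width))
  if (edge <= peak) floor(edge / step) * step else ceiling(edge / step) * step
}

#' Derive a post-stimulus response window from a latency histogram
#'
#' Finds the first and last post-stimulus bin whose frequency is at least
#' `factor` times the baseline frequency; the window edges are then rounded
#' away from the peak-frequency bin to one significant figure (step taken
#' from the magnitude of the raw window width).
#'
#' @param hist a [build_latency_histogram()] result.
#' @param factor threshold multiple of the baseline frequency.
#' @return a one-row tibble with `start`, `end` (ms), `peak_ms`, `raw_start`,
#'   `raw_end`.
#' @export
derive_window <- function(hist, factor = 1.5) {
  baseline <- attr(hist, "baseline")
  if (is.null(baseline) || baseline <= 0) {
    stop("histogram baseline must be positive to derive a window")
  }
  post <- hist[hist$bin_start >= 0, , drop = FALSE]
  cross <- post$freq >= factor * baseline
  if (!any(cross)) {
    stop("no post-stimulus bin reaches ", factor, "x the baseline frequency")
  }
  a <- post$bin_start[which(cross)[1]]
  b <- post$bin_end[max(which(cross))]
  peak_bin <- which.max(post$freq)
  peak <- (post$bin_start[peak_bin] + post$bin_end[peak_bin]) / 2
  width <- b - a
  tibble::tibble(
    start = round_edge_outward(a, peak, width),
    end = round_edge_outward(b, peak, width),
    peak_ms = peak,
    raw_start = a,
    raw_end = b
  )
}

#' Per-trial windowed spike counts
#'
#' Counts spikes in the pre- and post-stimulus windows of each trial using
#' half-open intervals `[start, end)`. The pre count is multiplied by the
#' window's `multiplier` (3 for the sustained thermal window, which compares
#' a 3 s post window against a 1 s pre window).
#'
#' @param spikes tibble of trial-aligned spikes with `trial`, `time_ms`.
#' @param window one row of [default_windows()] (or any row-compatible
#'   tibble with `pre_start`, `pre_end`, `post_start`, `post_end`,
#'   `multiplier`).
#' @param n_trials total number of trials (trials with no spikes still yield
#'   a row of zeros).
#' @param span_ms trial segment span; the window must lie inside it.
#' @return tibble with `trial`, `pre_count`, `post_count`.
#' @export
windowed_counts <- function(spikes, window, n_trials,
                            span_ms = NULL) {
  stopifnot(nrow(window) == 1)
  if (!is.null(span_ms)) {
    if (window$pre_start < span_ms[1] || window$post_end > span_ms[2]) {
      stop("window extends beyond the trial segment")
    }
  }
  trials <- seq_len(n_trials)
  inw <- function(t, lo, hi) t >= lo & t < hi
  pre <- spikes[inw(spikes$time_ms, window$pre_start, window$pre_end), ]
  post <- spikes[inw(spikes$time_ms, window$post_start, window$post_end), ]
  tibble::tibble(
    trial = trials,
    pre_count = tabulate(factor(pre$trial, levels = trials), n_trials) *
      window$multiplier,
    post_count = tabulate(factor(post$trial, levels = trials), n_trials)
  )
}
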