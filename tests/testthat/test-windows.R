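test_that("latency histograms tile the span, normalise, and expose the
           baseline", {
  set.seed(1)
  x <- stats::runif(1000, -1000, 1000)
  h <- build_latency_histogram(x, 10, span_ms = c(-1000, 1000))
  expect_equal(nrow(h), 200)
  expect_equal(sum(h$freq), 1)
  expect_true(any(h$bin_start == 0))  # edge at t = 0
  # uniform spikes: bins concentrate around 1/200 (multinomial oracle);
  # with 200 bins a uniform band of 4.5 SDs holds jointly
  p <- 1 / 200
  expect_true(all(abs(h$freq - p) < 4.5 * sqrt(p * (1 - p) / 1000)))
  # flat histogram: baseline equals a typical bin frequency
  expect_lt(abs(attr(h, "baseline") - p), 3 * sqrt(p * (1 - p) / 1000) / 10)

  # point mass: single nonzero bin [5, 6) ms at 1 ms bins
  hp <- build_latency_histogram(rep(5.2, 40), 1, span_ms = c(-40, 40))
  expect_equal(hp$bin_start[hp$freq > 0], 5)
  expect_equal(max(hp$freq), 1)

  expect_error(build_latency_histogram(numeric(0), 1), "empty")
})

test_that("window derivation reproduces the canonical tactile and thermal
           windows from specified crossings", {
  # tactile-like: 1 ms bins over [-40, 40); crossing bins [2,3) .. [37,38),
  # peak at 8 ms, low uniform baseline -> window 0-40 ms
  bins <- seq(-40, 39)
  freq <- rep(0.001, length(bins))
  freq[bins >= 2 & bins < 38] <- 0.01
  freq[bins == 8] <- 0.05
  h <- structure(
    tibble::tibble(bin_start = bins, bin_end = bins + 1, freq = freq / sum(freq)),
    class = c("latency_histogram", "tbl_df", "tbl", "data.frame"),
    bin_width = 1, baseline = 0.001 / sum(freq), n = 1000, modality = "tactile"
  )
  w <- derive_window(h)
  expect_equal(w$start, 0)
  expect_equal(w$end, 40)

  # thermal-like: 20 ms bins, crossings spanning 820-1480 ms, peak 1100 ms
  bins2 <- seq(-1000, 4480, by = 20)
  freq2 <- rep(0.0005, length(bins2))
  freq2[bins2 >= 820 & bins2 < 1480] <- 0.004
  freq2[bins2 == 1100] <- 0.02
  h2 <- structure(
    tibble::tibble(bin_start = bins2, bin_end = bins2 + 20,
                   freq = freq2 / sum(freq2)),
    class = c("latency_histogram", "tbl_df", "tbl", "data.frame"),
    bin_width = 20, baseline = 0.0005 / sum(freq2), n = 1000,
    modality = "noxious_thermal"
  )
  w2 <- derive_window(h2)
  expect_equal(w2$start, 800)
  expect_equal(w2$end, 1500)

  # uniform histogram: no bin reaches threshold
  h3 <- structure(
    tibble::tibble(bin_start = bins, bin_end = bins + 1,
                   freq = rep(1 / length(bins), length(bins))),
    class = c("latency_histogram", "tbl_df", "tbl", "data.frame"),
    bin_width = 1, baseline = 1 / length(bins), n = 100, modality = "x"
  )
  expect_error(derive_window(h3), "no post-stimulus bin")
})

test_that("derived windows are scale-invariant and widen outward with
           coarser bins", {
  set.seed(2)
  # spike pool with a burst over ~60-340 ms on a uniform background
  pool <- c(stats::runif(2000, -400, 400),
            stats::rnorm(3000, 200, 70))
  h10 <- build_latency_histogram(pool, 10, span_ms = c(-400, 400))
  w10 <- derive_window(h10)

  # rescaling all frequencies by a positive constant changes nothing
  h_scaled <- h10
  h_scaled$freq <- h_scaled$freq * 7
  attr(h_scaled, "baseline") <- attr(h10, "baseline") * 7
  expect_equal(derive_window(h_scaled)[, c("start", "end")],
               w10[, c("start", "end")])

  # coarser bins never move the start later nor the end earlier
  h20 <- build_latency_histogram(pool, 20, span_ms = c(-400, 400))
  w20 <- derive_window(h20)
  expect_lte(w20$start, w10$start)
  expect_gte(w20$end, w10$end)
})

test_that("derived windows reproduce the full canonical table from
           crossings inside the printed spans", {
  mk <- function(bin, span, c_lo, c_hi, peak) {
    bins <- seq(span[1], span[2] - bin, by = bin)
    freq <- rep(0.0004, length(bins))
    freq[bins >= c_lo & bins < c_hi] <- 0.004
    freq[bins == peak] <- 0.02
    structure(
      tibble::tibble(bin_start = bins, bin_end = bins + bin,
                     freq = freq / sum(freq)),
      class = c("latency_histogram", "tbl_df", "tbl", "data.frame"),
      bin_width = bin, baseline = 0.0004 / sum(freq), n = 1000, modality = "x"
    )
  }
  # press: 10 ms bins, crossings 0-460, peak 100 -> 0-500
  wp <- derive_window(mk(10, c(-1000, 1000), 0, 460, 100))
  expect_equal(c(wp$start, wp$end), c(0, 500))
  # proprioceptive: 10 ms bins, crossings 10-380, peak 60 -> 0-400
  wq <- derive_window(mk(10, c(-1000, 1000), 10, 380, 60))
  expect_equal(c(wq$start, wq$end), c(0, 400))
  # thermal main: 50 ms bins, crossings 850-1500, peak 1100 -> 800-1500
  wt <- derive_window(mk(50, c(-1000, 4500), 850, 1500, 1100))
  expect_equal(c(wt$start, wt$end), c(800, 1500))
})

test_that("windowed counts use half-open intervals and the sustained
           multiplier", {
  win_t <- default_windows()[default_windows()$modality == "tactile", ]
  spikes <- tibble::tibble(trial = 1L, time_ms = c(-20, 5, 20))
  cc <- windowed_counts(spikes, win_t, 1)
  expect_equal(cc$pre_count, 1)
  expect_equal(cc$post_count, 2)

  # spike exactly at the post end is not counted
  edge <- tibble::tibble(trial = 1L, time_ms = 40)
  expect_equal(windowed_counts(edge, win_t, 1)$post_count, 0)
  # spike exactly at the window start is counted
  at0 <- tibble::tibble(trial = 1L, time_ms = 0)
  expect_equal(windowed_counts(at0, win_t, 1)$post_count, 1)

  # sustained thermal: 2 spikes in [-1000, 0) -> pre = 6; 5 in [1500, 4500)
  w <- default_windows()
  win_s <- w[w$modality == "noxious_thermal" & w$window == "sustained", ]
  sp <- tibble::tibble(trial = 1L,
                       time_ms = c(-800, -100, 1600, 2000, 2500, 3000, 4499))
  cs <- windowed_counts(sp, win_s, 1)
  expect_equal(cs$pre_count, 6)
  expect_equal(cs$post_count, 5)

  # a window outside the trial segment errors
  expect_error(windowed_counts(sp, win_s, 1, span_ms = c(-500, 4500)),
               "beyond the trial segment")

  # trials with no spikes still appear as zero rows
  cc3 <- windowed_counts(spikes, win_t, 3)
  expect_equal(nrow(cc3), 3)
  expect_equal(cc3$post_count[2:3], c(0, 0))
})
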