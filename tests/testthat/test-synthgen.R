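test_that("templates are reproducible, scaled to snr, and mutually distinct", {
  geom <- electrode_geometry(n_channels = 32)
  tm1 <- make_templates(5, geom, snr = 8, noise_sd_uV = 5, seed = 7)
  tm2 <- make_templates(5, geom, snr = 8, noise_sd_uV = 5, seed = 7)
  expect_identical(tm1, tm2)

  for (w in tm1$templates) {
    expect_equal(dim(w), c(3, 48))
    # dominant-channel trough equals snr * noise_sd
    expect_equal(max(abs(w[2, ])), 40)
    expect_lt(max(abs(w[2, ])) * -1, 0) # trough is negative
    expect_equal(min(w[2, ]), -40)
    # flanking channels attenuated by at least 40%
    expect_lte(max(abs(w[1, ])), 0.6 * 40 + 1e-9)
    expect_lte(max(abs(w[3, ])), 0.6 * 40 + 1e-9)
  }
  # pairwise normalised cross-correlation below 0.95
  vecs <- sapply(tm1$templates, function(m) as.numeric(t(m)))
  cc <- abs(crossprod(vecs) /
              tcrossprod(sqrt(colSums(vecs^2)))[seq_len(5), seq_len(5)])
  expect_true(all(cc[upper.tri(cc)] < 0.95))

  expect_error(make_templates(2, electrode_geometry(n_channels = 2)),
               "3 channels")
})

test_that("tactile evoked latencies reproduce the configured 8.31 ms mean", {
  s <- sample_evoked_times("tactile", 1000, count_mean = 1.5,
                           latency_centre_ms = 8.31, seed = 2)
  expect_lt(abs(mean(s$time_ms) - 8.31), 1)
})

test_that("a zero-rate profile yields an empty train", {
  s <- sample_evoked_times("noxious_thermal", 10, count_mean = 0,
                           sustained_mean = 0, seed = 1)
  expect_equal(nrow(s), 0)
})

test_that("proprioceptive sampler puts its histogram peaks at the two modes", {
  s <- sample_evoked_times("proprioceptive", 500, count_mean = 4,
                           latency_centre_ms = 50, seed = 3)
  h <- hist(s$time_ms, breaks = seq(0, 400, 10), plot = FALSE)
  top2 <- h$mids[order(h$counts, decreasing = TRUE)[1:2]]
  expect_lt(abs(sort(top2)[1] - 50), 10 + 5)
  expect_lt(abs(sort(top2)[2] - 250), 10 + 5)
})

test_that("DC thinning is an identity at r = 0 and complete at r = 1", {
  spikes <- tibble::tibble(trial = rep(1:100, each = 100),
                           time_ms = rep(stats::runif(100, 0, 40), 100))
  out0 <- apply_dc_effect(spikes, c(0, 40), r = 0, phase = "during", seed = 4)
  expect_equal(out0$time_ms, dplyr::arrange(spikes, trial, time_ms)$time_ms)
  out1 <- apply_dc_effect(spikes, c(0, 40), r = 1, phase = "during", seed = 4)
  expect_equal(nrow(out1), 0)
  expect_error(apply_dc_effect(spikes, c(0, 40), r = 1.2, phase = "during"),
               "\\[0, 1\\]")
})

test_that("DC thinning preserves the binomial expectation across r", {
  n_spk <- 10000
  spikes <- tibble::tibble(trial = rep(1:1000, each = 10),
                           time_ms = stats::runif(n_spk, 0, 40))
  for (r in c(0.25, 0.5, 0.75)) {
    out <- apply_dc_effect(spikes, c(0, 40), r = r, phase = "during",
                           seed = 100 + r * 100)
    expect_lt(abs(nrow(out) - (1 - r) * n_spk),
              3 * sqrt(n_spk * r * (1 - r)))
  }
})

test_that("post-DC thinning decays with the configured half-life", {
  n_spk <- 20000
  spikes <- tibble::tibble(trial = rep(1:2000, each = 10),
                           time_ms = stats::runif(n_spk, 0, 40))
  # at one half-life, the block probability is r / 2
  out <- apply_dc_effect(spikes, c(0, 40), r = 1, phase = "post",
                         time_since_dc_end_min = 8, halflife_min = 8,
                         seed = 5)
  expect_lt(abs(nrow(out) - 0.5 * n_spk), 3 * sqrt(n_spk * 0.25))
})

test_that("the spontaneous gain adds activity outside the window only", {
  set.seed(6)
  spikes <- sample_spontaneous_times(20, 200, span_ms = c(-1000, 1000))
  out <- apply_dc_effect(spikes, c(0, 40), r = 0, phase = "during",
                         spont_rate_hz = 20, spont_gain = 1.1,
                         span_ms = c(-1000, 1000), n_trials = 200, seed = 7)
  pre_rate <- sum(spikes$time_ms < 0) / (200 * 1)
  dur_rate <- sum(out$time_ms < 0) / (200 * 1)
  expect_gt(dur_rate / pre_rate, 1.02)
  expect_lt(dur_rate / pre_rate, 1.18)
  # in-window content untouched at r = 0
  expect_equal(sum(out$time_ms >= 0 & out$time_ms < 40),
               sum(spikes$time_ms >= 0 & spikes$time_ms < 40))
})

test_that("voltage rendering has the configured noise floor and is linear", {
  geom <- electrode_geometry(n_channels = 3)
  tm <- make_templates(1, geom, seed = 9)
  tm$channels[1, 2:4] <- list(1L, 2L, 3L)
  none <- tibble::tibble(unit = integer(0), time_s = numeric(0))
  rec <- render_voltage(none, tm, 1, 1e6 / 30000, noise_sd_uV = 5, seed = 10)
  expect_lt(abs(stats::sd(rec$voltage) - 5) / 5, 0.02)

  one <- tibble::tibble(unit = 1L, time_s = 0.01)
  r1 <- render_voltage(one, tm, 3, 0.05, noise_sd_uV = 0, seed = 11)
  s0 <- round(0.01 * 30000) + 1
  a <- s0 - (tm$peak_sample - 1)
  expect_equal(r1$voltage[, a:(a + 47)], tm$templates[[1]])
  expect_true(all(r1$voltage[, -(a:(a + 47))] == 0))

  # linearity: merged spike sets render as the sum of separate renders
  sA <- tibble::tibble(unit = 1L, time_s = c(0.01, 0.03))
  sB <- tibble::tibble(unit = 1L, time_s = c(0.012, 0.04))
  rA <- render_voltage(sA, tm, 3, 0.06, noise_sd_uV = 0)
  rB <- render_voltage(sB, tm, 3, 0.06, noise_sd_uV = 0)
  rAB <- render_voltage(dplyr::bind_rows(sA, sB), tm, 3, 0.06, noise_sd_uV = 0)
  expect_equal(rAB$voltage, rA$voltage + rB$voltage)

  # bit-identical under a fixed seed
  r2 <- render_voltage(one, tm, 3, 0.05, noise_sd_uV = 5, seed = 12)
  r3 <- render_voltage(one, tm, 3, 0.05, noise_sd_uV = 5, seed = 12)
  expect_identical(r2, r3)
})

test_that("a session has the four DC permutations and ordered post sets", {
  cfg <- generator_config(modality = "tactile", treatment_group = "naive",
                          n_units = 3, seed = 13)
  ses <- generate_session(cfg, recovery = TRUE)
  during <- ses$sets[ses$sets$phase == "during", ]
  expect_equal(nrow(during), 4)
  expect_setequal(
    paste(during$amplitude_uA, during$polarity),
    c("500 cathodic_centre", "500 anodic_centre",
      "1000 cathodic_centre", "1000 anodic_centre")
  )
  post <- ses$sets[ses$sets$phase == "post", ]
  expect_equal(nrow(post), length(cfg$post_times_min))
  expect_true(all(diff(post$time_since_dc_end_min) > 0))

  ses2 <- generate_session(generator_config(modality = "tactile",
                                            treatment_group = "naive",
                                            n_units = 3, seed = 13),
                           recovery = TRUE)
  expect_identical(ses$sets, ses2$sets)
  expect_identical(ses$ground_truth, ses2$ground_truth)
})

test_that("unit-level tactile latencies are unimodal in naive sessions and
           bimodal in neuropathic sessions", {
  nd <- dip_null(200, n_boot = 500, seed = 20)
  p_naive <- vapply(1:5, function(s) {
    ses <- generate_session(generator_config(modality = "tactile",
                                             treatment_group = "naive",
                                             n_units = 200, seed = 20 + s))
    dip_test(ses$ground_truth$latency_centre_ms, null_dips = nd)$p_value
  }, numeric(1))
  expect_gt(stats::median(p_naive), 0.05)

  ses <- generate_session(generator_config(modality = "tactile",
                                           treatment_group = "neuropathic",
                                           n_units = 200, seed = 30))
  p_pain <- dip_test(ses$ground_truth$latency_centre_ms,
                     null_dips = nd)$p_value
  expect_lt(p_pain, 0.05)
  # the mixture weight reproduces the printed 10.85 ms neuropathic mean
  w <- generator_config(modality = "tactile",
                        treatment_group = "neuropathic")$tactile_mixture_weight
  expect_equal(8.31 + w * (16 - 8.31), 10.85, tolerance = 1e-8)
})
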