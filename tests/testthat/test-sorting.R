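test_that("template clustering recovers planted units and is deterministic", {
  geom <- electrode_geometry(n_channels = 3)
  tm <- make_templates(3, geom, snr = 8, noise_sd_uV = 5, seed = 11)
  ev <- waveform_events(tm, 150, noise_sd = 5, seed = 12)
  sol <- fit_template_clustering(ev, k_range = 2:6, seed = 13)
  expect_equal(sol$k, 3)
  expect_gte(ari(sol$assignment, ev$unit), 0.9)

  sol2 <- fit_template_clustering(ev, k_range = 2:6, seed = 13)
  expect_identical(sol$assignment, sol2$assignment)
})

test_that("a single-template event set falls back to one cluster", {
  geom <- electrode_geometry(n_channels = 3)
  tm <- make_templates(1, geom, snr = 8, noise_sd_uV = 5, seed = 14)
  ev <- waveform_events(tm, 120, noise_sd = 5, seed = 15)
  expect_warning(sol <- fit_template_clustering(ev, k_range = 2:3, seed = 16),
                 "fallback")
  expect_equal(sol$k, 1)
  expect_true(all(sol$assignment == 1L))
})

test_that("contamination fraction follows the inclusive ISI rule", {
  # all ISIs above 1 ms: clean
  expect_equal(contamination_fraction(cumsum(rep(0.002, 50))), 0)
  # 100 ISIs with exactly one at 1.0 ms: fraction 0.01, which IS flagged
  times <- cumsum(c(0, rep(0.002, 99), 0.001))
  expect_equal(contamination_fraction(times), 0.01)
  expect_gte(contamination_fraction(times), 0.01)  # inclusive comparison
  # ISIs 0.5, 0.5, 2, 2 ms
  expect_equal(contamination_fraction(cumsum(c(0, 0.0005, 0.0005, 0.002, 0.002))),
               0.5)
  # fewer than 2 spikes: defined as 0
  expect_equal(contamination_fraction(numeric(0)), 0)
  expect_equal(contamination_fraction(1.23), 0)
})

make_mixed_solution <- function(seed = 21, n_per_unit = 300) {
  # two refractory units merged into a single flagged cluster: scores are
  # well-separated blobs, times interleave so the merged ISIs violate the
  # refractory limit
  set.seed(seed)
  t1 <- enforce_refractory(sort(stats::runif(n_per_unit, 0, 3)))
  t2 <- enforce_refractory(sort(stats::runif(n_per_unit, 0, 3)))
  times <- c(t1, t2)
  unit <- rep(1:2, c(length(t1), length(t2)))
  o <- order(times)
  times <- times[o]
  unit <- unit[o]
  n <- length(times)
  scores <- matrix(rnorm(n * 3), n, 3) +
    cbind(ifelse(unit == 1, 0, 8), 0, 0)
  sol <- structure(list(
    center = numeric(3), rotation = diag(3), scores = scores,
    centroids = matrix(colMeans(scores), 1),
    assignment = rep(1L, n),
    events = tibble::tibble(event_id = seq_len(n), time_s = times),
    k = 1L, silhouette = NA_real_, seed = 21L
  ), class = "cluster_solution")
  sol$states <- spikedc:::cluster_states(sol)
  list(sol = sol, unit = unit)
}

test_that("one reiteration splits a merged pair of refractory units", {
  mx <- make_mixed_solution()
  expect_gte(mx$sol$states$contamination[1], 0.01)
  ref <- refine_contaminated(mx$sol, seed = 22)
  expect_equal(nrow(ref$states), 2)
  expect_true(all(ref$states$state == "reiterated"))
  expect_true(all(ref$states$n_reiterations == 1))
  expect_gte(ari(ref$assignment, mx$unit), 0.9)
})

test_that("a genuinely contaminated Poisson cluster is excluded after
           exactly four reiterations", {
  set.seed(23)
  n <- 4000
  times <- sort(stats::runif(n, 0, n / 1000))  # 1 kHz, no refractoriness
  scores <- matrix(rnorm(n * 3), n, 3)
  sol <- structure(list(
    center = numeric(3), rotation = diag(3), scores = scores,
    centroids = matrix(colMeans(scores), 1),
    assignment = rep(1L, n),
    events = tibble::tibble(event_id = seq_len(n), time_s = times),
    k = 1L, silhouette = NA_real_, seed = 23L
  ), class = "cluster_solution")
  sol$states <- spikedc:::cluster_states(sol)
  ref <- refine_contaminated(sol, seed = 24)
  expect_true(all(ref$states$state == "excluded"))
  expect_true(all(ref$states$n_reiterations == 4))
  expect_equal(ref$k, 0)
})

test_that("clean input is untouched by refinement", {
  geom <- electrode_geometry(n_channels = 3)
  tm <- make_templates(2, geom, seed = 25)
  ev <- waveform_events(tm, 150, noise_sd = 5, seed = 26)
  sol <- fit_template_clustering(ev, k_range = 2:4, seed = 27)
  ref <- refine_contaminated(sol, seed = 28)
  expect_identical(ref$assignment, sol$assignment)
  expect_true(all(ref$states$state == "clean"))
})

test_that("raising the contamination threshold never excludes clusters the
           default threshold kept", {
  set.seed(29)
  n <- 2000
  times <- sort(stats::runif(n, 0, n / 400))
  scores <- matrix(rnorm(n * 3), n, 3)
  sol <- structure(list(
    center = numeric(3), rotation = diag(3), scores = scores,
    centroids = matrix(colMeans(scores), 1),
    assignment = rep(1L, n),
    events = tibble::tibble(event_id = seq_len(n), time_s = times),
    k = 1L, silhouette = NA_real_, seed = 29L
  ), class = "cluster_solution")
  sol$states <- spikedc:::cluster_states(sol)
  lo <- refine_contaminated(sol, threshold = 0.01, seed = 30)
  hi <- refine_contaminated(sol, threshold = 0.05, seed = 30)
  excluded_events <- function(ref) {
    bad <- ref$states$cluster[ref$states$state == "excluded"]
    ref$events$event_id[ref$assignment %in% bad]
  }
  kept_by_lo <- setdiff(sol$events$event_id, excluded_events(lo))
  expect_true(all(!kept_by_lo %in% excluded_events(hi)) ||
                length(excluded_events(hi)) <= length(excluded_events(lo)))
})

test_that("template transfer is self-consistent and gates outliers", {
  geom <- electrode_geometry(n_channels = 3)
  tm <- make_templates(3, geom, snr = 8, seed = 31)
  ev <- waveform_events(tm, 150, noise_sd = 5, seed = 32)
  sol <- fit_template_clustering(ev, k_range = 2:5, seed = 33)

  # the template events themselves map to their own clusters
  tr <- apply_clustering(sol, ev)
  ok <- !is.na(tr$cluster)
  expect_gte(mean(ok), 0.95)
  expect_equal(tr$cluster[ok], sol$assignment[ok])

  # events from one planted unit only
  evA <- waveform_events(tm, 120, noise_sd = 5, seed = 34)
  evA <- evA[evA$unit == 1, ]
  trA <- apply_clustering(sol, evA)
  target <- unique(sol$assignment[ev$unit == 1])
  target <- target[which.max(tabulate(match(sol$assignment[ev$unit == 1],
                                            target)))]
  expect_gte(mean(trA$cluster == target, na.rm = TRUE), 0.95)

  # a 10x-amplitude artifact is left unassigned
  big <- evA[1, ]
  big$waveform[[1]] <- big$waveform[[1]] * 10
  trBig <- apply_clustering(sol, big)
  expect_true(is.na(trBig$cluster))

  # dimension mismatch errors
  bad <- evA[1, ]
  bad$waveform[[1]] <- bad$waveform[[1]][, 1:24]
  expect_error(apply_clustering(sol, bad), "dimensions")
})

test_that("modality classification excludes multimodal responses
           one-directionally", {
  set.seed(35)
  silent <- tibble::tibble(pre_count = rpois(50, 1), post_count = rpois(50, 1))
  responsive <- tibble::tibble(pre_count = rpois(50, 1),
                               post_count = rpois(50, 4))

  # press unit with no tactile response keeps its label
  r1 <- classify_modality("noxious_press", silent)
  expect_equal(r1$modality_label, "noxious_press")
  expect_false(r1$excluded)

  # press unit that also responds to the tactile probe is excluded
  r2 <- classify_modality("noxious_press", responsive)
  expect_equal(r2$modality_label, "multimodal_excluded")
  expect_true(r2$excluded)

  # tactile unit responding to a press probe is retained (rule is
  # one-directional): the tactile label short-circuits the check
  r3 <- classify_modality("tactile", responsive)
  expect_equal(r3$modality_label, "tactile")
  expect_false(r3$excluded)

  # missing tactile probe: label retained, flagged unverified
  r4 <- classify_modality("noxious_press", NULL)
  expect_equal(r4$modality_label, "noxious_press")
  expect_false(r4$tactile_checked)
})
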