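#' Fit the template clustering solution
#'
#' Concatenates each event's 3-channel waveform into one vector, projects the
#' collection onto its leading principal components (the first 10, or fewer
#' if 95% of the variance is reached earlier), and k-means-clusters the
#' scores. `k` is chosen from `k_range` by maximum mean silhouette width;
#' when even the best silhouette is weak (< `min_silhouette`) or there are
#' too few events (fewer than 10 per candidate cluster), the solution falls
#' back to a single cluster with a warning.
#'
#' @param events event table from [detect_spikes()] (needs `time_s` and the
#'   `waveform` list-column).
#' @param k_range candidate cluster counts.
#' @param n_pcs maximum number of principal components retained.
#' @param n_restarts k-means restarts.
#' @param min_silhouette silhouette floor below which a single cluster is
#'   returned.
#' @param seed integer seed (k-means initialisation).
#' @return an object of class `cluster_solution`: list with `center`,
#'   `rotation` (PCA basis), `centroids` (k x p), `assignment`, `events`,
#'   `states` (per-cluster tibble: `cluster`, `state`, `n_reiterations`,
#'   `contamination`, `gate_dist`), `k`, `silhouette`, `seed`.
#' @export
fit_template_clustering <- function(events, k_range = 2:8, n_pcs = 10,
                                    n_restarts = 10, min_silhouette = 0.3,
                                    seed = 1L) {
  n <- nrow(events)
  if (n < 2) stop("need at least 2 events to cluster")
  X <- do.call(rbind, lapply(events$waveform, function(w) as.numeric(t(w))))
  pca <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  cum <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
  p <- min(n_pcs, max(1, which(cum >= 0.95)[1]), ncol(pca$rotation))
  scores <- pca$x[, seq_len(p), drop = FALSE]

  local_rng(seed)
  ks <- k_range[k_range >= 2 & k_range * 10 <= n]
  fallback <- FALSE
  if (!length(ks)) {
    warning("too few events for the requested k_range; single-cluster fallback")
    fallback <- TRUE
  }

  best <- NULL
  if (!fallback) {
    d <- stats::dist(scores)
    sil_of <- function(cl) {
      mean(cluster::silhouette(cl, d)[, "sil_width"])
    }
    fits <- lapply(ks, function(k) {
      km <- stats::kmeans(scores, centers = k, nstart = n_restarts,
                          iter.max = 50)
      list(k = k, km = km, sil = sil_of(km$cluster))
    })
    sils <- vapply(fits, `[[`, numeric(1), "sil")
    best <- fits[[which.max(sils)]]
    if (best$sil < min_silhouette) {
      warning("best silhouette ", round(best$sil, 3),
              " below floor; single-cluster fallback")
      fallback <- TRUE
    }
  }

  if (fallback) {
    assignment <- rep(1L, n)
    centroids <- matrix(colMeans(scores), nrow = 1)
    k <- 1L
    sil <- NA_real_
  } else {
    assignment <- as.integer(best$km$cluster)
    centroids <- best$km$centers
    k <- best$k
    sil <- best$sil
  }

  sol <- structure(list(
    center = pca$center,
    rotation = pca$rotation[, seq_len(p), drop = FALSE],
    scores = scores,
    centroids = centroids,
    assignment = assignment,
    events = dplyr::select(events, -"waveform"),
    k = k,
    silhouette = sil,
    seed = as.integer(seed)
  ), class = "cluster_solution")
  sol$states <- cluster_states(sol)
  sol
}

# Per-cluster bookkeeping: contamination fraction and the transfer outlier
# gate (3x the 95th percentile of within-cluster centroid distance).
cluster_states <- function(sol, n_reiter = NULL) {
  ids <- sort(unique(sol$assignment))
  tibble::tibble(
    cluster = ids,
    state = "clean",
    n_reiterations = if (is.null(n_reiter)) 0L else n_reiter,
    contamination = vapply(ids, function(cl) {
      contamination_fraction(sol$events$time_s[sol$assignment == cl])
    }, numeric(1)),
    gate_dist = vapply(ids, function(cl) {
      sel <- sol$assignment == cl
      ce <- sol$centroids[match(cl, ids), ]
      dd <- sqrt(rowSums((sol$scores[sel, , drop = FALSE] -
                            matrix(ce, sum(sel), length(ce), byrow = TRUE))^2))
      stats::quantile(dd, 0.95, names = FALSE)
    }, numeric(1))
  )
}

#' Inter-spike-interval contamination fraction
#'
#' The fraction of a cluster's inter-spike intervals at or below the
#' refractory limit (1 ms). A cluster is considered contaminated when the
#' fraction is 1% or more (both comparisons inclusive). With fewer than two
#' spikes the fraction is defined as 0.
#'
#' @param times_s spike times of one cluster (s).
#' @param limit_s refractory limit (s).
#' @return contamination fraction in `[0, 1]`.
#' @export
contamination_fraction <- function(times_s, limit_s = 0.001) {
  if (length(times_s) < 2) return(0)
  isi <- diff(sort(times_s))
  # the comparison is inclusive; the tiny relative slack keeps an interval of
  # exactly 1 ms inside the rule despite floating-point subtraction
  mean(isi <= limit_s * (1 + 1e-9))
}

#' Refine contaminated clusters by reiterated k-means
#'
#' Every cluster whose ISI contamination fraction is at or above `threshold`
#' is isolated and re-clustered with k = 2 in the template's principal
#' component space; the resulting sub-clusters are re-checked. A lineage can
#' be reiterated up to `max_iters` times; a cluster still contaminated after
#' that is marked `excluded`. Clean clusters are untouched.
#'
#' @param sol a [fit_template_clustering()] solution.
#' @param threshold contamination threshold (inclusive).
#' @param max_iters reiteration budget per cluster lineage.
#' @param n_restarts k-means restarts per split.
#' @param seed integer seed.
#' @return the updated `cluster_solution`; `states` records each final
#'   cluster's state (`clean`, `reiterated`, or `excluded`) and reiteration
#'   count.
#' @export
refine_contaminated <- function(sol, threshold = 0.01, max_iters = 4,
                                n_restarts = 10, seed = 1L) {
  stopifnot(inherits(sol, "cluster_solution"))
  local_rng(seed)
  assignment <- sol$assignment
  times <- sol$events$time_s
  scores <- sol$scores

  next_id <- max(assignment) + 1L
  # queue entries: cluster id + its reiteration count
  queue <- lapply(sort(unique(assignment)), function(cl) list(id = cl, iter = 0L))
  states <- list()

  while (length(queue)) {
    item <- queue[[1]]
    queue <- queue[-1]
    sel <- assignment == item$id
    frac <- contamination_fraction(times[sel])
    if (frac < threshold) {
      states[[length(states) + 1]] <- tibble::tibble(
        cluster = item$id,
        state = if (item$iter > 0) "reiterated" else "clean",
        n_reiterations = item$iter, contamination = frac
      )
      next
    }
    if (item$iter >= max_iters || sum(sel) < 4) {
      states[[length(states) + 1]] <- tibble::tibble(
        cluster = item$id, state = "excluded",
        n_reiterations = item$iter, contamination = frac
      )
      next
    }
    km <- stats::kmeans(scores[sel, , drop = FALSE], centers = 2,
                        nstart = n_restarts, iter.max = 50)
    ids <- c(item$id, next_id)
    next_id <- next_id + 1L
    assignment[sel] <- ids[km$cluster]
    queue <- c(queue, list(list(id = ids[1], iter = item$iter + 1L),
                           list(id = ids[2], iter = item$iter + 1L)))
  }

  st <- dplyr::arrange(dplyr::bind_rows(states), .data$cluster)
  keep <- st$cluster[st$state != "excluded"]
  centroids <- t(vapply(st$cluster, function(cl) {
    colMeans(scores[assignment == cl, , drop = FALSE])
  }, numeric(ncol(scores))))

  sol$assignment <- assignment
  sol$centroids <- centroids
  gate <- vapply(seq_along(st$cluster), function(i) {
    sel <- assignment == st$cluster[i]
    dd <- sqrt(rowSums((scores[sel, , drop = FALSE] -
                          matrix(centroids[i, ], sum(sel), ncol(centroids),
                                 byrow = TRUE))^2))
    stats::quantile(dd, 0.95, names = FALSE)
  }, numeric(1))
  sol$states <- dplyr::mutate(st, gate_dist = gate)
  sol$k <- length(keep)
  sol
}

#' Apply a clustering solution to another recording set
#'
#' Projects new events onto the template's principal-component basis and
#' assigns each to the nearest non-excluded centroid (Euclidean distance).
#' Events farther than `outlier_mult` times the template cluster's 95th
#' percentile centroid distance are left unassigned, which keeps artifact
#' waveforms from contaminating units.
#'
#' @param sol a (possibly refined) `cluster_solution`.
#' @param events event table with a `waveform` list-column of the same
#'   snippet dimensions as the template events.
#' @param outlier_mult gate multiplier.
#' @return tibble with `event_id`, `time_s`, `cluster` (NA when gated out),
#'   `distance`.
#' @export
apply_clustering <- function(sol, events, outlier_mult = 3) {
  stopifnot(inherits(sol, "cluster_solution"))
  X <- do.call(rbind, lapply(events$waveform, function(w) as.numeric(t(w))))
  if (ncol(X) != length(sol$center)) {
    stop("waveform dimensions do not match the template solution")
  }
  S <- sweep(X, 2, sol$center) %*% sol$rotation
  st <- sol$states
  ok <- st$state != "excluded"
  ids <- st$cluster[ok]
  cents <- sol$centroids[ok, , drop = FALSE]
  gates <- st$gate_dist[ok] * outlier_mult
  dmat <- vapply(seq_along(ids), function(i) {
    sqrt(rowSums((S - matrix(cents[i, ], nrow(S), ncol(S), byrow = TRUE))^2))
  }, numeric(nrow(S)))
  dmat <- matrix(dmat, nrow = nrow(S))
  nearest <- max.col(-dmat)
  dist <- dmat[cbind(seq_len(nrow(S)), nearest)]
  cl <- ids[nearest]
  cl[dist > gates[nearest]] <- NA_integer_
  tibble::tibble(
    event_id = events$event_id,
    time_s = events$time_s,
    cluster = cl,
    distance = dist
  )
}

#' Classify a unit's modality, excluding multimodal responses
#'
#' A unit is labelled with the stimulus paradigm of its template recording.
#' Because press and proprioceptive stimuli unavoidably contain a tactile
#' component, a non-tactile unit that also shows a significant evoked
#' response to the tactile probe is excluded as multimodal. The rule is
#' one-directional: tactile-labelled units are never excluded for responding
#' to other probes.
#'
#' @param template_modality modality of the template paradigm.
#' @param tactile_probe_counts per-trial `(pre_count, post_count)` tibble
#'   from the tactile probe recording, or `NULL` when no probe exists.
#' @param alpha evoked-test level.
#' @return one-row tibble: `modality_label`, `excluded`, `tactile_checked`.
#' @export
classify_modality <- function(template_modality, tactile_probe_counts = NULL,
                              alpha = 0.05) {
  if (template_modality == "tactile" || is.null(tactile_probe_counts)) {
    return(tibble::tibble(
      modality_label = template_modality,
      excluded = FALSE,
      tactile_checked = template_modality == "tactile"
    ))
  }
  ev <- classify_evoked(tactile_probe_counts, alpha = alpha)
  tibble::tibble(
    modality_label = if (ev$evoked) "multimodal_excluded" else template_modality,
    excluded = ev$evoked,
    tactile_checked = TRUE
  )
}
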