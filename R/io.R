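#' Write a synthetic session to disk
#'
#' Serialises a session as plain-text files in a directory: a JSON manifest
#' (set metadata, configuration echo, ground truth) and one CSV of
#' trial-aligned spikes (`set_id`, `unit`, `trial`, `time_ms`). Voltage is
#' not stored; it is reproducible from the configuration seed via
#' [render_voltage()].
#'
#' @param session a [generate_session()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "synthetic_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- session$config
  manifest <- list(
    modality = cfg$modality,
    treatment_group = cfg$treatment_group,
    sex = cfg$sex,
    n_units = cfg$n_units,
    sampling_rate_hz = cfg$sampling_rate_hz,
    spontaneous_rate_hz = cfg$spontaneous_rate_hz,
    dc_spontaneous_gain = cfg$dc_spontaneous_gain,
    seed = cfg$seed,
    sets = session$sets[, setdiff(names(session$sets), "spikes")],
    ground_truth = session$ground_truth
  )
  jsonlite::write_json(manifest, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  spikes <- dplyr::bind_rows(lapply(seq_len(nrow(session$sets)), function(i) {
    dplyr::bind_rows(lapply(seq_along(session$sets$spikes[[i]]), function(u) {
      sp <- session$sets$spikes[[i]][[u]]
      if (!nrow(sp)) return(NULL)
      tibble::tibble(set_id = session$sets$set_id[i], unit = u,
                     trial = sp$trial, time_ms = sp$time_ms)
    }))
  }))
  utils::write.csv(spikes, file.path(dir, "spikes.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a serialised session
#'
#' @param dir directory written by [write_session()].
#' @return a list with `manifest` (parsed JSON, with `sets` and
#'   `ground_truth` as tibbles) and `spikes` (tibble).
#' @export
read_session <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "session.json"),
                                  simplifyVector = TRUE)
  manifest$sets <- tibble::as_tibble(manifest$sets)
  manifest$ground_truth <- tibble::as_tibble(manifest$ground_truth)
  spikes <- tibble::as_tibble(utils::read.csv(file.path(dir, "spikes.csv")))
  list(manifest = manifest, spikes = spikes)
}

#' Write a clustering solution as JSON
#'
#' Stores the PCA centre and basis, centroids, per-event assignments and
#' times, and the per-cluster states, so a template solution can be re-applied
#' to later recording sets with [apply_clustering()].
#'
#' @param sol a `cluster_solution`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cluster_solution <- function(sol, path) {
  stopifnot(inherits(sol, "cluster_solution"))
  obj <- list(
    center = sol$center,
    rotation = sol$rotation,
    centroids = sol$centroids,
    assignment = sol$assignment,
    events = sol$events,
    states = sol$states,
    k = sol$k,
    silhouette = sol$silhouette,
    seed = sol$seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", matrix = "rowmajor")
  invisible(path)
}

#' Read a clustering solution written by [write_cluster_solution()]
#'
#' @param path JSON file.
#' @return a `cluster_solution` (without the event scores, which are not
#'   needed for transfer).
#' @export
read_cluster_solution <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  states <- tibble::as_tibble(obj$states)
  centroids <- obj$centroids
  if (!is.matrix(centroids)) {
    centroids <- matrix(unlist(centroids), nrow = nrow(states), byrow = TRUE)
  }
  rotation <- obj$rotation
  if (!is.matrix(rotation)) {
    rotation <- matrix(unlist(rotation), ncol = ncol(centroids), byrow = TRUE)
  }
  structure(list(
    center = as.numeric(obj$center),
    rotation = rotation,
    centroids = centroids,
    assignment = as.integer(obj$assignment),
    events = tibble::as_tibble(obj$events),
    states = states,
    k = obj$k,
    silhouette = obj$silhouette,
    seed = obj$seed
  ), class = "cluster_solution")
}
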