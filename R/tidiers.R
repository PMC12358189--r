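#' Tidy a fitted mixed model
#'
#' Broom-style one-row-per-term summary of the fixed effects, with
#' Satterthwaite degrees of freedom and p values.
#'
#' @param x a [fit_mixed_model()] object.
#' @param ... unused.
#' @return a tibble with `term`, `estimate`, `std_error`, `df`, `statistic`,
#'   `p_value`.
#' @method tidy spikedc_lmm
#' @export
tidy.spikedc_lmm <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(co),
    estimate = co[, "Estimate"],
    std_error = co[, "Std. Error"],
    df = co[, "df"],
    statistic = co[, "t value"],
    p_value = co[, "Pr(>|t|)"]
  )
}

#' Glance at a fitted mixed model
#'
#' @param x a [fit_mixed_model()] object.
#' @param ... unused.
#' @return a one-row tibble with fit-level summaries, including the random
#'   effect standard deviations, residual sigma, singularity and convergence
#'   flags.
#' @method glance spikedc_lmm
#' @export
glance.spikedc_lmm <- function(x, ...) {
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  re <- vc[is.na(vc$var2) & vc$grp != "Residual", ]
  out <- tibble::tibble(
    nobs = stats::nobs(x$fit),
    sigma = stats::sigma(x$fit),
    logLik = as.numeric(stats::logLik(x$fit)),
    singular = x$singular,
    converged = x$converged
  )
  for (i in seq_len(nrow(re))) {
    out[[paste0("sd_", re$grp[i])]] <- re$sdcor[i]
  }
  out
}

#' Tidy a clustering solution
#'
#' One row per cluster with its state, reiteration count, contamination
#' fraction and event count.
#'
#' @param x a `cluster_solution`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy cluster_solution
#' @export
tidy.cluster_solution <- function(x, ...) {
  st <- x$states
  st$n_events <- vapply(st$cluster, function(cl) sum(x$assignment == cl),
                        integer(1))
  st
}

#' Glance at a clustering solution
#'
#' @param x a `cluster_solution`.
#' @param ... unused.
#' @return a one-row tibble: `k`, `n_events`, `n_components`, `silhouette`,
#'   `n_excluded`.
#' @method glance cluster_solution
#' @export
glance.cluster_solution <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n_events = length(x$assignment),
    n_components = ncol(x$rotation),
    silhouette = x$silhouette,
    n_excluded = sum(x$states$state == "excluded")
  )
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("<cluster_solution> k =", x$k, "(", length(x$assignment), "events,",
      ncol(x$rotation), "PCs )\n")
  print(x$states)
  invisible(x)
}
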