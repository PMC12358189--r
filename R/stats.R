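#' Fit a linear mixed-effects model for windowed spike counts
#'
#' Thin, contract-checked wrapper around `lmerTest::lmer` (REML with
#' Satterthwaite degrees of freedom). Fixed effects are supplied by name;
#' random effects are random intercepts per grouping factor (units nested in
#' animals is expressed by listing both factors). Convergence problems and
#' singular fits are surfaced on the returned object rather than hidden;
#' rank-deficient fixed effects are reported via the `dropped` element.
#'
#' @param data a tidy table with one row per trial/observation.
#' @param response response column name.
#' @param fixed character vector of fixed-effect column names.
#' @param random character vector of random-intercept grouping factors; each
#'   must have at least 2 levels in `data`.
#' @return an object of class `spikedc_lmm`: list with `fit` (the `lmerMod`),
#'   `formula`, `singular`, `converged`, `dropped`.
#' @export
fit_mixed_model <- function(data, response, fixed, random) {
  stopifnot(length(random) >= 1)
  for (g in random) {
    if (length(unique(data[[g]])) < 2) {
      stop("random factor '", g, "' has fewer than 2 levels")
    }
  }
  for (v in c(response, fixed, random)) {
    if (!v %in% names(data)) stop("column '", v, "' not found in data")
  }
  fml <- stats::as.formula(paste(
    response, "~", paste(fixed, collapse = " + "), "+",
    paste(sprintf("(1 | %s)", random), collapse = " + ")
  ))
  fit <- lmerTest::lmer(fml, data = data, REML = TRUE)
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  # a boundary (singular) fit is reported through the `singular` flag, not
  # as a convergence failure
  msgs <- msgs[!grepl("singular", msgs, ignore.case = TRUE)]
  converged <- length(msgs) == 0
  if (!converged) {
    warning("mixed model convergence messages: ",
            paste(msgs, collapse = "; "))
  }
  dropped <- attr(fit@pp$X, "col.dropped")
  structure(list(
    fit = fit,
    formula = fml,
    singular = lme4::isSingular(fit),
    converged = converged,
    dropped = if (is.null(dropped)) character(0) else names(dropped)
  ), class = "spikedc_lmm")
}

#' Estimated marginal means and Tukey-adjusted contrasts
#'
#' @param model a [fit_mixed_model()] object.
#' @param specs focal factor name (e.g. `"phase"`).
#' @param adjust multiplicity adjustment for the pairwise contrasts.
#' @return a list with `emmeans` (tibble: level, emmean, se, df) and
#'   `contrasts` (tibble: contrast, estimate, se, df, t, p_value).
#' @export
emm_table <- function(model, specs = "phase", adjust = "tukey") {
  stopifnot(inherits(model, "spikedc_lmm"))
  em <- emmeans::emmeans(model$fit, specs = specs,
                         lmer.df = "satterthwaite", lmerTest.limit = 20000)
  emdf <- as.data.frame(em)
  ct <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                        adjust = adjust))
  list(
    emmeans = tibble::tibble(
      level = as.character(emdf[[1]]),
      emmean = emdf$emmean,
      se = emdf$SE,
      df = emdf$df
    ),
    contrasts = tibble::tibble(
      contrast = as.character(ct$contrast),
      estimate = ct$estimate,
      se = ct$SE,
      df = ct$df,
      t = ct$t.ratio,
      p_value = ct$p.value
    )
  )
}

#' Rank-based group comparisons with Bonferroni adjustment
#'
#' With two groups, a Mann-Whitney/Wilcoxon rank-sum test; with more, a
#' Kruskal-Wallis omnibus test plus all pairwise rank-sum comparisons with
#' Bonferroni-adjusted p values (`p_adj = min(1, m * p)`).
#'
#' @param data tidy table.
#' @param value value column name.
#' @param group grouping column name.
#' @param alternative alternative hypothesis passed to the pairwise tests.
#' @param correction p-value adjustment method.
#' @return tibble of pairwise comparisons (`group1`, `group2`, `statistic`,
#'   `p_value`, `p_adjusted`) with the omnibus test (statistic, p) in
#'   attributes `omnibus_statistic`, `omnibus_p`, `omnibus_method`.
#' @export
rank_tests <- function(data, value, group, alternative = "two.sided",
                       correction = "bonferroni") {
  vals <- data[[value]]
  grp <- factor(data[[group]])
  lv <- levels(grp)
  if (length(lv) < 2) stop("need at least 2 groups")
  sizes <- table(grp)
  if (any(sizes == 0)) stop("every group needs at least one observation")
  # ties are expected in discrete data (e.g. gridded recovery times); the
  # rank tests then use the normal approximation without complaint
  wtest <- function(a, b) {
    withCallingHandlers(
      stats::wilcox.test(a, b, alternative = alternative),
      warning = function(w) {
        if (grepl("exact p-value", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
  }
  if (length(lv) == 2) {
    om <- wtest(vals[grp == lv[1]], vals[grp == lv[2]])
    om_method <- "mann-whitney"
  } else {
    om <- stats::kruskal.test(vals, grp)
    om_method <- "kruskal-wallis"
  }
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  res <- lapply(pairs, function(p) {
    ht <- wtest(vals[grp == p[1]], vals[grp == p[2]])
    tibble::tibble(group1 = p[1], group2 = p[2],
                   statistic = unname(ht$statistic), p_value = ht$p.value)
  })
  out <- dplyr::bind_rows(res)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = correction)
  structure(out,
            omnibus_statistic = unname(om$statistic),
            omnibus_p = om$p.value,
            omnibus_method = om_method)
}

#' Estimate the DC-mediated percent reduction from windowed counts
#'
#' Fits the windowed post-stimulus counts with a Gaussian linear mixed model
#' (`post_count ~ phase + covariates + (1 | unit) [+ (1 | animal)]`),
#' extracts the estimated marginal means of the pre and during phases, and
#' reports `100 * (1 - EMM_during / EMM_pre)` with a delta-method standard
#' error and the Tukey-adjusted phase contrast p value.
#'
#' @param counts tidy counts with at least `unit`, `phase`
#'   (`"pre"`/`"during"`), `post_count`; an `animal` column adds a second
#'   random intercept, and any `covariates` are added as fixed effects.
#' @param covariates extra fixed-effect column names.
#' @return one-row tibble: `emm_pre`, `se_pre`, `emm_during`, `se_during`,
#'   `pct_reduction`, `se_pct`, `p_value`, `singular`.
#' @export
estimate_reduction <- function(counts, covariates = character(0)) {
  counts$phase <- factor(counts$phase, levels = c("pre", "during"))
  random <- "unit"
  if ("animal" %in% names(counts) &&
      length(unique(counts$animal)) >= 2) {
    random <- c("animal", "unit")
  }
  model <- fit_mixed_model(counts, "post_count", c("phase", covariates), random)
  et <- emm_table(model, "phase")
  e <- et$emmeans
  pre <- e[e$level == "pre", ]
  dur <- e[e$level == "during", ]
  ratio_var <- (dur$se / pre$emmean)^2 +
    (dur$emmean * pre$se / pre$emmean^2)^2
  tibble::tibble(
    emm_pre = pre$emmean,
    se_pre = pre$se,
    emm_during = dur$emmean,
    se_during = dur$se,
    pct_reduction = percent_reduction(pre$emmean, dur$emmean),
    se_pct = 100 * sqrt(ratio_var),
    p_value = et$contrasts$p_value[1],
    singular = model$singular
  )
}
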