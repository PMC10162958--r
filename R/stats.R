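#' Least-squares-means contrasts for a cross-over metric table
#'
#' Fits a fixed-effects linear model `value ~ subject + treatment` (the
#' balanced cross-over makes this equivalent to the random-subject model
#' for the contrasts of interest) and reports least-squares (adjusted)
#' mean differences of every other condition against each reference
#' condition, with Wald t tests on the residual degrees of freedom.
#' Conditions observed only once are dropped from the contrast list with a
#' warning.
#'
#' @param table Tidy metric table: columns `subject_id`, `treatment`,
#'   `metric`, `value` (one row per subject x treatment x metric).
#' @param metric Which metric to analyze.
#' @param reference_labels Conditions to contrast against (default
#'   `"vehicle"`); each remaining condition is compared to each reference.
#' @param adjust Multiplicity adjustment passed to emmeans (default
#'   `"none"`; the source reporting applies none. `"holm"` available).
#' @return Data frame of `contrast_result` rows: `metric`, `comparison`
#'   (e.g. `"vs-vehicle"`), `level`, `estimate`, `se`, `t`, `df`, `p`,
#'   `n`.
#' @export
lsmeans_contrasts <- function(table, metric,
                              reference_labels = "vehicle",
                              adjust = "none") {
  d <- table[table$metric == metric & !is.na(table$value), , drop = FALSE]
  if (!nrow(d)) stop("no rows for metric '", metric, "'", call. = FALSE)
  d$subject_id <- factor(d$subject_id)
  d$treatment <- factor(d$treatment)
  counts <- table(d$treatment)
  singletons <- names(counts)[counts < 2]
  if (length(singletons)) {
    warning("conditions with a single observation skipped: ",
            paste(singletons, collapse = ", "))
    d <- droplevels(d[!d$treatment %in% singletons, , drop = FALSE])
  }
  if (nlevels(d$treatment) < 2 || nlevels(d$subject_id) < 2)
    stop("need >= 2 subjects and >= 2 conditions", call. = FALSE)
  fit <- stats::lm(value ~ subject_id + treatment, data = d)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design for metric '", metric, "'", call. = FALSE)
  em <- emmeans::emmeans(fit, "treatment")
  out <- list()
  for (ref in intersect(reference_labels, levels(d$treatment))) {
    cs <- summary(emmeans::contrast(
      em, "trt.vs.ctrl", ref = ref, adjust = adjust))
    out[[ref]] <- data.frame(
      metric = metric,
      comparison = paste0("vs-", ref),
      level = sub(" - .*$", "", cs$contrast),
      estimate = cs$estimate, se = cs$SE, t = cs$t.ratio,
      df = cs$df, p = cs$p.value,
      n = nlevels(d$subject_id))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("contrast_result", "data.frame")
  res
}

#' Two-way optogenetics-by-drug analysis
#'
#' Fixed-effects two-way analysis of variance with interaction,
#' `value ~ treatment * opto`, with the electrode (or unit) as replicate.
#' Degenerate inputs with zero between-cell variability report `F = 0`,
#' `p = 1`.
#'
#' @param table Tidy table with columns `treatment`, `opto` (logical),
#'   `metric`, `value`; all four treatment x opto cells must be occupied.
#' @param metric Which metric to analyze.
#' @return Data frame with one row per term (`main_drug`, `main_opto`,
#'   `interaction`): `term`, `df`, `F`, `p`.
#' @export
twoway_opto_drug <- function(table, metric) {
  d <- table[table$metric == metric & !is.na(table$value), , drop = FALSE]
  if (!nrow(d)) stop("no rows for metric '", metric, "'", call. = FALSE)
  d$treatment <- factor(d$treatment)
  d$opto <- factor(d$opto)
  cells <- table(d$treatment, d$opto)
  if (any(cells == 0)) stop("empty treatment x opto cell", call. = FALSE)
  if (stats::var(d$value) == 0) {
    return(data.frame(term = c("main_drug", "main_opto", "interaction"),
                      df = c(nlevels(d$treatment) - 1L, nlevels(d$opto) - 1L,
                             (nlevels(d$treatment) - 1L) *
                               (nlevels(d$opto) - 1L)),
                      F = 0, p = 1))
  }
  fit <- stats::lm(value ~ treatment * opto, data = d)
  a <- stats::anova(fit)
  pick <- function(term_name) {
    i <- match(term_name, rownames(a))
    f <- a[i, "F value"]; p <- a[i, "Pr(>F)"]
    if (!is.finite(f)) {
      # zero residual variance: a zero effect SS is F = 0, p = 1
      if (a[i, "Sum Sq"] < 1e-12) { f <- 0; p <- 1 } else { f <- Inf; p <- 0 }
    }
    data.frame(df = a[i, "Df"], F = f, p = p)
  }
  res <- rbind(
    cbind(term = "main_drug", pick("treatment")),
    cbind(term = "main_opto", pick("opto")),
    cbind(term = "interaction", pick("treatment:opto")))
  rownames(res) <- NULL
  res
}

#' Per-condition mean and SEM summary
#'
#' The bar-graph summary: mean and `sd/sqrt(n)` of the plotted
#' per-replicate values for each condition.
#'
#' @param table Tidy metric table.
#' @param metric Metric name.
#' @param by Grouping columns (default `"treatment"`).
#' @return Data frame with the grouping columns plus `mean`, `sem`, `n`.
#' @export
condition_summary <- function(table, metric, by = "treatment") {
  d <- table[table$metric == metric & !is.na(table$value), , drop = FALSE]
  agg <- stats::aggregate(d$value, d[by], function(v)
    c(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)), n = length(v)))
  out <- cbind(agg[by], as.data.frame(agg$x))
  out$n <- as.integer(out$n)
  out
}
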