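#' Agreement between two classifications of the same samples
#'
#' Cross-tabulates two labelings and computes the observed agreement
#' `p_o` (fraction of identically labeled samples), the agreement expected
#' by chance alone `p_e = sum_c marginal_a(c) * marginal_b(c)`, and
#' Cohen's kappa `(p_o - p_e) / (1 - p_e)`.  The number of possible
#' classes strongly influences chance agreement: two independent uniform
#' labelings over 10 classes agree by chance 10% of the time, and
#' non-uniform marginals push that figure up.
#'
#' @param labels_a,labels_b equal-length label vectors (factor or
#'   character).
#' @return An object of class `"agreement_report"`: `contingency` (A x B
#'   count table over the union label space, fixed sorted order),
#'   `percent_agreement` (0-100), `expected_agreement_pe`, `kappa`, `n`.
#' @export
agreement <- function(labels_a, labels_b) {
  a <- as.character(labels_a); b <- as.character(labels_b)
  if (length(a) != length(b))
    stop("labelings must have equal length", call. = FALSE)
  if (length(a) == 0L) stop("need at least 1 sample", call. = FALSE)
  space <- sort(unique(c(a, b)))
  fa <- factor(a, levels = space); fb <- factor(b, levels = space)
  tab <- table(fa, fb, dnn = c("a", "b"))
  n <- length(a)
  p_o <- sum(diag(tab)) / n
  p_e <- sum((rowSums(tab) / n) * (colSums(tab) / n))
  if (length(intersect(unique(a), unique(b))) == 0L)
    warning("label spaces are disjoint; percent agreement is 0")
  kappa <- if (p_e >= 1) 1 else (p_o - p_e) / (1 - p_e)
  structure(list(
    contingency = tab,
    percent_agreement = 100 * p_o,
    expected_agreement_pe = p_e,
    kappa = kappa,
    n = n
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Agreement: ", format(x$percent_agreement, digits = 3),
      "% observed, ", format(100 * x$expected_agreement_pe, digits = 3),
      "% expected by chance, kappa = ", format(x$kappa, digits = 3),
      " (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Proportion from printed event counts
#'
#' Turns an events/total count pair into a percentage, with the
#' display-rounded value matching how such rates are printed in clinical
#' tables (round half away from zero).
#'
#' @param events non-negative integer count of events.
#' @param total positive integer denominator.
#' @param digits decimal places of the display value (default 0: integer
#'   percent).
#' @return A list with `percent` (exact, 0-100), `display` (rounded),
#'   `events`, `total`.
#' @export
proportion_from_counts <- function(events, total, digits = 0) {
  if (total <= 0) stop("total must be positive", call. = FALSE)
  if (events < 0 || events > total)
    stop("events must lie in [0, total]", call. = FALSE)
  pct <- 100 * events / total
  f <- 10^digits
  display <- sign(pct) * floor(abs(pct) * f + 0.5) / f
  list(percent = pct, display = display, events = events, total = total)
}

#' Adjusted R-squared of a one-way ANOVA
#'
#' Fits the one-way ANOVA of `y` on group membership and returns the
#' adjusted coefficient of determination
#' `1 - (1 - R^2) (n - 1) / (n - k)`, which corrects the raw `R^2 =
#' 1 - SS_within / SS_total` for the number of groups and can be negative
#' when groups explain nothing.
#'
#' @param y numeric response (e.g. one gene's expression across samples).
#' @param groups per-sample group labels, at least 2 non-empty groups and
#'   more samples than groups.
#' @return The adjusted R-squared (scalar).
#' @export
anova_adjusted_r2 <- function(y, groups) {
  g <- droplevels(factor(groups))
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]; g <- droplevels(g[ok])
  n <- length(y); k <- nlevels(g)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  if (n <= k) stop("need more samples than groups", call. = FALSE)
  if (stats::var(y) == 0) stop("zero total variance in y", call. = FALSE)
  summary(stats::lm(y ~ g))$adj.r.squared
}

#' Compare how well two labelings explain per-gene expression
#'
#' For every gene, fits one-way ANOVAs of its expression on labeling A and
#' on labeling B and records the difference in adjusted R-squared; the
#' study estimate is the mean difference over genes (positive: A explains
#' more).  A percentile-bootstrap confidence interval is obtained by
#' resampling genes with replacement (samples held fixed), reproducibly
#' under `seed`.
#'
#' @param x feature x sample expression matrix.
#' @param labels_a,labels_b per-sample labelings covering all columns of
#'   `x`.
#' @param genes character vector of gene (row) ids to evaluate.
#' @param n_bootstrap bootstrap replicates (default 1000).
#' @param seed integer seed for the resampling.
#' @param conf confidence level (default 0.95).
#' @return An object of class `"explained_variation_report"`:
#'   `per_gene_adj_r2` (data.frame gene/adj_r2_a/adj_r2_b/delta),
#'   `mean_delta`, `ci_low`, `ci_high`, `n_bootstrap`, `study_weight`
#'   (number of samples).
#' @export
explained_variation_comparison <- function(x, labels_a, labels_b, genes,
                                           n_bootstrap = 1000L,
                                           seed = NULL, conf = 0.95) {
  if (length(genes) == 0L) stop("empty gene list", call. = FALSE)
  miss <- setdiff(genes, rownames(x))
  if (length(miss) > 0L)
    stop("gene(s) not in matrix: ", paste(utils::head(miss, 3L),
                                          collapse = ", "), call. = FALSE)
  if (length(labels_a) != ncol(x) || length(labels_b) != ncol(x))
    stop("labelings must cover all samples", call. = FALSE)
  ra <- vapply(genes, function(g) anova_adjusted_r2(x[g, ], labels_a),
               numeric(1))
  rb <- vapply(genes, function(g) anova_adjusted_r2(x[g, ], labels_b),
               numeric(1))
  delta <- ra - rb
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  G <- length(delta)
  boot <- vapply(seq_len(n_bootstrap), function(b) {
    mean(delta[sample.int(G, G, replace = TRUE)])
  }, numeric(1))
  alpha <- 1 - conf
  srt <- sort(boot)
  lo <- srt[max(1L, ceiling(alpha / 2 * n_bootstrap))]
  hi <- srt[min(n_bootstrap, ceiling((1 - alpha / 2) * n_bootstrap))]
  structure(list(
    per_gene_adj_r2 = data.frame(gene = genes, adj_r2_a = unname(ra),
                                 adj_r2_b = unname(rb),
                                 delta = unname(delta),
                                 stringsAsFactors = FALSE),
    mean_delta = mean(delta),
    ci_low = lo,
    ci_high = hi,
    n_bootstrap = as.integer(n_bootstrap),
    conf = conf,
    study_weight = ncol(x)
  ), class = "explained_variation_report")
}

#' @export
print.explained_variation_report <- function(x, ...) {
  cat("Explained-variation comparison over",
      nrow(x$per_gene_adj_r2), "genes:\n")
  cat("  mean delta adj-R2 =", format(x$mean_delta, digits = 3),
      sprintf("(%.0f%% CI %s to %s, %d bootstrap replicates)",
              100 * x$conf, format(x$ci_low, digits = 3),
              format(x$ci_high, digits = 3), x$n_bootstrap), "\n")
  invisible(x)
}

#' Study-size-weighted mean of per-study estimates
#'
#' The overall cross-study summary: `sum(estimate * n) / sum(n)`.
#'
#' @param estimates numeric per-study estimates.
#' @param n positive per-study sample sizes.
#' @return The weighted mean (scalar).
#' @export
weighted_mean_across_studies <- function(estimates, n) {
  if (length(estimates) == 0L) stop("empty study list", call. = FALSE)
  if (length(estimates) != length(n))
    stop("estimates and n must have equal length", call. = FALSE)
  if (any(n <= 0)) stop("all study sizes must be positive", call. = FALSE)
  sum(estimates * n) / sum(n)
}
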