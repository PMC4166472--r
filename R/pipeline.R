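#' Build a reference for cohort subtyping
#'
#' Prepares the index cohort against which new studies are classified:
#' expression (and optionally gene-level copy number derived from
#' segmented calls) is matched to the catalog, z-scored, and stored
#' together with the subtype labels.  [subtype_cohort()] re-estimates
#' centroids against this reference for whatever feature set a new study
#' provides.
#'
#' @param expression feature x sample matrix of the reference cohort
#'   (un-normalized; rownames are catalog expression feature ids).
#' @param labels per-sample subtype labels of the reference cohort.
#' @param catalog the [feature_catalog()].
#' @param segments optional [segment_set()] of the reference cohort,
#'   enabling `copy_number` and `combined` classification modes.
#' @return An object of class `"nsc_reference"` with normalized `expr`,
#'   `cn` and `combined` matrices (the latter two `NULL` without
#'   segments), `labels` and `catalog`.
#' @export
train_reference <- function(expression, labels, catalog, segments = NULL) {
  stopifnot(is.matrix(expression))
  labels <- factor(labels)
  if (ncol(expression) != length(labels))
    stop("length(labels) must equal ncol(expression)", call. = FALSE)
  m <- match_expression_features(expression, catalog, mode = "probe")
  ze <- zscore_features(m$x)
  cn <- combined <- NULL
  if (!is.null(segments)) {
    g <- segments_to_gene_matrix(segments, catalog,
                                 sample_ids = colnames(expression))
    zc <- zscore_features(g$x)
    cn <- zc$x
    shared <- intersect(colnames(ze$x), colnames(cn))
    combined <- assemble_combined(ze$x[, shared, drop = FALSE],
                                  cn[, shared, drop = FALSE])
  }
  structure(list(
    expr = ze$x,
    cn = cn,
    combined = combined,
    labels = labels,
    catalog = catalog,
    expr_match = m$report
  ), class = "nsc_reference")
}

#' @export
print.nsc_reference <- function(x, ...) {
  cat("Subtyping reference:", ncol(x$expr), "samples,",
      nrow(x$expr), "expression features",
      if (!is.null(x$cn)) paste0("+ ", nrow(x$cn), " CN features"),
      "\n")
  print(table(x$labels))
  invisible(x)
}

#' Classify a new cohort against a trained reference
#'
#' The full three-step workflow for one study: (1) match the study's
#' features against the reference catalog — expression by probe or gene
#' name, copy number by genomic position from segmented calls; (2) z-score
#' every matched feature within the study so it lands on the reference
#' scale; (3) re-estimate shrunken centroids against the reference cohort
#' using exactly the features the study provides (fresh cross-validated
#' threshold, reproducible under `seed`) and assign each sample to the
#' subtype minimizing the discriminant score.  A per-subtype goodness-of-
#' fit correlation against the training centroids is attached.
#'
#' @param reference an `"nsc_reference"` from [train_reference()].
#' @param expression feature x sample matrix of the new study
#'   (`expression` and `combined` modes).
#' @param segments a [segment_set()] for the new study (`copy_number` and
#'   `combined` modes).
#' @param mode `"expression"`, `"copy_number"` or `"combined"`.
#' @param feature_mode `"probe"` (exact id match) or `"gene"` (rows mapped
#'   to gene symbols, multi-row genes averaged).
#' @param gene_map optional dataset-feature-to-gene map for gene mode.
#' @param min_feature_fraction minimal fraction of reference features the
#'   study must provide (default 0.5).
#' @param seed integer seed for threshold cross-validation.
#' @param ... further arguments to [nsc()] (e.g. `n_folds`,
#'   `n_thresholds`).
#' @return An object of class `"subtype_fit"`: list with `result` (an
#'   `"nsc_classification"`), `gof` (a `"gof_report"`), `model` (the
#'   re-estimated `"nsc"`), `match_report`, `mode`, `seed`.
#' @export
subtype_cohort <- function(reference, expression = NULL, segments = NULL,
                           mode = c("expression", "copy_number",
                                    "combined"),
                           feature_mode = c("probe", "gene"),
                           gene_map = NULL, min_feature_fraction = 0.5,
                           seed = NULL, ...) {
  mode <- match.arg(mode)
  feature_mode <- match.arg(feature_mode)
  stopifnot(inherits(reference, "nsc_reference"))

  need_expr <- mode %in% c("expression", "combined")
  need_cn <- mode %in% c("copy_number", "combined")
  if (need_expr && is.null(expression))
    stop(mode, " mode requires an expression matrix", call. = FALSE)
  if (need_cn && is.null(segments))
    stop(mode, " mode requires segmented copy-number calls",
         call. = FALSE)
  if (need_cn && is.null(reference$cn))
    stop("reference was trained without copy-number data", call. = FALSE)

  x_expr <- report_expr <- NULL
  if (need_expr) {
    m <- match_expression_features(expression, reference$catalog,
                                   mode = feature_mode,
                                   gene_map = gene_map)
    x_expr <- zscore_features(m$x)$x
    report_expr <- m$report
  }
  x_cn <- report_cn <- NULL
  if (need_cn) {
    g <- segments_to_gene_matrix(segments, reference$catalog)
    x_cn <- zscore_features(g$x)$x
    report_cn <- g$report
  }

  if (mode == "expression") {
    x_new <- x_expr
    ref_x <- reference$expr
    report <- report_expr
  } else if (mode == "copy_number") {
    x_new <- x_cn
    ref_x <- reference$cn
    report <- report_cn
  } else {
    x_new <- assemble_combined(x_expr, x_cn)
    ref_x <- reference$combined
    report <- list(expression = report_expr, copy_number = report_cn)
  }

  model <- retrain_on_features(ref_x, reference$labels, rownames(x_new),
                               min_feature_fraction = min_feature_fraction,
                               seed = seed, ...)
  result <- predict(model, x_new,
                    min_feature_fraction = min_feature_fraction)
  gof <- per_class_gof(x_new, result, model)

  structure(list(
    result = result,
    gof = gof,
    model = model,
    match_report = report,
    mode = mode,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  ), class = "subtype_fit")
}

#' @export
print.subtype_fit <- function(x, ...) {
  cat("Cohort subtyping (", x$mode, " mode, ",
      x$result$n_features_used, " features)\n", sep = "")
  print(table(x$result$class))
  cat("study goodness of fit:", format(x$gof$study_gof, digits = 3), "\n")
  invisible(x)
}
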