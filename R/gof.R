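#' Goodness of fit of a classified cohort against the training centroids
#'
#' For each subtype with at least one assigned sample, computes the Pearson
#' correlation between the cohort's average expression profile for that
#' subtype (mean over its samples, restricted to the features shared with
#' the model) and the model's unshrunk training centroid.  The study-level
#' goodness of fit is the unweighted mean of the per-class correlations;
#' a value near 1 indicates the cohort reproduces the reference subtype
#' profiles faithfully.
#'
#' @param x normalized feature x sample matrix of the classified cohort.
#' @param result the `"nsc_classification"` for `x`.
#' @param model the fitted `"nsc"` model used for classification.
#' @param use_shrunken correlate against shrunken rather than raw training
#'   centroids (default `FALSE`: the raw class means of the reference).
#' @return An object of class `"gof_report"`: list with `per_class_r`
#'   (named numeric, `NA` for empty or degenerate classes), `study_gof`
#'   (mean of the defined per-class correlations), `n_features_used`,
#'   `n_samples_per_class`, `absent_reason` (named character for classes
#'   without a correlation).
#' @export
per_class_gof <- function(x, result, model, use_shrunken = FALSE) {
  stopifnot(is.matrix(x), inherits(result, "nsc_classification"),
            inherits(model, "nsc"))
  shared <- intersect(rownames(x), model$feature_ids)
  if (length(shared) < 3L)
    stop("need at least 3 features shared with the model", call. = FALSE)
  jj <- match(shared, model$feature_ids)
  targets <- if (use_shrunken) model$shrunk_centroids else model$centroids
  labels <- model$class_labels
  r <- stats::setNames(rep(NA_real_, length(labels)), labels)
  reason <- character(0)
  n_per <- stats::setNames(integer(length(labels)), labels)
  for (k in seq_along(labels)) {
    members <- which(as.character(result$class) == labels[k])
    n_per[k] <- length(members)
    if (length(members) == 0L) {
      reason[labels[k]] <- "no samples assigned"
      next
    }
    prof <- rowMeans(x[shared, result$sample_ids[members], drop = FALSE],
                     na.rm = TRUE)
    ok <- is.finite(prof)
    if (stats::sd(prof[ok]) == 0 || sum(ok) < 3L) {
      reason[labels[k]] <- "zero-variance mean profile"
      next
    }
    r[k] <- stats::cor(prof[ok], targets[k, jj][ok])
  }
  if (all(is.na(r)))
    stop("no class admits a goodness-of-fit correlation", call. = FALSE)
  structure(list(
    per_class_r = r,
    study_gof = mean(r, na.rm = TRUE),
    n_features_used = length(shared),
    n_samples_per_class = n_per,
    absent_reason = reason
  ), class = "gof_report")
}

#' @export
print.gof_report <- function(x, ...) {
  cat("Goodness of fit (study-level):",
      format(x$study_gof, digits = 3), "over", x$n_features_used,
      "features\n")
  print(round(x$per_class_r, 3))
  invisible(x)
}

#' Per-class average expression profiles
#'
#' Class x feature table of mean expression across the samples assigned to
#' each class — the numbers behind subtype profile plots.  When a catalog
#' is supplied, features are ordered by genomic position (chromosome, then
#' start).
#'
#' @param x feature x sample matrix.
#' @param result the `"nsc_classification"` for `x`.
#' @param catalog optional [feature_catalog()] used to order features by
#'   genomic position.
#' @return A class x feature numeric matrix (classes with no samples are
#'   omitted).
#' @export
average_profiles <- function(x, result, catalog = NULL) {
  stopifnot(is.matrix(x), inherits(result, "nsc_classification"))
  feats <- rownames(x)
  if (!is.null(catalog)) {
    cat_idx <- match(feats, catalog$feature_id)
    keep <- !is.na(cat_idx)
    feats <- feats[keep]
    cat_sub <- catalog[cat_idx[keep], ]
    chrom_num <- suppressWarnings(as.numeric(cat_sub$chromosome))
    ord <- order(is.na(chrom_num), chrom_num, cat_sub$chromosome,
                 cat_sub$start)
    feats <- feats[ord]
  }
  present <- levels(droplevels(result$class))
  out <- matrix(NA_real_, length(present), length(feats),
                dimnames = list(present, feats))
  for (cl in present) {
    members <- result$sample_ids[as.character(result$class) == cl]
    out[cl, ] <- rowMeans(x[feats, members, drop = FALSE], na.rm = TRUE)
  }
  out
}

#' Serialize a goodness-of-fit report to JSON
#' @param report a `"gof_report"`.
#' @param path file path.
#' @return Invisibly, `path`.
#' @export
write_gof_report <- function(report, path) {
  jsonlite::write_json(
    list(per_class_r = as.list(report$per_class_r),
         study_gof = report$study_gof,
         n_features_used = report$n_features_used,
         n_samples_per_class = as.list(report$n_samples_per_class),
         absent_reason = as.list(report$absent_reason)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
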