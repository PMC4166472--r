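#' @export
print.nsc <- function(x, ...) {
  cat("Nearest shrunken centroid classifier\n")
  cat("  classes:  ", length(x$class_labels), " (",
      paste(utils::head(x$class_labels, 5L), collapse = ", "),
      if (length(x$class_labels) > 5L) ", ..." else "", ")\n", sep = "")
  cat("  features: ", length(x$feature_ids), "\n", sep = "")
  cat("  samples:  ", x$n, " (class sizes ",
      paste(x$n_k, collapse = "/"), ")\n", sep = "")
  cat("  threshold:", format(x$threshold, digits = 4),
      if (!is.null(x$cv)) "(cross-validated)" else "(fixed)", "\n")
  active <- sum(colSums(x$d_shrunk != 0) > 0)
  cat("  features with nonzero shrunken offset:", active, "\n")
  invisible(x)
}

#' @export
summary.nsc <- function(object, ...) {
  active <- colSums(object$d_shrunk != 0) > 0
  out <- list(
    n_classes = length(object$class_labels),
    n_features = length(object$feature_ids),
    n_active_features = sum(active),
    threshold = object$threshold,
    s0 = object$s0,
    prior = stats::setNames(object$prior, object$class_labels),
    cv = object$cv
  )
  class(out) <- "summary.nsc"
  out
}

#' @export
print.summary.nsc <- function(x, ...) {
  cat("Shrunken centroid model: ", x$n_classes, " classes, ",
      x$n_active_features, "/", x$n_features,
      " features active at threshold ",
      format(x$threshold, digits = 4), "\n", sep = "")
  cat("s0 (fudge):", format(x$s0, digits = 4), "\n")
  cat("priors:\n")
  print(round(x$prior, 4))
  if (!is.null(x$cv)) {
    cat("CV error curve (threshold : misclassified):\n")
    print(stats::setNames(x$cv$errors, format(x$cv$grid, digits = 3)))
  }
  invisible(x)
}

#' Shrunken centroid matrix of a fitted model
#' @param object a fitted `"nsc"` model.
#' @param ... unused.
#' @return The K x p matrix of shrunken class centroids.
#' @export
coef.nsc <- function(object, ...) object$shrunk_centroids

#' Plot the cross-validation error curve of a fitted model
#' @param x a fitted `"nsc"` model with a CV record.
#' @param ... passed to [plot()].
#' @export
plot.nsc <- function(x, ...) {
  if (is.null(x$cv))
    stop("model was fitted with a fixed threshold; no CV curve",
         call. = FALSE)
  plot(x$cv$grid, x$cv$errors, type = "b", pch = 19,
       xlab = expression(paste("shrinkage threshold ", Delta)),
       ylab = "CV misclassification count", ...)
  graphics::abline(v = x$threshold, lty = 2)
  invisible(x)
}

#' Simulate samples from a fitted shrunken-centroid model
#'
#' Draws `nsim` samples per requested class from independent Gaussians
#' centered at the class's shrunken centroid with per-feature standard
#' deviation `s_j + s0` — the dispersion the discriminant assumes.  Useful
#' for sanity-checking a model's separability.
#'
#' @param object a fitted `"nsc"` model.
#' @param nsim samples per class.
#' @param seed optional integer seed.
#' @param classes class labels to simulate (default all).
#' @param ... unused.
#' @return A list with `x` (features x samples matrix) and `labels`.
#' @export
simulate.nsc <- function(object, nsim = 1, seed = NULL,
                         classes = object$class_labels, ...) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  p <- length(object$feature_ids)
  sd_j <- object$s + object$s0
  cols <- list(); labs <- character(0)
  for (cl in classes) {
    k <- match(cl, object$class_labels)
    mu <- object$shrunk_centroids[k, ]
    sim <- matrix(stats::rnorm(p * nsim, mean = mu, sd = sd_j), p, nsim)
    cols[[cl]] <- sim
    labs <- c(labs, rep(cl, nsim))
  }
  x <- do.call(cbind, cols)
  rownames(x) <- object$feature_ids
  colnames(x) <- sprintf("sim%03d", seq_len(ncol(x)))
  attr(x, "normalized") <- TRUE
  list(x = x, labels = factor(labs, levels = object$class_labels))
}

#' Residuals of a classification against a fitted model
#'
#' Per sample, the difference between its feature vector and the shrunken
#' centroid of its assigned class (restricted to shared features).
#'
#' @param object a fitted `"nsc"` model.
#' @param newdata the classified matrix (features x samples).
#' @param result the matching `"nsc_classification"`; recomputed when
#'   omitted.
#' @param ... passed to [predict.nsc()] when `result` is omitted.
#' @return A features x samples matrix of residuals.
#' @export
residuals.nsc <- function(object, newdata, result = NULL, ...) {
  if (is.null(result)) result <- predict(object, newdata, ...)
  shared <- intersect(object$feature_ids, rownames(newdata))
  jj <- match(shared, object$feature_ids)
  k <- match(as.character(result$class), object$class_labels)
  newdata[shared, , drop = FALSE] -
    t(object$shrunk_centroids[k, jj, drop = FALSE])
}

#' @export
print.nsc_classification <- function(x, ...) {
  cat("Subtype classification of", length(x$sample_ids), "samples",
      "using", x$n_features_used, "features\n")
  print(table(x$class))
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' Stores labels, feature ids, all numeric arrays, the threshold, seed and
#' CV curve so that [model_from_json()] reproduces predictions exactly
#' without retraining.
#'
#' @param model a fitted `"nsc"` model.
#' @param path file path.
#' @return Invisibly, `path`.
#' @export
model_to_json <- function(model, path) {
  obj <- model[c("class_labels", "feature_ids", "centroids", "overall",
                 "s", "s0", "m_k", "prior", "d", "d_shrunk",
                 "shrunk_centroids", "threshold", "n_k", "n",
                 "prior_type", "m_convention", "s0_floor", "seed")]
  obj$cv <- if (is.null(model$cv)) NULL else
    model$cv[c("threshold", "grid", "errors", "folds", "seed")]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Restore a fitted model from JSON
#' @param path file written by [model_to_json()].
#' @return A `"nsc"` model usable with [predict.nsc()].
#' @export
model_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("centroids", "d", "d_shrunk", "shrunk_centroids")) {
    obj[[f]] <- matrix(as.numeric(obj[[f]]),
                       nrow = length(obj$class_labels),
                       dimnames = list(obj$class_labels, obj$feature_ids))
  }
  names(obj$overall) <- obj$feature_ids
  obj$call <- NULL
  structure(obj, class = "nsc")
}
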