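#' Fit a nearest-shrunken-centroid classifier
#'
#' Trains the shrunken-centroid model at the heart of the subtyping
#' workflow.  For feature j and class k with class sizes n_k (n total, K
#' classes) the model computes class centroids `xbar_kj`, the overall
#' centroid `xbar_j`, the pooled within-class standard deviation `s_j`, the
#' fudge constant `s0` (median of the `s_j`), and the standardized
#' centroid offsets
#' \deqn{d_{kj} = (\bar x_{kj} - \bar x_j) / (m_k (s_j + s_0)),}
#' with \eqn{m_k = \sqrt{1/n_k - 1/n}} by default.  Offsets are soft-
#' thresholded by the shrinkage threshold `threshold` (Delta):
#' \eqn{d'_{kj} = \mathrm{sign}(d_{kj}) \max(|d_{kj}| - \Delta, 0)}, and
#' shrunken centroids are rebuilt as
#' \eqn{\bar x'_{kj} = \bar x_j + m_k (s_j + s_0) d'_{kj}}.  When
#' `threshold` is `NULL` it is chosen by stratified cross-validation over a
#' grid of `n_thresholds` values spanning `[0, max |d_kj|]`, taking the
#' largest grid value that attains the minimal cross-validated
#' misclassification count (preferring sparser models); with a fixed
#' `seed`, folds, error curve and the chosen threshold are exactly
#' reproducible.
#'
#' Features missing in more than `max_missing` of samples are dropped with
#' a warning; remaining missing cells are simply excluded from means and
#' standard deviations.
#'
#' @param x numeric matrix, features x samples, normalized (see
#'   [zscore_features()]).
#' @param labels per-sample class labels (factor or character); every class
#'   needs at least 2 samples.
#' @param threshold fixed shrinkage threshold Delta, or `NULL` to
#'   cross-validate.
#' @param n_folds number of stratified CV folds (default 10, capped at the
#'   smallest class size).
#' @param n_thresholds number of grid points on `[0, max |d_kj|]`.
#' @param prior `"empirical"` (class frequencies, the default) or
#'   `"uniform"`.
#' @param m_convention `"minus"` for \eqn{m_k = \sqrt{1/n_k - 1/n}} (the
#'   convention of the original shrunken-centroid software) or `"plus"` for
#'   \eqn{\sqrt{1/n_k + 1/n}}.
#' @param s0_floor lower bound applied to `s0` when all pooled sds vanish,
#'   keeping discriminant scores finite on degenerate noiseless inputs.
#' @param seed integer seed controlling fold assignment; `NULL` leaves the
#'   RNG state alone.
#' @param max_missing maximal tolerated fraction of missing cells per
#'   feature.
#' @return An object of class `"nsc"`: a list with `class_labels`,
#'   `centroids` (K x p), `overall` (p), `s`, `s0`, `m_k`, `prior`,
#'   `d` (unshrunk offsets), `d_shrunk`, `shrunk_centroids`, `threshold`,
#'   `feature_ids`, `cv` (grid, per-threshold error counts, fold ids) when
#'   cross-validated, `n_k`, `n`, `seed`, `call`.
#' @seealso [predict.nsc()], [nsc_shrink()], [retrain_on_features()]
#' @export
nsc <- function(x, labels, threshold = NULL, n_folds = 10L,
                n_thresholds = 30L, prior = c("empirical", "uniform"),
                m_convention = c("minus", "plus"), s0_floor = 1e-6,
                seed = NULL, max_missing = 0.5) {
  prior <- match.arg(prior)
  m_convention <- match.arg(m_convention)
  stopifnot(is.matrix(x))
  labels <- factor(labels)
  if (ncol(x) != length(labels))
    stop("length(labels) must equal ncol(x)", call. = FALSE)
  n_k <- table(labels)
  if (nlevels(labels) < 2L)
    stop("need at least 2 classes", call. = FALSE)
  if (any(n_k < 2L))
    stop("class ", names(n_k)[which(n_k < 2L)[1L]],
         " has fewer than 2 samples", call. = FALSE)

  miss_frac <- rowMeans(is.na(x))
  if (any(miss_frac > max_missing)) {
    warning(sum(miss_frac > max_missing),
            " feature(s) missing in more than ", 100 * max_missing,
            "% of samples dropped")
    x <- x[miss_frac <= max_missing, , drop = FALSE]
  }
  if (nrow(x) == 0L) stop("no usable features", call. = FALSE)

  fit <- nsc_statistics(x, labels, m_convention, s0_floor)
  pi_k <- if (prior == "empirical") as.numeric(n_k) / ncol(x)
          else rep(1 / nlevels(labels), nlevels(labels))

  model <- structure(list(
    class_labels = levels(labels),
    centroids = fit$centroids,
    overall = fit$overall,
    s = fit$s,
    s0 = fit$s0,
    m_k = fit$m_k,
    prior = pi_k,
    d = fit$d,
    d_shrunk = fit$d,
    shrunk_centroids = fit$centroids,
    threshold = 0,
    feature_ids = rownames(x),
    cv = NULL,
    n_k = as.integer(n_k),
    n = ncol(x),
    prior_type = prior,
    m_convention = m_convention,
    s0_floor = s0_floor,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    call = match.call()
  ), class = "nsc")

  if (is.null(threshold)) {
    cv <- nsc_cv(x, labels, n_thresholds = n_thresholds, n_folds = n_folds,
                 seed = seed, prior = prior, m_convention = m_convention,
                 s0_floor = s0_floor)
    model$cv <- cv
    threshold <- cv$threshold
  }
  nsc_shrink(model, threshold)
}

# Minimal unvalidated model used for CV fold fits.
nsc_fold_fit <- function(x, labels, prior, m_convention, s0_floor) {
  labels <- factor(labels)
  fit <- nsc_statistics(x, labels, m_convention, s0_floor)
  n_k <- as.numeric(table(labels))
  pi_k <- if (prior == "empirical") n_k / ncol(x)
          else rep(1 / nlevels(labels), nlevels(labels))
  structure(list(
    class_labels = levels(labels), centroids = fit$centroids,
    overall = fit$overall, s = fit$s, s0 = fit$s0, m_k = fit$m_k,
    prior = pi_k, d = fit$d, d_shrunk = fit$d,
    shrunk_centroids = fit$centroids, threshold = 0,
    feature_ids = rownames(x), cv = NULL, n_k = as.integer(n_k),
    n = ncol(x), prior_type = prior, m_convention = m_convention,
    s0_floor = s0_floor, seed = NA_integer_
  ), class = "nsc")
}

# Core centroid/dispersion statistics shared by nsc() and the CV loop.
# Missing cells are excluded from means and pooled sums of squares; the
# pooled sd uses the (n_obs - K) denominator.
nsc_statistics <- function(x, labels, m_convention, s0_floor) {
  K <- nlevels(labels)
  p <- nrow(x)
  n <- ncol(x)
  n_k <- as.numeric(table(labels))
  centroids <- matrix(NA_real_, K, p,
                      dimnames = list(levels(labels), rownames(x)))
  ss <- rep(0, p)
  n_obs <- rowSums(!is.na(x))
  for (k in seq_len(K)) {
    xk <- x[, labels == levels(labels)[k], drop = FALSE]
    ck <- rowMeans(xk, na.rm = TRUE)
    centroids[k, ] <- ck
    dev <- xk - ck
    ss <- ss + rowSums(dev^2, na.rm = TRUE)
  }
  overall <- rowMeans(x, na.rm = TRUE)
  df <- pmax(n_obs - K, 0L)
  s <- ifelse(df > 0, sqrt(ss / df), 0)
  s0 <- stats::median(s)
  if (s0 <= 0) s0 <- s0_floor
  m_k <- if (m_convention == "minus") sqrt(1 / n_k - 1 / n)
         else sqrt(1 / n_k + 1 / n)
  d <- (centroids - rep(overall, each = K)) /
    (m_k %o% (s + s0))
  list(centroids = centroids, overall = overall, s = s, s0 = s0,
       m_k = m_k, d = d)
}

#' Apply soft-threshold shrinkage to a fitted model
#'
#' Recomputes the shrunken offsets and centroids of a fitted `"nsc"` model
#' at a new threshold without refitting: `d'_kj = sign(d_kj) *
#' max(|d_kj| - Delta, 0)` and `xbar'_kj = xbar_j + m_k (s_j + s0) d'_kj`.
#' `Delta = 0` reproduces the unshrunk model; `Delta >= max |d_kj|` shrinks
#' every centroid onto the overall centroid, so prediction falls back to
#' the class priors.
#'
#' @param model a fitted `"nsc"` model.
#' @param threshold non-negative shrinkage threshold.
#' @return The model with `d_shrunk`, `shrunk_centroids` and `threshold`
#'   updated.
#' @export
nsc_shrink <- function(model, threshold) {
  stopifnot(inherits(model, "nsc"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    stop("threshold must be a single non-negative number", call. = FALSE)
  if (threshold == 0) {
    # exact identity: no rebuilt arithmetic at the no-shrinkage limit
    model$d_shrunk <- model$d
    model$shrunk_centroids <- model$centroids
    model$threshold <- 0
    return(model)
  }
  d_shrunk <- sign(model$d) * pmax(abs(model$d) - threshold, 0)
  dimnames(d_shrunk) <- dimnames(model$d)
  scale_kj <- model$m_k %o% (model$s + model$s0)
  model$d_shrunk <- d_shrunk
  model$shrunk_centroids <-
    rep(model$overall, each = length(model$class_labels)) +
    scale_kj * d_shrunk
  dimnames(model$shrunk_centroids) <- dimnames(model$centroids)
  model$threshold <- threshold
  model
}

#' Choose the shrinkage threshold by stratified cross-validation
#'
#' Lays a grid of `n_thresholds` equally spaced values on
#' `[0, max |d_kj|]` (offsets from the full-data fit), assigns samples to
#' stratified folds (fold count capped at the smallest class size),
#' refits the centroids on each training split and counts held-out
#' misclassifications at every grid value.  The chosen threshold is the
#' largest grid value attaining the minimal total error — the sparsest of
#' the best models.  An identical `seed` yields identical folds, error
#' curve and threshold.
#'
#' @inheritParams nsc
#' @return A list with `threshold` (the chosen Delta), `grid`, `errors`
#'   (misclassification count per grid value), `folds` (per-sample fold
#'   ids) and `seed`.
#' @export
nsc_cv <- function(x, labels, n_thresholds = 30L, n_folds = 10L,
                   seed = NULL, prior = c("empirical", "uniform"),
                   m_convention = c("minus", "plus"), s0_floor = 1e-6) {
  prior <- match.arg(prior)
  m_convention <- match.arg(m_convention)
  labels <- factor(labels)
  if (n_folds < 2L) stop("n_folds must be at least 2", call. = FALSE)
  if (n_thresholds < 1L)
    stop("n_thresholds must be at least 1", call. = FALSE)
  n_folds <- min(n_folds, min(table(labels)))

  full <- nsc_statistics(x, labels, m_convention, s0_floor)
  dmax <- max(abs(full$d))
  grid <- if (n_thresholds == 1L) 0 else seq(0, dmax,
                                             length.out = n_thresholds)

  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  folds <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }

  errors <- integer(length(grid))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    # fold fits bypass the user-level class-size validation: stratified
    # folds can leave a rare class with a single training sample, which
    # the centroid formulas tolerate
    fit <- nsc_fold_fit(x[, tr, drop = FALSE], labels[tr], prior,
                        m_convention, s0_floor)
    for (g in seq_along(grid)) {
      m_g <- nsc_shrink(fit, grid[g])
      pred <- predict(m_g, x[, !tr, drop = FALSE],
                      min_feature_fraction = 0)
      errors[g] <- errors[g] +
        sum(as.character(pred$class) != as.character(labels[!tr]))
    }
  }
  best <- max(grid[errors == min(errors)])
  list(threshold = best, grid = grid, errors = errors, folds = folds,
       seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Classify samples with a fitted shrunken-centroid model
#'
#' For each sample x the discriminant score of class k is
#' \deqn{\delta_k(x) = \sum_j (x_j - \bar x'_{kj})^2 / (s_j + s_0)^2
#'   - 2 \log \pi_k,}
#' summed over the model features available for that sample.  When some
#' features are absent (or missing in a sample) the sum is rescaled by
#' (number of model features) / (number present) so scores stay comparable,
#' and the whole prediction errors out if fewer than
#' `min_feature_fraction` of model features are present at all.  The
#' assigned class minimizes delta; ties are broken toward the larger prior,
#' then label order.  Posterior probabilities are the stabilized softmax
#' `exp(-delta/2)` normalized per sample.
#'
#' @param object a fitted `"nsc"` model.
#' @param newdata numeric matrix, features x samples, normalized on the
#'   same scale as the training data; rownames must be a subset-compatible
#'   feature id space.
#' @param min_feature_fraction minimal fraction of model features that must
#'   be present in `newdata` (default 0.5).
#' @param ... unused.
#' @return An object of class `"nsc_classification"` with `sample_ids`,
#'   `class` (factor over the model's class labels), `delta` (samples x K),
#'   `posterior` (samples x K, rows summing to 1), `n_features_used`,
#'   `seed`.
#' @export
predict.nsc <- function(object, newdata, min_feature_fraction = 0.5, ...) {
  stopifnot(is.matrix(newdata))
  shared <- intersect(object$feature_ids, rownames(newdata))
  p_model <- length(object$feature_ids)
  if (length(shared) < min_feature_fraction * p_model)
    stop("only ", length(shared), " of ", p_model, " model features ",
         "present (need >= ", min_feature_fraction * p_model,
         "); consider copy_number or combined mode", call. = FALSE)
  if (length(shared) == 0L) stop("no model features present", call. = FALSE)
  xs <- newdata[shared, , drop = FALSE]
  jj <- match(shared, object$feature_ids)
  w <- 1 / (object$s[jj] + object$s0)^2
  K <- length(object$class_labels)
  n <- ncol(xs)

  n_present <- colSums(!is.na(xs))
  if (any(n_present == 0L))
    stop("sample ", colnames(xs)[which(n_present == 0L)[1L]],
         " has no non-missing model features", call. = FALSE)
  delta <- matrix(NA_real_, n, K,
                  dimnames = list(colnames(xs), object$class_labels))
  for (k in seq_len(K)) {
    sq <- (xs - object$shrunk_centroids[k, jj])^2 * w
    delta[, k] <- colSums(sq, na.rm = TRUE) * (p_model / n_present) -
      2 * log(object$prior[k])
  }
  cls <- integer(n)
  for (i in seq_len(n)) {
    cand <- which(delta[i, ] == min(delta[i, ]))
    if (length(cand) > 1L)
      cand <- cand[order(-object$prior[cand], cand)]
    cls[i] <- cand[1L]
  }
  shifted <- -(delta - apply(delta, 1L, min)) / 2
  post <- exp(shifted)
  post <- post / rowSums(post)

  structure(list(
    sample_ids = colnames(xs),
    class = factor(object$class_labels[cls],
                   levels = object$class_labels),
    delta = delta,
    posterior = post,
    n_features_used = length(shared),
    seed = object$seed
  ), class = "nsc_classification")
}

#' Re-estimate the classifier on the feature subset a platform provides
#'
#' The mechanism by which missing genes are accommodated: rather than
#' predicting with absent features, the model is retrained from scratch
#' against the reference cohort using only the features the new platform
#' offers — fresh centroids, fresh cross-validated threshold — and the new
#' cohort is then classified with those re-estimated centroids.
#'
#' @param x reference cohort matrix (features x samples, normalized).
#' @param labels reference cohort class labels.
#' @param available_feature_ids feature ids the new platform provides.
#' @param min_feature_fraction minimal fraction of reference features that
#'   must be available.
#' @param ... passed on to [nsc()] (e.g. `seed`, `n_folds`).
#' @return A fitted `"nsc"` model on the available features.
#' @export
retrain_on_features <- function(x, labels, available_feature_ids,
                                min_feature_fraction = 0.5, ...) {
  keep <- intersect(rownames(x), available_feature_ids)
  if (length(keep) < min_feature_fraction * nrow(x))
    stop("only ", length(keep), " of ", nrow(x), " reference features ",
         "available (need >= ", min_feature_fraction * nrow(x),
         "); consider copy_number or combined mode", call. = FALSE)
  nsc(x[keep, , drop = FALSE], labels, ...)
}
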