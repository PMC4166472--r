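#' Scale each feature to a z-score
#'
#' Step 2 of the subtyping workflow: every feature (row) is centered and
#' scaled to unit standard deviation (denominator n - 1) over its
#' non-missing cells, so cohorts assayed on different platforms land on a
#' common scale.  Per-feature positive affine transforms of the input leave
#' the output unchanged, which is what makes downstream classification
#' platform-robust.  Zero-variance features (sd below `tol`) cannot be
#' scaled and are dropped, with a record kept.
#'
#' @param x numeric matrix, features x samples, at least 2 samples.
#' @param tol standard deviations below `tol` count as zero variance.
#' @return A list with:
#'   \describe{
#'     \item{x}{the z-scored matrix (retained features only), attribute
#'       `"normalized"` set to `TRUE`;}
#'     \item{record}{data.frame of per-feature `feature_id`, `mean`, `sd`,
#'       `n_used`;}
#'     \item{dropped_features}{character vector of zero-variance ids.}
#'   }
#' @export
zscore_features <- function(x, tol = 1e-12) {
  stopifnot(is.matrix(x))
  if (ncol(x) < 2L)
    stop("z-scoring requires at least 2 samples (sd undefined)",
         call. = FALSE)
  n_used <- rowSums(!is.na(x))
  mu <- rowMeans(x, na.rm = TRUE)
  sd_ <- apply(x, 1L, stats::sd, na.rm = TRUE)
  sd_[n_used < 2L] <- 0
  drop <- !is.finite(sd_) | sd_ < tol
  if (all(drop))
    stop("all features have zero variance", call. = FALSE)
  out <- (x[!drop, , drop = FALSE] - mu[!drop]) / sd_[!drop]
  attr(out, "normalized") <- TRUE
  list(
    x = out,
    record = data.frame(
      feature_id = rownames(x)[!drop],
      mean = unname(mu[!drop]),
      sd = unname(sd_[!drop]),
      n_used = unname(n_used[!drop]),
      stringsAsFactors = FALSE
    ),
    dropped_features = rownames(x)[drop]
  )
}

#' Serialize a normalization record to JSON for provenance
#' @param norm the list returned by [zscore_features()].
#' @param path file path.
#' @return Invisibly, `path`.
#' @export
write_normalization_record <- function(norm, path) {
  jsonlite::write_json(
    list(record = norm$record, dropped_features = norm$dropped_features),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
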