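#' Construct a feature catalog
#'
#' The feature catalog is the reference panel of classifier features: for
#' each feature an identifier (probe or gene id), a gene symbol, hg19-style
#' genomic coordinates (1-based, fully closed intervals) and a data type
#' (`"expression"` or `"copy_number"`).  A gene symbol may recur — several
#' probes can represent one gene — but feature ids must be unique.
#'
#' @param feature_id character vector of unique feature identifiers.
#' @param gene_symbol character vector of gene symbols (may repeat).
#' @param chromosome character vector of chromosome names (non-empty).
#' @param start,end integer vectors of 1-based inclusive coordinates.
#' @param data_type `"expression"` or `"copy_number"` per feature.
#' @return A `data.frame` of class `"feature_catalog"`.
#' @export
feature_catalog <- function(feature_id, gene_symbol, chromosome, start, end,
                            data_type) {
  cat <- data.frame(
    feature_id = as.character(feature_id),
    gene_symbol = as.character(gene_symbol),
    chromosome = as.character(chromosome),
    start = as.integer(start),
    end = as.integer(end),
    data_type = as.character(data_type),
    stringsAsFactors = FALSE
  )
  validate_feature_catalog(cat)
  class(cat) <- c("feature_catalog", "data.frame")
  cat
}

validate_feature_catalog <- function(cat) {
  dup <- cat$feature_id[duplicated(cat$feature_id)]
  if (length(dup) > 0L)
    stop("duplicate feature id ", dup[1L], call. = FALSE)
  if (any(!nzchar(cat$chromosome)) || anyNA(cat$chromosome))
    stop("catalog chromosome must be non-empty", call. = FALSE)
  bad <- which(cat$start > cat$end)
  if (length(bad) > 0L)
    stop("catalog entry ", cat$feature_id[bad[1L]], " has start > end",
         call. = FALSE)
  if (anyNA(cat$start) || anyNA(cat$end))
    stop("catalog entry lacking coordinates", call. = FALSE)
  ok <- cat$data_type %in% c("expression", "copy_number")
  if (!all(ok))
    stop("unknown data_type: ", cat$data_type[which(!ok)[1L]], call. = FALSE)
  invisible(cat)
}

#' Read a feature catalog from delimited text
#'
#' Expects columns `feature_id`, `gene_symbol`, `chromosome`, `start`,
#' `end`, `data_type`.
#'
#' @param path file path.
#' @param sep field separator, tab by default.
#' @return A [feature_catalog()].
#' @export
read_feature_catalog <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("feature_id", "gene_symbol", "chromosome", "start", "end",
            "data_type")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("catalog file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  feature_catalog(df$feature_id, df$gene_symbol, df$chromosome,
                  df$start, df$end, df$data_type)
}

#' Write a feature catalog to delimited text
#' @param catalog a [feature_catalog()].
#' @param path file path.
#' @param sep field separator.
#' @return Invisibly, `path`.
#' @export
write_feature_catalog <- function(catalog, path, sep = "\t") {
  utils::write.table(as.data.frame(catalog), path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature-by-sample expression (or gene-level copy-number) matrix
#'
#' The file is delimited text whose first column holds feature ids and
#' whose first row holds sample ids.  Cells equal to `missing_token` are
#' loaded as `NA` (flagged missing, never imputed at load time); all other
#' cells must parse as finite numbers.
#'
#' @param path file path.
#' @param missing_token string marking a missing cell (default `"NA"`).
#' @param sep field separator, tab by default (use `","` for CSV).
#' @return A numeric matrix (features x samples) with unique rownames
#'   (feature ids) and colnames (sample ids).  The attribute `"normalized"`
#'   is `FALSE`; [zscore_features()] sets it.
#' @export
read_expression_matrix <- function(path, missing_token = "NA", sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          comment.char = "", na.strings = character(0))
  feature_ids <- df[[1L]]
  sample_ids <- colnames(df)[-1L]
  dup <- feature_ids[duplicated(feature_ids)]
  if (length(dup) > 0L)
    stop("duplicate feature id ", dup[1L], call. = FALSE)
  dups <- sample_ids[duplicated(sample_ids)]
  if (length(dups) > 0L)
    stop("duplicate sample id ", dups[1L], call. = FALSE)
  raw <- as.matrix(df[, -1L, drop = FALSE])
  x <- matrix(NA_real_, nrow(raw), ncol(raw),
              dimnames = list(feature_ids, sample_ids))
  is_miss <- raw == missing_token
  vals <- suppressWarnings(as.numeric(raw[!is_miss]))
  bad <- which(!is_miss, arr.ind = TRUE)[which(!is.finite(vals)), , drop = FALSE]
  if (nrow(bad) > 0L)
    stop("non-numeric cell at feature ", feature_ids[bad[1L, 1L]],
         ", sample ", sample_ids[bad[1L, 2L]], call. = FALSE)
  x[!is_miss] <- vals
  attr(x, "normalized") <- FALSE
  x
}

#' Write a feature-by-sample matrix to delimited text
#' @param x numeric matrix with rownames and colnames.
#' @param path file path.
#' @param sep field separator.
#' @param missing_token string written for `NA` cells.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(x, path, sep = "\t",
                                    missing_token = "NA") {
  df <- data.frame(feature_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = missing_token)
  invisible(path)
}

#' Construct a set of segmented copy-number calls
#'
#' Validates the SEG-like record set: `start <= end` for every segment, and
#' segments belonging to one sample on one chromosome must not overlap
#' (coordinates are 1-based fully closed).
#'
#' @param sample_id,chromosome character vectors.
#' @param start,end integer 1-based inclusive coordinates.
#' @param log_ratio numeric log2 copy-number ratios.
#' @return A `data.frame` of class `"segment_set"`.
#' @export
segment_set <- function(sample_id, chromosome, start, end, log_ratio) {
  seg <- data.frame(
    sample_id = as.character(sample_id),
    chromosome = as.character(chromosome),
    start = as.integer(start),
    end = as.integer(end),
    log_ratio = as.numeric(log_ratio),
    stringsAsFactors = FALSE
  )
  bad <- which(seg$start > seg$end)
  if (length(bad) > 0L)
    stop("segment with start > end for sample ", seg$sample_id[bad[1L]],
         " on chromosome ", seg$chromosome[bad[1L]], call. = FALSE)
  if (nrow(seg) > 1L) {
    key <- paste(seg$sample_id, seg$chromosome, sep = "\r")
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      o <- idx[order(seg$start[idx])]
      ov <- which(seg$start[o][-1L] <= seg$end[o][-length(o)])
      if (length(ov) > 0L) {
        i <- o[ov[1L]]; j <- o[ov[1L] + 1L]
        stop(sprintf(
          "overlapping segments for sample %s chromosome %s: (%d..%d) and (%d..%d)",
          seg$sample_id[i], seg$chromosome[i], seg$start[i], seg$end[i],
          seg$start[j], seg$end[j]), call. = FALSE)
      }
    }
  }
  class(seg) <- c("segment_set", "data.frame")
  seg
}

#' Read segmented copy-number calls from a SEG-like file
#'
#' Expects columns `sample`, `chromosome`, `start`, `end`, `log_ratio`
#' (a `sample_id` header is accepted for the first column).  An empty file
#' with a header yields an empty, valid segment set.
#'
#' @param path file path.
#' @param sep field separator.
#' @return A [segment_set()].
#' @export
read_segments <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if ("sample" %in% names(df) && !"sample_id" %in% names(df))
    names(df)[names(df) == "sample"] <- "sample_id"
  need <- c("sample_id", "chromosome", "start", "end", "log_ratio")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("segment file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  segment_set(df$sample_id, df$chromosome, df$start, df$end, df$log_ratio)
}

#' Write segmented copy-number calls
#' @param segments a [segment_set()].
#' @param path file path.
#' @param sep field separator.
#' @return Invisibly, `path`.
#' @export
write_segments <- function(segments, path, sep = "\t") {
  utils::write.table(as.data.frame(segments), path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a classification result to delimited text
#'
#' One row per sample: `sample_id`, `assigned_class`, one posterior column
#' per class (named by class label, in the model's fixed class order), and
#' `max_posterior`.  Posterior row sums are re-validated on write.
#'
#' @param result an object of class `"nsc_classification"` as returned by
#'   [predict.nsc()].
#' @param path file path.
#' @param sep field separator.
#' @return Invisibly, `path`.
#' @export
write_classification <- function(result, path, sep = "\t") {
  stopifnot(inherits(result, "nsc_classification"))
  rs <- rowSums(result$posterior)
  if (any(abs(rs - 1) > 1e-9))
    stop("posterior rows do not sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")", call. = FALSE)
  df <- data.frame(
    sample_id = result$sample_ids,
    assigned_class = as.character(result$class),
    result$posterior,
    max_posterior = apply(result$posterior, 1L, max),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a classification written by [write_classification()]
#' @param path file path.
#' @param sep field separator.
#' @return An object of class `"nsc_classification"` with `sample_ids`,
#'   `class` and `posterior` populated (discriminant scores are not stored
#'   in the text representation).
#' @export
read_classification <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  labels <- setdiff(names(df), c("sample_id", "assigned_class",
                                 "max_posterior"))
  post <- as.matrix(df[, labels, drop = FALSE])
  rownames(post) <- df$sample_id
  structure(list(
    sample_ids = df$sample_id,
    class = factor(df$assigned_class, levels = labels),
    posterior = post,
    delta = NULL,
    n_features_used = NA_integer_,
    seed = NULL
  ), class = "nsc_classification")
}
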