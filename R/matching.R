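#' Match a dataset's expression features against the reference catalog
#'
#' Step 1 of the subtyping workflow.  In `"probe"` mode, dataset rownames
#' must equal catalog feature ids exactly.  In `"gene"` mode, dataset rows
#' are mapped to gene symbols (by `gene_map`, or their own rownames when no
#' map is given) and all dataset rows mapping to one catalog gene are
#' aggregated by their per-sample arithmetic mean.  The returned matrix
#' holds exactly the matched catalog entries, in catalog order.
#'
#' @param x numeric matrix, features x samples, rownames = dataset feature
#'   ids.
#' @param catalog a [feature_catalog()]; only its `"expression"` entries are
#'   used.
#' @param mode `"probe"` or `"gene"`.
#' @param gene_map optional named character vector mapping dataset feature
#'   ids to gene symbols (gene mode only).  Defaults to the identity map on
#'   rownames.
#' @return A list with `x` (matched matrix, rownames = catalog feature ids)
#'   and `report` (a `"match_report"`: `n_catalog`, `n_matched`,
#'   `unmatched_catalog_ids`, `ambiguous`, `match_mode`).
#' @export
match_expression_features <- function(x, catalog, mode = c("probe", "gene"),
                                      gene_map = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  cat <- catalog[catalog$data_type == "expression", , drop = FALSE]
  if (nrow(cat) == 0L)
    stop("catalog has no expression entries", call. = FALSE)

  if (mode == "probe") {
    hit <- rownames(x)[match(cat$feature_id, rownames(x))]
    matched <- which(!is.na(hit))
    if (length(matched) == 0L) stop("no features matched", call. = FALSE)
    out <- x[hit[matched], , drop = FALSE]
    rownames(out) <- cat$feature_id[matched]
    ambiguous <- list()
  } else {
    if (any(!nzchar(cat$gene_symbol)) || anyNA(cat$gene_symbol))
      stop("gene mode requires non-empty gene symbols in the catalog",
           call. = FALSE)
    if (is.null(gene_map)) {
      gene_map <- stats::setNames(rownames(x), rownames(x))
    }
    genes <- unname(gene_map[rownames(x)])
    matched <- which(cat$gene_symbol %in% genes)
    if (length(matched) == 0L) stop("no features matched", call. = FALSE)
    out <- matrix(NA_real_, length(matched), ncol(x),
                  dimnames = list(cat$feature_id[matched], colnames(x)))
    ambiguous <- list()
    for (i in seq_along(matched)) {
      rows <- which(genes == cat$gene_symbol[matched[i]])
      if (length(rows) > 1L) {
        ambiguous[[cat$feature_id[matched[i]]]] <- rownames(x)[rows]
        out[i, ] <- colMeans(x[rows, , drop = FALSE], na.rm = TRUE)
        out[i, ][is.nan(out[i, ])] <- NA_real_
      } else {
        out[i, ] <- x[rows, ]
      }
    }
  }
  attr(out, "normalized") <- isTRUE(attr(x, "normalized"))
  report <- structure(list(
    n_catalog = nrow(cat),
    n_matched = length(matched),
    unmatched_catalog_ids = cat$feature_id[setdiff(seq_len(nrow(cat)),
                                                   matched)],
    ambiguous = ambiguous,
    match_mode = mode
  ), class = "match_report")
  list(x = out, report = report)
}

#' Summarize segmented copy-number calls to gene level
#'
#' Matches copy-number features by genomic position: for each catalog gene
#' and sample, the gene-level value is the overlap-length-weighted mean of
#' the log ratios of all segments intersecting the gene span (the
#' `"midpoint"` rule instead takes the log ratio of the segment covering
#' the gene midpoint).  Genes with no overlapping segment in a sample are
#' missing (`NA`); genes never covered in any sample are listed in the
#' match report.
#'
#' @param segments a [segment_set()].
#' @param catalog a [feature_catalog()]; only `"copy_number"` entries are
#'   used and all must carry coordinates.
#' @param rule `"weighted"` (default) or `"midpoint"`.
#' @param sample_ids optional character vector fixing the sample set and
#'   column order (samples without segments yield all-missing columns);
#'   defaults to the samples present in `segments`.
#' @return A list with `x` (genes x samples numeric matrix, rownames =
#'   catalog feature ids) and `report` (a `"match_report"`).
#' @export
segments_to_gene_matrix <- function(segments, catalog,
                                    rule = c("weighted", "midpoint"),
                                    sample_ids = NULL) {
  rule <- match.arg(rule)
  cat <- catalog[catalog$data_type == "copy_number", , drop = FALSE]
  if (nrow(cat) == 0L)
    stop("catalog has no copy_number entries", call. = FALSE)
  if (anyNA(cat$start) || anyNA(cat$end))
    stop("catalog entry lacking coordinates", call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- unique(segments$sample_id)
  x <- matrix(NA_real_, nrow(cat), length(sample_ids),
              dimnames = list(cat$feature_id, sample_ids))

  if (nrow(segments) > 0L && length(sample_ids) > 0L) {
    if (rule == "midpoint") {
      q_start <- (cat$start + cat$end) %/% 2L
      q_end <- q_start
    } else {
      q_start <- cat$start
      q_end <- cat$end
    }
    genes_gr <- GenomicRanges::GRanges(
      cat$chromosome, IRanges::IRanges(q_start, q_end))
    segs_gr <- GenomicRanges::GRanges(
      segments$chromosome, IRanges::IRanges(segments$start, segments$end))
    hits <- GenomicRanges::findOverlaps(genes_gr, segs_gr)
    gi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    keep <- segments$sample_id[si] %in% sample_ids
    gi <- gi[keep]; si <- si[keep]
    if (length(gi) > 0L) {
      w <- pmin(cat$end[gi], segments$end[si]) -
        pmax(cat$start[gi], segments$start[si]) + 1
      cj <- match(segments$sample_id[si], sample_ids)
      cell <- (cj - 1L) * nrow(cat) + gi
      num <- rowsum(w * segments$log_ratio[si], cell)
      den <- rowsum(w, cell)
      x[as.integer(rownames(num))] <- num / den
    }
  }
  uncovered <- cat$feature_id[rowSums(!is.na(x)) == 0L]
  report <- structure(list(
    n_catalog = nrow(cat),
    n_matched = nrow(cat) - length(uncovered),
    unmatched_catalog_ids = uncovered,
    ambiguous = list(),
    match_mode = "position"
  ), class = "match_report")
  list(x = x, report = report)
}

#' Stack expression and gene-level copy-number matrices into one feature
#' space
#'
#' Both matrices must cover the same sample set (order may differ; output
#' sample order follows `expr`).  Feature ids are prefixed `"expr:"` and
#' `"cn:"` so the combined id space is unique, and [split_combined()]
#' recovers the two blocks exactly.
#'
#' @param expr expression matrix, features x samples.
#' @param cn gene-level copy-number matrix, features x samples.
#' @return The row-stacked numeric matrix.
#' @export
assemble_combined <- function(expr, cn) {
  a <- colnames(expr); b <- colnames(cn)
  if (!setequal(a, b)) {
    diff <- c(setdiff(a, b), setdiff(b, a))
    stop("sample sets differ: ", paste(diff, collapse = ", "),
         call. = FALSE)
  }
  cn <- cn[, a, drop = FALSE]
  out <- rbind(expr, cn)
  rownames(out) <- c(paste0("expr:", rownames(expr)),
                     paste0("cn:", rownames(cn)))
  attr(out, "normalized") <-
    isTRUE(attr(expr, "normalized")) && isTRUE(attr(cn, "normalized"))
  out
}

#' Split a combined matrix back into expression and copy-number blocks
#' @param x a matrix produced by [assemble_combined()].
#' @return A list with elements `expr` and `cn`, prefixes stripped.
#' @export
split_combined <- function(x) {
  is_expr <- startsWith(rownames(x), "expr:")
  is_cn <- startsWith(rownames(x), "cn:")
  if (!all(is_expr | is_cn))
    stop("matrix rows are not all 'expr:'/'cn:'-prefixed", call. = FALSE)
  expr <- x[is_expr, , drop = FALSE]
  cn <- x[is_cn, , drop = FALSE]
  rownames(expr) <- substring(rownames(expr), 6L)
  rownames(cn) <- substring(rownames(cn), 4L)
  list(expr = expr, cn = cn)
}

#' @export
print.match_report <- function(x, ...) {
  cat("Feature match (", x$match_mode, " mode): ", x$n_matched, " of ",
      x$n_catalog, " catalog features matched\n", sep = "")
  if (length(x$unmatched_catalog_ids) > 0L)
    cat("  unmatched:", length(x$unmatched_catalog_ids), "features\n")
  if (length(x$ambiguous) > 0L)
    cat("  aggregated (multi-row):", length(x$ambiguous), "features\n")
  invisible(x)
}

#' Serialize a match report to JSON
#' @param report a `"match_report"`.
#' @param path file path.
#' @return Invisibly, `path`.
#' @export
write_match_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
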