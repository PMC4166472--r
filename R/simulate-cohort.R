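#' Configuration for a synthetic subtype-structured cohort
#'
#' Describes the generative model the classifier assumes: `n_classes`
#' molecular subtypes at the given frequencies, each carrying a
#' characteristic copy-number archetype over `n_loci` loci; every locus
#' hosts `genes_per_locus` genes whose expression responds to locus dosage
#' in cis (`dosage_effect` per copy-number state), on top of a
#' subtype-specific basal expression profile (per class x gene shifts of
#' sd `basal_shift_sd`) and Gaussian measurement noise (`noise_sd`).
#' Individual tumors deviate from their archetype at each locus with
#' probability `state_deviation_rate`.  Copy-number states live in
#' \{-1, 0, +1, +2\} (loss, neutral, gain, amplification) and are emitted
#' as segmented calls with log ratio `cn_log_ratio_unit` per state unit on
#' a synthetic 22-chromosome genome.
#'
#' The default frequencies put the rarest subtype at 4.5% of tumors; the
#' default catalog has 17 loci x 36 genes = 612 genes.  `profile_seed`
#' fixes the class basal profiles so that cohorts drawn with different
#' `seed` values come from one and the same reference model.
#'
#' @param n_samples cohort size.
#' @param n_classes number of subtypes (default 10).
#' @param class_frequencies simplex vector of subtype frequencies.
#' @param n_loci number of CNA loci.
#' @param genes_per_locus genes per locus.
#' @param cna_archetypes class x locus integer matrix of states in
#'   \{-1, 0, 1, 2\} with distinct rows.
#' @param dosage_effect expression shift per copy-number state unit.
#' @param basal_shift_sd sd of the per class x gene basal expression
#'   shifts.
#' @param noise_sd sd of per-cell Gaussian measurement noise.
#' @param state_deviation_rate per sample x locus probability of deviating
#'   from the archetype state.
#' @param cn_log_ratio_unit segment log ratio per state unit.
#' @param profile_seed seed fixing the reference model (basal profiles).
#' @param seed seed for sample-level randomness.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_samples = 1000L,
                          n_classes = 10L,
                          class_frequencies = c(0.08, 0.045, 0.15, 0.17,
                                                0.09, 0.065, 0.11, 0.10,
                                                0.07, 0.12),
                          n_loci = 17L,
                          genes_per_locus = 36L,
                          cna_archetypes = default_archetypes(n_classes,
                                                              n_loci),
                          dosage_effect = 1,
                          basal_shift_sd = 0.5,
                          noise_sd = 1,
                          state_deviation_rate = 0.01,
                          cn_log_ratio_unit = 0.5,
                          profile_seed = 101L,
                          seed = 0L) {
  if (length(class_frequencies) != n_classes)
    stop("class_frequencies must have length n_classes", call. = FALSE)
  if (abs(sum(class_frequencies) - 1) > 1e-8 || any(class_frequencies <= 0))
    stop("class_frequencies must be a strictly positive simplex vector",
         call. = FALSE)
  if (!all(dim(cna_archetypes) == c(n_classes, n_loci)))
    stop("cna_archetypes must be n_classes x n_loci", call. = FALSE)
  if (!all(cna_archetypes %in% c(-1L, 0L, 1L, 2L)))
    stop("archetype states must be in {-1, 0, 1, 2}", call. = FALSE)
  if (anyDuplicated(apply(cna_archetypes, 1L, paste, collapse = ",")))
    stop("archetype rows must be distinct", call. = FALSE)
  structure(list(
    n_samples = as.integer(n_samples),
    n_classes = as.integer(n_classes),
    class_frequencies = class_frequencies,
    n_loci = as.integer(n_loci),
    genes_per_locus = as.integer(genes_per_locus),
    cna_archetypes = cna_archetypes,
    dosage_effect = dosage_effect,
    basal_shift_sd = basal_shift_sd,
    noise_sd = noise_sd,
    state_deviation_rate = state_deviation_rate,
    cn_log_ratio_unit = cn_log_ratio_unit,
    profile_seed = as.integer(profile_seed),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Default copy-number archetypes
#'
#' A deterministic class x locus state matrix loosely echoing the biology
#' of the 10-group taxonomy: one subtype carries a focal 11q13/14-like
#' amplification, one a 17q23-like amplification, one an ERBB2-like
#' amplicon, one is entirely CNA-devoid, and the rest mix gains and
#' losses.  No claim of fidelity to real tumor profiles is made; the point
#' is distinct, dosage-coupled archetypes.
#'
#' @param n_classes,n_loci dimensions; defaults cover the canonical 10 x 17
#'   layout, larger values are filled with shifted copies.
#' @return An integer matrix of states in \{-1, 0, 1, 2\}.
#' @export
default_archetypes <- function(n_classes = 10L, n_loci = 17L) {
  a <- matrix(0L, n_classes, n_loci)
  base <- list(
    list(c(13, 2), c(5, 1)),            # 17q23-like amplification
    list(c(11, 2)),                     # 11q13/14-like amplification
    list(c(8, -1), c(14, 1)),
    list(),                             # CNA-devoid class
    list(c(16, 2)),                     # ERBB2-like amplicon
    list(c(6, 2), c(2, -1)),
    list(c(10, 1), c(15, -1)),
    list(c(1, 1), c(12, -1)),
    list(c(7, 2), c(3, -1)),            # 8q24-like gain
    list(c(4, -1), c(5, 1), c(17, -1))
  )
  for (k in seq_len(n_classes)) {
    spec <- base[[((k - 1L) %% 10L) + 1L]]
    shift <- ((k - 1L) %/% 10L)
    for (sl in spec) {
      locus <- ((sl[1L] - 1L + shift) %% n_loci) + 1L
      a[k, locus] <- as.integer(sl[2L])
    }
  }
  if (anyDuplicated(apply(a, 1L, paste, collapse = ",")))
    stop("cannot build distinct archetypes for this geometry; ",
         "supply cna_archetypes explicitly", call. = FALSE)
  a
}

# Deterministic synthetic genome layout: 22 pseudo-chromosomes of 30 Mb,
# locus l on chromosome l, locus span 4-7 Mb, genes tiled from 5 Mb.
cohort_layout <- function(config) {
  n_genes <- config$n_loci * config$genes_per_locus
  locus <- rep(seq_len(config$n_loci), each = config$genes_per_locus)
  within <- rep(seq_len(config$genes_per_locus), times = config$n_loci)
  gene_id <- sprintf("G%03d", seq_len(n_genes))
  list(
    n_chromosomes = 22L,
    chrom_length = 3e7,
    locus_start = 4e6,
    locus_end = 7e6,
    gene_id = gene_id,
    gene_locus = locus,
    gene_chrom = as.character(locus),
    gene_start = 5e6 + (within - 1L) * 2e4,
    gene_end = 5e6 + (within - 1L) * 2e4 + 9999
  )
}

#' Feature catalog of a synthetic cohort configuration
#'
#' One expression entry (feature id = gene id) and one copy-number entry
#' (feature id = gene id + `"_cn"`) per gene, on the deterministic
#' synthetic genome.
#'
#' @param config a [cohort_config()].
#' @return A [feature_catalog()].
#' @export
cohort_catalog <- function(config) {
  lay <- cohort_layout(config)
  feature_catalog(
    feature_id = c(lay$gene_id, paste0(lay$gene_id, "_cn")),
    gene_symbol = c(lay$gene_id, lay$gene_id),
    chromosome = c(lay$gene_chrom, lay$gene_chrom),
    start = c(lay$gene_start, lay$gene_start),
    end = c(lay$gene_end, lay$gene_end),
    data_type = rep(c("expression", "copy_number"),
                    each = length(lay$gene_id))
  )
}

#' Generate a synthetic reference cohort
#'
#' Draws `n_samples` tumors: subtype from `class_frequencies`; per-locus
#' copy-number states from the subtype archetype with rare random
#' deviations; expression of each gene as `dosage_effect * state(locus)` +
#' subtype basal shift + Gaussian noise; and segmented copy-number calls
#' consistent with the locus states on the synthetic genome.  Fully
#' reproducible: the same config (including `seed`) yields an identical
#' cohort, and cohorts differing only in `seed` share the same reference
#' model (archetypes and basal profiles).
#'
#' @param config a [cohort_config()].
#' @return An object of class `"synthetic_cohort"`: list with `expression`
#'   (genes x samples matrix), `segments` ([segment_set()]), `catalog`
#'   ([feature_catalog()]), `labels` (factor `IC1`..`ICk`), `states`
#'   (samples x loci integer matrix actually used), `config`.
#' @export
make_reference_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  lay <- cohort_layout(config)
  n <- config$n_samples
  K <- config$n_classes
  class_labels <- paste0("IC", seq_len(K))

  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }

  # reference model: per class x gene basal expression profile
  set.seed(config$profile_seed)
  basal <- matrix(stats::rnorm(K * length(lay$gene_id), 0,
                               config$basal_shift_sd),
                  K, length(lay$gene_id),
                  dimnames = list(class_labels, lay$gene_id))

  # sample-level randomness
  set.seed(config$seed)
  cls <- sample.int(K, n, replace = TRUE, prob = config$class_frequencies)
  states <- config$cna_archetypes[cls, , drop = FALSE]
  dev <- matrix(stats::runif(n * config$n_loci) <
                  config$state_deviation_rate, n, config$n_loci)
  if (any(dev)) {
    idx <- which(dev)
    pool <- c(-1L, 0L, 1L, 2L)
    states[idx] <- vapply(states[idx], function(s)
      sample(setdiff(pool, s), 1L), integer(1))
  }
  sample_ids <- sprintf("S%04d", seq_len(n))
  dimnames(states) <- list(sample_ids, NULL)

  expr <- config$dosage_effect * t(states[, lay$gene_locus, drop = FALSE]) +
    t(basal[cls, , drop = FALSE]) +
    matrix(stats::rnorm(length(lay$gene_id) * n, 0, config$noise_sd),
           length(lay$gene_id), n)
  dimnames(expr) <- list(lay$gene_id, sample_ids)
  attr(expr, "normalized") <- FALSE

  segments <- cohort_segments(states, lay, config$cn_log_ratio_unit)

  structure(list(
    expression = expr,
    segments = segments,
    catalog = cohort_catalog(config),
    labels = factor(class_labels[cls], levels = class_labels),
    states = states,
    config = config
  ), class = "synthetic_cohort")
}

# Emit per-sample segmented calls: on each locus chromosome three segments
# (flanks at log ratio 0, locus segment at unit * state); loci-free
# chromosomes get a single neutral segment.
cohort_segments <- function(states, lay, unit) {
  n <- nrow(states)
  sample_ids <- rownames(states)
  per_chrom <- function(chrom) {
    if (chrom <= ncol(states)) {
      data.frame(
        sample_id = rep(sample_ids, each = 3L),
        chromosome = as.character(chrom),
        start = rep(c(1, lay$locus_start, lay$locus_end + 1), times = n),
        end = rep(c(lay$locus_start - 1, lay$locus_end, lay$chrom_length),
                  times = n),
        log_ratio = as.numeric(rbind(0, unit * states[, chrom], 0)),
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(
        sample_id = sample_ids,
        chromosome = as.character(chrom),
        start = 1, end = lay$chrom_length, log_ratio = 0,
        stringsAsFactors = FALSE
      )
    }
  }
  seg <- do.call(rbind, lapply(seq_len(lay$n_chromosomes), per_chrom))
  segment_set(seg$sample_id, seg$chromosome, seg$start, seg$end,
              seg$log_ratio)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", ncol(x$expression), "samples,",
      nrow(x$expression), "genes,", x$config$n_classes, "subtypes\n")
  print(table(x$labels))
  invisible(x)
}

#' Apply platform-style perturbations to a cohort
#'
#' Emulates what an external study does to the measured expression: only a
#' random subset of catalog features is available
#' (`ceiling(keep_fraction * p)` retained), each retained feature is
#' rescaled by a log-normal factor and shifted (sd `feature_scale_sd` on
#' both), and extra Gaussian noise is added.  True labels, segments and
#' catalog are untouched.  Because downstream z-scoring is invariant to
#' per-feature positive affine maps, pure rescaling (no added noise) does
#' not change classifications.
#'
#' @param cohort a `"synthetic_cohort"`.
#' @param keep_fraction fraction of features retained, in (0, 1].
#' @param feature_scale_sd sd of the log scale factors and of the additive
#'   shifts.
#' @param extra_noise_sd sd of added cell-level Gaussian noise.
#' @param seed integer seed.
#' @return The perturbed `"synthetic_cohort"`.
#' @export
perturb_platform <- function(cohort, keep_fraction = 1,
                             feature_scale_sd = 0, extra_noise_sd = 0,
                             seed = 0L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop("keep_fraction must be in (0, 1]", call. = FALSE)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  x <- cohort$expression
  p <- nrow(x)
  keep <- sort(sample.int(p, ceiling(keep_fraction * p)))
  x <- x[keep, , drop = FALSE]
  scale <- exp(stats::rnorm(nrow(x), 0, feature_scale_sd))
  shift <- stats::rnorm(nrow(x), 0, feature_scale_sd)
  x <- x * scale + shift
  if (extra_noise_sd > 0)
    x <- x + matrix(stats::rnorm(length(x), 0, extra_noise_sd),
                    nrow(x), ncol(x))
  attr(x, "normalized") <- FALSE
  cohort$expression <- x
  cohort
}

#' Draw a panel of perturbed external-study cohorts
#'
#' Stand-in for a multi-study compendium: `n_studies` independent cohorts
#' are drawn from the same reference model (shared archetypes and basal
#' profiles), each with its own size and platform perturbation sampled
#' uniformly from the given ranges, then perturbed with
#' [perturb_platform()].  Reproducible from `seed`.
#'
#' @param config a [cohort_config()] defining the reference model.
#' @param n_studies number of studies.
#' @param size_range integer range of per-study sample counts.
#' @param keep_fraction_range range of feature-retention fractions.
#' @param feature_scale_sd_range range of rescaling sds.
#' @param extra_noise_sd_range range of added-noise sds.
#' @param seed integer seed.
#' @return A list of `"synthetic_cohort"` objects.
#' @export
make_study_panel <- function(config, n_studies,
                             size_range = c(100L, 500L),
                             keep_fraction_range = c(0.8, 1),
                             feature_scale_sd_range = c(0, 0.2),
                             extra_noise_sd_range = c(0, 0.3),
                             seed = 0L) {
  if (n_studies < 1L) stop("n_studies must be at least 1", call. = FALSE)
  chk <- function(r, what) {
    if (length(r) != 2L || r[1L] > r[2L])
      stop("invalid ", what, " range", call. = FALSE)
  }
  chk(size_range, "size"); chk(keep_fraction_range, "keep_fraction")
  chk(feature_scale_sd_range, "feature_scale_sd")
  chk(extra_noise_sd_range, "extra_noise_sd")
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  draws <- data.frame(
    n = sample(seq(size_range[1L], size_range[2L]), n_studies,
               replace = TRUE),
    keep = stats::runif(n_studies, keep_fraction_range[1L],
                        keep_fraction_range[2L]),
    scale_sd = stats::runif(n_studies, feature_scale_sd_range[1L],
                            feature_scale_sd_range[2L]),
    noise_sd = stats::runif(n_studies, extra_noise_sd_range[1L],
                            extra_noise_sd_range[2L])
  )
  seeds <- sample.int(.Machine$integer.max %/% 2L, 2L * n_studies)
  cohort_seeds <- seeds[seq_len(n_studies)]
  perturb_seeds <- seeds[n_studies + seq_len(n_studies)]
  lapply(seq_len(n_studies), function(s) {
    cfg <- config
    cfg$n_samples <- draws$n[s]
    cfg$seed <- cohort_seeds[s]
    perturb_platform(make_reference_cohort(cfg),
                     keep_fraction = draws$keep[s],
                     feature_scale_sd = draws$scale_sd[s],
                     extra_noise_sd = draws$noise_sd[s],
                     seed = perturb_seeds[s])
  })
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits expression TSV, segments TSV, catalog TSV, truth-label TSV and the
#' config as JSON into a directory.
#'
#' @param cohort a `"synthetic_cohort"`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(cohort$expression,
                          file.path(dir, "expression.tsv"))
  write_segments(cohort$segments, file.path(dir, "segments.tsv"))
  write_feature_catalog(cohort$catalog, file.path(dir, "catalog.tsv"))
  utils::write.table(
    data.frame(sample_id = colnames(cohort$expression),
               label = as.character(cohort$labels)),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  cfg <- cohort$config
  cfg$cna_archetypes <- apply(cfg$cna_archetypes, 1L, paste,
                              collapse = ",")
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
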