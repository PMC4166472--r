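# Independent, deliberately naive reference implementations used to check
# the package's vectorized code.  Everything here is written with explicit
# loops straight from the formulas and shares no code with R/.

# Full shrunken-centroid computation: centroids, pooled sd, offsets,
# soft-thresholded offsets and shrunken centroids.
oracle_nsc <- function(x, labels, delta = 0,
                       m_convention = c("minus", "plus"),
                       s0_floor = 1e-6) {
  m_convention <- match.arg(m_convention)
  labels <- factor(labels)
  cls <- levels(labels)
  K <- length(cls); p <- nrow(x); n <- ncol(x)
  n_k <- sapply(cls, function(l) sum(labels == l))
  centroids <- matrix(0, K, p, dimnames = list(cls, rownames(x)))
  overall <- numeric(p)
  s <- numeric(p)
  for (j in seq_len(p)) {
    overall[j] <- mean(x[j, ], na.rm = TRUE)
    ss <- 0; n_obs <- 0
    for (k in seq_len(K)) {
      xs <- x[j, labels == cls[k]]
      centroids[k, j] <- mean(xs, na.rm = TRUE)
      for (v in xs[!is.na(xs)]) {
        ss <- ss + (v - centroids[k, j])^2
        n_obs <- n_obs + 1
      }
    }
    s[j] <- if (n_obs - K > 0) sqrt(ss / (n_obs - K)) else 0
  }
  s0 <- median(s)
  if (s0 <= 0) s0 <- s0_floor
  m_k <- numeric(K)
  for (k in seq_len(K))
    m_k[k] <- if (m_convention == "minus") sqrt(1 / n_k[k] - 1 / n)
              else sqrt(1 / n_k[k] + 1 / n)
  d <- dsh <- shrunk <- matrix(0, K, p, dimnames = dimnames(centroids))
  for (k in seq_len(K)) for (j in seq_len(p)) {
    d[k, j] <- (centroids[k, j] - overall[j]) / (m_k[k] * (s[j] + s0))
    dsh[k, j] <- sign(d[k, j]) * max(abs(d[k, j]) - delta, 0)
    shrunk[k, j] <- overall[j] + m_k[k] * (s[j] + s0) * dsh[k, j]
  }
  list(class_labels = cls, centroids = centroids, overall = overall,
       s = s, s0 = s0, m_k = m_k, d = d, d_shrunk = dsh,
       shrunk_centroids = shrunk, prior = as.numeric(n_k) / n)
}

# Discriminant scores and posteriors for one oracle model.
oracle_predict <- function(or, xnew, prior = or$prior) {
  K <- length(or$class_labels)
  n <- ncol(xnew); p <- nrow(xnew)
  delta <- matrix(0, n, K, dimnames = list(colnames(xnew),
                                           or$class_labels))
  for (i in seq_len(n)) for (k in seq_len(K)) {
    acc <- 0
    for (j in seq_len(p)) {
      jj <- match(rownames(xnew)[j], colnames(or$centroids))
      acc <- acc + (xnew[j, i] - or$shrunk_centroids[k, jj])^2 /
        (or$s[jj] + or$s0)^2
    }
    delta[i, k] <- acc - 2 * log(prior[k])
  }
  post <- matrix(0, n, K, dimnames = dimnames(delta))
  cls <- character(n)
  for (i in seq_len(n)) {
    e <- exp(-(delta[i, ] - min(delta[i, ])) / 2)
    post[i, ] <- e / sum(e)
    cls[i] <- or$class_labels[which.min(delta[i, ])]
  }
  list(delta = delta, posterior = post, class = cls)
}

# Per-basepair brute force for segment-to-gene summarization.
oracle_gene_cn <- function(segments, gene_chrom, gene_start, gene_end,
                           sample_id) {
  vals <- c(); w <- c()
  for (r in seq_len(nrow(segments))) {
    if (segments$sample_id[r] != sample_id) next
    if (segments$chromosome[r] != gene_chrom) next
    for (bp in gene_start:gene_end) {
      if (bp >= segments$start[r] && bp <= segments$end[r]) {
        vals <- c(vals, segments$log_ratio[r])
        w <- c(w, 1)
      }
    }
  }
  if (length(vals) == 0) return(NA_real_)
  sum(vals * w) / sum(w)
}

# Longhand one-way ANOVA adjusted R-squared from sums of squares.
oracle_adj_r2 <- function(y, groups) {
  g <- factor(groups)
  n <- length(y); k <- nlevels(g)
  grand <- mean(y)
  ss_tot <- sum((y - grand)^2)
  ss_within <- 0
  for (lv in levels(g)) {
    ys <- y[g == lv]
    ss_within <- ss_within + sum((ys - mean(ys))^2)
  }
  r2 <- 1 - ss_within / ss_tot
  1 - (1 - r2) * (n - 1) / (n - k)
}

# Cohen's kappa from a contingency table, term by term.
oracle_kappa <- function(tab) {
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- 0
  for (c in seq_len(nrow(tab)))
    p_e <- p_e + (sum(tab[c, ]) / n) * (sum(tab[, c]) / n)
  (p_o - p_e) / (1 - p_e)
}

# Small labeled Gaussian fixture with class-separated means.
make_fixture <- function(p = 4, n_per_class = 6, K = 3, sep = 2,
                         seed = 1) {
  set.seed(seed)
  cls <- paste0("C", seq_len(K))
  labels <- factor(rep(cls, each = n_per_class), levels = cls)
  mu <- matrix(rnorm(K * p, sd = sep), K, p)
  x <- matrix(rnorm(p * length(labels)), p, length(labels)) +
    t(mu[as.integer(labels), , drop = FALSE])
  dimnames(x) <- list(paste0("f", seq_len(p)),
                      paste0("s", seq_along(labels)))
  list(x = x, labels = labels)
}

small_config <- function(n_samples = 150L, ...) {
  cohort_config(n_samples = n_samples, n_loci = 6L, genes_per_locus = 10L,
                cna_archetypes = default_archetypes(10L, 6L), ...)
}
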