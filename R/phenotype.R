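#' Principal component reduction to a cumulative variance threshold
#'
#' Centers the features, computes the full principal component decomposition
#' and keeps the smallest number of leading components whose cumulative
#' explained-variance ratio reaches `variance_threshold`. Loadings follow a
#' deterministic sign convention: the largest-magnitude element of each
#' loading vector is positive.
#'
#' @param features patients x features numeric matrix (typically z-scored
#'   and harmonized upstream; columns are centered here, not re-scaled).
#' @param variance_threshold fraction of variance to retain, in (0, 1]
#'   (default 0.85).
#' @return list with `scores` (n x m), `loadings` (p x m),
#'   `explained_variance_ratio` (length m), `full_variance_ratio` (entire
#'   spectrum), `m`, and `variance_threshold`.
#' @export
pca_reduce <- function(features, variance_threshold = 0.85) {
  x <- as_feature_matrix(features)
  if (!is.numeric(variance_threshold) || length(variance_threshold) != 1L ||
      variance_threshold <= 0 || variance_threshold > 1)
    stop_radphen("variance_threshold must be in (0, 1]")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  m <- which(cumsum(evr) >= variance_threshold - 1e-12)[1]
  ## sign convention: largest-|loading| entry positive
  flip <- vapply(seq_len(m), function(j) {
    v <- pc$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  loadings <- sweep(pc$rotation[, seq_len(m), drop = FALSE], 2, flip, "*")
  scores <- sweep(pc$x[, seq_len(m), drop = FALSE], 2, flip, "*")
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(m))
  list(scores = scores, loadings = loadings,
       explained_variance_ratio = evr[seq_len(m)],
       full_variance_ratio = evr, m = m,
       variance_threshold = variance_threshold)
}

#' Select the number of clusters by consensus clustering
#'
#' For each candidate `k`, patients are repeatedly subsampled without
#' replacement, clustered by complete-linkage hierarchical clustering on
#' Euclidean distances, and the dendrogram is cut at `k`. The consensus
#' matrix entry (i, j) is the fraction of co-sampled resamples in which i
#' and j landed in the same cluster. Stability is scored by the proportion
#' of ambiguous clustering (PAC): the fraction of defined off-diagonal
#' consensus entries strictly inside (0.1, 0.9). The `k` minimizing PAC
#' wins; ties go to the smaller `k`. Pairs never co-sampled give undefined
#' entries, excluded from PAC with a warning.
#'
#' The same subsample and tree serve all `k` (one linkage per resample, cut
#' at each candidate), which leaves the per-`k` consensus matrices coupled
#' but unbiased.
#'
#' @param scores n x m numeric matrix of PC scores.
#' @param k_range integer candidates, within `[2, n - 1]`.
#' @param n_resamples number of subsampling repetitions (default 1000).
#' @param subsample_fraction fraction of patients per resample, in (0.5, 1).
#' @param seed integer seed.
#' @return list with `k`, `pac_scores` (named per k), and `consensus`
#'   (named list of n x n matrices, unit diagonal, `NA` where undefined).
#' @export
consensus_select_k <- function(scores, k_range = 2:6, n_resamples = 1000L,
                               subsample_fraction = 0.8, seed = 1L) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2L) || any(k_range > n - 1L))
    stop_radphen("k_range must lie within [2, n - 1]")
  if (subsample_fraction <= 0.5 || subsample_fraction >= 1)
    stop_radphen("subsample_fraction must be in (0.5, 1)")
  if (n_resamples < 1L) stop_radphen("n_resamples must be >= 1")
  set.seed(seed)
  m_sub <- max(2L, floor(subsample_fraction * n))
  d_full <- as.matrix(stats::dist(scores))
  co_sampled <- matrix(0L, n, n)
  co_clustered <- lapply(k_range, function(k) matrix(0L, n, n))
  names(co_clustered) <- as.character(k_range)
  for (r in seq_len(n_resamples)) {
    idx <- sort(sample.int(n, m_sub))
    co_sampled[idx, idx] <- co_sampled[idx, idx] + 1L
    hc <- stats::hclust(stats::as.dist(d_full[idx, idx]), method = "complete")
    for (k in k_range) {
      if (k > m_sub) next
      cl <- stats::cutree(hc, k = k)
      same <- outer(cl, cl, "==")
      kk <- as.character(k)
      co_clustered[[kk]][idx, idx] <- co_clustered[[kk]][idx, idx] + same
    }
  }
  consensus <- list()
  pac <- stats::setNames(rep(NA_real_, length(k_range)), as.character(k_range))
  undefined_any <- FALSE
  for (k in k_range) {
    kk <- as.character(k)
    cons <- co_clustered[[kk]] / co_sampled
    cons[co_sampled == 0L] <- NA_real_
    diag(cons) <- 1
    dimnames(cons) <- list(rownames(scores), rownames(scores))
    consensus[[kk]] <- cons
    up <- cons[upper.tri(cons)]
    if (anyNA(up)) { undefined_any <- TRUE; up <- up[!is.na(up)] }
    pac[kk] <- mean(up > 0.1 & up < 0.9)
  }
  if (undefined_any)
    warning("some patient pairs were never co-sampled; their consensus entries are undefined and excluded from PAC")
  k_best <- k_range[which.min(pac)]   # ties resolve to the smaller k
  list(k = k_best, pac_scores = pac, consensus = consensus,
       n_resamples = n_resamples, subsample_fraction = subsample_fraction)
}

#' Cut a complete-linkage dendrogram into k clusters
#'
#' Agglomerative hierarchical clustering with complete (maximum-distance)
#' linkage on Euclidean distances over the PC scores, cut to exactly `k`
#' clusters. Merge ties are resolved deterministically by the ordering of
#' the distance matrix (lowest pair index first).
#'
#' @param scores n x m numeric matrix.
#' @param k number of clusters, `2 <= k <= n`.
#' @return integer cluster labels in `1..k`, named by patient.
#' @export
cluster_phenotype <- function(scores, k) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (k > n) stop_radphen("k must not exceed the number of patients")
  if (k < 1L) stop_radphen("k must be >= 1")
  hc <- stats::hclust(stats::dist(scores), method = "complete")
  stats::cutree(hc, k = k)
}

#' Orient a binary clustering as low/high risk of death
#'
#' The cluster with the higher observed event fraction becomes `"high"`;
#' ties break toward the cluster with the shorter median observed time.
#'
#' @param labels binary cluster labels (two distinct values).
#' @param survival data.frame with `time` and `event`, same order as labels.
#' @return factor with levels `low`, `high`; attribute `mapping` records
#'   which input cluster became which risk group.
#' @export
orient_risk <- function(labels, survival) {
  u <- sort(unique(labels))
  if (length(u) != 2L) stop_radphen("risk orientation requires exactly 2 clusters")
  ef <- vapply(u, function(cl) mean(survival$event[labels == cl]), numeric(1))
  if (ef[1] != ef[2]) {
    high <- u[which.max(ef)]
  } else {
    med <- vapply(u, function(cl) stats::median(survival$time[labels == cl]),
                  numeric(1))
    high <- u[which.min(med)]
  }
  out <- factor(ifelse(labels == high, "high", "low"), levels = c("low", "high"))
  names(out) <- names(labels)
  attr(out, "mapping") <- stats::setNames(ifelse(u == high, "high", "low"),
                                          as.character(u))
  out
}

#' Derive the binary radiomic phenotype
#'
#' Full phenotyping stage: PCA truncation at the cumulative-variance
#' threshold, consensus-clustering selection of the cluster number (skipped
#' when `k` is given), complete-linkage hierarchical clustering, and (for
#' `k = 2`) orientation of the clusters as low/high risk. Orientation is
#' outcome-aware by default (event fractions); `outcome_blind = TRUE`
#' instead labels the cluster with the higher mean first-PC score `"high"`,
#' which never looks at survival.
#'
#' @param features harmonized (or merely z-scored, for the non-harmonized
#'   comparator) patients x features matrix.
#' @param survival data.frame with `time`, `event` (required unless
#'   `outcome_blind = TRUE` or `k != 2`).
#' @param variance_threshold PCA cumulative-variance cutoff (default 0.85).
#' @param k fixed cluster number; `NULL` (default) selects it by consensus.
#' @param k_range,n_resamples,subsample_fraction consensus parameters.
#' @param seed seed for the consensus resampling.
#' @param outcome_blind orient risk by first-PC mean instead of outcomes.
#' @return object of class `radphen_phenotype`: the [pca_reduce()] fields
#'   plus `k`, `pac_scores`, `consensus`, `labels`, `risk_labels`.
#' @export
derive_phenotype <- function(features, survival = NULL,
                             variance_threshold = 0.85, k = NULL,
                             k_range = 2:6, n_resamples = 1000L,
                             subsample_fraction = 0.8, seed = 1L,
                             outcome_blind = FALSE) {
  pca <- pca_reduce(features, variance_threshold)
  cons <- NULL
  if (is.null(k)) {
    cons <- consensus_select_k(pca$scores, k_range = k_range,
                               n_resamples = n_resamples,
                               subsample_fraction = subsample_fraction,
                               seed = seed)
    k <- cons$k
  }
  labels <- cluster_phenotype(pca$scores, k)
  risk <- NULL
  if (k == 2L) {
    if (outcome_blind) {
      u <- sort(unique(labels))
      pc1 <- vapply(u, function(cl) mean(pca$scores[labels == cl, 1L]), numeric(1))
      high <- u[which.max(pc1)]
      risk <- factor(ifelse(labels == high, "high", "low"),
                     levels = c("low", "high"))
      names(risk) <- names(labels)
    } else {
      if (is.null(survival))
        stop_radphen("survival outcomes are required for outcome-aware risk orientation")
      risk <- orient_risk(labels, survival)
    }
  }
  structure(c(pca,
              list(k = k,
                   pac_scores = cons$pac_scores,
                   consensus = cons$consensus,
                   labels = labels,
                   risk_labels = risk,
                   outcome_blind = outcome_blind)),
            class = "radphen_phenotype")
}

#' @export
print.radphen_phenotype <- function(x, ...) {
  cat(sprintf("radiomic phenotype: %d PCs (%.1f%% variance), k = %d\n",
              x$m, 100 * sum(x$explained_variance_ratio), x$k))
  if (!is.null(x$risk_labels)) print(table(risk = x$risk_labels))
  invisible(x)
}

#' Test phenotype-covariate associations
#'
#' Kruskal-Wallis tests across the phenotype groups for the continuous
#' covariates (age, BMI, pack-years) and uncorrected Pearson chi-squared
#' contingency tests for the categorical ones (sex, race, ECOG) and for the
#' event of death. Degenerate covariates (a single observed value, or a
#' contingency table with an all-zero row or column) are reported as
#' non-significant with `NA` statistics and a warning.
#'
#' @param risk_labels per-patient phenotype group (factor or vector).
#' @param clinical clinical table with `age`, `bmi`, `pack_years`, `sex`,
#'   `race`, `ecog`.
#' @param survival data.frame with `event` (used for the death association).
#' @param alpha significance level for the flags (default 0.05).
#' @return data.frame with columns `covariate`, `test`, `statistic`,
#'   `p_value`, `significant`.
#' @export
associate_covariates <- function(risk_labels, clinical, survival,
                                 alpha = 0.05) {
  grp <- factor(risk_labels)
  if (nlevels(grp) < 2L) stop_radphen("both phenotype groups must be non-empty")
  rows <- list()
  kw <- function(name, x) {
    if (length(unique(x[!is.na(x)])) < 2L) {
      warning(sprintf("covariate '%s' is degenerate; reported as non-significant", name))
      return(data.frame(covariate = name, test = "kruskal-wallis",
                        statistic = NA_real_, p_value = NA_real_,
                        significant = FALSE))
    }
    t <- stats::kruskal.test(x, grp)
    data.frame(covariate = name, test = "kruskal-wallis",
               statistic = unname(t$statistic), p_value = t$p.value,
               significant = t$p.value < alpha)
  }
  cs <- function(name, x) {
    tab <- table(grp, x)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) || ncol(tab) < 2L) {
      warning(sprintf("contingency table for '%s' is degenerate; test skipped", name))
      return(data.frame(covariate = name, test = "chi-squared",
                        statistic = NA_real_, p_value = NA_real_,
                        significant = FALSE))
    }
    t <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    data.frame(covariate = name, test = "chi-squared",
               statistic = unname(t$statistic), p_value = t$p.value,
               significant = t$p.value < alpha)
  }
  rows$age  <- kw("age", clinical$age)
  rows$bmi  <- kw("bmi", clinical$bmi)
  rows$pack <- kw("pack_years", clinical$pack_years)
  rows$sex  <- cs("sex", clinical$sex)
  rows$race <- cs("race", clinical$race)
  rows$ecog <- cs("ecog", clinical$ecog)
  rows$death <- cs("event_of_death", factor(survival$event, levels = c(0, 1)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
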