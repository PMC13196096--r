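# Integration-quality and downstream ranking metrics.

#' Centroid-based silhouette scores
#'
#' Variant of the silhouette coefficient where the inter-class term is the
#' mean Euclidean distance to the nearest other-class centroids: for sample
#' i, `a(i)` is the mean distance to the other samples of its own class
#' (0 for singleton classes) and `b(i)` the mean distance to the
#' `min(n_nearest_centroids, #other classes)` nearest centroids of other
#' classes; the score is `(b - a) / max(a, b)`.
#'
#' @param embedding Samples x dimensions numeric matrix (any space: raw
#'   expression, latent, or a low-dimensional embedding).
#' @param labels Per-sample labels (>= 2 distinct).
#' @param n_nearest_centroids Number of other-class centroids entering
#'   `b(i)` (default 10).
#' @return Numeric vector of per-sample scores in \[-1, 1\].
#' @export
centroidSilhouette <- function(embedding, labels, n_nearest_centroids = 10) {
  embedding <- as.matrix(embedding)
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) < 2) stop("need at least 2 distinct labels")
  n <- nrow(embedding)
  centroids <- t(vapply(classes, function(cc)
    colMeans(embedding[labels == cc, , drop = FALSE]),
    numeric(ncol(embedding))))
  # distances to centroids, computed by explicit differences for accuracy
  d2c <- vapply(seq_len(nrow(centroids)), function(j)
    sqrt(rowSums(sweep(embedding, 2, centroids[j, ], "-")^2)), numeric(n))
  a <- numeric(n); b <- numeric(n)
  for (cc in classes) {
    idx <- which(labels == cc)
    sub <- embedding[idx, , drop = FALSE]
    dd <- as.matrix(stats::dist(sub))
    a[idx] <- if (length(idx) > 1) rowSums(dd) / (length(idx) - 1) else 0
    other <- which(classes != cc)
    k <- min(n_nearest_centroids, length(other))
    b[idx] <- apply(d2c[idx, other, drop = FALSE], 1, function(v)
      mean(sort(v)[seq_len(k)]))
  }
  s <- (b - a) / pmax(pmax(a, b), .Machine$double.eps)
  s[a == 0 & b == 0] <- 0
  s
}

#' Neighborhood batch-mixing rejection rate
#'
#' For every sample, the batch composition of its k nearest neighbors
#' (Euclidean, excluding the sample itself) is tested against the global
#' batch proportions with a chi-square goodness-of-fit test; the rejection
#' rate is the fraction of samples with p below `alpha`. Lower rates
#' indicate better mixing of batches.
#'
#' @param embedding Samples x dimensions matrix.
#' @param batch_labels Per-sample batch labels (>= 2 batches, all
#'   non-empty).
#' @param k Neighborhood size (default `max(10, ceiling(0.005 * N))`; must
#'   be < N).
#' @param alpha Significance level (default 0.05).
#' @return The rejection rate, with attributes `p_values` and `k`.
#' @export
batchMixingRejectionRate <- function(embedding, batch_labels, k = NULL,
                                     alpha = 0.05) {
  embedding <- as.matrix(embedding)
  batch <- factor(batch_labels)
  if (nlevels(batch) < 2) stop("need at least 2 batches")
  if (any(table(batch) == 0)) stop("every batch must contain samples")
  n <- nrow(embedding)
  if (is.null(k)) k <- max(10, ceiling(0.005 * n))
  if (k >= n) stop("k must be smaller than the number of samples")
  props <- as.numeric(table(batch)) / n
  B <- nlevels(batch)
  sq <- rowSums(embedding^2)
  bi <- as.integer(batch)
  pvals <- numeric(n)
  # row-blocked distance computation to bound memory
  block <- max(1L, floor(2e7 / n))
  for (s in seq(1, n, by = block)) {
    rows <- s:min(s + block - 1L, n)
    dd <- outer(sq[rows], sq, "+") - 2 * embedding[rows, , drop = FALSE] %*%
      t(embedding)
    for (r in seq_along(rows)) {
      i <- rows[r]
      ord <- order(dd[r, ])
      nb <- setdiff(ord, i)[seq_len(k)]
      obs <- tabulate(bi[nb], nbins = B)
      expct <- k * props
      stat <- sum((obs - expct)^2 / expct)
      pvals[i] <- pchisq(stat, df = B - 1, lower.tail = FALSE)
    }
  }
  rate <- mean(pvals < alpha)
  attr(rate, "p_values") <- pvals
  attr(rate, "k") <- k
  rate
}

topNByAbs <- function(v, top_n) {
  names(v)[order(-abs(v), seq_along(v))[seq_len(min(top_n, length(v)))]]
}

#' Overlap of top differential genes before and after correction
#'
#' Counts the genes shared between the top `top_n` genes by absolute logFC
#' in the corrected and reference vectors. Ties break by gene-index order,
#' so the result is deterministic.
#'
#' @param corrected_logfc,reference_logfc Named numeric vectors on the same
#'   gene index, or matrices with matching rownames (one row per class
#'   pair), in which case a per-row count vector is returned.
#' @param top_n Number of top genes per side (default 100).
#' @return Integer overlap count (or vector of counts).
#' @export
topDEOverlap <- function(corrected_logfc, reference_logfc, top_n = 100) {
  if (is.matrix(corrected_logfc)) {
    stopifnot(identical(rownames(corrected_logfc), rownames(reference_logfc)))
    return(vapply(rownames(corrected_logfc), function(r)
      topDEOverlap(corrected_logfc[r, ], reference_logfc[r, ], top_n), 0L))
  }
  stopifnot(identical(names(corrected_logfc), names(reference_logfc)))
  if (length(corrected_logfc) < top_n)
    warning("fewer genes than top_n; using all")
  length(intersect(topNByAbs(corrected_logfc, top_n),
                   topNByAbs(reference_logfc, top_n)))
}

#' Spearman consistency of expression ratios
#'
#' Spearman rank correlation (average ranks for ties) between predicted and
#' reference logFC vectors; zero-variance vectors yield `NA`.
#'
#' @param predicted_logfc,reference_logfc Numeric vectors (>= 3 genes), or
#'   matrices with one row per class pair.
#' @return Correlation, or per-row vector of correlations.
#' @export
ratioSpearman <- function(predicted_logfc, reference_logfc) {
  if (is.matrix(predicted_logfc)) {
    stopifnot(identical(rownames(predicted_logfc), rownames(reference_logfc)))
    return(vapply(rownames(predicted_logfc), function(r)
      ratioSpearman(predicted_logfc[r, ], reference_logfc[r, ]), 0))
  }
  stopifnot(length(predicted_logfc) >= 3,
            length(predicted_logfc) == length(reference_logfc))
  if (sd(predicted_logfc) == 0 || sd(reference_logfc) == 0) return(NA_real_)
  cor(predicted_logfc, reference_logfc, method = "spearman")
}

rankDesc <- function(v) {
  r <- integer(length(v))
  r[order(-v, seq_along(v))] <- seq_along(v)
  names(r) <- names(v)
  r
}

#' Universal high-frequency gene ranking
#'
#' Within each class, genes are ranked by logFC versus the baseline
#' (descending, rank 1 = most upregulated) and the top `top_n` taken; the
#' recurrence of a gene is the number of classes whose top list contains it.
#' Genes are reported sorted by recurrence (descending), then mean rank
#' across the classes where they appear, then gene-index order.
#'
#' @param per_class_logfc Classes x genes logFC matrix versus the baseline.
#' @param top_n Per-class list length (default 100).
#' @param report_top Number of genes returned (default 20).
#' @return data.frame with columns `gene`, `recurrence`, `mean_rank`.
#' @export
universalGeneRanking <- function(per_class_logfc, top_n = 100,
                                 report_top = 20) {
  stopifnot(nrow(per_class_logfc) >= 2)
  genes <- colnames(per_class_logfc)
  ranks <- t(apply(per_class_logfc, 1, rankDesc))
  in_top <- ranks <= min(top_n, ncol(per_class_logfc))
  recurrence <- colSums(in_top)
  hit <- which(recurrence > 0)
  mean_rank <- vapply(hit, function(g) mean(ranks[in_top[, g], g]), 0)
  ord <- order(-recurrence[hit], mean_rank, hit)
  sel <- ord[seq_len(min(report_top, length(ord)))]
  data.frame(gene = genes[hit][sel],
             recurrence = as.integer(recurrence[hit][sel]),
             mean_rank = mean_rank[sel], row.names = NULL)
}

#' Class-specificity gene scores
#'
#' Genes are ranked per class by descending logFC; the specificity score of
#' a gene for the target class is the difference between its best (lowest)
#' rank among all other classes and its rank in the target class. High
#' scores mark genes far more upregulated in the target class than anywhere
#' else.
#'
#' @param per_class_logfc Classes x genes logFC matrix versus the baseline.
#' @param target_class Row name of the target class.
#' @param report_top Number of genes returned (default 20).
#' @return data.frame with columns `gene`, `score`, `rank_target`,
#'   `best_rank_other`, sorted by score (descending, ties by gene order).
#' @export
classSpecificityScores <- function(per_class_logfc, target_class,
                                   report_top = 20) {
  stopifnot(nrow(per_class_logfc) >= 2, target_class %in%
              rownames(per_class_logfc))
  ranks <- t(apply(per_class_logfc, 1, rankDesc))
  rt <- ranks[target_class, ]
  ro <- apply(ranks[rownames(ranks) != target_class, , drop = FALSE], 2, min)
  score <- ro - rt
  ord <- order(-score, seq_along(score))
  sel <- ord[seq_len(min(report_top, length(ord)))]
  data.frame(gene = colnames(per_class_logfc)[sel], score = score[sel],
             rank_target = rt[sel], best_rank_other = ro[sel],
             row.names = NULL)
}

#' Integration evaluation report
#'
#' Bundles the comparison of a corrected matrix against its uncorrected
#' input: centroid silhouettes by class and by dataset, the batch-mixing
#' rejection rate, and (when logFC matrices are supplied) top-gene overlap
#' and Spearman ratio consistency per class.
#'
#' @param corrected,raw Genes x samples matrices on the same samples.
#' @param class_labels,batch_labels Per-sample annotations.
#' @param corrected_logfc,reference_logfc Optional classes x genes logFC
#'   matrices for the signal-retention metrics.
#' @param top_n Top-gene list length for the overlap metric (default 100).
#' @param k,alpha Passed to [batchMixingRejectionRate()].
#' @return A list of class `"EvaluationReport"`.
#' @export
evaluateIntegration <- function(corrected, raw, class_labels, batch_labels,
                                corrected_logfc = NULL,
                                reference_logfc = NULL, top_n = 100,
                                k = NULL, alpha = 0.05) {
  emb_c <- t(corrected); emb_r <- t(raw)
  rep <- list(
    silhouette_class = list(
      corrected = centroidSilhouette(emb_c, class_labels),
      raw = centroidSilhouette(emb_r, class_labels)),
    silhouette_batch = list(
      corrected = centroidSilhouette(emb_c, batch_labels),
      raw = centroidSilhouette(emb_r, batch_labels)),
    rejection_rate = list(
      corrected = as.numeric(batchMixingRejectionRate(emb_c, batch_labels,
                                                      k, alpha)),
      raw = as.numeric(batchMixingRejectionRate(emb_r, batch_labels, k,
                                                alpha))))
  if (!is.null(corrected_logfc) && !is.null(reference_logfc)) {
    rep$de_overlap <- topDEOverlap(corrected_logfc, reference_logfc, top_n)
    rep$ratio_spearman <- ratioSpearman(corrected_logfc, reference_logfc)
  }
  structure(rep, class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat("EvaluationReport\n")
  cat(sprintf("  class silhouette (mean): corrected %.3f | raw %.3f\n",
              mean(x$silhouette_class$corrected),
              mean(x$silhouette_class$raw)))
  cat(sprintf("  batch silhouette (mean): corrected %.3f | raw %.3f\n",
              mean(x$silhouette_batch$corrected),
              mean(x$silhouette_batch$raw)))
  cat(sprintf("  batch-mixing rejection:  corrected %.3f | raw %.3f\n",
              x$rejection_rate$corrected, x$rejection_rate$raw))
  if (!is.null(x$de_overlap))
    cat(sprintf("  mean top-gene overlap: %.1f | mean Spearman rho: %.3f\n",
                mean(x$de_overlap), mean(x$ratio_spearman, na.rm = TRUE)))
  invisible(x)
}
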