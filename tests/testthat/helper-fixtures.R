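# Shared builders for small in-code fixtures.

# genes x samples matrix with named dims
namedMat <- function(values, genes, samples) {
  matrix(values, length(genes), length(samples),
         dimnames = list(genes, samples))
}

randDataset <- function(id, genes, classes_per_sample, platform = "p1",
                        mean = 5, sd = 1) {
  n <- length(classes_per_sample)
  m <- namedMat(rnorm(length(genes) * n, mean, sd), genes,
                paste0(id, "_s", seq_len(n)))
  rawDataset(id, m, classes_per_sample, platform)
}

# compendium built directly (already harmonized / normalized), bypassing the
# preprocessing pipeline: one matrix + annotations
directComp <- function(m, dataset_id, class_label,
                       platform_category = NULL) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%04d", seq_len(nrow(m)))
  info <- data.frame(sample_id = colnames(m), dataset_id = dataset_id,
                     platform_label = paste0("plat", dataset_id),
                     platform_category = if (is.null(platform_category))
                       as.integer(factor(dataset_id)) else platform_category,
                     class_label = class_label, stringsAsFactors = FALSE)
  presence <- matrix(TRUE, nrow(m), length(unique(dataset_id)),
                     dimnames = list(rownames(m), unique(dataset_id)))
  caae:::newCompendium(m, info, presence)
}

# class templates with exact additive structure on a gene grid
additiveTemplates <- function(C, M, seed = 1) {
  set.seed(seed)
  base <- runif(M, 2, 10)
  tpl <- matrix(rep(base, each = C), C, M)
  for (i in seq_len(C)[-1]) tpl[i, ] <- tpl[i, ] + rnorm(M, 0, 1)
  rownames(tpl) <- c("healthy", paste0("disease", seq_len(C - 1)))
  colnames(tpl) <- sprintf("G%03d", seq_len(M))
  tpl
}

# brute-force double-loop centroid silhouette used as the independent oracle
bruteSilhouette <- function(emb, labels, n_nearest = 10) {
  n <- nrow(emb)
  classes <- unique(labels)
  cents <- lapply(classes, function(cc)
    colMeans(emb[labels == cc, , drop = FALSE]))
  names(cents) <- classes
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    a <- if (length(own)) mean(vapply(own, function(j)
      sqrt(sum((emb[i, ] - emb[j, ])^2)), 0)) else 0
    others <- setdiff(classes, labels[i])
    dc <- sort(vapply(others, function(cc)
      sqrt(sum((emb[i, ] - cents[[cc]])^2)), 0))
    b <- mean(dc[seq_len(min(n_nearest, length(dc)))])
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  s
}
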