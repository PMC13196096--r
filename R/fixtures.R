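# Deterministic toy fixture with planted preprocessing events, plus the
# plain-text readers/writers used by the fixture and the command-line
# wrapper.

#' Write a compendium of raw datasets to delimited text files
#'
#' One TSV per dataset (genes in rows, header = sample ids, first column
#' `gene`) plus a phenotype TSV (`sample_id`, `dataset_id`,
#' `platform_label`, `class_label`). Values are written with a fixed number
#' of decimals so files are byte-stable across runs.
#'
#' @param datasets List of [RawDataset-class].
#' @param dir Output directory (created if needed).
#' @param digits Decimals used for the expression values (default 3).
#' @return Invisibly, the paths written.
#' @export
writeRawDatasets <- function(datasets, dir, digits = 3) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  pheno <- NULL
  for (d in datasets) {
    m <- d@exprs
    df <- data.frame(gene = rownames(m),
                     apply(m, 2, function(col)
                       ifelse(is.na(col), "NA",
                              sprintf(paste0("%.", digits, "f"), col))),
                     check.names = FALSE, stringsAsFactors = FALSE)
    f <- file.path(dir, paste0(d@dataset_id, ".tsv"))
    write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, f)
    pheno <- rbind(pheno, data.frame(sample_id = colnames(m),
                                     dataset_id = d@dataset_id,
                                     platform_label = d@platform_label,
                                     class_label = d@classes,
                                     stringsAsFactors = FALSE))
  }
  pf <- file.path(dir, "pheno.tsv")
  write.table(pheno, pf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, pf))
}

#' Read raw datasets written by [writeRawDatasets()]
#'
#' @param dir Directory containing per-dataset TSVs and `pheno.tsv`.
#' @return List of [RawDataset-class].
#' @export
readRawDatasets <- function(dir) {
  pheno <- read.delim(file.path(dir, "pheno.tsv"), stringsAsFactors = FALSE)
  out <- list()
  for (d in unique(pheno$dataset_id)) {
    df <- read.delim(file.path(dir, paste0(d, ".tsv")), check.names = FALSE,
                     stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$gene
    ph <- pheno[pheno$dataset_id == d, ]
    m <- m[, ph$sample_id, drop = FALSE]
    out[[d]] <- rawDataset(d, m, ph$class_label, ph$platform_label[1])
  }
  out
}

#' Build the deterministic mirror fixture
#'
#' A small five-dataset, four-class, 50-gene compendium with planted
#' preprocessing events used for regression tests:
#' * genes `G031`-`G034` are absent from two of five datasets (missing
#'   fraction 0.4 > 0.2) and must be removed by the missingness filter;
#' * genes `G035`-`G050` are absent from `F5` only (0.2, boundary) and must
#'   be retained;
#' * after the gene filter, dataset `F5` covers 30/46 genes (< 0.8) and
#'   must be excluded;
#' * dataset `F1` contains one triplet and one pair of identical samples
#'   (three duplicate columns collapse);
#' * dataset `F2` is scaled so its maximum exceeds 100 (log2 trigger);
#' * dataset `F3` carries one extreme spike above 10x its mean (clip
#'   trigger).
#'
#' @param dir Optional directory; when given, the fixture is written there
#'   via [writeRawDatasets()] (byte-stable).
#' @return List with `datasets`, and `expected` planted counts
#'   (`removed_genes`, `removed_datasets`, `duplicates_removed`,
#'   `clip_datasets`, `log2_datasets`, `n_final_genes`).
#' @export
makeMirrorFixture <- function(dir = NULL) {
  genes <- sprintf("G%03d", 1:50)
  classes <- c("healthy", "disease1", "disease2", "disease3")
  set.seed(42)
  base <- round(runif(50, 2, 10), 3)
  mkmat <- function(g, n, scale = 1, shift = 0) {
    m <- matrix(base[match(g, genes)] + rnorm(length(g) * n, 0, 0.8),
                length(g), n)
    m <- round(pmax(m, 0.2) * scale + shift, 3)
    rownames(m) <- g
    m
  }
  # F1: all genes, 10 samples; columns 1-3 identical, 4-5 identical
  m1 <- mkmat(genes, 10)
  m1[, 2] <- m1[, 1]; m1[, 3] <- m1[, 1]; m1[, 5] <- m1[, 4]
  colnames(m1) <- sprintf("F1_S%02d", 1:10)
  d1 <- rawDataset("F1", m1, rep(classes, length.out = 10), "chipA")
  # F2: all genes, scaled x30 so max > 100 -> log2 trigger
  m2 <- mkmat(genes, 8, scale = 30)
  colnames(m2) <- sprintf("F2_S%02d", 1:8)
  d2 <- rawDataset("F2", m2, rep(classes, length.out = 8), "chipB")
  # F3: all genes, one spike far above 10x the mean -> clip trigger
  m3 <- mkmat(genes, 8)
  m3[5, 3] <- 500
  colnames(m3) <- sprintf("F3_S%02d", 1:8)
  d3 <- rawDataset("F3", m3, rep(classes, length.out = 8), "chipA")
  # F4: missing G031-G034
  g4 <- genes[-(31:34)]
  m4 <- mkmat(g4, 8)
  colnames(m4) <- sprintf("F4_S%02d", 1:8)
  d4 <- rawDataset("F4", m4, rep(classes, length.out = 8), "chipC")
  # F5: missing G031-G050 -> shares the removal of G031-G034 and causes
  # its own coverage 30/46 < 0.8 after the gene filter
  g5 <- genes[1:30]
  m5 <- mkmat(g5, 6)
  colnames(m5) <- sprintf("F5_S%02d", 1:6)
  d5 <- rawDataset("F5", m5, rep(classes, length.out = 6), "chipB")

  datasets <- list(d1, d2, d3, d4, d5)
  if (!is.null(dir)) writeRawDatasets(datasets, dir)
  list(datasets = datasets,
       expected = list(removed_genes = 4L, removed_datasets = 1L,
                       duplicates_removed = 3L, clip_datasets = "F3",
                       log2_datasets = "F2", n_final_genes = 46L))
}
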