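# Preprocessing: harmonize raw per-dataset matrices onto a unified gene
# index, apply the fixed filter/transform pipeline, and deliver a compendium
# on the [0, 1] scale with no missing values.
#
# Fixed pipeline order (see preprocessCompendium):
#   harmonize -> gene missingness filter -> dataset coverage filter ->
#   per-dataset clipping -> per-dataset log2 -> duplicate-sample removal ->
#   within-gene mean imputation -> per-dataset min-max scaling.

#' Harmonize datasets onto a unified gene index
#'
#' The unified index is the union of all gene identifiers, in order of first
#' appearance. Genes a dataset did not measure are marked missing (`NA`) in
#' its columns; the original measurement pattern is kept in the
#' `gene_presence` metadata so the missingness and coverage filters operate
#' on dataset-level gene coverage rather than sporadic missing entries.
#'
#' @param raw List of [RawDataset-class] objects.
#' @return An [ExpressionCompendium-class].
#' @export
harmonizeGeneSpace <- function(raw) {
  if (length(raw) == 0) stop("no datasets supplied")
  for (d in raw) {
    if (nrow(d@exprs) == 0) stop("dataset '", d@dataset_id, "' has no genes")
    if (anyDuplicated(rownames(d@exprs)))
      stop("duplicate gene identifiers in dataset '", d@dataset_id, "'")
  }
  ids <- vapply(raw, function(d) d@dataset_id, "")
  if (anyDuplicated(ids)) stop("duplicate dataset ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  genes <- unique(unlist(lapply(raw, function(d) rownames(d@exprs))))
  presence <- matrix(FALSE, length(genes), length(raw),
                     dimnames = list(genes, ids))
  mats <- vector("list", length(raw))
  infos <- vector("list", length(raw))
  for (i in seq_along(raw)) {
    d <- raw[[i]]
    m <- matrix(NA_real_, length(genes), ncol(d@exprs),
                dimnames = list(genes, colnames(d@exprs)))
    m[rownames(d@exprs), ] <- d@exprs
    presence[rownames(d@exprs), i] <- TRUE
    mats[[i]] <- m
    infos[[i]] <- data.frame(sample_id = colnames(d@exprs),
                             dataset_id = d@dataset_id,
                             platform_label = d@platform_label,
                             platform_category = NA_integer_,
                             class_label = d@classes,
                             stringsAsFactors = FALSE)
  }
  exprs <- do.call(cbind, mats)
  info <- do.call(rbind, infos)
  if (anyDuplicated(info$sample_id))
    stop("sample ids must be unique across datasets")
  comp <- newCompendium(exprs, info, presence)
  logStep(comp, "harmonize", n_genes = length(genes), n_datasets = length(raw))
}

#' Remove genes absent from too many datasets
#'
#' A gene counts as missing in a dataset when that dataset did not measure it
#' at all. Genes whose missing fraction exceeds `max_missing_fraction`
#' (strictly) are removed; a fraction exactly at the threshold is retained.
#'
#' @param comp Harmonized [ExpressionCompendium-class].
#' @param max_missing_fraction Maximum tolerated fraction of datasets lacking
#'   the gene (default 0.20).
#' @return Filtered compendium.
#' @export
filterGenesByMissingness <- function(comp, max_missing_fraction = 0.20) {
  presence <- genePresence(comp)
  frac_missing <- rowMeans(!presence)
  keep <- frac_missing <= max_missing_fraction
  if (!any(keep)) warning("all genes removed by the missingness filter")
  removed <- rownames(presence)[!keep]
  out <- comp[keep, ]
  S4Vectors::metadata(out)$gene_presence <- presence[keep, , drop = FALSE]
  S4Vectors::metadata(out)$provenance <- provenanceLog(comp)
  logStep(out, "filter_genes", removed = removed,
          max_missing_fraction = max_missing_fraction)
}

#' Remove datasets with low coverage of the unified gene set
#'
#' A dataset is retained when it measured at least `min_coverage` of the
#' current unified gene index.
#'
#' @param comp Harmonized [ExpressionCompendium-class].
#' @param min_coverage Minimum gene coverage fraction (default 0.80).
#' @return Filtered compendium.
#' @export
filterDatasetsByCoverage <- function(comp, min_coverage = 0.80) {
  presence <- genePresence(comp)
  coverage <- colMeans(presence)
  keep_ds <- names(coverage)[coverage >= min_coverage]
  if (length(keep_ds) == 0) stop("all datasets removed by the coverage filter")
  removed <- setdiff(colnames(presence), keep_ds)
  out <- comp[, datasetIds(comp) %in% keep_ds]
  S4Vectors::metadata(out)$gene_presence <-
    presence[, keep_ds, drop = FALSE]
  S4Vectors::metadata(out)$provenance <- provenanceLog(comp)
  logStep(out, "filter_datasets", removed = removed,
          min_coverage = min_coverage)
}

#' Conditionally clip extreme values of one dataset's matrix
#'
#' Clipping triggers only when the maximum (non-missing) value exceeds 10
#' times the mean of all non-missing entries; values are then clamped into
#' the 1st and 99th percentiles of the pooled within-dataset distribution
#' (linear-interpolation quantiles). Otherwise the matrix is unchanged.
#'
#' @param values Numeric matrix (one dataset; `NA` entries are ignored in the
#'   mean/percentile computation and left untouched).
#' @param trigger_ratio Max/mean ratio above which clipping fires (default 10).
#' @param probs Lower/upper percentile bounds (default `c(0.01, 0.99)`).
#' @return The matrix, with attributes `clipped` (logical) and, when
#'   triggered, `bounds` (the clamp interval).
#' @export
clipExtremeValues <- function(values, trigger_ratio = 10,
                              probs = c(0.01, 0.99)) {
  v <- values[!is.na(values)]
  if (length(v) == 0) stop("all values missing; cannot assess clipping")
  triggered <- max(v) > trigger_ratio * mean(v)
  if (triggered) {
    b <- quantile(v, probs, names = FALSE, type = 7)
    values[!is.na(values)] <- pmin(pmax(v, b[1]), b[2])
    attr(values, "bounds") <- b
  }
  attr(values, "clipped") <- triggered
  values
}

#' Conditionally log2-transform one dataset's matrix
#'
#' The transform fires when the maximum non-missing value exceeds 100, or
#' when the range (max - min) exceeds 50 while the first quartile is greater
#' than 0. When it fires, every non-missing value x becomes `log2(x + 1)`;
#' negative values under a triggered transform are an error.
#'
#' @param values Numeric matrix (one dataset).
#' @return The matrix, with attribute `log2` recording the decision.
#' @export
maybeLog2 <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) == 0) stop("all values missing; cannot assess log transform")
  q1 <- quantile(v, 0.25, names = FALSE, type = 7)
  triggered <- max(v) > 100 || ((max(v) - min(v)) > 50 && q1 > 0)
  if (triggered) {
    if (min(v) < 0)
      stop("negative values present while the log2 transform triggers")
    values[!is.na(values)] <- log2(v + 1)
  }
  attr(values, "log2") <- triggered
  values
}

# apply a per-dataset matrix transform across the compendium, logging the
# per-dataset decision
applyPerDataset <- function(comp, fun, step, flag_attr) {
  m <- assayMatrix(comp)
  ds <- datasetIds(comp)
  fired <- character()
  for (d in unique(ds)) {
    sel <- ds == d
    res <- fun(m[, sel, drop = FALSE])
    if (isTRUE(attr(res, flag_attr))) fired <- c(fired, d)
    attributes(res) <- attributes(res)[c("dim", "dimnames")]
    m[, sel] <- res
  }
  SummarizedExperiment::assay(comp, "exprs") <- m
  logStep(comp, step, triggered_datasets = fired)
}

#' Remove duplicate samples
#'
#' Among samples anywhere in the compendium whose expression vectors are
#' exactly identical, only the first in input order is kept.
#'
#' @param comp An [ExpressionCompendium-class].
#' @return Compendium without duplicate columns.
#' @export
dropDuplicateSamples <- function(comp) {
  m <- assayMatrix(comp)
  dup <- duplicated(t(m))
  out <- comp[, !dup]
  S4Vectors::metadata(out)$gene_presence <- genePresence(comp)
  S4Vectors::metadata(out)$provenance <- provenanceLog(comp)
  logStep(out, "drop_duplicates", removed = colnames(m)[dup])
}

#' Impute remaining missing entries by within-gene means
#'
#' Each missing entry is replaced by the mean of that gene's non-missing
#' values pooled across all samples in the compendium.
#'
#' @param comp An [ExpressionCompendium-class] (filters already applied).
#' @return Compendium without missing values.
#' @export
imputeMissing <- function(comp) {
  m <- assayMatrix(comp)
  na_idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(na_idx)) {
    gm <- rowMeans(m, na.rm = TRUE)
    if (any(is.nan(gm[unique(na_idx[, 1])])))
      stop("gene(s) missing in every sample: ",
           paste(rownames(m)[unique(na_idx[, 1])][
             is.nan(gm[unique(na_idx[, 1])])], collapse = ", "))
    m[na_idx] <- gm[na_idx[, 1]]
    SummarizedExperiment::assay(comp, "exprs") <- m
  }
  logStep(comp, "impute", n_imputed = nrow(na_idx))
}

#' Min-max scale each dataset independently to \[0, 1\]
#'
#' Uses the dataset-wide minimum and maximum (pooled over genes and samples).
#' A constant dataset maps to all zeros.
#'
#' @param comp An [ExpressionCompendium-class] with no missing values.
#' @return Normalized compendium.
#' @export
minmaxPerDataset <- function(comp) {
  m <- assayMatrix(comp)
  ds <- datasetIds(comp)
  for (d in unique(ds)) {
    sel <- ds == d
    x <- m[, sel, drop = FALSE]
    rng <- range(x)
    m[, sel] <- if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else 0
  }
  SummarizedExperiment::assay(comp, "exprs") <- m
  logStep(comp, "minmax")
}

#' Assign platform categories from a label mapping
#'
#' @param comp An [ExpressionCompendium-class].
#' @param mapping Named integer vector: platform label -> category id. Every
#'   platform label occurring in the compendium must be mapped.
#' @return Compendium with the `platform_category` column filled in.
#' @export
assignPlatformCategory <- function(comp, mapping) {
  labs <- as.character(colData(comp)$platform_label)
  unmapped <- setdiff(unique(labs), names(mapping))
  if (length(unmapped))
    stop("unmapped platform labels: ", paste(unmapped, collapse = ", "))
  colData(comp)$platform_category <- as.integer(mapping[labs])
  logStep(comp, "platform_categories", n_categories = length(unique(mapping[labs])))
}

#' Run the full preprocessing pipeline
#'
#' Applies, in fixed order: gene-space harmonization, the gene missingness
#' filter, the dataset coverage filter, per-dataset conditional clipping,
#' per-dataset conditional log2 transformation, duplicate-sample removal,
#' within-gene mean imputation and per-dataset min-max scaling. Each step is
#' recorded in the provenance log.
#'
#' @param raw List of [RawDataset-class] objects, or an already harmonized
#'   [ExpressionCompendium-class].
#' @param max_missing_fraction Gene filter threshold (default 0.20).
#' @param min_coverage Dataset coverage threshold (default 0.80).
#' @param platform_map Optional platform label -> category mapping; by
#'   default each distinct label becomes its own category.
#' @return A finalized [ExpressionCompendium-class] in \[0, 1\] with no
#'   missing values.
#' @export
preprocessCompendium <- function(raw, max_missing_fraction = 0.20,
                                 min_coverage = 0.80, platform_map = NULL) {
  comp <- if (is(raw, "ExpressionCompendium")) raw else harmonizeGeneSpace(raw)
  comp <- filterGenesByMissingness(comp, max_missing_fraction)
  comp <- filterDatasetsByCoverage(comp, min_coverage)
  comp <- applyPerDataset(comp, clipExtremeValues, "clip", "clipped")
  comp <- applyPerDataset(comp, maybeLog2, "log2", "log2")
  comp <- dropDuplicateSamples(comp)
  comp <- imputeMissing(comp)
  comp <- minmaxPerDataset(comp)
  if (is.null(platform_map)) {
    labs <- unique(as.character(colData(comp)$platform_label))
    platform_map <- setNames(seq_along(labs), labs)
  }
  assignPlatformCategory(comp, platform_map)
}
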