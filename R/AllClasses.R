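#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- colData colData<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom stats cor median quantile rnorm runif sd setNames pchisq optim
#' @importFrom utils head read.delim write.table
NULL

# ---------------------------------------------------------------------------
# RawDataset: one platform-specific expression matrix before harmonization.
# ---------------------------------------------------------------------------

#' RawDataset: a single unharmonized expression dataset
#'
#' Container for one dataset as deposited: a genes x samples matrix (possibly
#' with missing entries, on an unknown linear or log scale), its platform
#' label and per-sample class annotations.
#'
#' @slot dataset_id Character scalar, unique dataset identifier.
#' @slot platform_label Character scalar naming the measurement platform.
#' @slot exprs Numeric genes x samples matrix with rownames (gene symbols)
#'   and colnames (sample ids).
#' @slot classes Character vector of class labels, one per sample.
#' @exportClass RawDataset
setClass("RawDataset",
  representation(
    dataset_id = "character",
    platform_label = "character",
    exprs = "matrix",
    classes = "character"
  )
)

setValidity("RawDataset", function(object) {
  m <- object@exprs
  msgs <- character()
  if (length(object@dataset_id) != 1L) msgs <- c(msgs, "dataset_id must be a single string")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    msgs <- c(msgs, sprintf("duplicate or missing gene identifiers in dataset '%s'",
                            object@dataset_id))
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    msgs <- c(msgs, sprintf("duplicate or missing sample ids in dataset '%s'",
                            object@dataset_id))
  if (length(object@classes) != ncol(m))
    msgs <- c(msgs, "classes must have one entry per sample")
  if (length(msgs)) msgs else TRUE
})

#' Construct a RawDataset
#'
#' @param dataset_id Dataset identifier.
#' @param exprs Genes x samples numeric matrix with dimnames.
#' @param classes Character vector of per-sample class labels.
#' @param platform_label Platform name (defaults to `"unknown"`).
#' @return A [RawDataset-class] object.
#' @export
rawDataset <- function(dataset_id, exprs, classes, platform_label = "unknown") {
  new("RawDataset", dataset_id = as.character(dataset_id),
      platform_label = as.character(platform_label),
      exprs = as.matrix(exprs), classes = as.character(classes))
}

setMethod("show", "RawDataset", function(object) {
  cat(sprintf("RawDataset '%s' [%s]: %d genes x %d samples, %d classes\n",
              object@dataset_id, object@platform_label,
              nrow(object@exprs), ncol(object@exprs),
              length(unique(object@classes))))
})

# ---------------------------------------------------------------------------
# ExpressionCompendium: harmonized multi-dataset container.
# ---------------------------------------------------------------------------

#' ExpressionCompendium: harmonized multi-dataset expression container
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with a single assay
#' `"exprs"` holding all samples on a unified gene index. Per-sample metadata
#' columns are `sample_id`, `dataset_id`, `platform_label`,
#' `platform_category` and `class_label`. The object metadata carries a
#' `provenance` list (ordered record of applied transforms) and a
#' `gene_presence` logical genes x datasets matrix recording which genes each
#' dataset measured before harmonization.
#'
#' @exportClass ExpressionCompendium
setClass("ExpressionCompendium", contains = "SummarizedExperiment")

setValidity("ExpressionCompendium", function(object) {
  msgs <- character()
  need <- c("sample_id", "dataset_id", "platform_label", "platform_category",
            "class_label")
  missing_cols <- setdiff(need, colnames(colData(object)))
  if (length(missing_cols))
    msgs <- c(msgs, paste("missing colData columns:",
                          paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(colnames(object)))
    msgs <- c(msgs, "sample ids must be unique across the compendium")
  if (length(msgs)) msgs else TRUE
})

newCompendium <- function(exprs, info, presence, provenance = list()) {
  cd <- S4Vectors::DataFrame(info, row.names = info$sample_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs), colData = cd)
  out <- new("ExpressionCompendium", se)
  S4Vectors::metadata(out)$gene_presence <- presence
  S4Vectors::metadata(out)$provenance <- provenance
  out
}

#' @describeIn ExpressionCompendium-accessors The unified expression matrix
#'   (genes x samples).
#' @export
setGeneric("assayMatrix", function(x) standardGeneric("assayMatrix"))

#' Accessors for ExpressionCompendium
#'
#' @param x An [ExpressionCompendium-class].
#' @return `assayMatrix`: genes x samples matrix; `sampleInfo`: data.frame of
#'   per-sample annotations; `datasetIds`, `classLabels`: per-sample vectors;
#'   `geneIndex`: character vector of unified gene symbols; `provenanceLog`:
#'   list of transform records; `genePresence`: logical genes x datasets
#'   matrix.
#' @name ExpressionCompendium-accessors
NULL

#' @rdname ExpressionCompendium-accessors
#' @export
setMethod("assayMatrix", "ExpressionCompendium", function(x)
  SummarizedExperiment::assay(x, "exprs"))

#' @rdname ExpressionCompendium-accessors
#' @export
sampleInfo <- function(x) as.data.frame(colData(x))

#' @rdname ExpressionCompendium-accessors
#' @export
datasetIds <- function(x) as.character(colData(x)$dataset_id)

#' @rdname ExpressionCompendium-accessors
#' @export
classLabels <- function(x) as.character(colData(x)$class_label)

#' @rdname ExpressionCompendium-accessors
#' @export
geneIndex <- function(x) rownames(x)

#' @rdname ExpressionCompendium-accessors
#' @export
provenanceLog <- function(x) S4Vectors::metadata(x)$provenance

#' @rdname ExpressionCompendium-accessors
#' @export
genePresence <- function(x) S4Vectors::metadata(x)$gene_presence

setMethod("show", "ExpressionCompendium", function(object) {
  ds <- unique(datasetIds(object))
  cat(sprintf("ExpressionCompendium: %d genes x %d samples\n",
              nrow(object), ncol(object)))
  cat(sprintf("  datasets: %d (%s)\n", length(ds),
              paste(head(ds, 5), collapse = ", ")))
  cat(sprintf("  classes: %s\n",
              paste(sort(unique(classLabels(object))), collapse = ", ")))
  cat(sprintf("  provenance steps: %d\n", length(provenanceLog(object))))
})

# internal: append a provenance record
logStep <- function(comp, step, ...) {
  rec <- c(list(step = step), list(...))
  S4Vectors::metadata(comp)$provenance <-
    c(S4Vectors::metadata(comp)$provenance, list(rec))
  comp
}

# ---------------------------------------------------------------------------
# PairRelationshipMap
# ---------------------------------------------------------------------------

#' PairRelationshipMap: co-occurrence classification of class pairs
#'
#' For every unordered class pair, records whether the two classes co-occur in
#' at least one dataset (`DIRECT`), are linked only through a bridge class
#' (`INDIRECT`) or share neither a dataset nor a bridge (`ISOLATED`).
#'
#' @slot pairs data.frame with columns `class_a`, `class_b`, `relation`.
#' @slot details Named list (key `"a|b"`); each element holds
#'   `supporting_datasets` (DIRECT) or `bridges` (INDIRECT: named list of
#'   bridge class -> list(candidates, partners) dataset ids).
#' @exportClass PairRelationshipMap
setClass("PairRelationshipMap",
  representation(pairs = "data.frame", details = "list"))

setMethod("show", "PairRelationshipMap", function(object) {
  tab <- table(factor(object@pairs$relation,
                      levels = c("DIRECT", "INDIRECT", "ISOLATED")))
  cat(sprintf("PairRelationshipMap: %d pairs (%d direct, %d indirect, %d isolated)\n",
              nrow(object@pairs), tab[["DIRECT"]], tab[["INDIRECT"]],
              tab[["ISOLATED"]]))
})

#' @describeIn PairRelationshipMap-class Data frame of pair relations.
#' @param x A PairRelationshipMap.
#' @export
pairRelations <- function(x) x@pairs

#' @describeIn PairRelationshipMap-class Relation of one pair (order-free).
#' @param class_a,class_b Class labels.
#' @export
pairRelation <- function(x, class_a, class_b) {
  key <- pairKey(class_a, class_b)
  i <- match(key, x@pairs$key)
  if (is.na(i)) stop("no such class pair: ", class_a, " / ", class_b)
  x@pairs$relation[i]
}

#' @describeIn PairRelationshipMap-class Supporting details of one pair.
#' @export
pairDetails <- function(x, class_a, class_b) x@details[[pairKey(class_a, class_b)]]

pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

# ---------------------------------------------------------------------------
# LogFCRecord / LogFCMatrix
# ---------------------------------------------------------------------------

#' LogFCRecord: log fold-change estimate for one class pair
#'
#' Sign convention: `aggregate` is logFC(class_a) - logFC(class_b), i.e. the
#' per-gene difference of class means on the log-scale normalized data.
#'
#' @slot class_a,class_b Class labels of the pair.
#' @slot relation One of `DIRECT`, `INDIRECT`, `ISOLATED`.
#' @slot sources Named list of per-source logFC vectors (dataset ids for
#'   direct pairs, `"bridge:d1->d2"` keys for indirect pairs).
#' @slot retained Names of the sources surviving the concordance filter.
#' @slot aggregate Unweighted mean of the retained per-source vectors.
#' @slot confidence `"high"` or `"low"` (non-overlapping strategy).
#' @exportClass LogFCRecord
setClass("LogFCRecord",
  representation(class_a = "character", class_b = "character",
                 relation = "character", sources = "list",
                 retained = "character", aggregate = "numeric",
                 confidence = "character"))

setMethod("show", "LogFCRecord", function(object) {
  cat(sprintf("LogFCRecord %s vs %s [%s, confidence %s]: %d genes, %d/%d sources retained\n",
              object@class_a, object@class_b, object@relation,
              object@confidence, length(object@aggregate),
              length(object@retained), length(object@sources)))
})

#' @describeIn LogFCRecord-class Aggregate logFC vector of a record.
#' @param x A LogFCRecord.
#' @export
aggregateLogFC <- function(x) x@aggregate

#' Negate a logFC record (swap the class pair)
#'
#' @param x A [LogFCRecord-class].
#' @return The record for (class_b, class_a): all vectors negated.
#' @export
flipRecord <- function(x) {
  new("LogFCRecord", class_a = x@class_b, class_b = x@class_a,
      relation = x@relation, sources = lapply(x@sources, function(v) -v),
      retained = x@retained, aggregate = -x@aggregate,
      confidence = x@confidence)
}

#' LogFCMatrix: class x gene log fold changes against a reference class
#'
#' @slot reference The baseline (reference) class label.
#' @slot lfc Numeric classes x genes matrix; the reference row is all zeros.
#' @slot provenance Named list, per class: relation and retained sources used.
#' @exportClass LogFCMatrix
setClass("LogFCMatrix",
  representation(reference = "character", lfc = "matrix",
                 provenance = "list"))

setMethod("show", "LogFCMatrix", function(object) {
  cat(sprintf("LogFCMatrix vs '%s': %d classes x %d genes\n",
              object@reference, nrow(object@lfc), ncol(object@lfc)))
})

#' @describeIn LogFCMatrix-class The classes x genes logFC matrix.
#' @param x A LogFCMatrix.
#' @export
logfcValues <- function(x) x@lfc

#' @describeIn LogFCMatrix-class The reference class.
#' @export
referenceClass <- function(x) x@reference

# ---------------------------------------------------------------------------
# BaselineCenters
# ---------------------------------------------------------------------------

#' BaselineCenters: pooled and refined baseline-class expression centers
#'
#' @slot baseline_classes Ordered baseline class labels.
#' @slot centers Baselines x genes matrix (current, possibly refined).
#' @slot centers_init Snapshot of the initialization.
#' @slot trace data.frame with one row per recorded iteration:
#'   `iteration`, `lambda`, `consistency`, `regularization`, `total`.
#' @exportClass BaselineCenters
setClass("BaselineCenters",
  representation(baseline_classes = "character", centers = "matrix",
                 centers_init = "matrix", trace = "data.frame"))

setValidity("BaselineCenters", function(object) {
  if (!identical(dim(object@centers), dim(object@centers_init)))
    return("centers and centers_init must share a shape")
  TRUE
})

setMethod("show", "BaselineCenters", function(object) {
  cat(sprintf("BaselineCenters: %d baseline classes x %d genes (%d optimization steps)\n",
              nrow(object@centers), ncol(object@centers),
              max(0L, nrow(object@trace) - 1L)))
})

#' @describeIn BaselineCenters-class Current center matrix.
#' @param x A BaselineCenters.
#' @export
centerValues <- function(x) x@centers

#' @describeIn BaselineCenters-class Objective trace of the optimization.
#' @export
objectiveTrace <- function(x) x@trace

# ---------------------------------------------------------------------------
# ProportionTensor
# ---------------------------------------------------------------------------

#' ProportionTensor: class-specific modulation weights
#'
#' A nonnegative D x C x M array (components x classes x genes) that
#' modulates each class's contribution to each gene per latent component.
#' For every component d and gene g the weights sum to one over classes.
#'
#' @slot P The D x C x M array with dimnames on the class axis.
#' @exportClass ProportionTensor
setClass("ProportionTensor", representation(P = "array"))

setValidity("ProportionTensor", function(object) {
  s <- apply(object@P, c(1, 3), sum)
  if (any(abs(s - 1) > 1e-6))
    return("proportions must sum to 1 over classes for every (component, gene)")
  if (any(object@P < 0)) return("proportions must be nonnegative")
  TRUE
})

setMethod("show", "ProportionTensor", function(object) {
  d <- dim(object@P)
  cat(sprintf("ProportionTensor: %d components x %d classes x %d genes\n",
              d[1], d[2], d[3]))
})

#' @describeIn ProportionTensor-class The underlying D x C x M array.
#' @param x A ProportionTensor.
#' @export
proportionValues <- function(x) x@P

# ---------------------------------------------------------------------------
# CAAEModel
# ---------------------------------------------------------------------------

#' CAAEModel: trained class-aware adversarial autoencoder
#'
#' Holds the encoder/decoder/discriminator parameters, the fixed proportion
#' tensor and expected signal matrix, the running latent class centers, the
#' per-epoch training log and the corrected (reconstructed) expression matrix
#' for all training samples.
#'
#' @slot params Named list of weight matrices and bias vectors.
#' @slot config Model configuration (see [modelConfig()]).
#' @slot P The [ProportionTensor-class] used for reconstruction.
#' @slot W_expected Expected signal matrix (components x genes).
#' @slot mu Running latent class centers (classes x components).
#' @slot log data.frame, one row per epoch with all six loss components.
#' @slot corrected Genes x samples corrected expression matrix.
#' @slot gene_index Unified gene symbols the model was trained on.
#' @slot sample_info Per-sample annotations of the training compendium.
#' @exportClass CAAEModel
setClass("CAAEModel",
  representation(params = "list", config = "list", P = "ProportionTensor",
                 W_expected = "matrix", mu = "matrix", log = "data.frame",
                 corrected = "matrix", gene_index = "character",
                 sample_info = "data.frame"))

setMethod("show", "CAAEModel", function(object) {
  cat(sprintf("CAAEModel: %d genes, %d classes, %d latent components, %d epochs\n",
              length(object@gene_index), dim(object@P@P)[2], dim(object@P@P)[1],
              nrow(object@log)))
  if (nrow(object@log))
    cat(sprintf("  final total loss: %.4g\n", object@log$total[nrow(object@log)]))
})

#' @describeIn CAAEModel-class Corrected (reconstructed) genes x samples matrix.
#' @param x A CAAEModel.
#' @export
correctedMatrix <- function(x) x@corrected

#' @describeIn CAAEModel-class Per-epoch training log.
#' @export
trainingLog <- function(x) x@log
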