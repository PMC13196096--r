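# Hierarchical cross-dataset log fold-change estimation.
#
# Class pairs are classified by co-occurrence: directly shared pairs are
# estimated within datasets, indirectly shared pairs are bridged through an
# intermediate class shared with both, and non-overlapping pairs fall back
# to merging and joint linear batch adjustment (flagged low confidence).
# All logFCs are differences of class means on the log-scale normalized
# matrix, with the sign convention logFC = class_a - class_b.

#' Classify every class pair by dataset co-occurrence
#'
#' @param comp An [ExpressionCompendium-class] with >= 2 classes.
#' @return A [PairRelationshipMap-class]: a pair is `DIRECT` when both
#'   classes co-occur in at least one dataset, `INDIRECT` when they are
#'   linked only through a bridge class co-occurring with each member, and
#'   `ISOLATED` otherwise.
#' @export
classifyPairRelationships <- function(comp) {
  cls <- classLabels(comp); ds <- datasetIds(comp)
  classes <- unique(cls)
  if (length(classes) < 2) stop("need at least 2 classes")
  datasets <- unique(ds)
  inc <- vapply(datasets, function(d)
    classes %in% cls[ds == d], logical(length(classes)))
  dim(inc) <- c(length(classes), length(datasets))
  dimnames(inc) <- list(classes, datasets)

  pairs <- t(utils::combn(classes, 2))
  relation <- character(nrow(pairs))
  details <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    # bridge host sets are stored for the lexicographically sorted pair:
    # candidates host min(a, b), partners host max(a, b)
    a <- min(pairs[i, ]); b <- max(pairs[i, ])
    both <- inc[a, ] & inc[b, ]
    if (any(both)) {
      relation[i] <- "DIRECT"
      details[[i]] <- list(supporting_datasets = datasets[both])
    } else {
      bridges <- list()
      for (br in setdiff(classes, c(a, b))) {
        host_a <- inc[a, ] & inc[br, ]
        host_b <- inc[b, ] & inc[br, ]
        if (any(host_a) && any(host_b))
          bridges[[br]] <- list(candidates = datasets[host_a],
                                partners = datasets[host_b])
      }
      if (length(bridges)) {
        relation[i] <- "INDIRECT"
        details[[i]] <- list(bridges = bridges)
      } else {
        relation[i] <- "ISOLATED"
        details[[i]] <- list()
      }
    }
  }
  df <- data.frame(class_a = pairs[, 1], class_b = pairs[, 2],
                   relation = relation, stringsAsFactors = FALSE)
  df$key <- pairKey(df$class_a, df$class_b)
  names(details) <- df$key
  new("PairRelationshipMap", pairs = df, details = details)
}

classMeans <- function(m, labels, cls) {
  rowMeans(m[, labels == cls, drop = FALSE])
}

#' Filter discordant per-dataset logFC profiles
#'
#' With more than `min_datasets_to_filter` profiles, a profile is retained
#' only when its Pearson correlation with at least one other profile reaches
#' `r_threshold`; if that criterion would retain none, or with few profiles,
#' all are retained. Zero-variance profiles never satisfy the criterion.
#'
#' @param profiles Genes x sources numeric matrix (or list of vectors).
#' @param r_threshold Correlation threshold (default 0.3).
#' @param min_datasets_to_filter Filtering only applies above this count
#'   (default 3).
#' @return Integer indices of the retained profiles.
#' @export
filterDiscordantDatasets <- function(profiles, r_threshold = 0.3,
                                     min_datasets_to_filter = 3) {
  if (is.list(profiles)) profiles <- do.call(cbind, profiles)
  k <- ncol(profiles)
  if (k == 0) stop("no profiles supplied")
  if (k <= min_datasets_to_filter) return(seq_len(k))
  sds <- apply(profiles, 2, sd)
  cc <- suppressWarnings(cor(profiles))
  diag(cc) <- NA
  cc[sds == 0, ] <- NA
  cc[, sds == 0] <- NA
  best <- apply(cc, 1, function(r) if (all(is.na(r))) -Inf else max(r, na.rm = TRUE))
  keep <- unname(which(best >= r_threshold))
  if (length(keep) == 0) seq_len(k) else keep
}

#' Direct logFC for a pair co-occurring within datasets
#'
#' For every dataset hosting both classes, the per-gene logFC is the
#' difference of within-dataset class means; discordant datasets are filtered
#' and the retained vectors averaged.
#'
#' @param comp An [ExpressionCompendium-class] (log-scale, normalized).
#' @param class_a,class_b The class pair (sign: `class_a - class_b`).
#' @param r_threshold,min_datasets_to_filter See
#'   [filterDiscordantDatasets()].
#' @return A [LogFCRecord-class] with confidence `"high"`.
#' @export
directPairLogFC <- function(comp, class_a, class_b, r_threshold = 0.3,
                            min_datasets_to_filter = 3) {
  m <- assayMatrix(comp); cls <- classLabels(comp); ds <- datasetIds(comp)
  sources <- list()
  for (d in unique(ds)) {
    sel <- ds == d
    na <- sum(cls[sel] == class_a); nb <- sum(cls[sel] == class_b)
    if (na >= 1 && nb >= 1) {
      md <- m[, sel, drop = FALSE]; ld <- cls[sel]
      sources[[d]] <- classMeans(md, ld, class_a) - classMeans(md, ld, class_b)
    }
  }
  if (length(sources) == 0)
    stop("classes ", class_a, " and ", class_b, " never co-occur in a dataset")
  keep <- filterDiscordantDatasets(do.call(cbind, sources), r_threshold,
                                   min_datasets_to_filter)
  retained <- names(sources)[keep]
  agg <- rowMeans(do.call(cbind, sources[retained]))
  new("LogFCRecord", class_a = class_a, class_b = class_b,
      relation = "DIRECT", sources = sources, retained = retained,
      aggregate = agg, confidence = "high")
}

#' Match candidate and partner datasets through a bridge class
#'
#' Similarity between two datasets is the Pearson correlation over genes of
#' the mean expression profile of the bridge class in each. Per candidate the
#' `top_k` most similar partners are kept; among kept pairs those with
#' similarity above `sim_threshold` are selected, and when none qualifies the
#' `fallback_pairs` globally highest-similarity kept pairs are used instead.
#'
#' @param comp An [ExpressionCompendium-class].
#' @param bridge_class The shared intermediate class.
#' @param candidates,partners Dataset ids hosting the bridge class on each
#'   side of the pair.
#' @param sim_threshold Preferential similarity cutoff (default 0.6).
#' @param top_k Partners kept per candidate (default 3).
#' @param fallback_pairs Global fallback count (default 10).
#' @return data.frame with columns `candidate`, `partner`, `similarity`.
#' @export
matchBridgeDatasets <- function(comp, bridge_class, candidates, partners,
                                sim_threshold = 0.6, top_k = 3,
                                fallback_pairs = 10) {
  if (length(candidates) == 0 || length(partners) == 0)
    stop("need at least one candidate and one partner dataset")
  m <- assayMatrix(comp); cls <- classLabels(comp); ds <- datasetIds(comp)
  profile <- function(d) {
    sel <- ds == d & cls == bridge_class
    if (!any(sel)) stop("bridge class '", bridge_class,
                        "' absent from dataset '", d, "'")
    rowMeans(m[, sel, drop = FALSE])
  }
  prof <- vapply(unique(c(candidates, partners)), profile,
                 numeric(nrow(m)))
  kept <- NULL
  for (cand in candidates) {
    pts <- setdiff(partners, cand)
    if (length(pts) == 0) next
    sims <- vapply(pts, function(p)
      suppressWarnings(cor(prof[, cand], prof[, p])), 0)
    sims[is.na(sims)] <- -Inf
    ord <- order(-sims, seq_along(sims))[seq_len(min(top_k, length(pts)))]
    kept <- rbind(kept, data.frame(candidate = cand, partner = pts[ord],
                                   similarity = sims[ord],
                                   stringsAsFactors = FALSE))
  }
  if (is.null(kept) || nrow(kept) == 0)
    stop("no candidate-partner dataset pairs available")
  sel <- kept[kept$similarity > sim_threshold, , drop = FALSE]
  if (nrow(sel) == 0) {
    ord <- order(-kept$similarity, seq_len(nrow(kept)))
    sel <- kept[ord[seq_len(min(fallback_pairs, nrow(kept)))], , drop = FALSE]
  }
  rownames(sel) <- NULL
  sel
}

#' Remove batch effects by joint per-gene least squares
#'
#' Fits each gene on batch indicators and preserved-class indicators jointly
#' and subtracts the fitted batch component. Class-mean differences of
#' classes balanced across batches are preserved exactly. Batch columns
#' aliased with preserved classes are dropped with a warning (those
#' components are inestimable and left in the data).
#'
#' @param m Genes x samples matrix.
#' @param batch Per-sample batch labels (single batch returns `m` unchanged).
#' @param preserve Optional per-sample class labels to protect.
#' @return Adjusted matrix of the same shape.
#' @export
removeBatchLinear <- function(m, batch, preserve = NULL) {
  batch <- factor(batch)
  if (nlevels(batch) < 2) return(m)
  X_class <- if (is.null(preserve)) {
    matrix(1, ncol(m), 1)
  } else {
    stats::model.matrix(~ factor(preserve))
  }
  X_batch <- stats::model.matrix(~ batch)[, -1, drop = FALSE]
  X <- cbind(X_class, X_batch)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- qr_x$pivot[seq.int(qr_x$rank + 1L, ncol(X))]
    warning("dropping aliased design column(s): ",
            paste(colnames(X)[aliased], collapse = ", "))
    keep <- sort(qr_x$pivot[seq_len(qr_x$rank)])
    X <- X[, keep, drop = FALSE]
    qr_x <- qr(X)
    batch_cols <- which(keep > ncol(X_class))
  } else {
    batch_cols <- seq.int(ncol(X_class) + 1L, ncol(X))
  }
  if (length(batch_cols) == 0) return(m)
  beta <- qr.coef(qr_x, t(m))
  beta[is.na(beta)] <- 0
  fit_batch <- X[, batch_cols, drop = FALSE] %*%
    beta[batch_cols, , drop = FALSE]
  m - t(fit_batch)
}

#' Indirect logFC through a bridge class
#'
#' For each matched (candidate, partner) dataset pair the partner is aligned
#' by the per-gene difference of the bridge-class medians, the pair is
#' merged, residual batch structure is removed by [removeBatchLinear()] with
#' class labels preserved, and the logFC is the difference of adjusted class
#' means. Vectors are averaged over dataset pairs and then over bridges.
#'
#' @param comp An [ExpressionCompendium-class].
#' @param class_a,class_b The pair (present only on opposite sides).
#' @param relmap Optional precomputed [classifyPairRelationships()] result.
#' @param sim_threshold,top_k,fallback_pairs See [matchBridgeDatasets()].
#' @return A [LogFCRecord-class] with confidence `"high"`.
#' @export
indirectPairLogFC <- function(comp, class_a, class_b, relmap = NULL,
                              sim_threshold = 0.6, top_k = 3,
                              fallback_pairs = 10) {
  if (is.null(relmap)) relmap <- classifyPairRelationships(comp)
  det <- pairDetails(relmap, class_a, class_b)
  if (is.null(det$bridges) || length(det$bridges) == 0)
    stop("pair ", class_a, "/", class_b, " has no bridge class")
  # details are stored under the sorted pair; orient candidate side to class_a
  flip <- class_a > class_b
  m <- assayMatrix(comp); cls <- classLabels(comp); ds <- datasetIds(comp)
  sources <- list(); bridge_means <- list()
  for (br in names(det$bridges)) {
    hosts <- det$bridges[[br]]
    cand <- if (flip) hosts$partners else hosts$candidates
    part <- if (flip) hosts$candidates else hosts$partners
    matched <- matchBridgeDatasets(comp, br, cand, part, sim_threshold,
                                   top_k, fallback_pairs)
    per_pair <- list()
    for (i in seq_len(nrow(matched))) {
      d1 <- matched$candidate[i]; d2 <- matched$partner[i]
      sel1 <- ds == d1; sel2 <- ds == d2
      b1 <- ds == d1 & cls == br; b2 <- ds == d2 & cls == br
      if (sum(b1) < 2 || sum(b2) < 2)
        warning("bridge class '", br, "' has < 2 samples in ", d1, " or ", d2)
      shift <- apply(m[, b1, drop = FALSE], 1, median) -
        apply(m[, b2, drop = FALSE], 1, median)
      merged <- cbind(m[, sel1, drop = FALSE],
                      m[, sel2, drop = FALSE] + shift)
      lab <- c(cls[sel1], cls[sel2])
      bat <- c(ds[sel1], ds[sel2])
      adj <- removeBatchLinear(merged, bat, lab)
      v <- classMeans(adj, lab, class_a) - classMeans(adj, lab, class_b)
      key <- sprintf("%s:%s->%s", br, d1, d2)
      per_pair[[key]] <- v
      sources[[key]] <- v
    }
    bridge_means[[br]] <- rowMeans(do.call(cbind, per_pair))
  }
  agg <- rowMeans(do.call(cbind, bridge_means))
  new("LogFCRecord", class_a = class_a, class_b = class_b,
      relation = "INDIRECT", sources = sources,
      retained = names(sources), aggregate = agg, confidence = "high")
}

#' logFC for a non-overlapping class pair
#'
#' All datasets containing either class are merged, batch structure is
#' removed by joint least squares with class labels preserved, and the logFC
#' is the difference of adjusted class means. Because no class links the two
#' sides, between-side batch components are confounded with the class
#' contrast and cannot be fully removed; the record is flagged
#' `confidence = "low"`.
#'
#' @param comp An [ExpressionCompendium-class].
#' @param class_a,class_b The non-overlapping pair.
#' @return A [LogFCRecord-class] with confidence `"low"`.
#' @export
nonoverlapPairLogFC <- function(comp, class_a, class_b) {
  m <- assayMatrix(comp); cls <- classLabels(comp); ds <- datasetIds(comp)
  host <- unique(ds[cls %in% c(class_a, class_b)])
  sel <- ds %in% host
  merged <- m[, sel, drop = FALSE]
  lab <- cls[sel]; bat <- ds[sel]
  adj <- withCallingHandlers(
    removeBatchLinear(merged, bat, lab),
    warning = function(w) {
      if (grepl("aliased design column", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  v <- classMeans(adj, lab, class_a) - classMeans(adj, lab, class_b)
  new("LogFCRecord", class_a = class_a, class_b = class_b,
      relation = "ISOLATED", sources = list(merged = v),
      retained = "merged", aggregate = v, confidence = "low")
}

#' Compute logFC records for class pairs
#'
#' Dispatches each pair to the direct, bridged-indirect or non-overlapping
#' strategy according to its co-occurrence relation.
#'
#' @param comp An [ExpressionCompendium-class] (log-scale, normalized).
#' @param pairs Optional 2-column matrix/data.frame of class pairs; defaults
#'   to all unordered pairs.
#' @param relmap Optional precomputed [PairRelationshipMap-class].
#' @param ... Passed through to the per-strategy estimators.
#' @return Named list of [LogFCRecord-class], keyed `"class_a|class_b"` in
#'   the requested orientation.
#' @export
computeLogFC <- function(comp, pairs = NULL, relmap = NULL, ...) {
  if (is.null(relmap)) relmap <- classifyPairRelationships(comp)
  if (is.null(pairs)) pairs <- as.matrix(relmap@pairs[, c("class_a", "class_b")])
  pairs <- as.matrix(pairs)
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    rel <- pairRelation(relmap, a, b)
    rec <- switch(rel,
      DIRECT = directPairLogFC(comp, a, b, ...),
      INDIRECT = indirectPairLogFC(comp, a, b, relmap = relmap),
      ISOLATED = nonoverlapPairLogFC(comp, a, b))
    out[[paste(a, b, sep = "|")]] <- rec
  }
  out
}

#' Assemble the multi-class logFC matrix against a reference class
#'
#' @param records Named list of [LogFCRecord-class] from [computeLogFC()].
#' @param reference The baseline class label.
#' @param classes Optional class universe (defaults to all classes occurring
#'   in the records plus the reference).
#' @return A [LogFCMatrix-class]: one row per class, the reference row all
#'   zeros; rows are taken from the matching record or the sign-flipped
#'   reverse record. Missing pairs are an error.
#' @export
assembleLogFCMatrix <- function(records, reference, classes = NULL) {
  rec_classes <- unique(unlist(lapply(records, function(r)
    c(r@class_a, r@class_b))))
  if (is.null(classes)) classes <- union(reference, rec_classes)
  genes <- names(records[[1]]@aggregate)
  M <- length(records[[1]]@aggregate)
  lfc <- matrix(0, length(classes), M, dimnames = list(classes, genes))
  prov <- list()
  missing <- character()
  for (cc in setdiff(classes, reference)) {
    fwd <- records[[paste(cc, reference, sep = "|")]]
    rev <- records[[paste(reference, cc, sep = "|")]]
    rec <- if (!is.null(fwd)) fwd else if (!is.null(rev)) flipRecord(rev) else NULL
    if (is.null(rec)) { missing <- c(missing, cc); next }
    lfc[cc, ] <- rec@aggregate
    prov[[cc]] <- list(relation = rec@relation, retained = rec@retained,
                       confidence = rec@confidence)
  }
  if (length(missing))
    stop("no logFC record versus '", reference, "' for: ",
         paste(missing, collapse = ", "))
  prov[[reference]] <- list(relation = "SELF", retained = character(),
                            confidence = "high")
  new("LogFCMatrix", reference = reference, lfc = lfc, provenance = prov)
}
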