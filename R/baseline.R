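# Baseline-center optimization.
#
# Baseline (reference) class expression centers are initialized as pooled
# per-gene class means and refined by plain gradient descent so that the
# expression of a one-hop shared class, predicted from different baselines
# via center + logFC, agrees across baselines. A scheduled L2 penalty
# anchors the centers to their initialization.

#' Initialize baseline-class centers from pooled class means
#'
#' @param comp An [ExpressionCompendium-class].
#' @param baseline_classes Character vector of baseline class labels.
#' @return A [BaselineCenters-class] with `centers == centers_init`.
#' @export
initCenters <- function(comp, baseline_classes) {
  m <- assayMatrix(comp); cls <- classLabels(comp)
  absent <- setdiff(baseline_classes, unique(cls))
  if (length(absent))
    stop("baseline class(es) absent from the compendium: ",
         paste(absent, collapse = ", "))
  centers <- t(vapply(baseline_classes, function(b)
    rowMeans(m[, cls == b, drop = FALSE]), numeric(nrow(m))))
  rownames(centers) <- baseline_classes
  new("BaselineCenters", baseline_classes = baseline_classes,
      centers = centers, centers_init = centers,
      trace = data.frame(iteration = integer(), lambda = numeric(),
                         consistency = numeric(), regularization = numeric(),
                         total = numeric()))
}

#' One-hop sharing map for baseline optimization
#'
#' Identifies, for each non-baseline class, the baseline classes it directly
#' shares a dataset with, together with the corresponding logFC vectors
#' (class versus baseline).
#'
#' @param comp An [ExpressionCompendium-class].
#' @param baseline_classes Baseline class labels.
#' @param records Named list of [LogFCRecord-class] (from [computeLogFC()]);
#'   computed for the needed DIRECT pairs when `NULL`.
#' @param relmap Optional precomputed [PairRelationshipMap-class].
#' @return Named list, one element per one-hop class `c`: a list with
#'   `baselines` (the sharing baseline classes) and `logfc` (named list of
#'   vectors logFC(c vs b)). Classes sharing with fewer than one baseline
#'   are omitted.
#' @export
oneHopMap <- function(comp, baseline_classes, records = NULL, relmap = NULL) {
  if (is.null(relmap)) relmap <- classifyPairRelationships(comp)
  classes <- setdiff(unique(classLabels(comp)), baseline_classes)
  out <- list()
  for (cc in classes) {
    sharing <- baseline_classes[vapply(baseline_classes, function(b)
      pairRelation(relmap, cc, b) == "DIRECT", TRUE)]
    if (length(sharing) == 0) next
    lfc <- list()
    for (b in sharing) {
      key_f <- paste(cc, b, sep = "|"); key_r <- paste(b, cc, sep = "|")
      rec <- if (!is.null(records[[key_f]])) records[[key_f]]
             else if (!is.null(records[[key_r]])) flipRecord(records[[key_r]])
             else directPairLogFC(comp, cc, b)
      lfc[[b]] <- rec@aggregate
    }
    out[[cc]] <- list(baselines = sharing, logfc = lfc)
  }
  out
}

#' Consistency objective for baseline centers
#'
#' The prediction of one-hop class `c` from baseline `b` is
#' `center[b] + logFC(c vs b)`. The consistency term sums, over one-hop
#' classes and over pairs of sharing baselines, the mean squared per-gene
#' disagreement between the two predictions; the regularization term is
#' `lambda` times the summed mean squared deviation of each center from its
#' initialization. One-hop classes shared by fewer than two baselines
#' contribute nothing.
#'
#' @param centers A [BaselineCenters-class].
#' @param onehop A [oneHopMap()] result.
#' @param lambda Nonnegative regularization weight.
#' @return List with `total`, `consistency` and `regularization`.
#' @export
consistencyObjective <- function(centers, onehop, lambda = 0) {
  stopifnot(lambda >= 0)
  cm <- centers@centers
  M <- ncol(cm)
  cons <- 0
  for (hop in onehop) {
    bs <- hop$baselines
    if (length(bs) < 2) next
    for (i in seq_len(length(bs) - 1)) for (j in seq.int(i + 1, length(bs))) {
      d <- (cm[bs[i], ] + hop$logfc[[bs[i]]]) -
        (cm[bs[j], ] + hop$logfc[[bs[j]]])
      cons <- cons + mean(d^2)
    }
  }
  reg <- lambda * sum(rowMeans((cm - centers@centers_init)^2))
  list(total = cons + reg, consistency = cons, regularization = reg)
}

# analytic gradient of the objective with respect to the center matrix
consistencyGradient <- function(centers, onehop, lambda) {
  cm <- centers@centers
  M <- ncol(cm)
  grad <- matrix(0, nrow(cm), M, dimnames = dimnames(cm))
  for (hop in onehop) {
    bs <- hop$baselines
    if (length(bs) < 2) next
    for (i in seq_len(length(bs) - 1)) for (j in seq.int(i + 1, length(bs))) {
      d <- (cm[bs[i], ] + hop$logfc[[bs[i]]]) -
        (cm[bs[j], ] + hop$logfc[[bs[j]]])
      grad[bs[i], ] <- grad[bs[i], ] + 2 * d / M
      grad[bs[j], ] <- grad[bs[j], ] - 2 * d / M
    }
  }
  grad + lambda * 2 * (cm - centers@centers_init) / M
}

#' Refine baseline centers by scheduled gradient descent
#'
#' Plain gradient descent on the consistency objective with the
#' regularization weight recomputed each iteration on a linear schedule
#' `lambda_t = lambda_start + t/(T-1) * (lambda_end - lambda_start)` for
#' `t = 0, ..., T-1`. The trace records the objective at initialization and
#' after every iteration (`iterations + 1` rows).
#'
#' @param centers A [BaselineCenters-class] (data on the normalized scale).
#' @param onehop A [oneHopMap()] result.
#' @param iterations Number of gradient steps (default 100).
#' @param learning_rate Fixed step size (default 0.001).
#' @param lambda_start,lambda_end Endpoints of the linear regularization
#'   schedule (defaults 1e-4 and 1e-3).
#' @return The refined [BaselineCenters-class] with the objective trace.
#' @export
optimizeCenters <- function(centers, onehop, iterations = 100,
                            learning_rate = 0.001, lambda_start = 1e-4,
                            lambda_end = 1e-3) {
  lam <- if (iterations > 1) {
    lambda_start + (seq_len(iterations) - 1) / (iterations - 1) *
      (lambda_end - lambda_start)
  } else rep(lambda_end, iterations)
  obj0 <- consistencyObjective(centers, onehop, lam[1])
  trace <- data.frame(iteration = 0L, lambda = lam[1],
                      consistency = obj0$consistency,
                      regularization = obj0$regularization,
                      total = obj0$total)
  for (t in seq_len(iterations)) {
    g <- consistencyGradient(centers, onehop, lam[t])
    if (!all(is.finite(g)))
      stop("non-finite gradient at iteration ", t,
           "; check logFC inputs and the data scale")
    centers@centers <- centers@centers - learning_rate * g
    obj <- consistencyObjective(centers, onehop, lam[t])
    trace <- rbind(trace, data.frame(iteration = t, lambda = lam[t],
                                     consistency = obj$consistency,
                                     regularization = obj$regularization,
                                     total = obj$total))
  }
  centers@trace <- trace
  centers
}
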