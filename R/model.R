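# Class-aware adversarial autoencoder.
#
# Architecture: an MLP encoder (hidden 512-256-128-64, CELU activations,
# dropout) maps samples to a D-dimensional latent representation Z. Instead
# of a free decoder, all bias-free linear decoder layers are collapsed into
# a single gene-level signal matrix W (D x M); reconstruction modulates the
# latent components by a fixed class-specific proportion tensor P:
#
#   F_i[d, g] = Z[i, d] * P[d, c_i, g] * C * W[d, g],   Xhat_i = sum_d F_i[d, ]
#
# (the factor C makes a uniform P the neutral element, Xhat = Z W). Training
# jointly minimizes reconstruction, signal-matrix anchoring, latent class
# centering, component consistency, and a cooperative class discriminator
# loss, while an adversarial batch discriminator reaches the encoder through
# gradient-sign reversal. A single Adam optimizer updates all parameters
# simultaneously. Everything is plain R matrix code; no GPU framework is
# involved.

#' Model configuration
#'
#' @param n_components Latent dimension D; defaults to the number of classes
#'   when `NULL` so P and the signal matrix stay directly interpretable.
#' @param encoder_hidden Encoder hidden widths (default `c(512,256,128,64)`).
#' @param decoder_hidden Hidden width of the two bias-free decoder layers
#'   (default 64; must be >= D).
#' @param dropout_rate Encoder dropout rate in training mode (default 0.1).
#' @param disc_hidden Discriminator hidden widths (default `c(64, 32)`).
#' @param loss_weights Named weights for the six loss components
#'   (`recon`, `sig`, `batch`, `class`, `center`, `intermediate`), default
#'   all 1.
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param batch_size Mini-batch size (default 128).
#' @param epochs Training epochs (default 100).
#' @param center_momentum Momentum of the running latent class centers
#'   (default 0.9).
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @return A list of class `"ModelConfig"`.
#' @export
modelConfig <- function(n_components = NULL,
                        encoder_hidden = c(512, 256, 128, 64),
                        decoder_hidden = 64, dropout_rate = 0.1,
                        disc_hidden = c(64, 32),
                        loss_weights = c(recon = 1, sig = 1, batch = 1,
                                         class = 1, center = 1,
                                         intermediate = 1),
                        learning_rate = 1e-4, batch_size = 128,
                        epochs = 100, center_momentum = 0.9, seed = 0) {
  stopifnot(all(encoder_hidden >= 1), all(disc_hidden >= 1),
            all(loss_weights >= 0), dropout_rate >= 0, dropout_rate < 1)
  w <- c(recon = 1, sig = 1, batch = 1, class = 1, center = 1,
         intermediate = 1)
  w[names(loss_weights)] <- loss_weights
  structure(list(n_components = n_components,
                 encoder_hidden = encoder_hidden,
                 decoder_hidden = decoder_hidden,
                 dropout_rate = dropout_rate, disc_hidden = disc_hidden,
                 loss_weights = w, learning_rate = learning_rate,
                 batch_size = batch_size, epochs = epochs,
                 center_momentum = center_momentum, seed = as.integer(seed)),
            class = "ModelConfig")
}

# ---------------------------------------------------------------------------
# activations / initialization
# ---------------------------------------------------------------------------

celu <- function(x) {
  neg <- x < 0
  x[neg] <- expm1(x[neg])
  x
}

celuGrad <- function(a) {
  g <- array(1, dim(a))
  neg <- a < 0
  g[neg] <- exp(a[neg])
  g
}

xavier <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# class templates on the normalized scale: baseline center + logFC, clamped
classTemplates <- function(logfc, centers) {
  ref <- referenceClass(logfc)
  cm <- centerValues(centers)
  base <- if (ref %in% rownames(cm)) cm[ref, ] else cm[1, ]
  tpl <- sweep(logfcValues(logfc), 2, base, "+")
  pmin(pmax(tpl, 0), 1)
}

#' Build the class-specific proportion tensor
#'
#' Class templates are reconstructed as baseline center + logFC (clamped to
#' the \[0, 1\] data scale); the proportion of class c at gene g is the
#' softmax over classes of the template values, shared across all latent
#' components at initialization. Columns therefore sum to one over classes
#' for every (component, gene).
#'
#' @param logfc A [LogFCMatrix-class] versus the baseline class.
#' @param centers A [BaselineCenters-class] containing the baseline row.
#' @param n_components Latent dimension D (default: number of classes).
#' @return A [ProportionTensor-class] (D x C x M).
#' @export
buildProportionTensor <- function(logfc, centers, n_components = NULL) {
  tpl <- classTemplates(logfc, centers)
  C <- nrow(tpl); M <- ncol(tpl)
  D <- if (is.null(n_components)) C else n_components
  e <- exp(tpl)
  p <- sweep(e, 2, colSums(e), "/") # C x M
  P <- array(0, c(D, C, M), dimnames = list(NULL, rownames(tpl), colnames(tpl)))
  for (d in seq_len(D)) P[d, , ] <- p
  new("ProportionTensor", P = P)
}

#' Expected signal matrix from pre-training artifacts
#'
#' With D equal to the number of classes, row d of the expected signal
#' matrix is the template of class d (baseline center + logFC on the
#' normalized scale). With D < C it is the rank-D least-squares factor of
#' the C x M template matrix (from the SVD), so that the best rank-D
#' approximation of the templates is reachable through it. D > C is an
#' error.
#'
#' @param centers A [BaselineCenters-class].
#' @param logfc A [LogFCMatrix-class].
#' @param n_components Latent dimension D (default: number of classes).
#' @return D x M numeric matrix.
#' @export
expectedSignalMatrix <- function(centers, logfc, n_components = NULL) {
  tpl <- classTemplates(logfc, centers)
  C <- nrow(tpl)
  D <- if (is.null(n_components)) C else n_components
  if (D > C) stop("n_components must not exceed the number of classes")
  if (D == C) {
    out <- tpl
    rownames(out) <- NULL
    return(out)
  }
  sv <- svd(tpl, nu = D, nv = D)
  diag(sv$d[seq_len(D)], D, D) %*% t(sv$v)
}

#' Collapse bias-free linear decoder layers into a signal matrix
#'
#' @param layers Ordered list of weight matrices, applied left to right:
#'   a latent row vector z maps to `z %*% layers[[1]] %*% layers[[2]] ...`.
#' @return The matrix product; applying it equals applying the layers
#'   sequentially.
#' @export
collapseDecoder <- function(layers) {
  stopifnot(length(layers) >= 1)
  W <- layers[[1]]
  for (l in layers[-1]) {
    if (ncol(W) != nrow(l))
      stop("incompatible decoder layer dimensions: ", ncol(W), " vs ", nrow(l))
    W <- W %*% l
  }
  W
}

# ---------------------------------------------------------------------------
# reconstruction and losses
# ---------------------------------------------------------------------------

#' Class-aware reconstruction from latent components
#'
#' @param Z Samples x components latent matrix.
#' @param P A [ProportionTensor-class] or the raw D x C x M array.
#' @param W Signal matrix (components x genes).
#' @param class_labels Per-sample class labels (matching P's class names).
#' @return List with `xhat` (samples x genes) and `contributions`
#'   (samples x components x genes array F with
#'   `xhat[i, g] == sum_d F[i, d, g]` exactly).
#' @export
reconstructExpression <- function(Z, P, W, class_labels) {
  if (is(P, "ProportionTensor")) P <- P@P
  D <- dim(P)[1]; C <- dim(P)[2]; M <- dim(P)[3]
  stopifnot(ncol(Z) == D, nrow(W) == D, ncol(W) == M)
  ci <- match(as.character(class_labels), dimnames(P)[[2]])
  if (anyNA(ci)) stop("unknown class label(s): ",
                      paste(unique(class_labels[is.na(ci)]), collapse = ", "))
  N <- nrow(Z)
  xhat <- matrix(0, N, M)
  contrib <- array(0, c(N, D, M))
  for (cc in unique(ci)) {
    idx <- which(ci == cc)
    B <- C * matrix(P[, cc, ], D, M) * W
    xhat[idx, ] <- Z[idx, , drop = FALSE] %*% B
    for (d in seq_len(D))
      contrib[idx, d, ] <- outer(Z[idx, d], B[d, ])
  }
  rownames(xhat) <- rownames(Z); colnames(xhat) <- colnames(W)
  list(xhat = xhat, contributions = contrib)
}

#' Reconstruction loss (squared Frobenius norm)
#'
#' @param xhat,x Matrices of identical shape.
#' @param reduction `"sum"` (squared Frobenius norm, default) or `"mean"`.
#' @return Scalar loss.
#' @export
lossReconstruction <- function(xhat, x, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  if (!identical(dim(xhat), dim(x))) stop("shape mismatch")
  d <- (xhat - x)^2
  if (reduction == "sum") sum(d) else mean(d)
}

#' Signal-matrix anchoring loss
#'
#' @param W,W_expected Components x genes matrices of identical shape.
#' @inheritParams lossReconstruction
#' @return Scalar loss `||W - W_expected||^2`.
#' @export
lossSignal <- function(W, W_expected, reduction = c("sum", "mean")) {
  lossReconstruction(W, W_expected, reduction)
}

#' Latent class-center loss with running centers
#'
#' The loss is the summed squared distance of each latent vector to the
#' current running center of its class (centers treated as constants);
#' afterwards the centers of the classes present in the batch are updated by
#' an exponential moving average. Classes seen for the first time initialize
#' their center at the batch class mean.
#'
#' @param Z Samples x components latent matrix.
#' @param class_labels Per-sample class labels.
#' @param centers Running centers (classes x components with rownames) or
#'   `NULL` on the first batch.
#' @param momentum EMA momentum (default 0.9).
#' @return List with `value` and the updated `centers`.
#' @export
lossCenter <- function(Z, class_labels, centers = NULL, momentum = 0.9) {
  labs <- as.character(class_labels)
  if (is.null(centers))
    centers <- matrix(numeric(0), 0, ncol(Z))
  batch_means <- list()
  for (cc in unique(labs)) {
    bm <- colMeans(Z[labs == cc, , drop = FALSE])
    batch_means[[cc]] <- bm
    if (!cc %in% rownames(centers)) {
      centers <- rbind(centers, matrix(bm, 1, ncol(Z),
                                       dimnames = list(cc, NULL)))
    }
  }
  value <- sum((Z - centers[labs, , drop = FALSE])^2)
  for (cc in names(batch_means))
    centers[cc, ] <- momentum * centers[cc, ] +
      (1 - momentum) * batch_means[[cc]]
  list(value = value, centers = centers)
}

#' Component-consistency loss
#'
#' Mean squared pairwise distance between the per-component gene
#' contribution rows of each sample, normalized by `1/(N * D^2)`; the
#' diagonal (f1 = f2) terms are included and contribute zero.
#'
#' @param contributions Samples x components x genes array F (from
#'   [reconstructExpression()]).
#' @return Scalar loss.
#' @export
lossIntermediate <- function(contributions) {
  d <- dim(contributions)
  N <- d[1]; D <- d[2]
  total <- 0
  for (i in seq_len(N)) {
    Fi <- matrix(contributions[i, , ], D)
    s <- colSums(Fi)
    total <- total + 2 * D * sum(Fi^2) - 2 * sum(s^2)
  }
  total / (N * D^2)
}

#' Weighted total loss
#'
#' @param components Named numeric vector with elements `recon`, `sig`,
#'   `batch`, `class`, `center`, `intermediate`.
#' @param weights Named weights (default all 1, the plain sum).
#' @return Scalar weighted sum.
#' @export
totalLoss <- function(components, weights = NULL) {
  if (is.null(weights)) weights <- setNames(rep(1, length(components)),
                                            names(components))
  sum(weights[names(components)] * components)
}

# ---------------------------------------------------------------------------
# internal network machinery
# ---------------------------------------------------------------------------

initModelParams <- function(M, C, D, K_batch, config, W_expected) {
  H <- config$decoder_hidden
  if (H < D) stop("decoder_hidden must be >= the latent dimension")
  widths <- c(M, config$encoder_hidden, D)
  p <- list()
  for (l in seq_len(length(widths) - 1)) {
    p[[paste0("enc_W", l)]] <- xavier(widths[l], widths[l + 1])
    p[[paste0("enc_b", l)]] <- numeric(widths[l + 1])
  }
  # signal-aware decoder initialization: collapsed product equals W_expected
  p$dec_A1 <- cbind(diag(D), matrix(0, D, H - D))
  p$dec_A2 <- rbind(W_expected, matrix(0, H - D, M))
  for (nm in c("db", "dc")) {
    K <- if (nm == "db") K_batch else C
    widths_d <- c(D, config$disc_hidden, K)
    for (l in seq_len(length(widths_d) - 1)) {
      p[[paste0(nm, "_W", l)]] <- xavier(widths_d[l], widths_d[l + 1])
      p[[paste0(nm, "_b", l)]] <- numeric(widths_d[l + 1])
    }
  }
  p
}

encForward <- function(p, X, config, train = FALSE) {
  n_hidden <- length(config$encoder_hidden)
  h <- X
  cache <- list(h = list(X), a = list(), mask = list())
  for (l in seq_len(n_hidden)) {
    a <- sweep(h %*% p[[paste0("enc_W", l)]], 2, p[[paste0("enc_b", l)]], "+")
    z <- celu(a)
    if (train && config$dropout_rate > 0) {
      mask <- matrix((runif(length(z)) >= config$dropout_rate) /
                       (1 - config$dropout_rate), nrow(z), ncol(z))
      z <- z * mask
      cache$mask[[l]] <- mask
    }
    cache$a[[l]] <- a
    cache$h[[l + 1]] <- z
    h <- z
  }
  lf <- n_hidden + 1
  Z <- sweep(h %*% p[[paste0("enc_W", lf)]], 2, p[[paste0("enc_b", lf)]], "+")
  list(Z = Z, cache = cache)
}

encBackward <- function(p, dZ, cache, config) {
  n_hidden <- length(config$encoder_hidden)
  g <- list()
  lf <- n_hidden + 1
  g[[paste0("enc_W", lf)]] <- crossprod(cache$h[[lf]], dZ)
  g[[paste0("enc_b", lf)]] <- colSums(dZ)
  dh <- tcrossprod(dZ, p[[paste0("enc_W", lf)]])
  for (l in rev(seq_len(n_hidden))) {
    if (length(cache$mask) >= l && !is.null(cache$mask[[l]]))
      dh <- dh * cache$mask[[l]]
    da <- dh * celuGrad(cache$a[[l]])
    g[[paste0("enc_W", l)]] <- crossprod(cache$h[[l]], da)
    g[[paste0("enc_b", l)]] <- colSums(da)
    dh <- tcrossprod(da, p[[paste0("enc_W", l)]])
  }
  g
}

discForward <- function(p, prefix, Z) {
  h1a <- sweep(Z %*% p[[paste0(prefix, "_W1")]], 2,
               p[[paste0(prefix, "_b1")]], "+")
  h1 <- celu(h1a)
  h2a <- sweep(h1 %*% p[[paste0(prefix, "_W2")]], 2,
               p[[paste0(prefix, "_b2")]], "+")
  h2 <- celu(h2a)
  logits <- sweep(h2 %*% p[[paste0(prefix, "_W3")]], 2,
                  p[[paste0(prefix, "_b3")]], "+")
  list(logits = logits, h1a = h1a, h1 = h1, h2a = h2a, h2 = h2)
}

softmaxRows <- function(logits) {
  e <- exp(logits - apply(logits, 1, max))
  e / rowSums(e)
}

# mean multiclass cross-entropy and its gradient w.r.t. the logits
crossEntropy <- function(logits, labels_int) {
  n <- nrow(logits)
  pr <- softmaxRows(logits)
  value <- -mean(log(pmax(pr[cbind(seq_len(n), labels_int)], 1e-12)))
  dlogits <- pr
  dlogits[cbind(seq_len(n), labels_int)] <-
    dlogits[cbind(seq_len(n), labels_int)] - 1
  list(value = value, dlogits = dlogits / n)
}

discBackward <- function(p, prefix, fwd, dlogits, Z) {
  g <- list()
  g[[paste0(prefix, "_W3")]] <- crossprod(fwd$h2, dlogits)
  g[[paste0(prefix, "_b3")]] <- colSums(dlogits)
  dh2 <- tcrossprod(dlogits, p[[paste0(prefix, "_W3")]]) * celuGrad(fwd$h2a)
  g[[paste0(prefix, "_W2")]] <- crossprod(fwd$h1, dh2)
  g[[paste0(prefix, "_b2")]] <- colSums(dh2)
  dh1 <- tcrossprod(dh2, p[[paste0(prefix, "_W2")]]) * celuGrad(fwd$h1a)
  g[[paste0(prefix, "_W1")]] <- crossprod(Z, dh1)
  g[[paste0(prefix, "_b1")]] <- colSums(dh1)
  g$dZ <- tcrossprod(dh1, p[[paste0(prefix, "_W1")]])
  g
}

adamInit <- function(p) {
  list(m = lapply(p, function(x) x * 0), v = lapply(p, function(x) x * 0),
       t = 0L)
}

adamStep <- function(p, g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  corr1 <- 1 - beta1^st$t
  corr2 <- 1 - beta2^st$t
  for (nm in names(g)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g[[nm]]^2
    p[[nm]] <- p[[nm]] - lr * (st$m[[nm]] / corr1) /
      (sqrt(st$v[[nm]] / corr2) + eps)
  }
  list(p = p, st = st)
}

#' Encode samples into the latent space
#'
#' @param model A trained [CAAEModel-class].
#' @param X Samples x genes matrix aligned to the model's gene index.
#' @param mode `"eval"` (deterministic, dropout off, default) or `"train"`
#'   (dropout active, consumes the RNG stream).
#' @return Samples x components latent matrix Z.
#' @export
encodeSamples <- function(model, X, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (ncol(X) != length(model@gene_index))
    stop("X has ", ncol(X), " genes but the model expects ",
         length(model@gene_index))
  encForward(model@params, X, model@config, train = mode == "train")$Z
}

# ---------------------------------------------------------------------------
# training
# ---------------------------------------------------------------------------

# assemble the full gradient of the weighted training objective for one
# mini-batch; returns gradients, loss components and the updated running
# centers (separated from the Adam update so the gradient can be verified
# against finite differences)
caaeComputeGrads <- function(p, Xb, ci, bi, P, W_expected, mu, config,
                             train = TRUE) {
  n <- nrow(Xb)
  D <- dim(P)[1]; C <- dim(P)[2]; M <- dim(P)[3]
  w <- config$loss_weights

  ef <- encForward(p, Xb, config, train = train)
  Z <- ef$Z
  W <- p$dec_A1 %*% p$dec_A2

  # reconstruction + component consistency, grouped by class
  xhat <- matrix(0, n, M)
  dZ <- matrix(0, n, D)
  dW <- matrix(0, D, M)
  int_loss <- 0
  groups <- split(seq_len(n), ci)
  B_list <- list()
  for (cc in names(groups)) {
    B_list[[cc]] <- C * matrix(P[, as.integer(cc), ], D, M) * W
    idx <- groups[[cc]]
    xhat[idx, ] <- Z[idx, , drop = FALSE] %*% B_list[[cc]]
  }
  G <- 2 * (xhat - Xb) # d(recon)/d(xhat), weight applied below
  recon_loss <- sum((xhat - Xb)^2)
  for (cc in names(groups)) {
    idx <- groups[[cc]]
    B <- B_list[[cc]]
    Zg <- Z[idx, , drop = FALSE]
    Gg <- G[idx, , drop = FALSE]
    dZ[idx, ] <- dZ[idx, ] + w[["recon"]] * tcrossprod(Gg, B)
    dB <- w[["recon"]] * crossprod(Zg, Gg)
    if (D > 1) {
      r <- rowSums(B^2)              # per component, sum_g B^2
      q <- colSums(Zg^2)             # per component, sum_i Z^2
      Xg <- xhat[idx, , drop = FALSE]
      int_loss <- int_loss +
        (2 * D * sum(sweep(Zg^2, 2, r, "*")) - 2 * sum(Xg^2)) / (n * D^2)
      coef <- 4 * w[["intermediate"]] / (n * D^2)
      dZ[idx, ] <- dZ[idx, ] +
        coef * (D * sweep(Zg, 2, r, "*") - tcrossprod(Xg, B))
      dB <- dB + coef * (D * B * q - crossprod(Zg, Xg))
    }
    dW <- dW + C * matrix(P[, as.integer(cc), ], D, M) * dB
  }

  # signal anchoring
  sig_loss <- sum((W - W_expected)^2)
  dW <- dW + 2 * w[["sig"]] * (W - W_expected)
  g <- list(dec_A1 = tcrossprod(dW, p$dec_A2),
            dec_A2 = crossprod(p$dec_A1, dW))

  # latent class centers (loss against current centers, then EMA update)
  labs <- as.character(ci)
  cl <- lossCenter(Z, labs, mu, config$center_momentum)
  center_loss <- cl$value
  mu_for_grad <- if (is.null(mu)) cl$centers else {
    # centers used in the loss: pre-update values, newly seen classes at
    # their batch mean; reconstruct from cl$centers is not possible, so
    # recompute the constant used
    mu
  }
  if (is.null(mu_for_grad) || !all(labs %in% rownames(mu_for_grad))) {
    miss <- setdiff(labs, rownames(mu_for_grad))
    for (cc in miss) {
      bm <- colMeans(Z[labs == cc, , drop = FALSE])
      mu_for_grad <- rbind(mu_for_grad,
                           matrix(bm, 1, D, dimnames = list(cc, NULL)))
    }
  }
  dZ <- dZ + 2 * w[["center"]] * (Z - mu_for_grad[labs, , drop = FALSE])
  mu <- cl$centers

  # discriminators: batch head is adversarial (gradient-sign reversal on the
  # encoder path), class head is cooperative
  fb <- discForward(p, "db", Z)
  ceb <- crossEntropy(fb$logits, bi)
  gb <- discBackward(p, "db", fb, ceb$dlogits, Z)
  fc <- discForward(p, "dc", Z)
  cec <- crossEntropy(fc$logits, ci)
  gc <- discBackward(p, "dc", fc, cec$dlogits, Z)
  dZ <- dZ - w[["batch"]] * gb$dZ + w[["class"]] * gc$dZ
  for (nm in setdiff(names(gb), "dZ")) g[[nm]] <- w[["batch"]] * gb[[nm]]
  for (nm in setdiff(names(gc), "dZ")) g[[nm]] <- w[["class"]] * gc[[nm]]

  g <- c(g, encBackward(p, dZ, ef$cache, config))

  comps <- c(recon = recon_loss, sig = sig_loss, batch = ceb$value,
             class = cec$value, center = center_loss,
             intermediate = int_loss)
  if (!all(is.finite(comps))) stop("non-finite loss; aborting training step")
  list(g = g, mu = mu, components = comps)
}

# one mini-batch Adam update
caaeTrainStep <- function(p, st, Xb, ci, bi, P, W_expected, mu, config) {
  cg <- caaeComputeGrads(p, Xb, ci, bi, P, W_expected, mu, config)
  upd <- adamStep(p, cg$g, st, config$learning_rate)
  list(p = upd$p, st = upd$st, mu = cg$mu, components = cg$components)
}

#' Train the class-aware adversarial autoencoder
#'
#' Mini-batch training with a single Adam optimizer over encoder, decoder
#' and discriminators (the batch-discriminator gradient reaches the encoder
#' with reversed sign). The proportion tensor and expected signal matrix are
#' built from the supplied logFC matrix and baseline centers and kept fixed.
#' After training, the corrected expression matrix is the eval-mode
#' reconstruction of every sample.
#'
#' @param comp A preprocessed [ExpressionCompendium-class] (values in
#'   \[0, 1\], no missing entries).
#' @param logfc A [LogFCMatrix-class] whose rows cover every class in
#'   `comp`.
#' @param centers A [BaselineCenters-class] providing the baseline profile.
#' @param config A [modelConfig()].
#' @param batch_by Which annotation defines the technical batch for the
#'   adversarial head: `"platform"` (platform category, default) or
#'   `"dataset"`.
#' @return A trained [CAAEModel-class].
#' @export
fitCAAE <- function(comp, logfc, centers, config = modelConfig(),
                    batch_by = c("platform", "dataset")) {
  batch_by <- match.arg(batch_by)
  X <- t(assayMatrix(comp))
  labs <- classLabels(comp)
  classes <- rownames(logfcValues(logfc))
  if (!all(labs %in% classes))
    stop("classes missing from the logFC matrix: ",
         paste(setdiff(labs, classes), collapse = ", "))
  ci <- match(labs, classes)
  bvec <- if (batch_by == "platform") colData(comp)$platform_category
          else datasetIds(comp)
  if (anyNA(bvec)) bvec <- datasetIds(comp)
  bi <- as.integer(factor(bvec))
  K <- max(bi)
  C <- length(classes)
  D <- if (is.null(config$n_components)) C else config$n_components
  M <- ncol(X); N <- nrow(X)

  Pt <- buildProportionTensor(logfc, centers, D)
  W_expected <- expectedSignalMatrix(centers, logfc, D)

  set.seed(config$seed)
  p <- initModelParams(M, C, D, K, config, W_expected)
  st <- adamInit(p)
  mu <- NULL
  log_rows <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(N)
    starts <- seq(1, N, by = config$batch_size)
    acc <- NULL
    for (s in starts) {
      idx <- perm[s:min(s + config$batch_size - 1, N)]
      step <- caaeTrainStep(p, st, X[idx, , drop = FALSE], ci[idx], bi[idx],
                            Pt@P, W_expected, mu, config)
      p <- step$p; st <- step$st; mu <- step$mu
      acc <- rbind(acc, step$components)
    }
    cm <- colMeans(acc)
    log_rows[[epoch]] <- data.frame(epoch = epoch, t(cm),
                                    total = totalLoss(cm, config$loss_weights))
  }
  log_df <- do.call(rbind, log_rows)

  Z_all <- encForward(p, X, config, train = FALSE)$Z
  W <- p$dec_A1 %*% p$dec_A2
  xhat <- matrix(0, N, M)
  for (cc in unique(ci)) {
    idx <- which(ci == cc)
    B <- C * matrix(Pt@P[, cc, ], D, M) * W
    xhat[idx, ] <- Z_all[idx, , drop = FALSE] %*% B
  }
  corrected <- t(xhat)
  dimnames(corrected) <- dimnames(assayMatrix(comp))
  mu_out <- mu
  rownames(mu_out) <- classes[as.integer(rownames(mu))]
  cfg <- unclass(config)
  cfg$n_components <- D
  new("CAAEModel", params = p, config = cfg, P = Pt,
      W_expected = W_expected, mu = mu_out, log = log_df,
      corrected = corrected, gene_index = rownames(assayMatrix(comp)),
      sample_info = sampleInfo(comp))
}

#' Rebuild a compendium holding corrected expression values
#'
#' Convenience helper: returns a copy of `comp` whose assay is replaced by
#' the model's corrected matrix, so the evaluation and logFC machinery can
#' run on corrected data unchanged.
#'
#' @param comp The training [ExpressionCompendium-class].
#' @param model A trained [CAAEModel-class].
#' @return An [ExpressionCompendium-class] with corrected values.
#' @export
correctedCompendium <- function(comp, model) {
  m <- correctedMatrix(model)
  stopifnot(identical(dim(m), dim(assayMatrix(comp))))
  SummarizedExperiment::assay(comp, "exprs") <- m
  logStep(comp, "caae_corrected")
}
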