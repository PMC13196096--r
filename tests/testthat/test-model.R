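toyLogFCMatrix <- function(tpl, reference = rownames(tpl)[1]) {
  lfc <- sweep(tpl, 2, tpl[reference, ], "-")
  new("LogFCMatrix", reference = reference, lfc = lfc, provenance = list())
}

toyCenters <- function(tpl, reference = rownames(tpl)[1]) {
  new("BaselineCenters", baseline_classes = reference,
      centers = tpl[reference, , drop = FALSE],
      centers_init = tpl[reference, , drop = FALSE], trace = data.frame())
}

test_that("proportion tensor is a per-gene softmax over class templates", {
  # identical templates -> uniform proportions
  tpl <- matrix(0.5, 3, 6, dimnames = list(c("h", "a", "b"),
                                           sprintf("g%d", 1:6)))
  P <- proportionValues(buildProportionTensor(toyLogFCMatrix(tpl),
                                              toyCenters(tpl)))
  expect_equal(dim(P), c(3, 3, 6))
  expect_true(all(abs(P - 1 / 3) < 1e-12))
  # normalization holds for random templates
  set.seed(30)
  tpl2 <- matrix(runif(4 * 8), 4, 8,
                 dimnames = list(c("h", "a", "b", "c"), sprintf("g%d", 1:8)))
  P2 <- proportionValues(buildProportionTensor(toyLogFCMatrix(tpl2),
                                               toyCenters(tpl2)))
  expect_true(all(abs(apply(P2, c(1, 3), sum) - 1) < 1e-9))
  # 2 classes, one gene with templates (1, 0): closed-form softmax
  tpl3 <- matrix(c(1, 0), 2, 1, dimnames = list(c("h", "a"), "g1"))
  P3 <- proportionValues(buildProportionTensor(toyLogFCMatrix(tpl3),
                                               toyCenters(tpl3)))
  expect_equal(P3[1, , 1], c(h = exp(1) / (exp(1) + 1),
                             a = 1 / (exp(1) + 1)))
})

test_that("decoder collapse equals sequential application", {
  # single layer and identity stacks
  A <- matrix(rnorm(12), 3, 4)
  expect_identical(collapseDecoder(list(A)), A)
  expect_equal(collapseDecoder(list(diag(3), diag(3))), diag(3))
  expect_error(collapseDecoder(list(A, A)), "incompatible")
  # random stacks vs sequential application
  set.seed(31)
  for (rep in 1:20) {
    dims <- sample(2:7, sample(2:4, 1), replace = TRUE)
    layers <- lapply(seq_len(length(dims) - 1), function(i)
      matrix(rnorm(dims[i] * dims[i + 1]), dims[i], dims[i + 1]))
    Z <- matrix(rnorm(5 * dims[1]), 5, dims[1])
    seq_out <- Z
    for (l in layers) seq_out <- seq_out %*% l
    expect_equal(Z %*% collapseDecoder(layers), seq_out, tolerance = 1e-10)
  }
})

test_that("reconstruction is neutral under uniform proportions", {
  set.seed(32)
  D <- 4; C <- 4; M <- 7; N <- 5
  tpl <- matrix(0.3, C, M, dimnames = list(paste0("c", 1:C), NULL))
  P <- buildProportionTensor(toyLogFCMatrix(tpl), toyCenters(tpl))
  Z <- matrix(rnorm(N * D), N, D)
  W <- matrix(rnorm(D * M), D, M)
  labs <- sample(paste0("c", 1:C), N, TRUE)
  rec <- reconstructExpression(Z, P, W, labs)
  expect_equal(rec$xhat, Z %*% W, ignore_attr = TRUE)
  # xhat is exactly the component sum
  expect_equal(rec$xhat, apply(rec$contributions, c(1, 3), sum),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(reconstructExpression(Z, P, W, rep("nope", N)), "unknown")
})

test_that("single-component reconstruction matches the hand formula", {
  P <- array(0, c(1, 2, 3), dimnames = list(NULL, c("a", "b"), NULL))
  P[1, "a", ] <- c(0.6, 0.5, 0.4); P[1, "b", ] <- c(0.4, 0.5, 0.6)
  Pt <- new("ProportionTensor", P = P)
  Z <- matrix(c(2, -1), 2, 1)
  W <- matrix(c(1, 2, 3), 1, 3)
  rec <- reconstructExpression(Z, Pt, W, c("a", "b"))
  expect_equal(rec$xhat[1, ], 2 * c(0.6, 0.5, 0.4) * 2 * c(1, 2, 3))
  expect_equal(rec$xhat[2, ], -1 * c(0.4, 0.5, 0.6) * 2 * c(1, 2, 3))
})

test_that("loss components match their printed formulas", {
  x <- matrix(0, 2, 3)
  xh <- matrix(1, 2, 3)
  expect_equal(lossReconstruction(xh, x), 6)
  expect_equal(lossReconstruction(x, x), 0)
  expect_equal(lossReconstruction(2 * xh, x), 4 * lossReconstruction(xh, x))
  expect_error(lossReconstruction(xh, matrix(0, 3, 2)), "shape")
  W <- matrix(rnorm(6), 2, 3)
  expect_equal(lossSignal(W, W), 0)
  W2 <- W; W2[1, 1] <- W2[1, 1] + 1
  expect_equal(lossSignal(W2, W), 1)
  # total loss is a dot product
  comps <- c(recon = 1, sig = 2, batch = 3, class = 4, center = 5,
             intermediate = 6)
  w <- c(recon = 0.1, sig = 0.2, batch = 0.3, class = 0.4, center = 0.5,
         intermediate = 0.6)
  expect_equal(totalLoss(comps, w), sum(comps * w))
  expect_equal(totalLoss(rep(0, 6)), 0)
  expect_equal(totalLoss(setNames(rep(1, 6), names(comps))), 6)
})

test_that("center loss uses current centers then applies the EMA update", {
  Z <- rbind(c(1, 0), c(0, 1), c(1, 1))
  labs <- c("a", "a", "b")
  # first batch: centers at batch means -> loss is within-class scatter
  out <- lossCenter(Z, labs, centers = NULL, momentum = 0.9)
  expect_equal(out$value, sum((Z[1:2, ] - rep(c(0.5, 0.5), each = 2))^2))
  # single sample at distance d from its center -> d^2
  mu <- matrix(c(0, 0), 1, 2, dimnames = list("a", NULL))
  out2 <- lossCenter(matrix(c(3, 4), 1, 2), "a", mu)
  expect_equal(out2$value, 25)
  expect_equal(out2$centers["a", ], 0.9 * c(0, 0) + 0.1 * c(3, 4))
  # class absent from the batch keeps its center
  mu2 <- rbind(a = c(0, 0), b = c(5, 5))
  out3 <- lossCenter(matrix(c(1, 1), 1, 2), "a", mu2)
  expect_equal(out3$centers["b", ], c(5, 5))
})

test_that("component-consistency loss matches its normalization", {
  # D = 1: no distinct pairs
  f1 <- array(rnorm(6), c(2, 1, 3))
  expect_equal(lossIntermediate(f1), 0)
  # N = 1, D = 2, rows differ by v: 2||v||^2 / 4
  v <- c(1, -2, 0.5)
  f2 <- array(0, c(1, 2, 3))
  f2[1, 1, ] <- c(1, 1, 1); f2[1, 2, ] <- c(1, 1, 1) + v
  expect_equal(lossIntermediate(f2), sum(v^2) / 2)
  # identical rows -> 0
  f3 <- array(rep(rnorm(3), each = 2), c(1, 2, 3))
  expect_equal(lossIntermediate(f3), 0)
})

test_that("uniform discriminator predictions give ln K cross-entropy", {
  logits <- matrix(0, 5, 3)
  ce <- caae:::crossEntropy(logits, c(1, 2, 3, 1, 2))
  expect_equal(ce$value, log(3))
  # single class present is well-defined
  ce2 <- caae:::crossEntropy(matrix(c(10, -10), 1, 2), 1L)
  expect_lt(ce2$value, 1e-6)
})

test_that("expected signal matrix reproduces templates and rank factors", {
  set.seed(33)
  tpl <- matrix(runif(4 * 10), 4, 10,
                dimnames = list(paste0("c", 1:4), sprintf("g%d", 1:10)))
  lfc <- toyLogFCMatrix(tpl); ctr <- toyCenters(tpl)
  W <- expectedSignalMatrix(ctr, lfc)
  expect_equal(W, tpl, ignore_attr = TRUE)
  # D = C = 1: the baseline center itself
  tpl1 <- tpl[1, , drop = FALSE]
  W1 <- expectedSignalMatrix(toyCenters(tpl1), toyLogFCMatrix(tpl1))
  expect_equal(W1, tpl1, ignore_attr = TRUE)
  # D < C: rank-D factor reaches the best rank-D approximation
  W2 <- expectedSignalMatrix(ctr, lfc, n_components = 2)
  sv <- svd(tpl)
  best2 <- sv$u[, 1:2] %*% diag(sv$d[1:2]) %*% t(sv$v[, 1:2])
  fit <- tpl %*% t(W2) %*% solve(W2 %*% t(W2)) %*% W2
  expect_equal(fit, best2, tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(expectedSignalMatrix(ctr, lfc, n_components = 5), "exceed")
})

test_that("encoding is deterministic in eval mode with correct shapes", {
  set.seed(34)
  tpl <- additiveTemplates(3, 30, seed = 35) / 10
  m <- do.call(cbind, lapply(rownames(tpl), function(cc)
    matrix(rep(pmin(pmax(tpl[cc, ], 0), 1), 4), ncol = 4) +
      matrix(runif(120, 0, 0.05), ncol = 4)))
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  comp <- directComp(m, rep("D1", 12), rep(rownames(tpl), each = 4))
  lfc <- toyLogFCMatrix(pmin(pmax(tpl, 0), 1))
  ctr <- initCenters(comp, "healthy")
  fit <- fitCAAE(comp, lfc, ctr,
                 modelConfig(epochs = 2, batch_size = 6, seed = 1,
                             encoder_hidden = c(16, 8, 8, 4)),
                 batch_by = "dataset")
  X <- t(assayMatrix(comp))
  Z1 <- encodeSamples(fit, X)
  Z2 <- encodeSamples(fit, X)
  expect_identical(Z1, Z2)
  expect_identical(dim(Z1), c(12L, 3L))
  expect_true(all(is.finite(Z1)))
  expect_error(encodeSamples(fit, X[, 1:10]), "genes")
  expect_identical(nrow(trainingLog(fit)), 2L)
  expect_identical(dim(correctedMatrix(fit)), dim(assayMatrix(comp)))
})

test_that("training-objective gradients match finite differences", {
  set.seed(36)
  M <- 9; C <- 3; D <- 3; K <- 2; n <- 6
  cfg <- modelConfig(n_components = D, encoder_hidden = c(7, 6, 5, 4),
                     decoder_hidden = 5, dropout_rate = 0,
                     disc_hidden = c(5, 4), seed = 1)
  Wexp <- matrix(rnorm(D * M), D, M)
  p <- caae:::initModelParams(M, C, D, K, cfg, Wexp)
  p$dec_A1 <- p$dec_A1 + matrix(rnorm(length(p$dec_A1), 0, 0.1), D)
  tpl <- matrix(runif(C * M), C, M, dimnames = list(paste0("c", 1:C), NULL))
  P <- proportionValues(buildProportionTensor(toyLogFCMatrix(tpl),
                                              toyCenters(tpl)))
  Xb <- matrix(runif(n * M), n, M)
  ci <- rep(1:3, 2); bi <- rep(1:2, 3)
  mu <- matrix(rnorm(C * D), C, D, dimnames = list(as.character(1:C), NULL))
  cg <- caae:::caaeComputeGrads(p, Xb, ci, bi, P, Wexp, mu, cfg,
                                train = FALSE)
  w <- cfg$loss_weights
  objective <- function(p, enc) {
    comps <- caae:::caaeComputeGrads(p, Xb, ci, bi, P, Wexp, mu, cfg,
                                     train = FALSE)$components
    w2 <- w
    if (enc) w2["batch"] <- -w2["batch"] # sign reversal on the encoder path
    sum(w2 * comps[names(w2)])
  }
  eps <- 1e-6
  set.seed(37)
  for (nm in names(cg$g)) {
    enc <- grepl("^enc_", nm)
    idx <- sample(length(p[[nm]]), min(3, length(p[[nm]])))
    for (i in idx) {
      up <- p; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- p; dn[[nm]][i] <- dn[[nm]][i] - eps
      num <- (objective(up, enc) - objective(dn, enc)) / (2 * eps)
      expect_equal(cg$g[[nm]][i], num, tolerance = 1e-4)
    }
  }
})
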