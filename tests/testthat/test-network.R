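# finite-difference oracle over a sample of coordinates of every parameter
numericGradCheck <- function(cfg, seed = 7, nCoords = 3, eps = 1e-5) {
  set.seed(seed)
  Tn <- 11
  V <- matrix(stats::rnorm(cfg$nMels * Tn), cfg$nMels, Tn)
  mask <- c(rep(1, 8), 0, 1, 0)
  model <- atfInit(cfg, seed = 123)
  lab <- 2L
  lossAt <- function(params) {
    m2 <- model
    m2$params <- params
    fw <- atfForward(m2, V, mask, training = TRUE, applyGating = FALSE,
                     keepCache = TRUE)
    aamSoftmaxLoss(fw$cache$z, lab, params$head_w, cfg$aamScale,
                   cfg$aamMargin)$loss
  }
  lg <- atfLossGrad(model, V, mask, lab, training = TRUE, applyGating = FALSE)
  worst <- 0
  for (nm in names(model$params)) {
    n <- length(model$params[[nm]])
    coords <- if (n <= nCoords) seq_len(n) else sample.int(n, nCoords)
    for (ci in coords) {
      pp <- model$params; pp[[nm]][ci] <- pp[[nm]][ci] + eps
      pm <- model$params; pm[[nm]][ci] <- pm[[nm]][ci] - eps
      num <- (lossAt(pp) - lossAt(pm)) / (2 * eps)
      ana <- lg$grads[[nm]][ci]
      worst <- max(worst, abs(num - ana) / max(abs(num), abs(ana), 1e-6))
    }
  }
  worst
}

test_that("hand-written backprop matches finite differences in every variant", {
  expect_lt(numericGradCheck(microAtfConfig()), 1e-3)
  expect_lt(numericGradCheck(microAtfConfig(useTfd = FALSE)), 1e-3)
  expect_lt(numericGradCheck(microAtfConfig(useTa = FALSE)), 1e-3)
  expect_lt(numericGradCheck(microAtfConfig(convFrontOnly = TRUE,
                                            useTa = FALSE)), 1e-3)
})

test_that("conv front end reduces 80 x 98 to channels x 40 x 49", {
  cfg <- tinyAtfConfig()
  model <- atfInit(cfg, 1)
  V <- matrix(stats::rnorm(80 * 98), 80, 98)
  fw <- atfForward(model, V, rep(1, 98), keepCache = TRUE)
  expect_equal(fw$cache$dims, c(40, 49, 4))
  expect_length(fw$maskEnc, 49)
})

test_that("with unit batch-norm and a pass-through kernel the front end is a block mean of the ReLU", {
  cfg <- microAtfConfig(convFrontOnly = TRUE)
  model <- atfInit(cfg, 1)
  # center-tap kernel per channel, no bias, inference BN with unit statistics
  model$params$conv_w <- matrix(0, 2, 9)
  model$params$conv_w[, 5] <- 1
  model$params$conv_b[] <- 0
  model$params$bn_g[] <- 1
  model$params$bn_b[] <- 0
  model$bnState <- list(mean = c(0, 0), var = c(1, 1) - 1e-5)
  V <- matrix(stats::rnorm(8 * 10), 8, 10)
  fw <- atfForward(model, V, rep(1, 10), training = FALSE, keepCache = TRUE)
  R <- pmax(V, 0)
  blockMean <- sapply(seq_len(5), function(t2)
    sapply(seq_len(4), function(f2)
      mean(R[(2 * f2 - 1):(2 * f2), (2 * t2 - 1):(2 * t2)])))
  gvec <- fw$cache$gvec
  expect_equal(gvec[1], mean(blockMean), tolerance = 1e-9)
})

test_that("triplet attention with saturated gates recovers scaled identities", {
  cfg <- microAtfConfig()
  model <- atfInit(cfg, 2)
  arr <- array(stats::rnorm(4 * 5 * 2), c(4, 5, 2))
  p <- model$params
  for (b in c("tf", "ct", "cf")) {
    p[[paste0("ta_", b, "_w")]][] <- 0
    p[[paste0("ta_", b, "_b")]] <- 50      # sigmoid -> 1
  }
  out <- SwineVox:::taForward(arr, p)$arr
  expect_equal(out, arr, tolerance = 1e-9)
  # two open branches, one closed: mean over branches gives (2/3) input
  p$ta_tf_b <- -50
  out2 <- SwineVox:::taForward(arr, p)$arr
  expect_equal(out2, (2 / 3) * arr, tolerance = 1e-9)
  expect_equal(dim(out2), dim(arr))
})

test_that("encoder block output is permutation-equivariant without positional encoding", {
  cfg <- microAtfConfig(usePosenc = FALSE)
  model <- atfInit(cfg, 3)
  Tn <- 7
  X <- matrix(stats::rnorm(Tn * cfg$modelDim), Tn, cfg$modelDim)
  mask <- c(1, 1, 0, 1, 1, 1, 1)
  out <- SwineVox:::blockForward(X, mask, model$params, "b1_", cfg, FALSE)$out
  perm <- c(3, 1, 6, 2, 7, 5, 4)
  out2 <- SwineVox:::blockForward(X[perm, ], mask[perm], model$params, "b1_",
                                  cfg, FALSE)$out
  expect_equal(out2, out[perm, ], tolerance = 1e-9)
})

test_that("masked frames cannot influence unmasked frames through attention", {
  cfg <- microAtfConfig()
  model <- atfInit(cfg, 4)
  Tn <- 8
  X <- matrix(stats::rnorm(Tn * cfg$modelDim), Tn, cfg$modelDim)
  mask <- c(1, 1, 1, 0, 1, 1, 0, 1)
  out1 <- SwineVox:::blockForward(X, mask, model$params, "b1_", cfg, FALSE)$out
  X2 <- X
  X2[c(4, 7), ] <- stats::rnorm(2 * cfg$modelDim) * 5
  out2 <- SwineVox:::blockForward(X2, mask, model$params, "b1_", cfg, FALSE)$out
  keep <- mask == 1
  expect_equal(out2[keep, ], out1[keep, ], tolerance = 1e-9)
})

test_that("pooling weights are a valid distribution and ignore masked content", {
  set.seed(5)
  D <- 8
  Tn <- 9
  X <- matrix(stats::rnorm(Tn * D), Tn, D)
  w <- stats::rnorm(D)
  mask <- c(1, 0, 1, 1, 0, 1, 1, 1, 0)
  pl <- SwineVox:::poolForward(X, mask, w)
  expect_gte(min(pl$alpha), 0)
  expect_equal(sum(pl$alpha), 1, tolerance = 1e-9)
  expect_true(all(pl$alpha[mask == 0] == 0))
  # uniform attention (w = 0), full mask: mean of frames up to epsilon
  pl2 <- SwineVox:::poolForward(X, rep(1, Tn), numeric(D))
  expect_equal(pl2$z, colMeans(X), tolerance = 1e-6)
  # a single unmasked frame is returned as-is up to epsilon
  one <- c(rep(0, 8), 1)
  pl3 <- SwineVox:::poolForward(X, one, w)
  expect_equal(pl3$z, X[9, ], tolerance = 1e-6)
  expect_error(SwineVox:::poolForward(X, rep(0, Tn), w), "no valid frames")
})

test_that("AAM loss with zero margin equals softmax cross-entropy on scaled cosines", {
  set.seed(6)
  for (i in 1:20) {
    D <- 6
    z <- stats::rnorm(D)
    W <- matrix(stats::rnorm(5 * D), 5, D)
    lab <- sample.int(5, 1)
    s <- stats::runif(1, 5, 40)
    got <- aamSoftmaxLoss(z, lab, W, s = s, m = 0)$loss
    cosv <- as.numeric((W / sqrt(rowSums(W^2))) %*% (z / sqrt(sum(z^2))))
    logits <- s * cosv
    ce <- -(logits[lab] - log(sum(exp(logits))))
    expect_equal(got, ce, tolerance = 1e-9)
  }
})

test_that("AAM loss matches the closed form for aligned/orthogonal weights", {
  # embedding collinear with the target weight, other weight orthogonal
  z <- c(2, 0)
  W <- rbind(c(1, 0), c(0, 1))
  got <- aamSoftmaxLoss(z, 1L, W, s = 1, m = 0.2)$loss
  expect_equal(got, -log(exp(cos(0.2)) / (exp(cos(0.2)) + exp(0))),
               tolerance = 1e-9)
})

test_that("AAM loss is non-decreasing in the margin while theta_y + m <= pi/2", {
  z <- c(1, 0.3)
  W <- rbind(c(1, 0.1), c(-0.4, 1))
  ms <- seq(0, 0.7, by = 0.05)
  losses <- vapply(ms, function(m) aamSoftmaxLoss(z, 1L, W, s = 10, m = m)$loss,
                   numeric(1))
  expect_true(all(diff(losses) >= -1e-12))
  expect_error(aamSoftmaxLoss(c(0, 0), 1L, W), "zero-norm")
})

test_that("forward gives a probability simplex and deterministic inference", {
  cfg <- tinyAtfConfig()
  model <- atfInit(cfg, 9)
  V <- matrix(stats::rnorm(80 * 60), 80, 60)
  mask <- rep(1, 60)
  f1 <- atfForward(model, V, mask)
  f2 <- atfForward(model, V, mask)
  expect_equal(sum(f1$probs), 1, tolerance = 1e-6)
  expect_identical(f1$probs, f2$probs)
  expect_equal(f1$predLabel, pigClasses()[which.max(f1$logits)])
  expect_true(all(is.finite(f1$embedding)))
})

test_that("ablation switches change parameter counts and computation as designed", {
  base <- tinyAtfConfig()
  nFull <- atfParamCount(base)
  expect_equal(atfParamCount(tinyAtfConfig(useGating = FALSE)), nFull)
  # triplet attention owns 3 x (2*49 weights + 1 bias)
  expect_equal(nFull - atfParamCount(tinyAtfConfig(useTa = FALSE)), 3 * 99)
  expect_equal(atfParamCount(tinyAtfConfig(useTfd = FALSE)), nFull)
  expect_lt(atfParamCount(tinyAtfConfig(convFrontOnly = TRUE, useTa = FALSE)),
            nFull / 5)

  # gating and the block style change the computed function
  V <- matrix(stats::rnorm(80 * 40, sd = 2), 80, 40)
  mask <- rep(1, 40)
  m1 <- atfInit(base, 5)
  m2 <- atfInit(tinyAtfConfig(useGating = FALSE), 5)
  expect_false(identical(atfForward(m1, V, mask)$logits,
                         atfForward(m2, V, mask)$logits))
  m3 <- atfInit(tinyAtfConfig(useTfd = FALSE), 5)
  expect_false(identical(atfForward(m1, V, mask)$logits,
                         atfForward(m3, V, mask)$logits))
})

test_that("a tiny model can fit a separable two-class toy problem", {
  set.seed(11)
  cfg <- microAtfConfig(nClasses = 5)
  model <- atfInit(cfg, 1)
  opt <- SwineVox:::adamInit(model$params)
  mkSample <- function(cls) {
    V <- matrix(stats::rnorm(8 * 10, sd = 0.3), 8, 10)
    if (cls == 1) V[2, ] <- V[2, ] + 3 else V[6, ] <- V[6, ] + 3
    V
  }
  lossOf <- function(m) {
    mean(vapply(1:10, function(i) {
      cls <- 1 + i %% 2
      atfLossGrad(m, mkSample(cls), rep(1, 10), as.integer(cls),
                  training = FALSE)$loss
    }, numeric(1)))
  }
  init <- lossOf(model)
  for (step in 1:50) {
    cls <- 1 + step %% 2
    lg <- atfLossGrad(model, mkSample(cls), rep(1, 10), as.integer(cls),
                      training = TRUE)
    model$bnState <- lg$bnNew
    upd <- SwineVox:::adamStep(model$params, lg$grads, opt, 0.003)
    model$params <- upd$params
    opt <- upd$state
  }
  expect_lt(lossOf(model), init)
})
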