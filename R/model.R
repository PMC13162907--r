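## Full-model forward/backward composition and the AAM-softmax objective.

#' Additive angular margin softmax loss
#'
#' Cross-entropy on scaled cosine logits with an additive angular margin `m`
#' (radians) on the true class: the true-class logit is
#' `s * cos(theta_y + m)` with `theta_y + m` clamped to `[0, pi]`, the other
#' logits are `s * cos(theta_j)`. With `m = 0` this reduces exactly to
#' softmax cross-entropy on `s * cos(theta)`.
#'
#' @param emb embedding vector (nonzero).
#' @param label true class index (1-based).
#' @param weights class weight matrix, one row per class (nonzero rows).
#' @param s scale factor.
#' @param m angular margin in radians.
#' @param withGrad if TRUE also return gradients w.r.t. `emb` and `weights`.
#' @return list with `loss`, `cos`, `logits` (and `gEmb`, `gW` when
#'   `withGrad`).
#' @export
aamSoftmaxLoss <- function(emb, label, weights, s = 30, m = 0.2,
                           withGrad = FALSE) {
  nz <- sqrt(sum(emb^2))
  nw <- sqrt(rowSums(weights^2))
  if (nz == 0 || any(nw == 0)) stopInvalid("zero-norm embedding or class weight")
  zn <- emb / nz
  Wn <- weights / nw
  cosv <- as.numeric(Wn %*% zn)

  cy <- min(max(cosv[label], -1), 1)
  theta <- acos(cy)
  if (theta + m < pi) {
    cym <- cos(theta + m)
    # 1/sin(theta) is guarded; it only matters for the gradient at the poles
    dcym <- sin(theta + m) / max(sin(theta), 1e-7)
  } else {
    cym <- -1
    dcym <- 0
  }
  logits <- s * cosv
  logits[label] <- s * cym
  lse <- logsumexp(logits)
  loss <- lse - logits[label]
  out <- list(loss = loss, cos = cosv, logits = logits)
  if (!withGrad) return(out)

  pr <- exp(logits - lse)
  dl <- pr
  dl[label] <- dl[label] - 1
  gcos <- s * dl
  gcos[label] <- gcos[label] * dcym

  # through the L2 normalizations
  gEmb <- as.numeric(crossprod(Wn, gcos) - sum(gcos * cosv) * zn) / nz
  gW <- (tcrossprod(gcos, zn) - (gcos * cosv) * Wn) / nw
  out$gEmb <- gEmb
  out$gW <- gW
  out
}

#' @keywords internal
downsampleMask <- function(maskVec, T2) {
  vapply(seq_len(T2), function(t) max(maskVec[(2 * t - 1):(2 * t)]), numeric(1))
}

#' @keywords internal
asSpecMatrix <- function(spec) {
  if (is(spec, "MelSpectrogram")) melValues(spec) else as.matrix(spec)
}

#' @keywords internal
asMaskVec <- function(mask, T) {
  v <- if (is(mask, "FrameMask")) maskBits(mask) else as.numeric(mask)
  if (length(v) != T) stopInvalid("mask length ", length(v),
                                  " does not match frame count ", T)
  v
}

#' Forward pass through the ATF-Conformer
#'
#' Composes spectral gating (if enabled), the conv front end, triplet
#' attention, the frame-sequence projection, the encoder blocks, masked
#' attentive pooling and the normalized-cosine head. With
#' `convFrontOnly = TRUE` the pipeline short-circuits after the front end to
#' global average pooling plus head.
#'
#' @param model an `AtfModel` from [atfInit()].
#' @param spec [MelSpectrogram-class] or plain F x T matrix of log-mel values.
#' @param mask [FrameMask-class] or 0/1 vector of length T.
#' @param training TRUE enables batch-norm batch statistics and dropout.
#' @param applyGating set FALSE when `spec` is already gated (feature caches).
#' @param keepCache keep intermediates for a backward pass.
#' @return list with `logits`, `probs`, `predLabel`, `embedding`, `alpha`
#'   (pooling weights or NULL), `maskEnc`, `bnNew` and (optionally) `cache`.
#' @export
atfForward <- function(model, spec, mask, training = FALSE,
                       applyGating = TRUE, keepCache = FALSE) {
  cfg <- model$cfg
  p <- model$params
  V <- asSpecMatrix(spec)
  if (nrow(V) != cfg$nMels)
    stopInvalid("spectrogram has ", nrow(V), " mel bins, config expects ", cfg$nMels)
  mv <- asMaskVec(mask, ncol(V))
  if (cfg$useGating && applyGating) V <- gateValues(V, cfg$gating)

  fr <- frontForward(V, p, model$bnState, training)
  arr <- fr$arr
  F2 <- dim(arr)[1]; T2 <- dim(arr)[2]; Cc <- dim(arr)[3]
  mE <- downsampleMask(mv, T2)

  cache <- list(front = fr$cache, maskVec = mv, maskEnc = mE)
  alpha <- NULL
  if (cfg$convFrontOnly) {
    gvec <- colMeans(matrix(arr, F2 * T2, Cc))
    z <- as.numeric(gvec %*% p$gap_w) + p$gap_b
    cache$gvec <- gvec
    cache$dims <- c(F2, T2, Cc)
  } else {
    if (cfg$useTa) {
      ta <- taForward(arr, p)
      cache$ta <- ta$cache
      arrTa <- ta$arr
    } else arrTa <- arr
    SeqIn <- matrix(aperm(arrTa, c(2, 1, 3)), T2, F2 * Cc)
    X <- addRowVec(SeqIn %*% p$proj_w, p$proj_b)
    if (cfg$usePosenc) X <- X + posEncoding(T2, cfg$modelDim)
    cache$SeqIn <- SeqIn
    cache$dims <- c(F2, T2, Cc)
    blocks <- vector("list", cfg$nBlocks)
    for (i in seq_len(cfg$nBlocks)) {
      bf <- blockForward(X, mE, p, paste0("b", i, "_"), cfg, training)
      blocks[[i]] <- bf$cache
      X <- bf$out
    }
    cache$blocks <- blocks
    pl <- poolForward(X, mE, p$pool_w)
    z <- pl$z
    alpha <- pl$alpha
    cache$pool <- pl$cache
  }
  cache$z <- z

  nz <- sqrt(sum(z^2))
  nw <- sqrt(rowSums(p$head_w^2))
  cosv <- as.numeric((p$head_w / nw) %*% (z / max(nz, 1e-12)))
  logits <- cfg$aamScale * cosv
  pr <- exp(logits - logsumexp(logits))
  names(pr) <- pigClasses()[seq_len(cfg$nClasses)]
  out <- list(logits = logits, probs = pr,
              predLabel = pigClasses()[which.max(logits)],
              embedding = z, alpha = alpha, maskEnc = mE, bnNew = fr$bnNew)
  if (keepCache) out$cache <- cache
  out
}

#' Loss and parameter gradients for one training example
#'
#' Runs the forward pass with caches, evaluates the AAM-softmax loss against
#' `labelIdx` and backpropagates through every stage by hand.
#'
#' @inheritParams atfForward
#' @param labelIdx 1-based true class index.
#' @return list with `loss`, `grads` (named like `model$params`), `bnNew`,
#'   `predLabel`.
#' @export
atfLossGrad <- function(model, spec, mask, labelIdx, training = TRUE,
                        applyGating = TRUE) {
  cfg <- model$cfg
  p <- model$params
  fw <- atfForward(model, spec, mask, training = training,
                   applyGating = applyGating, keepCache = TRUE)
  cache <- fw$cache
  z <- cache$z

  aam <- aamSoftmaxLoss(z, labelIdx, p$head_w, cfg$aamScale, cfg$aamMargin,
                        withGrad = TRUE)
  grads <- list(head_w = aam$gW)
  gz <- aam$gEmb

  if (cfg$convFrontOnly) {
    grads$gap_w <- tcrossprod(cache$gvec, gz)
    grads$gap_b <- gz
    gGvec <- as.numeric(p$gap_w %*% gz)
    d <- cache$dims
    gArr <- array(rep(gGvec, each = d[1] * d[2]) / (d[1] * d[2]), d)
  } else {
    pb <- poolBackward(gz, p$pool_w, cache$pool)
    grads$pool_w <- pb$gw
    gX <- pb$gX
    for (i in rev(seq_len(cfg$nBlocks))) {
      bb <- blockBackward(gX, p, paste0("b", i, "_"), cfg, cache$blocks[[i]])
      grads <- c(grads, bb$gparams)
      gX <- bb$gX
    }
    # positional encoding is additive: gradient passes through unchanged
    grads$proj_w <- crossprod(cache$SeqIn, gX)
    grads$proj_b <- colSums(gX)
    gSeqIn <- gX %*% t(p$proj_w)
    d <- cache$dims
    gArr <- aperm(array(gSeqIn, c(d[2], d[1], d[3])), c(2, 1, 3))
    if (cfg$useTa) {
      tb <- taBackward(gArr, p, cache$ta)
      grads <- c(grads, tb$gparams)
      gArr <- tb$gArr
    }
  }
  fb <- frontBackward(gArr, p, cache$front)
  grads <- c(grads, fb$gparams)
  list(loss = aam$loss, grads = grads, bnNew = fw$bnNew,
       predLabel = fw$predLabel)
}

#' Predict labels and class probabilities for cached features
#'
#' @param model an `AtfModel`.
#' @param features feature cache list (see [featureCache()]).
#' @param idx indices into `features` to score.
#' @return list with `labels` (character) and `probs` (matrix, one row per
#'   sample, columns in [pigClasses()] order).
#' @export
atfPredict <- function(model, features, idx = seq_along(features)) {
  cfg <- model$cfg
  probs <- matrix(0, length(idx), cfg$nClasses,
                  dimnames = list(NULL, pigClasses()[seq_len(cfg$nClasses)]))
  labels <- character(length(idx))
  for (j in seq_along(idx)) {
    f <- features[[idx[j]]]
    V <- if (cfg$useGating) f$gated else f$raw
    fw <- atfForward(model, V, f$mask, training = FALSE, applyGating = FALSE)
    probs[j, ] <- fw$probs
    labels[j] <- fw$predLabel
  }
  list(labels = labels, probs = probs)
}

#' Save / load a model checkpoint
#'
#' The checkpoint records weights, the architecture config, batch-norm state
#' and the training seed.
#'
#' @param model an `AtfModel`.
#' @param path file path.
#' @param seed training seed to record.
#' @return `path` invisibly / the restored `AtfModel`.
#' @export
saveCheckpoint <- function(model, path, seed = NA_integer_) {
  saveRDS(list(cfg = model$cfg, params = model$params,
               bnState = model$bnState, seed = seed), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  x <- readRDS(path)
  structure(list(cfg = x$cfg, params = x$params, bnState = x$bnState),
            class = "AtfModel")
}
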