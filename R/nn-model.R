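## ATF-Conformer network in pure R: conv front end, triplet attention,
## time-frequency decoupled Conformer blocks, masked attentive pooling and an
## additive angular margin softmax head. Forward passes cache every
## intermediate needed by the matching hand-written reverse-mode backward
## pass; finite-difference checks in the test suite are the gradient oracle.

#' Model architecture configuration
#'
#' All ablation variants are expressed through the four switches:
#' `useGating` (adaptive spectral gating at the input), `useTa` (triplet
#' attention after the conv front end), `useTfd` (decoupled block with
#' frequency-axis local convolution vs. a standard Conformer-style block with
#' time-axis convolution), and `convFrontOnly` (short-circuit to global
#' average pooling directly after the front end).
#'
#' @param nClasses number of classes (default 5).
#' @param nMels input mel bins (default 80; must be even).
#' @param frontChannels conv front-end output channels C' (default 32).
#' @param modelDim encoder dimension D (default 128; divisible by `nHeads`).
#' @param nHeads attention heads (default 4).
#' @param nBlocks encoder blocks (default 2).
#' @param freqKernel odd kernel length of the local conv branch (default 15).
#' @param ffnExpansion feed-forward expansion factor (default 4).
#' @param dropout dropout probability on the feed-forward hidden layer
#'   (default 0.1; training only).
#' @param aamScale AAM-softmax scale s (default 30).
#' @param aamMargin AAM-softmax additive angular margin m in radians
#'   (default 0.2).
#' @param useGating,useTa,useTfd,convFrontOnly ablation switches.
#' @param usePosenc add sinusoidal positional encoding before the first block
#'   (default TRUE).
#' @param gating a [gatingConfig()] used when `useGating` is TRUE.
#' @return an `AtfConfig` list.
#' @export
atfConfig <- function(nClasses = 5, nMels = 80, frontChannels = 32,
                      modelDim = 128, nHeads = 4, nBlocks = 2,
                      freqKernel = 15, ffnExpansion = 4, dropout = 0.1,
                      aamScale = 30, aamMargin = 0.2,
                      useGating = TRUE, useTa = TRUE, useTfd = TRUE,
                      convFrontOnly = FALSE, usePosenc = TRUE,
                      gating = gatingConfig()) {
  stopifnot(modelDim %% nHeads == 0, freqKernel %% 2 == 1,
            aamMargin >= 0, aamMargin < pi / 2, aamScale > 0,
            nMels %% 2 == 0, dropout >= 0, dropout < 1)
  structure(list(nClasses = nClasses, nMels = nMels,
                 frontChannels = frontChannels, modelDim = modelDim,
                 nHeads = nHeads, nBlocks = nBlocks, freqKernel = freqKernel,
                 ffnExpansion = ffnExpansion, dropout = dropout,
                 aamScale = aamScale, aamMargin = aamMargin,
                 useGating = useGating, useTa = useTa, useTfd = useTfd,
                 convFrontOnly = convFrontOnly, usePosenc = usePosenc,
                 gating = gating),
            class = "AtfConfig")
}

## ---- small tensor helpers -------------------------------------------------

# shift matrix columns: out[, d] = M[, d - s] (zero pad)
#' @keywords internal
shiftCols <- function(M, s) {
  if (s == 0) return(M)
  D <- ncol(M)
  out <- matrix(0, nrow(M), D)
  if (s > 0) out[, (1 + s):D] <- M[, 1:(D - s), drop = FALSE]
  else out[, 1:(D + s)] <- M[, (1 - s):D, drop = FALSE]
  out
}

# shift matrix rows: out[t, ] = M[t - s, ]
#' @keywords internal
shiftRows <- function(M, s) {
  if (s == 0) return(M)
  T <- nrow(M)
  out <- matrix(0, T, ncol(M))
  if (s > 0) out[(1 + s):T, ] <- M[1:(T - s), , drop = FALSE]
  else out[1:(T + s), ] <- M[(1 - s):T, , drop = FALSE]
  out
}

#' @keywords internal
addRowVec <- function(M, v) M + rep(v, each = nrow(M))

#' @keywords internal
rowMax <- function(M) do.call(pmax, lapply(seq_len(ncol(M)), function(j) M[, j]))

#' @keywords internal
softmaxRows <- function(S) {
  m <- rowMax(S)
  E <- exp(S - m)
  E / rowSums(E)
}

## linear indices of all k x k patches of an (n1, n2) plane inside its
## zero-padded copy: (n1*n2) x k^2 matrix, patch offsets column-major
.patchIndexCache <- new.env(parent = emptyenv())

#' @keywords internal
patchIndex <- function(n1, n2, k) {
  key <- paste(n1, n2, k, sep = "x")
  hit <- .patchIndexCache[[key]]
  if (!is.null(hit)) return(hit)
  h <- (k - 1) / 2
  np1 <- n1 + 2 * h
  ci <- rep((1:n1) + h, n2) + (rep((1:n2) + h - 1, each = n1)) * np1
  off <- as.vector(outer(-h:h, (-h:h) * np1, "+"))
  idx <- outer(ci, off, "+")
  if (length(.patchIndexCache) < 400) .patchIndexCache[[key]] <- idx
  idx
}

#' @keywords internal
padPlane <- function(P, h) {
  n1 <- nrow(P); n2 <- ncol(P)
  Pp <- matrix(0, n1 + 2 * h, n2 + 2 * h)
  Pp[(1:n1) + h, (1:n2) + h] <- P
  Pp
}

## im2col for a k x k conv over C stacked planes (zero padded, same size)
#' @keywords internal
im2colPlanes <- function(planes, k, idx = NULL) {
  n1 <- nrow(planes[[1]]); n2 <- ncol(planes[[1]])
  if (is.null(idx)) idx <- patchIndex(n1, n2, k)
  h <- (k - 1) / 2
  do.call(cbind, lapply(planes, function(P) {
    matrix(padPlane(P, h)[idx], n1 * n2, k * k)
  }))
}

## ---- parameter initialization --------------------------------------------

#' Initialize an ATF-Conformer model
#'
#' @param cfg an [atfConfig()].
#' @param seed integer seed for the parameter draw.
#' @return an `AtfModel` list with `cfg`, `params` (named list of arrays) and
#'   `bnState` (running batch-norm statistics).
#' @export
atfInit <- function(cfg, seed = 42) {
  withLocalSeed(seed, {
    Cc <- cfg$frontChannels; D <- cfg$modelDim; k <- cfg$freqKernel
    E <- cfg$ffnExpansion; F2 <- cfg$nMels / 2
    rn <- function(n, sd) stats::rnorm(n, 0, sd)
    p <- list(
      conv_w = matrix(rn(Cc * 9, sqrt(2 / 9)), Cc, 9),
      conv_b = numeric(Cc),
      bn_g = rep(1, Cc), bn_b = numeric(Cc)
    )
    if (cfg$convFrontOnly) {
      p$gap_w <- matrix(rn(Cc * D, sqrt(2 / Cc)), Cc, D)
      p$gap_b <- numeric(D)
    } else {
      if (cfg$useTa) {
        for (b in c("tf", "ct", "cf")) {
          p[[paste0("ta_", b, "_w")]] <- rn(98, sqrt(2 / 98))
          p[[paste0("ta_", b, "_b")]] <- 0
        }
      }
      p$proj_w <- matrix(rn(Cc * F2 * D, sqrt(2 / (Cc * F2))), Cc * F2, D)
      p$proj_b <- numeric(D)
      for (i in seq_len(cfg$nBlocks)) {
        pre <- paste0("b", i, "_")
        for (w in c("wq", "wk", "wv", "wo"))
          p[[paste0(pre, w)]] <- matrix(rn(D * D, sqrt(1 / D)), D, D)
        for (b in c("bq", "bk", "bv", "bo")) p[[paste0(pre, b)]] <- numeric(D)
        p[[paste0(pre, "cw1")]] <- matrix(rn(D * D, sqrt(2 / D)), D, D)
        p[[paste0(pre, "cb1")]] <- numeric(D)
        p[[paste0(pre, "ck")]] <- rn(k, sqrt(1 / k))
        p[[paste0(pre, "cb2")]] <- numeric(D)
        p[[paste0(pre, "fw1")]] <- matrix(rn(2 * D * E * D, sqrt(2 / (2 * D))), 2 * D, E * D)
        p[[paste0(pre, "fb1")]] <- numeric(E * D)
        p[[paste0(pre, "fw2")]] <- matrix(rn(E * D * D, sqrt(2 / (E * D))), E * D, D)
        p[[paste0(pre, "fb2")]] <- numeric(D)
        p[[paste0(pre, "ln_g")]] <- rep(1, D)
        p[[paste0(pre, "ln_b")]] <- numeric(D)
      }
      p$pool_w <- rn(D, sqrt(1 / D))
    }
    p$head_w <- matrix(rn(cfg$nClasses * D, sqrt(1 / D)), cfg$nClasses, D)
    structure(list(cfg = cfg, params = p,
                   bnState = list(mean = numeric(Cc), var = rep(1, Cc))),
              class = "AtfModel")
  })
}

#' Number of trainable parameters of a model or config
#' @param x an `AtfModel` or `AtfConfig`.
#' @return integer parameter count.
#' @export
atfParamCount <- function(x) {
  if (inherits(x, "AtfConfig")) x <- atfInit(x, seed = 1)
  sum(vapply(x$params, length, integer(1)))
}

## ---- stage forwards/backwards ---------------------------------------------

## conv front end: 3x3 conv (same padding) + BN + ReLU + 2x2 average pool
#' @keywords internal
frontForward <- function(S, p, bnState, training) {
  F <- nrow(S); T <- ncol(S)
  if (T < 2) stopInvalid("input too short: need at least 2 frames")
  X9 <- matrix(padPlane(S, 1)[patchIndex(F, T, 3)], F * T, 9)
  A <- addRowVec(X9 %*% t(p$conv_w), p$conv_b)   # (F*T) x Cc

  N <- nrow(A)
  if (training) {
    mu <- colMeans(A)
    xc <- addRowVec(A, -mu)
    va <- colMeans(xc^2)
    bnNew <- list(mean = 0.9 * bnState$mean + 0.1 * mu,
                  var = 0.9 * bnState$var + 0.1 * va * N / max(N - 1, 1))
  } else {
    mu <- bnState$mean
    va <- bnState$var
    xc <- addRowVec(A, -mu)
    bnNew <- bnState
  }
  istd <- 1 / sqrt(va + 1e-5)
  xhat <- xc * rep(istd, each = N)
  B <- addRowVec(xhat * rep(p$bn_g, each = N), p$bn_b)
  R <- pmax(B, 0)

  F2 <- F %/% 2; T2 <- T %/% 2
  fidx <- rep(seq(1, 2 * F2, by = 2), T2)
  tidx <- rep(seq(1, 2 * T2, by = 2), each = F2)
  i1 <- fidx + (tidx - 1) * F
  i2 <- i1 + 1
  i3 <- i1 + F
  i4 <- i3 + 1
  P <- 0.25 * (R[i1, , drop = FALSE] + R[i2, , drop = FALSE] +
               R[i3, , drop = FALSE] + R[i4, , drop = FALSE])
  arr <- array(P, c(F2, T2, ncol(P)))
  list(arr = arr, bnNew = bnNew,
       cache = list(S = S, X9 = X9, xhat = xhat, istd = istd, B = B,
                    idx = list(i1, i2, i3, i4), F = F, T = T, F2 = F2, T2 = T2,
                    training = training))
}

#' @keywords internal
frontBackward <- function(gArr, p, cache) {
  F2 <- cache$F2; T2 <- cache$T2; F <- cache$F; T <- cache$T
  Cc <- dim(gArr)[3]
  gP <- matrix(gArr, F2 * T2, Cc) * 0.25
  gR <- matrix(0, F * T, Cc)
  ix <- cache$idx
  gR[ix[[1]], ] <- gP
  gR[ix[[2]], ] <- gP
  gR[ix[[3]], ] <- gP
  gR[ix[[4]], ] <- gP

  gB <- gR * (cache$B > 0)
  N <- nrow(gB)
  gbn_g <- colSums(gB * cache$xhat)
  gbn_b <- colSums(gB)
  gxhat <- gB * rep(p$bn_g, each = N)
  if (cache$training) {
    # batch-norm backward through per-sample statistics
    mh <- colMeans(gxhat)
    mxh <- colMeans(gxhat * cache$xhat)
    gA <- (gxhat - rep(mh, each = N) - cache$xhat * rep(mxh, each = N)) *
      rep(cache$istd, each = N)
  } else {
    gA <- gxhat * rep(cache$istd, each = N)
  }
  gconv_w <- t(gA) %*% cache$X9
  gconv_b <- colSums(gA)
  list(gparams = list(conv_w = gconv_w, conv_b = gconv_b,
                      bn_g = gbn_g, bn_b = gbn_b))
}

## triplet attention: three rotated axis-pair branches with Z-pool + 7x7 conv
TA_BRANCHES <- list(
  tf = list(perm = c(1, 2, 3)),   # keep (F, T), compress channels
  ct = list(perm = c(2, 3, 1)),   # keep (T, C), compress frequency
  cf = list(perm = c(1, 3, 2))    # keep (F, C), compress time
)

#' @keywords internal
taForward <- function(arr, p) {
  d0 <- dim(arr)
  out <- array(0, d0)
  caches <- list()
  for (nm in names(TA_BRANCHES)) {
    perm <- TA_BRANCHES[[nm]]$perm
    B <- aperm(arr, perm)
    db <- dim(B)
    n1 <- db[1]; n2 <- db[2]; K <- db[3]
    M <- matrix(B, n1 * n2, K)
    amax <- max.col(M, ties.method = "first")
    rows <- seq_len(n1 * n2)
    zmax <- M[cbind(rows, amax)]
    zmean <- rowMeans(M)
    idx <- patchIndex(n1, n2, 7)
    Z <- im2colPlanes(list(matrix(zmax, n1, n2), matrix(zmean, n1, n2)), 7, idx)
    w <- p[[paste0("ta_", nm, "_w")]]
    logit <- as.numeric(Z %*% w) + p[[paste0("ta_", nm, "_b")]]
    a <- sigmoid(logit)
    outM <- M * a
    out <- out + aperm(array(outM, db), order(perm)) / 3
    caches[[nm]] <- list(M = M, a = a, amax = amax, Z = Z, idx = idx,
                         n1 = n1, n2 = n2, K = K, perm = perm)
  }
  list(arr = out, cache = caches)
}

#' @keywords internal
taBackward <- function(gOut, p, caches) {
  gArr <- NULL
  gparams <- list()
  for (nm in names(TA_BRANCHES)) {
    cc <- caches[[nm]]
    gB <- aperm(gOut, cc$perm) / 3
    gM <- matrix(gB, cc$n1 * cc$n2, cc$K)
    w <- p[[paste0("ta_", nm, "_w")]]

    gDirect <- gM * cc$a
    ga <- rowSums(gM * cc$M)
    glogit <- ga * cc$a * (1 - cc$a)
    gparams[[paste0("ta_", nm, "_w")]] <- as.numeric(crossprod(cc$Z, glogit))
    gparams[[paste0("ta_", nm, "_b")]] <- sum(glogit)
    # adjoint of the rank-1 conv gradient = conv of the logit-gradient plane
    # with the reversed kernel (one per z-pool channel)
    Zg <- im2colPlanes(list(matrix(glogit, cc$n1, cc$n2)), 7, cc$idx)
    gzmax <- as.numeric(Zg %*% rev(w[1:49]))
    gzmean <- as.numeric(Zg %*% rev(w[50:98]))
    gPool <- matrix(0, nrow(gM), cc$K)
    gPool[cbind(seq_len(nrow(gM)), cc$amax)] <- gzmax
    gPool <- gPool + gzmean / cc$K

    gTot <- gDirect + gPool
    contrib <- aperm(array(gTot, c(cc$n1, cc$n2, cc$K)), order(cc$perm))
    gArr <- if (is.null(gArr)) contrib else gArr + contrib
  }
  list(gArr = gArr, gparams = gparams)
}

## layer norm over the feature axis of a T x D matrix
#' @keywords internal
lnForward <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  va <- rowMeans(xc^2)
  istd <- 1 / sqrt(va + 1e-5)
  xhat <- xc * istd
  list(out = addRowVec(xhat * rep(g, each = nrow(X)), b),
       cache = list(xhat = xhat, istd = istd))
}

#' @keywords internal
lnBackward <- function(gOut, g, cache) {
  N <- nrow(gOut)
  gg <- colSums(gOut * cache$xhat)
  gb <- colSums(gOut)
  gxhat <- gOut * rep(g, each = N)
  mh <- rowMeans(gxhat)
  mxh <- rowMeans(gxhat * cache$xhat)
  gX <- (gxhat - mh - cache$xhat * mxh) * cache$istd
  list(gX = gX, g_g = gg, g_b = gb)
}

## masked multi-head self-attention over time
#' @keywords internal
mhsaForward <- function(X, maskVec, p, pre, nHeads) {
  D <- ncol(X)
  dh <- D %/% nHeads
  Q <- addRowVec(X %*% p[[paste0(pre, "wq")]], p[[paste0(pre, "bq")]])
  K <- addRowVec(X %*% p[[paste0(pre, "wk")]], p[[paste0(pre, "bk")]])
  V <- addRowVec(X %*% p[[paste0(pre, "wv")]], p[[paste0(pre, "bv")]])
  O <- matrix(0, nrow(X), D)
  As <- vector("list", nHeads)
  dead <- which(maskVec == 0)
  for (h in seq_len(nHeads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    Sc <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dh)
    if (length(dead)) Sc[, dead] <- -Inf
    A <- softmaxRows(Sc)
    As[[h]] <- A
    O[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  HT <- addRowVec(O %*% p[[paste0(pre, "wo")]], p[[paste0(pre, "bo")]])
  list(out = HT, cache = list(X = X, Q = Q, K = K, V = V, O = O, As = As,
                              dh = dh, nHeads = nHeads))
}

#' @keywords internal
mhsaBackward <- function(gHT, p, pre, cache) {
  X <- cache$X; dh <- cache$dh
  gO <- gHT %*% t(p[[paste0(pre, "wo")]])
  gp <- list()
  gp[[paste0(pre, "wo")]] <- crossprod(cache$O, gHT)
  gp[[paste0(pre, "bo")]] <- colSums(gHT)
  gQ <- matrix(0, nrow(X), ncol(X))
  gK <- gQ; gV <- gQ
  for (h in seq_len(cache$nHeads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    A <- cache$As[[h]]
    Vh <- cache$V[, cols, drop = FALSE]
    gOh <- gO[, cols, drop = FALSE]
    gA <- tcrossprod(gOh, Vh)
    gV[, cols] <- crossprod(A, gOh)
    gS <- A * (gA - rowSums(A * gA))
    gQ[, cols] <- gS %*% cache$K[, cols, drop = FALSE] / sqrt(dh)
    gK[, cols] <- crossprod(gS, cache$Q[, cols, drop = FALSE]) / sqrt(dh)
  }
  gX <- gQ %*% t(p[[paste0(pre, "wq")]]) +
        gK %*% t(p[[paste0(pre, "wk")]]) +
        gV %*% t(p[[paste0(pre, "wv")]])
  gp[[paste0(pre, "wq")]] <- crossprod(X, gQ)
  gp[[paste0(pre, "wk")]] <- crossprod(X, gK)
  gp[[paste0(pre, "wv")]] <- crossprod(X, gV)
  gp[[paste0(pre, "bq")]] <- colSums(gQ)
  gp[[paste0(pre, "bk")]] <- colSums(gK)
  gp[[paste0(pre, "bv")]] <- colSums(gV)
  list(gX = gX, gparams = gp)
}

## encoder block: temporal attention branch + local conv branch, fused by an
## FFN over the concatenation, wrapped in residual + layer norm
#' @keywords internal
blockForward <- function(X, maskVec, p, pre, cfg, training) {
  mh <- mhsaForward(X, maskVec, p, pre, cfg$nHeads)
  HT <- mh$out

  X2 <- addRowVec(X %*% p[[paste0(pre, "cw1")]], p[[paste0(pre, "cb1")]])
  k <- cfg$freqKernel
  h <- (k - 1) / 2
  ck <- p[[paste0(pre, "ck")]]
  shiftFun <- if (cfg$useTfd) shiftCols else shiftRows
  Cs <- vector("list", k)
  Y <- matrix(0, nrow(X), ncol(X))
  for (j in seq_len(k)) {
    Cs[[j]] <- shiftFun(X2, -(j - h - 1))
    Y <- Y + ck[j] * Cs[[j]]
  }
  Y <- addRowVec(Y, p[[paste0(pre, "cb2")]])
  HF <- silu(Y)

  U <- cbind(HT, HF)
  U1 <- addRowVec(U %*% p[[paste0(pre, "fw1")]], p[[paste0(pre, "fb1")]])
  V1 <- silu(U1)
  dm <- NULL
  V1d <- V1
  if (training && cfg$dropout > 0) {
    dm <- matrix(stats::rbinom(length(V1), 1, 1 - cfg$dropout) / (1 - cfg$dropout),
                 nrow(V1), ncol(V1))
    V1d <- V1 * dm
  }
  Ff <- addRowVec(V1d %*% p[[paste0(pre, "fw2")]], p[[paste0(pre, "fb2")]])
  R <- X + Ff
  ln <- lnForward(R, p[[paste0(pre, "ln_g")]], p[[paste0(pre, "ln_b")]])
  list(out = ln$out,
       cache = list(mh = mh$cache, X = X, X2 = X2, Cs = Cs, Y = Y, HT = HT,
                    HF = HF, U = U, U1 = U1, V1 = V1, V1d = V1d, dm = dm,
                    ln = ln$cache))
}

#' @keywords internal
blockBackward <- function(gOut, p, pre, cfg, cache) {
  lnb <- lnBackward(gOut, p[[paste0(pre, "ln_g")]], cache$ln)
  gp <- list()
  gp[[paste0(pre, "ln_g")]] <- lnb$g_g
  gp[[paste0(pre, "ln_b")]] <- lnb$g_b
  gR <- lnb$gX
  gX <- gR                              # residual path

  gF <- gR
  gp[[paste0(pre, "fw2")]] <- crossprod(cache$V1d, gF)
  gp[[paste0(pre, "fb2")]] <- colSums(gF)
  gV1d <- gF %*% t(p[[paste0(pre, "fw2")]])
  gV1 <- if (is.null(cache$dm)) gV1d else gV1d * cache$dm
  gU1 <- gV1 * siluGrad(cache$U1)
  gp[[paste0(pre, "fw1")]] <- crossprod(cache$U, gU1)
  gp[[paste0(pre, "fb1")]] <- colSums(gU1)
  gU <- gU1 %*% t(p[[paste0(pre, "fw1")]])
  D <- ncol(cache$X)
  gHT <- gU[, 1:D, drop = FALSE]
  gHF <- gU[, (D + 1):(2 * D), drop = FALSE]

  # conv branch backward
  gY <- gHF * siluGrad(cache$Y)
  gp[[paste0(pre, "cb2")]] <- colSums(gY)
  k <- cfg$freqKernel
  h <- (k - 1) / 2
  ck <- p[[paste0(pre, "ck")]]
  shiftFun <- if (cfg$useTfd) shiftCols else shiftRows
  gck <- numeric(k)
  gX2 <- matrix(0, nrow(gY), ncol(gY))
  for (j in seq_len(k)) {
    gck[j] <- sum(gY * cache$Cs[[j]])
    gX2 <- gX2 + ck[j] * shiftFun(gY, j - h - 1)
  }
  gp[[paste0(pre, "ck")]] <- gck
  gp[[paste0(pre, "cw1")]] <- crossprod(cache$X, gX2)
  gp[[paste0(pre, "cb1")]] <- colSums(gX2)
  gX <- gX + gX2 %*% t(p[[paste0(pre, "cw1")]])

  mhb <- mhsaBackward(gHT, p, pre, cache$mh)
  gX <- gX + mhb$gX
  list(gX = gX, gparams = c(gp, mhb$gparams))
}

#' @keywords internal
posEncoding <- function(T, D) {
  pos <- seq_len(T) - 1
  i <- seq_len(D)
  div <- 10000^(((i - 1) %/% 2) * 2 / D)
  PE <- outer(pos, div, "/")
  odd <- i %% 2 == 1
  PE[, odd] <- sin(PE[, odd, drop = FALSE])
  PE[, !odd] <- cos(PE[, !odd, drop = FALSE])
  PE
}

## masked attentive pooling: softmax attention over valid frames only
#' @keywords internal
poolForward <- function(X, maskVec, w, eps = 1e-8) {
  valid <- which(maskVec == 1)
  if (length(valid) == 0) stopInvalid("no valid frames to pool")
  score <- as.numeric(X %*% w)
  score[maskVec == 0] <- -Inf
  mx <- max(score)
  e <- exp(score - mx)
  alpha <- e / sum(e)
  denom <- sum(alpha[valid]) + eps
  z <- as.numeric(crossprod(X, alpha)) / denom
  list(z = z, alpha = alpha, cache = list(X = X, alpha = alpha, denom = denom,
                                          maskVec = maskVec))
}

#' @keywords internal
poolBackward <- function(gz, w, cache) {
  X <- cache$X
  alpha <- cache$alpha
  gAlphaDir <- as.numeric(X %*% gz) / cache$denom
  # denom = sum(alpha) + eps over valid frames (alpha is 0 on masked frames)
  znum <- as.numeric(crossprod(X, alpha))
  gDen <- -sum(gz * znum) / cache$denom^2
  gAlpha <- gAlphaDir + gDen * as.numeric(cache$maskVec == 1)
  gScore <- alpha * (gAlpha - sum(alpha * gAlpha))
  gw <- as.numeric(crossprod(X, gScore))
  gX <- tcrossprod(alpha, gz) + tcrossprod(gScore, w)
  list(gX = gX, gw = gw)
}
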