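#' Class-imbalance-weighted binary cross-entropy
#'
#' `-(1/(N*M)) * (mu * sum_{Y+} log a' + sum_{Y-} log(1 - a'))` where `Y+`
#' are the known (training) associations, `Y-` the unknown pairs, and
#' `mu = |Y-|/|Y+|` up-weights the scarce positives. Probabilities are
#' clipped to `[eps, 1-eps]` before the logs.
#'
#' @param prob matrix of predicted probabilities in `(0, 1)`.
#' @param target binary matrix of the same shape (training associations).
#' @param mu positive-class weight (> 0).
#' @param eps clipping floor (default 1e-7).
#' @return Non-negative loss scalar.
#' @examples
#' weightedBCE(matrix(c(0.5, 0.5), 1), matrix(c(1, 0), 1), mu = 1)  # log(2)
#' @export
weightedBCE <- function(prob, target, mu, eps = 1e-7) {
  if (mu <= 0) stop("mu must be positive", call. = FALSE)
  stopifnot(identical(dim(prob), dim(target)))
  p <- pmin(pmax(prob, eps), 1 - eps)
  pos <- target == 1
  -(mu * sum(log(p[pos])) + sum(log(1 - p[!pos]))) / length(target)
}

#' Triangular cyclic learning rate
#'
#' Rises linearly from `lrBase` to `lrMax` over the first half of each cycle
#' and falls back over the second half; step 0 is `lrBase`, step
#' `cycleLen / 2` is `lrMax`.
#'
#' @param step 0-based step (epoch) index.
#' @param lrBase,lrMax schedule bounds, `0 < lrBase <= lrMax`.
#' @param cycleLen cycle length in steps (>= 2).
#' @return Learning rate in `[lrBase, lrMax]`.
#' @export
cyclicalLR <- function(step, lrBase, lrMax, cycleLen) {
  if (lrBase > lrMax || lrBase <= 0)
    stop("need 0 < lrBase <= lrMax", call. = FALSE)
  if (cycleLen < 2) stop("cycleLen must be >= 2", call. = FALSE)
  pos <- step %% cycleLen
  half <- cycleLen / 2
  frac <- ifelse(pos <= half, pos / half, (cycleLen - pos) / half)
  # clamp away float overshoot at the triangle apex
  pmin(pmax(lrBase + (lrMax - lrBase) * frac, lrBase), lrMax)
}

#' Node dropout on the input graph
#'
#' Zeroes symmetric edge entries of `B` with probability `rate` and rescales
#' survivors by `1/(1 - rate)` (inverted dropout), so the dropped graph is
#' unbiased in expectation. Identity when `training = FALSE` or `rate = 0`.
#'
#' @param B symmetric input graph.
#' @param rate dropout probability in `[0, 1)`.
#' @param training logical.
#' @return The perturbed (still symmetric) graph.
#' @export
applyNodeDropout <- function(B, rate, training = TRUE) {
  .checkRate(rate)
  if (!training || rate == 0) return(B)
  n <- nrow(B)
  m <- matrix(0, n, n)
  ut <- upper.tri(m, diag = TRUE)
  m[ut] <- (runif(sum(ut)) >= rate)
  m <- m + t(m)
  diag(m) <- diag(m) / 2
  B * m / (1 - rate)
}

#' Regular (elementwise) dropout on an embedding
#'
#' @param H embedding matrix.
#' @inheritParams applyNodeDropout
#' @return The perturbed embedding (identity at evaluation time).
#' @export
applyRegularDropout <- function(H, rate, training = TRUE) {
  .checkRate(rate)
  if (!training || rate == 0) return(H)
  H * ((runif(length(H)) >= rate) / (1 - rate))
}

.checkRate <- function(rate) {
  if (rate < 0 || rate >= 1)
    stop("dropout rate must be in [0, 1)", call. = FALSE)
}

# ---- loss + gradients -------------------------------------------------------
#
# Reverse-mode gradients of the weighted cross-entropy through the full
# forward pass. theta: list(W = list, a = numeric, We = list, be = list()).
# P is the (possibly node-dropped) propagation operator; regMasks is a list
# of per-layer inverted-dropout masks on each layer input (NULL = identity).
.pdaLossGrad <- function(theta, P, H0, target, mu, flags,
                         regMasks = NULL) {
  L <- length(theta$W)
  M <- nrow(target); N <- ncol(target)
  useBias <- length(theta$be) > 0L
  if (is.null(regMasks)) regMasks <- vector("list", L)

  # forward, caching layer inputs (after dropout) and pre-activations
  Hin <- vector("list", L)   # dropped input of layer l
  Z <- vector("list", L)     # pre-activation of layer l
  Hl <- vector("list", L)    # output of layer l
  Hprev <- H0
  for (l in seq_len(L)) {
    Hd <- if (is.null(regMasks[[l]])) Hprev else Hprev * regMasks[[l]]
    Hin[[l]] <- Hd
    Z[[l]] <- P %*% (Hd %*% theta$W[[l]])
    Hl[[l]] <- .relu(Z[[l]])
    Hprev <- Hl[[l]]
  }
  Hc <- attentionCombine(Hl, theta$a)
  HP <- Hc[seq_len(M), , drop = FALSE]
  HD <- Hc[M + seq_len(N), , drop = FALSE]

  X <- vector("list", 4L)    # ETG activations, X[[1]] = HP
  Ze <- vector("list", 3L)
  X[[1L]] <- HP
  for (i in 1:3) {
    Ze[[i]] <- X[[i]] %*% theta$We[[i]]
    if (useBias) Ze[[i]] <- sweep(Ze[[i]], 2L, theta$be[[i]], "+")
    X[[i + 1L]] <- if (flags$etgActivation) .relu(Ze[[i]]) else Ze[[i]]
  }
  E <- X[[4L]]

  cosine <- flags$scoreMode == "cosine"
  if (cosine) {
    nE <- sqrt(rowSums(E^2));  invE <- ifelse(nE > 0, 1 / nE, 0)
    nD <- sqrt(rowSums(HD^2)); invD <- ifelse(nD > 0, 1 / nD, 0)
    En <- E * invE
    Dn <- HD * invD
  } else {
    En <- E; Dn <- HD
  }
  S <- tcrossprod(En, Dn)
  prob <- .sigmoid(S)
  loss <- weightedBCE(prob, target, mu)

  # backward
  pos <- target == 1
  G <- (prob * (!pos) - mu * (1 - prob) * pos) / length(target)   # dL/dS
  dEn <- G %*% Dn
  dDn <- crossprod(G, En)
  if (cosine) {
    dE <- invE * (dEn - En * rowSums(En * dEn))
    dHD <- invD * (dDn - Dn * rowSums(Dn * dDn))
  } else {
    dE <- dEn
    dHD <- dDn
  }

  gWe <- vector("list", 3L)
  gbe <- if (useBias) vector("list", 3L) else list()
  dX <- dE
  for (i in 3:1) {
    dZ <- if (flags$etgActivation) dX * (Ze[[i]] > 0) else dX
    gWe[[i]] <- crossprod(X[[i]], dZ)
    if (useBias) gbe[[i]] <- colSums(dZ)
    dX <- tcrossprod(dZ, theta$We[[i]])
  }
  dHP <- dX

  dHc <- rbind(dHP, dHD)
  ga <- vapply(Hl, function(h) sum(h * dHc), 0)

  gW <- vector("list", L)
  R <- theta$a[[L]] * dHc
  for (l in L:1) {
    dZ <- R * (Z[[l]] > 0)
    PdZ <- P %*% dZ           # P symmetric
    gW[[l]] <- crossprod(Hin[[l]], PdZ)
    if (l > 1L) {
      dHd <- tcrossprod(PdZ, theta$W[[l]])
      if (!is.null(regMasks[[l]])) dHd <- dHd * regMasks[[l]]
      R <- theta$a[[l - 1L]] * dHc + dHd
    }
  }

  list(loss = loss, prob = prob,
       grads = list(W = gW, a = ga, We = gWe, be = gbe))
}

.modelTheta <- function(model) {
  list(W = model@gcnWeights, a = model@attention,
       We = model@etgWeights, be = model@etgBiases)
}

.thetaModel <- function(model, theta) {
  model@gcnWeights <- theta$W
  model@attention <- theta$a
  model@etgWeights <- theta$We
  model@etgBiases <- theta$be
  model
}

# Flat views over the trainable tensors, for Adam. Attention scalars are
# trainable only when the attention mechanism is on.
.trainableNames <- function(theta, useAttention) {
  nm <- c(paste0("W", seq_along(theta$W)), if (useAttention) "a",
          paste0("We", 1:3), if (length(theta$be)) paste0("be", 1:3))
  nm
}

.getTensor <- function(theta, nm) {
  if (nm == "a") theta$a
  else if (startsWith(nm, "We")) theta$We[[as.integer(substring(nm, 3))]]
  else if (startsWith(nm, "be")) theta$be[[as.integer(substring(nm, 3))]]
  else theta$W[[as.integer(substring(nm, 2))]]
}

.setTensor <- function(theta, nm, value) {
  if (nm == "a") theta$a <- value
  else if (startsWith(nm, "We")) theta$We[[as.integer(substring(nm, 3))]] <- value
  else if (startsWith(nm, "be")) theta$be[[as.integer(substring(nm, 3))]] <- value
  else theta$W[[as.integer(substring(nm, 2))]] <- value
  theta
}

#' Train the association model
#'
#' Full-graph gradient descent on the weighted cross-entropy with Adam, a
#' triangular cyclic learning rate, node dropout on the input graph and
#' regular dropout on each layer input. The positive weight
#' `mu = |Y-|/|Y+|` is computed from the supplied (training) association
#' matrix, so held-out positives masked out of `network` never influence the
#' loss. Deterministic given the seed in `params`.
#'
#' @param network a [HeteroNetwork-class] built from the training association
#'   matrix.
#' @param params a [pdaParams()] list.
#' @param model optional starting [PDAModel-class]; defaults to a fresh
#'   [newPDAModel()].
#' @return List with `model` (fitted [PDAModel-class]) and `history`
#'   (data.frame of `epoch`, `lr`, `loss`; empty when `epochs = 0`).
#' @export
trainPDAModel <- function(network, params = pdaParams(), model = NULL) {
  A <- network@assoc
  M <- nrow(A); N <- ncol(A)
  if (is.null(model)) model <- newPDAModel(M, N, params)
  nPos <- sum(A == 1)
  if (nPos == 0) stop("no positive associations to train on", call. = FALSE)
  mu <- (length(A) - nPos) / nPos
  B <- inputGraph(network)
  H0 <- initEmbedding(A)
  theta <- .modelTheta(model)
  flags <- list(etgActivation = params$etgActivation,
                scoreMode = params$scoreMode)
  L <- params$gcnLayers

  if (params$epochs == 0L)
    return(list(model = model,
                history = data.frame(epoch = integer(), lr = numeric(),
                                     loss = numeric())))

  nms <- .trainableNames(theta, params$useAttention)
  adamM <- adamV <- setNames(vector("list", length(nms)), nms)
  for (nm in nms) adamM[[nm]] <- adamV[[nm]] <- .getTensor(theta, nm) * 0
  b1 <- 0.9; b2 <- 0.999; aeps <- 1e-8

  # separate RNG streams so node-dropout draws never shift the regular ones
  set.seed(.deriveSeed(params$seed, .streamOffsets[["nodeDropout"]]))
  nodeState <- .currentRNG()
  set.seed(.deriveSeed(params$seed, .streamOffsets[["regularDropout"]]))
  regState <- .currentRNG()
  dims <- c(ncol(H0), rep(params$embeddingDim, L - 1L))
  history <- data.frame(epoch = seq_len(params$epochs), lr = NA_real_,
                        loss = NA_real_)
  for (epoch in seq_len(params$epochs)) {
    lr <- cyclicalLR(epoch - 1L, params$lrBase, params$lrMax, params$cycleLen)
    .restoreRNG(nodeState)
    Bt <- applyNodeDropout(B, params$nodeDropout, training = TRUE)
    nodeState <- .currentRNG()
    P <- .propagate(Bt, Bref = B)
    regMasks <- NULL
    if (params$regularDropout > 0) {
      .restoreRNG(regState)
      regMasks <- lapply(dims, function(d)
        matrix((runif((M + N) * d) >= params$regularDropout) /
                 (1 - params$regularDropout), M + N, d))
      regState <- .currentRNG()
    }
    res <- .pdaLossGrad(theta, P, H0, A, mu, flags, regMasks)
    if (!is.finite(res$loss))
      stop(sprintf("non-finite loss at epoch %d; check inputs/learning rate",
                   epoch), call. = FALSE)
    for (nm in nms) {
      g <- .getTensor(res$grads, nm)
      adamM[[nm]] <- b1 * adamM[[nm]] + (1 - b1) * g
      adamV[[nm]] <- b2 * adamV[[nm]] + (1 - b2) * g^2
      mh <- adamM[[nm]] / (1 - b1^epoch)
      vh <- adamV[[nm]] / (1 - b2^epoch)
      theta <- .setTensor(theta, nm,
                          .getTensor(theta, nm) - lr * mh / (sqrt(vh) + aeps))
    }
    history$lr[epoch] <- lr
    history$loss[epoch] <- res$loss
  }
  list(model = .thetaModel(model, theta), history = history)
}
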