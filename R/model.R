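#' Initial node embedding of the heterogeneous graph
#'
#' `H^(0) = [[0, A], [t(A), 0]]`: each node starts from its raw association
#' profile, so the encoder sees only link structure at layer zero.
#'
#' @param A binary association matrix (M x N).
#' @return Symmetric (M+N) x (M+N) matrix.
#' @export
initEmbedding <- function(A) {
  M <- nrow(A); N <- ncol(A)
  H0 <- matrix(0, M + N, M + N)
  H0[seq_len(M), M + seq_len(N)] <- A
  H0[M + seq_len(N), seq_len(M)] <- t(A)
  H0
}

# D^(-1/2) B D^(-1/2) with D = diag(rowSums(Bref)); Bref defaults to B itself.
# During training Bref is the un-dropped graph so the degrees stay fixed.
.propagate <- function(B, Bref = B) {
  d <- rowSums(Bref)
  if (any(d <= 0))
    stop(sprintf("zero-degree node %d in the input graph",
                 which(d <= 0)[1L]), call. = FALSE)
  inv <- 1 / sqrt(d)
  B * tcrossprod(inv)
}

#' One graph convolution layer
#'
#' `ReLU(D^(-1/2) B D^(-1/2) H W)` with `D = diag(rowSums(B))`. When
#' `training = TRUE`, node dropout perturbs the graph `B` and regular dropout
#' the input embedding `H` (both with inverted-dropout rescaling); at
#' evaluation time both are identity.
#'
#' @param B symmetric input graph.
#' @param H input embedding, rows = nodes.
#' @param W layer weight matrix.
#' @param nodeDropout,regularDropout dropout rates in `[0, 1)`.
#' @param training logical; dropout is only active when `TRUE`.
#' @return The next-layer embedding.
#' @export
gcnLayer <- function(B, H, W, nodeDropout = 0, regularDropout = 0,
                     training = FALSE) {
  if (nrow(H) != nrow(B) || ncol(H) != nrow(W))
    stop("non-conformable shapes in GCN layer", call. = FALSE)
  Bt <- applyNodeDropout(B, nodeDropout, training)
  Ht <- applyRegularDropout(H, regularDropout, training)
  .relu(.propagate(Bt, Bref = B) %*% Ht %*% W)
}

#' Layer-attention initialization
#'
#' Every layer's attention scalar starts at `1/(L+1)`; the scalars are then
#' free (unconstrained) learnables.
#'
#' @param L number of GCN layers.
#' @return Numeric vector of length `L`.
#' @export
initAttention <- function(L) rep(1 / (L + 1), L)

#' Combine per-layer embeddings by attention
#'
#' `H = sum_l a_l H^(l)`: a learned weighted sum of the embeddings produced by
#' the successive convolution layers, letting neighbourhoods at different hop
#' distances contribute differently.
#'
#' @param HList list of per-layer embeddings, all the same shape.
#' @param a numeric attention weights, one per layer.
#' @return The combined embedding.
#' @export
attentionCombine <- function(HList, a) {
  if (length(HList) != length(a))
    stop("one attention weight per layer required", call. = FALSE)
  dims <- lapply(HList, dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1L]])))
    stop("per-layer embeddings differ in shape", call. = FALSE)
  out <- a[[1L]] * HList[[1L]]
  for (l in seq_along(HList)[-1L]) out <- out + a[[l]] * HList[[l]]
  out
}

#' Split the combined embedding into piRNA and disease parts
#'
#' @param H combined embedding with `M + N` rows.
#' @param M,N numbers of piRNAs and diseases.
#' @return List with `HP` (first M rows) and `HD` (last N rows).
#' @export
splitEmbeddings <- function(H, M, N) {
  if (nrow(H) != M + N)
    stop("embedding row count does not equal M + N", call. = FALSE)
  list(HP = H[seq_len(M), , drop = FALSE],
       HD = H[M + seq_len(N), , drop = FALSE])
}

#' Embedding transformation (ETG) decoder forward pass
#'
#' Three bias-free dense maps widen and re-compress the piRNA embedding
#' (k -> 2k -> 4k -> k) to carry it into the disease embedding space, with a
#' ReLU after every map. Setting `activation = FALSE` linearizes the decoder
#' (ablation).
#'
#' @param HP piRNA embedding (M x k).
#' @param weights list of the three weight matrices (k x 2k, 2k x 4k, 4k x k).
#' @param biases optional list of three bias vectors (lengths 2k, 4k, k);
#'   empty list for the bias-free reference decoder.
#' @param activation apply ReLU after each map (default `TRUE`).
#' @return Transformed M x k matrix.
#' @export
etgForward <- function(HP, weights, biases = list(), activation = TRUE) {
  X <- HP
  for (i in 1:3) {
    if (ncol(X) != nrow(weights[[i]]))
      stop("ETG weight shape mismatch at layer ", i, call. = FALSE)
    X <- X %*% weights[[i]]
    if (length(biases)) X <- sweep(X, 2L, biases[[i]], "+")
    if (activation) X <- .relu(X)
  }
  X
}

#' ETG decoder parameter count
#'
#' The bias-free decoder has `k*2k + 2k*4k + 4k*k = 14 k^2` weights
#' (`+ 7k` biases when enabled). At the default `k = 16` this is
#' `3584 = 3.50 * 1024` parameters.
#'
#' @param k embedding dimension (>= 1).
#' @param bias count bias terms too.
#' @return Integer parameter count.
#' @examples
#' etgParamCount(16) / 1024   # 3.5
#' @export
etgParamCount <- function(k, bias = FALSE) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  14L * k * k + if (bias) 7L * k else 0L
}

# Row-wise L2 normalization; zero rows stay zero.
.rowNormalize <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  inv <- ifelse(nrm > 0, 1 / nrm, 0)
  X * inv
}

#' Score piRNA-disease pairs from embeddings
#'
#' Cosine mode (default) L2-normalizes the rows of both embeddings before the
#' matrix product, so each score is the cosine similarity of a transformed
#' piRNA embedding and a disease embedding (zero rows score 0). Dot mode is
#' the raw product.
#'
#' @param E transformed piRNA embedding (M x k).
#' @param HD disease embedding (N x k).
#' @param mode `"cosine"` or `"dot"`.
#' @return M x N score matrix.
#' @export
scorePairs <- function(E, HD, mode = c("cosine", "dot")) {
  mode <- match.arg(mode)
  if (mode == "cosine") tcrossprod(.rowNormalize(E), .rowNormalize(HD))
  else tcrossprod(E, HD)
}

# Xavier-uniform weight matrix.
.xavier <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

# Identity-preserving init for the bias-free ReLU decoder: tiled identity
# maps plus small Xavier noise. On non-negative inputs the composition starts
# as (approximately) the identity, so every unit is alive; with a plain
# symmetric init around zero, half the pre-activations of each ReLU layer
# start dead and the bias-free decoder cannot revive them.
.etgInit <- function(k, noise = 0.05) {
  list(cbind(diag(k), diag(k)) + noise * .xavier(k, 2L * k),
       cbind(diag(2L * k), diag(2L * k)) + noise * .xavier(2L * k, 4L * k),
       rbind(diag(k), diag(k), diag(k), diag(k)) / 4 +
         noise * .xavier(4L * k, k))
}

#' Initialize a model
#'
#' GCN weights are Xavier-uniform; the ETG decoder starts as a noisy
#' identity map (tiled identities plus small Xavier noise) so its ReLU units
#' are alive on the non-negative encoder output. Attention scalars start at
#' `1/(L+1)`. All draws come from the run seed's init stream.
#'
#' @param M,N numbers of piRNAs and diseases.
#' @param params a [pdaParams()] list.
#' @return An untrained [PDAModel-class].
#' @export
newPDAModel <- function(M, N, params = pdaParams()) {
  k <- params$embeddingDim; L <- params$gcnLayers
  set.seed(.deriveSeed(params$seed, .streamOffsets[["init"]]))
  gcn <- vector("list", L)
  gcn[[1L]] <- .xavier(M + N, k)
  if (L > 1L) for (l in 2:L) gcn[[l]] <- .xavier(k, k)
  etg <- .etgInit(k)
  biases <- if (params$etgBias)
    list(numeric(2L * k), numeric(4L * k), numeric(k)) else list()
  att <- if (params$useAttention) initAttention(L) else rep(1, L)
  new("PDAModel", gcnWeights = gcn, attention = att, etgWeights = etg,
      etgBiases = biases, params = params, seed = params$seed)
}

# Deterministic full forward pass (no dropout). Returns all intermediates.
.pdaForward <- function(model, B, A) {
  p <- model@params
  M <- nrow(A); N <- ncol(A)
  P <- .propagate(B)
  H0 <- initEmbedding(A)
  HList <- vector("list", length(model@gcnWeights))
  H <- H0
  for (l in seq_along(model@gcnWeights)) {
    H <- .relu(P %*% H %*% model@gcnWeights[[l]])
    HList[[l]] <- H
  }
  Hc <- attentionCombine(HList, model@attention)
  sp <- splitEmbeddings(Hc, M, N)
  E <- etgForward(sp$HP, model@etgWeights, model@etgBiases, p$etgActivation)
  S <- scorePairs(E, sp$HD, p$scoreMode)
  dimnames(S) <- dimnames(A)
  list(HList = HList, H = Hc, HP = sp$HP, HD = sp$HD, E = E, scores = S)
}

#' Predict association scores
#'
#' Runs the deterministic forward pass (encoder, attention, ETG decoder,
#' scoring) of a fitted model over a heterogeneous network.
#'
#' @param model a [PDAModel-class].
#' @param network a [HeteroNetwork-class] (its association block defines the
#'   initial embedding).
#' @param type `"score"` for raw (cosine) scores or `"probability"` for their
#'   sigmoid view in `(0, 1)`.
#' @return M x N matrix with the dataset's id dimnames.
#' @export
predictAssociations <- function(model, network,
                                type = c("score", "probability")) {
  type <- match.arg(type)
  fw <- .pdaForward(model, inputGraph(network), network@assoc)
  if (type == "score") fw$scores else .sigmoid(fw$scores)
}

#' Rank candidate piRNAs for a disease
#'
#' Orders piRNAs by descending predicted score for one disease, ties broken
#' by piRNA id; known positives can be excluded, mirroring how novel
#' candidates are short-listed for literature follow-up.
#'
#' @param scores M x N score matrix with id dimnames.
#' @param diseaseId disease column to rank.
#' @param exclude optional binary association matrix; piRNAs with a known
#'   association to `diseaseId` are dropped from the ranking.
#' @param topK maximum number of rows returned.
#' @return data.frame with columns `pirna_id`, `score`, in rank order.
#' @export
rankCandidates <- function(scores, diseaseId, exclude = NULL, topK = 10L) {
  if (!diseaseId %in% colnames(scores))
    stop(sprintf("unknown disease '%s'", diseaseId), call. = FALSE)
  s <- scores[, diseaseId]
  if (!is.null(exclude)) s <- s[exclude[, diseaseId] == 0]
  ord <- order(-s, names(s))
  out <- data.frame(pirna_id = names(s)[ord], score = unname(s[ord]),
                    stringsAsFactors = FALSE)
  head(out, topK)
}
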