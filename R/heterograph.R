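#' Symmetric degree normalization
#'
#' `D^(-1/2) S D^(-1/2)` with `D = diag(rowSums(S))`. Used to put the fused
#' similarity layers on a common scale before they enter the heterogeneous
#' network.
#'
#' @param S square non-negative matrix with strictly positive row sums.
#' @return The normalized matrix (symmetric if `S` is).
#' @export
symmetricNormalize <- function(S) {
  .stopIfNotSquare(S, "similarity matrix")
  d <- rowSums(S)
  if (any(d <= 0)) {
    who <- if (!is.null(rownames(S))) rownames(S)[d <= 0][1L]
           else paste("row", which(d <= 0)[1L])
    stop(sprintf("zero degree for entity '%s'; cannot normalize", who),
         call. = FALSE)
  }
  inv <- 1 / sqrt(d)
  S * tcrossprod(inv)
}

#' Assemble the heterogeneous adjacency
#'
#' Block matrix `[[NSPG, A], [t(A), NSDG]]` joining the two (normalized)
#' similarity layers through the bipartite association block.
#'
#' @param nspg M x M normalized piRNA similarity.
#' @param nsdg N x N normalized disease similarity.
#' @param A M x N binary association matrix.
#' @return The (M+N) x (M+N) symmetric heterogeneous adjacency.
#' @export
assembleHetero <- function(nspg, nsdg, A) {
  M <- nrow(A); N <- ncol(A)
  if (!identical(dim(nspg), c(M, M)) || !identical(dim(nsdg), c(N, N)))
    stop("block shapes do not match the association matrix", call. = FALSE)
  rbind(cbind(nspg, A), cbind(t(A), nsdg))
}

#' Apply the similarity penalty factor
#'
#' Scales the two similarity blocks of the heterogeneous adjacency by `omega`,
#' leaving the association blocks untouched; `omega` controls how much the
#' similarity layers contribute during graph convolution.
#'
#' @param ah (M+N) x (M+N) heterogeneous adjacency.
#' @param omega penalty factor, >= 0.
#' @param nPirnas M, the size of the leading piRNA block.
#' @return The penalty-weighted input graph `B`.
#' @export
applyPenalty <- function(ah, omega, nPirnas) {
  .stopIfNotSquare(ah, "heterogeneous adjacency")
  if (omega < 0) stop("penalty factor must be non-negative", call. = FALSE)
  M <- nPirnas
  B <- ah
  B[seq_len(M), seq_len(M)] <- omega * ah[seq_len(M), seq_len(M)]
  rest <- (M + 1L):nrow(ah)
  B[rest, rest] <- omega * ah[rest, rest]
  B
}

#' Build the two-layer heterogeneous network
#'
#' Normalizes the fused similarities ([symmetricNormalize()]), assembles the
#' heterogeneous adjacency and applies the penalty factor, returning a
#' [HeteroNetwork-class].
#'
#' @param spg fused piRNA similarity (M x M).
#' @param sdg fused disease similarity (N x N).
#' @param A binary association matrix (M x N).
#' @param omega similarity penalty factor (default 1).
#' @return A [HeteroNetwork-class].
#' @examples
#' A <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("p1","p2"), c("d1","d2")))
#' net <- buildHeteroNetwork(diag(2), diag(2), A)
#' inputGraph(net)
#' @export
buildHeteroNetwork <- function(spg, sdg, A, omega = 1) {
  nspg <- symmetricNormalize(spg)
  nsdg <- symmetricNormalize(sdg)
  ah <- assembleHetero(nspg, nsdg, A)
  b <- applyPenalty(ah, omega, nrow(A))
  new("HeteroNetwork", nspg = nspg, nsdg = nsdg, assoc = A, ah = ah, b = b,
      omega = omega)
}
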