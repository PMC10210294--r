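#' Needleman-Wunsch global alignment score
#'
#' Optimal global alignment score under a linear gap penalty, computed by the
#' full dynamic program (C++ inner loop).
#'
#' @param a,b non-empty sequences over the normalized alphabet.
#' @param match,mismatch,gap scoring scheme (defaults +1 / -1 / -1).
#' @return The raw alignment score (a single number, can be negative).
#' @examples
#' nwScore("ACGT", "ACGT")   # 4
#' nwScore("ACGT", "AGT")    # 2
#' @export
nwScore <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  if (!nzchar(a) || !nzchar(b))
    stop("sequences must be non-empty", call. = FALSE)
  nw_score_cpp(a, b, match, mismatch, gap)
}

#' All-pairs Needleman-Wunsch score matrix
#'
#' @param seqs named character vector of sequences.
#' @inheritParams nwScore
#' @return Symmetric matrix of raw alignment scores, self-alignments on the
#'   diagonal, dimnames from `seqs`.
#' @export
nwScoreMatrix <- function(seqs, match = 1, mismatch = -1, gap = -1) {
  if (any(!nzchar(seqs)))
    stop("sequences must be non-empty", call. = FALSE)
  out <- nw_score_matrix_cpp(unname(seqs), match, mismatch, gap)
  dimnames(out) <- list(names(seqs), names(seqs))
  out
}

#' Min-max standardization of a score matrix
#'
#' Rescales `(x - min) / (max - min)` with the minimum and maximum taken over
#' all entries. A constant matrix is degenerate: all entries become 0, with a
#' warning.
#'
#' @param m finite numeric matrix.
#' @return Matrix with range `[0, 1]` (all zeros if degenerate).
#' @export
minmaxStandardize <- function(m) {
  stopifnot(is.matrix(m))
  if (!all(is.finite(m))) stop("matrix has non-finite entries", call. = FALSE)
  lo <- min(m); hi <- max(m)
  if (hi == lo) {
    warning("degenerate standardization: all entries equal; returning zeros")
    return(array(0, dim(m), dimnames(m)))
  }
  (m - lo) / (hi - lo)
}

#' piRNA sequence similarity matrix
#'
#' Raw Needleman-Wunsch scores for all pairs are min-max standardized over the
#' whole matrix (self-alignments included), then the diagonal is overwritten
#' with 1 (a piRNA is maximally similar to itself by definition).
#'
#' @param seqs named character vector of sequences (one per piRNA).
#' @inheritParams nwScore
#' @return Symmetric similarity matrix in `[0, 1]` with unit diagonal.
#' @export
pirnaSequenceSimilarity <- function(seqs, match = 1, mismatch = -1,
                                    gap = -1) {
  raw <- nwScoreMatrix(seqs, match, mismatch, gap)
  S <- minmaxStandardize(raw)
  diag(S) <- 1
  S
}

#' Gaussian interaction profile (GIP) kernel similarity
#'
#' Similarity between association profiles:
#' `exp(-phi * ||V(a) - V(b)||^2)` where `V` is the row (piRNA axis) or
#' column (disease axis) of the association matrix and the bandwidth
#' `phi = 1 / mean(||V||^2)` over all profiles on that axis.
#'
#' @param A binary association matrix (piRNAs x diseases).
#' @param axis `"pirna"` (rows) or `"disease"` (columns).
#' @return Symmetric similarity matrix with unit diagonal, entries in
#'   `(0, 1]`.
#' @examples
#' A <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("p1", "p2"), c("d1", "d2")))
#' gipKernel(A, "pirna")["p1", "p2"]   # exp(-2)
#' @export
gipKernel <- function(A, axis = c("pirna", "disease")) {
  axis <- match.arg(axis)
  stopifnot(is.matrix(A))
  V <- if (axis == "pirna") A else t(A)
  msq <- mean(rowSums(V^2))
  if (msq == 0)
    stop("all association profiles are zero; GIP bandwidth undefined",
         call. = FALSE)
  phi <- 1 / msq
  d2 <- as.matrix(dist(V))^2
  G <- exp(-phi * d2)
  dimnames(G) <- list(rownames(V), rownames(V))
  G
}

#' Fuse a primary similarity with its GIP fallback
#'
#' Elementwise selection: where both entities have primary data (sequence or
#' DAG membership) the primary similarity is used, otherwise the GIP kernel.
#' The mask is data availability, not a value threshold.
#'
#' @param primary square similarity matrix (entries where `mask` is `FALSE`
#'   are ignored and may be `NA`).
#' @param gip GIP kernel matrix of the same shape.
#' @param mask logical matrix, `TRUE` where the primary similarity is defined;
#'   defaults to all-`TRUE`.
#' @return Fused symmetric similarity matrix with unit diagonal.
#' @export
fuseSimilarity <- function(primary, gip, mask = NULL) {
  stopifnot(is.matrix(primary), is.matrix(gip))
  if (!identical(dim(primary), dim(gip)))
    stop("primary and GIP matrices differ in shape", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, dim(primary))
  if (!identical(dim(mask), dim(primary)))
    stop("mask shape mismatch", call. = FALSE)
  out <- ifelse(mask, primary, gip)
  diag(out) <- 1
  dimnames(out) <- dimnames(gip)
  out
}

#' Availability mask for similarity fusion
#'
#' @param ids entity identifiers in matrix order.
#' @param available identifiers for which primary data (a sequence, or DAG
#'   membership) exists.
#' @return Logical matrix, `TRUE` where both entities are available.
#' @export
availabilityMask <- function(ids, available) {
  has <- ids %in% available
  outer(has, has, "&")
}

#' Compute the full similarity bundle for a dataset
#'
#' Computes (as available) the sequence similarity `SP`, the semantic
#' similarity `SD`, the two GIP kernels `Gp`/`Gd` from the supplied
#' association matrix, and the fused matrices `SPG`/`SDG`. piRNAs without a
#' sequence and diseases absent from the DAG fall back to the GIP kernel via
#' the availability masks.
#'
#' @param dataset a [PDADataset-class].
#' @param params a [pdaParams()] list (alignment scheme, contribution factor).
#' @param A association matrix to compute GIP kernels from; defaults to the
#'   dataset's full matrix. During cross-validation pass the training-fold
#'   matrix here so held-out positives never leak into the kernels.
#' @param seqSim,semSim optional precomputed `SP` / `SD` blocks (they do not
#'   depend on `A`, so cross-validation computes them once).
#' @return List with elements `SP`, `Gp`, `SPG`, `SD`, `Gd`, `SDG`,
#'   `maskP`, `maskD` (`SP`/`SD` may be `NULL` when no sequences / no DAG).
#' @export
similarityBundle <- function(dataset, params = pdaParams(),
                             A = associationMatrix(dataset),
                             seqSim = NULL, semSim = NULL) {
  pids <- pirnaIds(dataset); dids <- diseaseIds(dataset)
  Gp <- gipKernel(A, "pirna")
  Gd <- gipKernel(A, "disease")

  seqs <- pirnaSequences(dataset)
  withSeq <- intersect(pids, names(seqs))
  SP <- seqSim
  if (is.null(SP) && length(withSeq) >= 2L) {
    SP <- matrix(NA_real_, length(pids), length(pids),
                 dimnames = list(pids, pids))
    SP[withSeq, withSeq] <- pirnaSequenceSimilarity(
      seqs[withSeq], params$nwMatch, params$nwMismatch, params$nwGap)
  }
  maskP <- availabilityMask(pids, withSeq)
  SPG <- if (is.null(SP)) fuseSimilarity(Gp, Gp)
         else fuseSimilarity(SP, Gp, maskP)

  dag <- diseaseDAG(dataset)
  inDag <- if (is.null(dag)) character() else intersect(dids, dagNodes(dag))
  SD <- semSim
  if (is.null(SD) && length(inDag) >= 2L) {
    SD <- matrix(NA_real_, length(dids), length(dids),
                 dimnames = list(dids, dids))
    SD[inDag, inDag] <- semanticSimilarityMatrix(dag, inDag,
                                                 params$contributionFactor)
  }
  maskD <- availabilityMask(dids, inDag)
  SDG <- if (is.null(SD)) fuseSimilarity(Gd, Gd)
         else fuseSimilarity(SD, Gd, maskD)

  list(SP = SP, Gp = Gp, SPG = SPG, SD = SD, Gd = Gd, SDG = SDG,
       maskP = maskP, maskD = maskD)
}
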