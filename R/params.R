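#' Hyper-parameters for the association model
#'
#' Collects and validates every tunable parameter of the pipeline. Defaults
#' follow the values reported as best-performing for the method (embedding
#' dimension 16, maximum cyclic learning rate 0.01, node dropout 0.6, regular
#' dropout 0.4, semantic contribution factor 0.5) and documented package
#' choices for the rest (see the methods vignette).
#'
#' @param embeddingDim k, the embedding dimension of the GCN output (>= 1).
#' @param gcnLayers L, number of graph convolution layers (>= 1).
#' @param penalty omega, factor scaling the similarity blocks in the GCN input
#'   graph (>= 0).
#' @param lrMax maximum of the triangular cyclic learning rate.
#' @param lrBase minimum of the cyclic learning rate (default `lrMax / 10`).
#' @param epochs number of full-graph training epochs (>= 0).
#' @param cycleLen cyclic learning-rate period in epochs (default
#'   `max(epochs %/% 4, 2)`).
#' @param nodeDropout probability of dropping a graph edge during training,
#'   in `[0, 1)`.
#' @param regularDropout probability of dropping an embedding entry during
#'   training, in `[0, 1)`.
#' @param nwMatch,nwMismatch,nwGap Needleman-Wunsch scoring scheme (linear
#'   gap penalty).
#' @param contributionFactor Delta, per-layer decay of ancestor contributions
#'   in the DAG semantic similarity, in `(0, 1]`.
#' @param threshold probability threshold for accuracy/recall/specificity.
#' @param scoreMode `"cosine"` (row-normalized product, the default) or
#'   `"dot"` (raw product).
#' @param useAttention if `FALSE`, layers are combined by a plain unweighted
#'   sum instead of learned attention scalars (ablation).
#' @param etgActivation if `FALSE`, the ETG decoder drops its ReLU
#'   non-linearities and becomes linear (ablation).
#' @param etgBias if `TRUE`, the ETG decoder layers carry bias terms (off by
#'   default; the bias-free decoder is the reference architecture).
#' @param negativeSet negatives used for test metrics: `"all_unknown"` (every
#'   unknown pair) or `"sampled_1to1"` (as many sampled negatives as
#'   positives).
#' @param seed integer run seed; every random draw in the pipeline derives
#'   from it.
#'
#' @return A validated named list of class `PDAParams`.
#' @examples
#' p <- pdaParams(embeddingDim = 8, epochs = 50, seed = 7)
#' p$embeddingDim
#' @export
pdaParams <- function(embeddingDim = 16L, gcnLayers = 3L, penalty = 1,
                      lrMax = 0.01, lrBase = lrMax / 10, epochs = 400L,
                      cycleLen = NULL, nodeDropout = 0.6,
                      regularDropout = 0.4, nwMatch = 1, nwMismatch = -1,
                      nwGap = -1, contributionFactor = 0.5, threshold = 0.5,
                      scoreMode = c("cosine", "dot"), useAttention = TRUE,
                      etgActivation = TRUE, etgBias = FALSE,
                      negativeSet = c("all_unknown", "sampled_1to1"),
                      seed = 1L) {
  scoreMode <- match.arg(scoreMode)
  negativeSet <- match.arg(negativeSet)
  embeddingDim <- as.integer(embeddingDim)
  gcnLayers <- as.integer(gcnLayers)
  epochs <- as.integer(epochs)
  if (is.null(cycleLen)) cycleLen <- max(epochs %/% 4L, 2L)
  cycleLen <- as.integer(cycleLen)
  stopifnot(embeddingDim >= 1L, gcnLayers >= 1L, penalty >= 0,
            lrBase <= lrMax, lrBase > 0, epochs >= 0L, cycleLen >= 2L,
            nodeDropout >= 0, nodeDropout < 1,
            regularDropout >= 0, regularDropout < 1,
            contributionFactor > 0, contributionFactor <= 1,
            threshold > 0, threshold < 1)
  structure(list(
    embeddingDim = embeddingDim, gcnLayers = gcnLayers, penalty = penalty,
    lrMax = lrMax, lrBase = lrBase, epochs = epochs, cycleLen = cycleLen,
    nodeDropout = nodeDropout, regularDropout = regularDropout,
    nwMatch = nwMatch, nwMismatch = nwMismatch, nwGap = nwGap,
    contributionFactor = contributionFactor, threshold = threshold,
    scoreMode = scoreMode, useAttention = useAttention,
    etgActivation = etgActivation, etgBias = etgBias,
    negativeSet = negativeSet, seed = as.integer(seed)),
    class = "PDAParams")
}

#' @export
print.PDAParams <- function(x, ...) {
  cat("PDAParams:\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
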