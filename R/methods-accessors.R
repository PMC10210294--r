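#' @rdname pdaGCN-accessors
setMethod("associationMatrix", "PDADataset", function(x) x@assoc)

#' @rdname pdaGCN-accessors
setMethod("pirnaIds", "PDADataset", function(x) rownames(x@assoc))

#' @rdname pdaGCN-accessors
setMethod("diseaseIds", "PDADataset", function(x) colnames(x@assoc))

#' @rdname pdaGCN-accessors
setMethod("pirnaSequences", "PDADataset", function(x) x@sequences)

#' @rdname pdaGCN-accessors
setMethod("diseaseDAG", "PDADataset", function(x) x@dag)

#' @rdname pdaGCN-accessors
setMethod("positivePairs", "PDADataset", function(x) {
  idx <- which(x@assoc == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  dimnames(idx) <- list(NULL, c("pirna", "disease"))
  idx
})

#' @rdname pdaGCN-accessors
setMethod("positiveCount", "PDADataset", function(x) sum(x@assoc == 1))

#' @rdname pdaGCN-accessors
setMethod("unknownCount", "PDADataset",
  function(x) length(x@assoc) - sum(x@assoc == 1))

#' @rdname pdaGCN-accessors
setMethod("dagNodes", "DiseaseDAG", function(x) x@nodes)

#' @rdname pdaGCN-accessors
setMethod("inputGraph", "HeteroNetwork", function(x) x@b)

#' @rdname pdaGCN-accessors
setMethod("heteroAdjacency", "HeteroNetwork", function(x) x@ah)

#' @rdname pdaGCN-accessors
setMethod("syntheticDataset", "SyntheticWorld", function(x) x@dataset)

#' @rdname pdaGCN-accessors
setMethod("pirnaClusters", "SyntheticWorld", function(x) x@pirnaClusters)

#' @rdname pdaGCN-accessors
setMethod("diseaseClusters", "SyntheticWorld", function(x) x@diseaseClusters)

#' @rdname pdaGCN-accessors
setMethod("hiddenPositives", "SyntheticWorld", function(x) x@hiddenPositives)

setMethod("show", "PDADataset", function(object) {
  A <- object@assoc
  cat(sprintf("PDADataset: %d piRNAs x %d diseases\n", nrow(A), ncol(A)))
  cat(sprintf("  known associations: %d (density %.2f%%)\n",
              sum(A == 1), 100 * mean(A == 1)))
  cat(sprintf("  sequences: %d of %d piRNAs\n",
              sum(rownames(A) %in% names(object@sequences)), nrow(A)))
  if (is.null(object@dag)) {
    cat("  disease DAG: none\n")
  } else {
    cat(sprintf("  disease DAG: %d nodes (%d of %d diseases present)\n",
                length(object@dag@nodes),
                sum(colnames(A) %in% object@dag@nodes), ncol(A)))
  }
})

setMethod("show", "DiseaseDAG", function(object) {
  nEdges <- sum(lengths(object@parents))
  cat(sprintf("DiseaseDAG: %d nodes, %d child->parent edges\n",
              length(object@nodes), nEdges))
})

setMethod("show", "HeteroNetwork", function(object) {
  M <- nrow(object@assoc); N <- ncol(object@assoc)
  cat(sprintf("HeteroNetwork: %d piRNAs + %d diseases (omega = %g)\n",
              M, N, object@omega))
})

setMethod("show", "PDAModel", function(object) {
  L <- length(object@gcnWeights)
  k <- ncol(object@gcnWeights[[1L]])
  cat(sprintf("PDAModel: %d-layer GCN encoder, embedding dim %d\n", L, k))
  cat(sprintf("  attention weights: %s\n",
              paste(sprintf("%.3f", object@attention), collapse = ", ")))
  cat(sprintf("  ETG decoder: %d -> %d -> %d -> %d (%s)\n",
              k, 2L * k, 4L * k, k,
              if (length(object@etgBiases)) "with bias" else "bias-free"))
})

setMethod("show", "SyntheticWorld", function(object) {
  cat(sprintf("SyntheticWorld (seed %d)\n", object@seed))
  show(object@dataset)
  cat(sprintf("  planted clusters: %d piRNA x %d disease; %d hidden positives\n",
              length(unique(object@pirnaClusters)),
              length(unique(object@diseaseClusters)),
              nrow(object@hiddenPositives)))
})
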