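#' @import methods
#' @importFrom stats rnorm runif setNames dist rbinom
#' @importFrom utils head write.table read.table
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))
setOldClass("PDAParams")

#' Disease directed acyclic graph
#'
#' Holds a MeSH-style disease hierarchy as a child-to-parent edge set over a
#' node vocabulary. Semantic similarity between diseases is computed from the
#' ancestor closure of each node with layer-wise decayed contributions
#' (see [semanticSimilarity()]).
#'
#' @slot nodes character vector of node identifiers (diseases and internal
#'   hierarchy terms).
#' @slot parents named list; for each node, the character vector of its direct
#'   parents (possibly empty).
#'
#' @seealso [DiseaseDAG()], [ancestors()], [dagContributions()]
#' @exportClass DiseaseDAG
setClass("DiseaseDAG",
  representation(nodes = "character", parents = "list"))

setValidity("DiseaseDAG", function(object) {
  msgs <- character()
  if (anyDuplicated(object@nodes))
    msgs <- c(msgs, "duplicated node identifiers")
  if (!all(names(object@parents) %in% object@nodes))
    msgs <- c(msgs, "parents list names outside node set")
  allp <- unlist(object@parents, use.names = FALSE)
  if (length(allp) && !all(allp %in% object@nodes))
    msgs <- c(msgs, "edge endpoint missing from node set")
  cyc <- .findCycleNode(object@nodes, object@parents)
  if (!is.null(cyc))
    msgs <- c(msgs, sprintf("cycle detected involving node '%s'", cyc))
  if (length(msgs)) msgs else TRUE
})

setClassUnion("DiseaseDAGOrNULL", c("DiseaseDAG", "NULL"))

#' piRNA-disease association dataset
#'
#' The central data container: a binary association matrix with piRNAs as rows
#' and diseases as columns, optionally accompanied by piRNA sequences and a
#' disease DAG. Row/column order is the identifier vocabulary order and is
#' never reordered by sequence or DAG inputs.
#'
#' @slot assoc binary (0/1) matrix, rows = piRNAs, columns = diseases, with
#'   identifier dimnames.
#' @slot sequences named character vector of piRNA sequences over
#'   \code{A,C,G,T,N} (may cover only a subset of the piRNAs; piRNAs without a
#'   sequence fall back to the Gaussian interaction profile kernel).
#' @slot dag a [DiseaseDAG-class] or `NULL`; diseases absent from the DAG fall
#'   back to the GIP kernel.
#'
#' @seealso [PDADataset()], [readAssociations()], [benchmarkWorld()]
#' @exportClass PDADataset
setClass("PDADataset",
  representation(assoc = "matrix", sequences = "character",
                 dag = "DiseaseDAGOrNULL"))

setValidity("PDADataset", function(object) {
  A <- object@assoc
  msgs <- character()
  if (is.null(rownames(A)) || is.null(colnames(A)))
    msgs <- c(msgs, "association matrix must carry id dimnames")
  else {
    if (anyDuplicated(rownames(A))) msgs <- c(msgs, "duplicated piRNA ids")
    if (anyDuplicated(colnames(A))) msgs <- c(msgs, "duplicated disease ids")
  }
  if (!all(A %in% c(0, 1)))
    msgs <- c(msgs, "association matrix entries must be 0 or 1")
  if (length(object@sequences) && is.null(names(object@sequences)))
    msgs <- c(msgs, "sequences must be named by piRNA id")
  if (length(msgs)) msgs else TRUE
})

#' Two-layer heterogeneous network
#'
#' Block matrix combining the normalized fused piRNA similarity, the normalized
#' fused disease similarity, and the bipartite association matrix, together
#' with the penalty-weighted input graph used by the graph convolutional
#' encoder.
#'
#' @slot nspg normalized fused piRNA similarity (M x M).
#' @slot nsdg normalized fused disease similarity (N x N).
#' @slot assoc binary association matrix (M x N).
#' @slot ah the heterogeneous adjacency \code{[[NSPG, A], [t(A), NSDG]]}.
#' @slot b the GCN input graph: `ah` with the similarity blocks scaled by the
#'   penalty factor `omega`.
#' @slot omega similarity penalty factor (>= 0).
#'
#' @seealso [buildHeteroNetwork()]
#' @exportClass HeteroNetwork
setClass("HeteroNetwork",
  representation(nspg = "matrix", nsdg = "matrix", assoc = "matrix",
                 ah = "matrix", b = "matrix", omega = "numeric"))

setValidity("HeteroNetwork", function(object) {
  M <- nrow(object@assoc); N <- ncol(object@assoc)
  msgs <- character()
  if (!identical(dim(object@nspg), c(M, M)))
    msgs <- c(msgs, "piRNA similarity block has wrong shape")
  if (!identical(dim(object@nsdg), c(N, N)))
    msgs <- c(msgs, "disease similarity block has wrong shape")
  if (!identical(dim(object@ah), c(M + N, M + N)))
    msgs <- c(msgs, "heterogeneous adjacency has wrong shape")
  if (length(object@omega) != 1L || object@omega < 0)
    msgs <- c(msgs, "omega must be a single non-negative number")
  if (max(abs(object@ah - t(object@ah))) > 1e-9)
    msgs <- c(msgs, "heterogeneous adjacency not symmetric")
  if (length(msgs)) msgs else TRUE
})

#' Fitted association model
#'
#' Weights of the layer-attention GCN encoder and the embedding transformation
#' (ETG) decoder, plus the hyper-parameters and seed they were created with.
#'
#' @slot gcnWeights list of L weight matrices; the first maps (M+N) -> k, the
#'   rest k -> k.
#' @slot attention numeric vector of L layer-attention scalars (initialized to
#'   1/(L+1) each).
#' @slot etgWeights list of the three bias-free dense maps k -> 2k -> 4k -> k.
#' @slot etgBiases list of three bias vectors, or empty list when the decoder
#'   is bias-free (the default).
#' @slot params hyper-parameter list (see [pdaParams()]).
#' @slot seed integer seed the weights were initialized from.
#'
#' @seealso [newPDAModel()], [trainPDAModel()], [predictAssociations()]
#' @exportClass PDAModel
setClass("PDAModel",
  representation(gcnWeights = "list", attention = "numeric",
                 etgWeights = "list", etgBiases = "list",
                 params = "PDAParams", seed = "integer"))

setValidity("PDAModel", function(object) {
  msgs <- character()
  if (length(object@gcnWeights) != length(object@attention))
    msgs <- c(msgs, "one attention scalar per GCN layer required")
  if (length(object@etgWeights) != 3L)
    msgs <- c(msgs, "ETG decoder must have exactly three weight matrices")
  if (!all(vapply(object@gcnWeights, function(w) all(is.finite(w)), TRUE)))
    msgs <- c(msgs, "non-finite GCN weights")
  k <- ncol(object@gcnWeights[[1L]])
  dims <- vapply(object@etgWeights, dim, integer(2))
  if (!identical(as.vector(dims), c(k, 2L*k, 2L*k, 4L*k, 4L*k, k)))
    msgs <- c(msgs, "ETG dims must be k -> 2k -> 4k -> k")
  if (length(msgs)) msgs else TRUE
})

#' Synthetic benchmark world
#'
#' A fully self-contained synthetic dataset (sequences, disease DAG,
#' associations) with planted, recoverable cluster structure, plus the ground
#' truth used to generate it.
#'
#' @slot dataset the generated [PDADataset-class].
#' @slot pirnaClusters named integer vector of latent piRNA cluster labels.
#' @slot diseaseClusters named integer vector of latent disease cluster labels.
#' @slot affinity cluster-affinity matrix of Bernoulli association rates.
#' @slot hiddenPositives integer matrix (rows = pairs, columns = piRNA/disease
#'   index) of positives drawn but withheld from the association matrix.
#' @slot seed generation seed.
#' @slot genParams list of generator parameters.
#'
#' @seealso [benchmarkWorld()]
#' @exportClass SyntheticWorld
setClass("SyntheticWorld",
  representation(dataset = "PDADataset", pirnaClusters = "integer",
                 diseaseClusters = "integer", affinity = "matrix",
                 hiddenPositives = "matrix", seed = "integer",
                 genParams = "list"))
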