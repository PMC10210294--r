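#' @name pdaGCN-accessors
#' @title Accessors for pdaGCN data classes
#'
#' @description Accessor generics for the [PDADataset-class],
#' [DiseaseDAG-class], [HeteroNetwork-class] and [SyntheticWorld-class]
#' containers. All user code should go through these rather than slots.
#'
#' @param x an object of the relevant class.
#' @param node a node identifier (for `ancestors`).
#' @return The requested component: matrices, id vectors, counts, or index
#'   pairs as documented per method.
NULL

#' @rdname pdaGCN-accessors
#' @export
setGeneric("associationMatrix", function(x) standardGeneric("associationMatrix"))

#' @rdname pdaGCN-accessors
#' @export
setGeneric("pirnaIds", function(x) standardGeneric("pirnaIds"))

#' @rdname pdaGCN-accessors
#' @export
setGeneric("diseaseIds", function(x) standardGeneric("diseaseIds"))

#' @rdname pdaGCN-accessors
#' @export
setGeneric("pirnaSequences", function(x) standardGeneric("pirnaSequences"))

#' @rdname pdaGCN-accessors
#' @export
setGeneric("diseaseDAG", function(x) standardGeneric("diseaseDAG"))

#' @rdname pdaGCN-accessors
#' @export
setGeneric("positivePairs", function(x) standardGeneric("positivePairs"))

#' @rdname pdaGCN-accessors
#' @export
setGeneric("positiveCount", function(x) standardGeneric("positiveCount"))

#' @rdname pdaGCN-accessors
#' @export
setGeneric("unknownCount", function(x) standardGeneric("unknownCount"))

#' @rdname pdaGCN-accessors
#' @export
setGeneric("dagNodes", function(x) standardGeneric("dagNodes"))

#' @rdname pdaGCN-accessors
#' @export
setGeneric("ancestors", function(x, node) standardGeneric("ancestors"))

#' @rdname pdaGCN-accessors
#' @export
setGeneric("inputGraph", function(x) standardGeneric("inputGraph"))

#' @rdname pdaGCN-accessors
#' @export
setGeneric("heteroAdjacency", function(x) standardGeneric("heteroAdjacency"))

#' @rdname pdaGCN-accessors
#' @export
setGeneric("syntheticDataset", function(x) standardGeneric("syntheticDataset"))

#' @rdname pdaGCN-accessors
#' @export
setGeneric("pirnaClusters", function(x) standardGeneric("pirnaClusters"))

#' @rdname pdaGCN-accessors
#' @export
setGeneric("diseaseClusters", function(x) standardGeneric("diseaseClusters"))

#' @rdname pdaGCN-accessors
#' @export
setGeneric("hiddenPositives", function(x) standardGeneric("hiddenPositives"))
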