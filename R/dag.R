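#' Construct a disease DAG
#'
#' @param nodes character vector of node identifiers; endpoints of `edges` are
#'   added automatically.
#' @param edges two-column character matrix or data.frame of child -> parent
#'   edges (may have zero rows).
#'
#' @return A validated [DiseaseDAG-class].
#' @examples
#' dag <- DiseaseDAG(edges = cbind(c("d1", "d2"), c("root", "root")))
#' ancestors(dag, "d1")
#' @export
DiseaseDAG <- function(nodes = character(), edges = NULL) {
  parents <- list()
  if (!is.null(edges)) {
    edges <- as.matrix(edges)
    if (ncol(edges) < 2L)
      stop("edges must have two columns (child, parent)", call. = FALSE)
    storage.mode(edges) <- "character"
    nodes <- union(nodes, c(edges[, 1L], edges[, 2L]))
    parents <- split(edges[, 2L], factor(edges[, 1L], levels = unique(edges[, 1L])))
    parents <- lapply(parents, unique)
  }
  nodes <- unique(nodes)
  missing <- setdiff(nodes, names(parents))
  parents[missing] <- replicate(length(missing), character(), simplify = FALSE)
  new("DiseaseDAG", nodes = nodes, parents = parents[nodes])
}

#' @rdname pdaGCN-accessors
setMethod("ancestors", "DiseaseDAG", function(x, node) {
  if (!node %in% x@nodes)
    stop(sprintf("node '%s' not in DAG", node), call. = FALSE)
  seen <- node
  frontier <- node
  while (length(frontier)) {
    ps <- unique(unlist(x@parents[frontier], use.names = FALSE))
    frontier <- setdiff(ps, seen)
    seen <- c(seen, frontier)
  }
  seen
})

#' Semantic contribution values of a disease's ancestor set
#'
#' The disease itself contributes 1; each step up the hierarchy decays the
#' contribution by the factor `delta`, and a node reachable along several
#' paths keeps the largest (least-decayed) contribution, i.e.
#' `delta^d` where `d` is the shortest hop distance from the disease.
#'
#' @param dag a [DiseaseDAG-class].
#' @param disease a node identifier present in the DAG.
#' @param delta semantic contribution factor in `(0, 1]` (default 0.5).
#'
#' @return Named numeric vector of contributions over the disease's ancestor
#'   closure (the disease included, value 1).
#' @examples
#' dag <- DiseaseDAG(edges = cbind("d1", "root"))
#' dagContributions(dag, "d1")   # d1 = 1, root = 0.5
#' @export
dagContributions <- function(dag, disease, delta = 0.5) {
  stopifnot(is(dag, "DiseaseDAG"), delta > 0, delta <= 1)
  if (!disease %in% dag@nodes)
    stop(sprintf("disease '%s' not in DAG", disease), call. = FALSE)
  dist <- setNames(0L, disease)
  frontier <- disease
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    ps <- setdiff(unique(unlist(dag@parents[frontier], use.names = FALSE)),
                  names(dist))
    if (length(ps)) dist[ps] <- d
    frontier <- ps
  }
  setNames(delta ^ as.numeric(dist), names(dist))
}

#' DAG semantic similarity between two diseases
#'
#' Wang-style measure: the ancestor closures of the two diseases are scored
#' with decayed contributions ([dagContributions()]); similarity is the summed
#' contribution of shared ancestors from both sides, normalized by the total
#' contribution mass of the two closures. Identical diseases score 1; diseases
#' whose closures share no node score 0.
#'
#' @param dag a [DiseaseDAG-class].
#' @param da,db disease identifiers present in the DAG.
#' @param delta semantic contribution factor in `(0, 1]`.
#'
#' @return A similarity value in `[0, 1]`.
#' @examples
#' dag <- DiseaseDAG(edges = cbind(c("d1", "d2"), c("root", "root")))
#' semanticSimilarity(dag, "d1", "d2")   # shared root only: 1/3
#' @export
semanticSimilarity <- function(dag, da, db, delta = 0.5) {
  if (identical(da, db)) {
    if (!da %in% dag@nodes)
      stop(sprintf("disease '%s' not in DAG", da), call. = FALSE)
    return(1)
  }
  dva <- dagContributions(dag, da, delta)
  dvb <- dagContributions(dag, db, delta)
  common <- intersect(names(dva), names(dvb))
  if (!length(common)) return(0)
  (sum(dva[common]) + sum(dvb[common])) / (sum(dva) + sum(dvb))
}

#' Pairwise semantic similarity matrix
#'
#' @param dag a [DiseaseDAG-class].
#' @param diseases identifiers to score (all must be in the DAG).
#' @param delta semantic contribution factor.
#'
#' @return Symmetric matrix in `[0, 1]` with unit diagonal, dimnames =
#'   `diseases`.
#' @export
semanticSimilarityMatrix <- function(dag, diseases, delta = 0.5) {
  dv <- lapply(setNames(nm = diseases), dagContributions, dag = dag,
               delta = delta)
  tot <- vapply(dv, sum, 0)
  n <- length(diseases)
  S <- diag(1, n)
  dimnames(S) <- list(diseases, diseases)
  if (n < 2L) return(S)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    common <- intersect(names(dv[[i]]), names(dv[[j]]))
    s <- if (length(common))
      (sum(dv[[i]][common]) + sum(dv[[j]][common])) / (tot[[i]] + tot[[j]])
    else 0
    S[i, j] <- S[j, i] <- s
  }
  S
}
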