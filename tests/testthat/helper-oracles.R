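# Independent oracles used to validate the package implementations.
# Each is deliberately written by a different method than the code it checks.

# Global alignment score by exhaustive enumeration of all alignments
# (exponential; only for short sequences).
bruteNW <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  rec <- function(i, j) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv))
      best <- max(best,
                  (if (av[i] == bv[j]) match else mismatch) + rec(i + 1L, j + 1L))
    if (i <= length(av)) best <- max(best, gap + rec(i + 1L, j))
    if (j <= length(bv)) best <- max(best, gap + rec(i, j + 1L))
    best
  }
  rec(1L, 1L)
}

# Ancestor closure by plain recursive DFS over the parent lists.
dfsAncestors <- function(parents, node) {
  seen <- character()
  visit <- function(n) {
    if (n %in% seen) return(invisible())
    seen <<- c(seen, n)
    for (p in parents[[n]]) visit(p)
  }
  visit(node)
  sort(seen)
}

# Contribution map by exhaustive path enumeration: every upward path is
# walked and each node keeps max(delta^pathlen) over all paths reaching it.
bruteDV <- function(parents, node, delta = 0.5) {
  dv <- setNames(1, node)
  walk <- function(n, depth) {
    for (p in parents[[n]]) {
      v <- delta ^ (depth + 1L)
      if (is.na(dv[p]) || v > dv[p]) dv[p] <<- v
      walk(p, depth + 1L)
    }
  }
  walk(node, 0L)
  dv
}

bruteSemantic <- function(parents, da, db, delta = 0.5) {
  if (identical(da, db)) return(1)
  dva <- bruteDV(parents, da, delta)
  dvb <- bruteDV(parents, db, delta)
  common <- intersect(names(dva), names(dvb))
  if (!length(common)) return(0)
  (sum(dva[common]) + sum(dvb[common])) / (sum(dva) + sum(dvb))
}

# Random DAG as a parents list: node i may only point at lower-numbered
# nodes, which guarantees acyclicity.
randomParents <- function(nNodes) {
  nodes <- paste0("n", seq_len(nNodes))
  parents <- setNames(vector("list", nNodes), nodes)
  for (i in seq_len(nNodes)) {
    parents[[i]] <- if (i == 1L) character()
    else nodes[sample.int(i - 1L, min(sample(0:2, 1L), i - 1L))]
  }
  parents
}

parentsToDAG <- function(parents) {
  edges <- do.call(rbind, lapply(names(parents), function(ch) {
    if (length(parents[[ch]])) cbind(ch, parents[[ch]]) else NULL
  }))
  DiseaseDAG(nodes = names(parents), edges = edges)
}

# AUC by direct pairwise comparison (Mann-Whitney definition).
bruteAUC <- function(pos, neg) {
  cmp <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
  mean(cmp)
}
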