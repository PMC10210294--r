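# Internal numeric/RNG helpers shared across modules.

.relu <- function(x) x * (x > 0)

.sigmoid <- function(x) 1 / (1 + exp(-x))

# Derive a substream seed from a run seed; stays below 2^31 - 1. Offsets keep
# the streams (weight init, node dropout, regular dropout, fold split,
# generators) separated so changing one consumer never shifts another.
.deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(offset)) %% 2147483647)
}

.streamOffsets <- c(init = 101L, nodeDropout = 202L, regularDropout = 303L,
                    foldSplit = 404L, sequences = 505L, dag = 606L,
                    associations = 707L, repeats = 808L, negatives = 909L)

.stopIfNotSquare <- function(m, what) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(what, " must be a square matrix", call. = FALSE)
}

.currentRNG <- function() get(".Random.seed", envir = globalenv())

.restoreRNG <- function(state)
  assign(".Random.seed", state, envir = globalenv())

# Kahn's algorithm on child->parent edges; returns NULL if acyclic,
# otherwise the name of one node on a cycle.
.findCycleNode <- function(nodes, parents) {
  if (!length(nodes)) return(NULL)
  parents <- parents[intersect(names(parents), nodes)]
  outdeg <- setNames(integer(length(nodes)), nodes)   # edges node -> parent
  children <- lapply(setNames(nm = nodes), function(n) character())
  for (child in names(parents)) {
    ps <- parents[[child]]
    outdeg[child] <- length(ps)
    for (p in ps) children[[p]] <- c(children[[p]], child)
  }
  queue <- names(outdeg)[outdeg == 0L]
  seen <- 0L
  while (length(queue)) {
    n <- queue[[1L]]; queue <- queue[-1L]
    seen <- seen + 1L
    for (ch in children[[n]]) {
      outdeg[ch] <- outdeg[ch] - 1L
      if (outdeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen == length(nodes)) NULL else names(outdeg)[outdeg > 0L][1L]
}
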