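#' Construct a piRNA-disease dataset
#'
#' @param assoc binary matrix with piRNA ids as rownames and disease ids as
#'   colnames, or a two-column character matrix/data.frame of (piRNA id,
#'   disease id) positive pairs.
#' @param sequences optional named character vector of piRNA sequences (see
#'   [readPirnaFasta()] for normalization rules; applied here too).
#' @param dag optional [DiseaseDAG-class].
#'
#' @return A validated [PDADataset-class]. When `assoc` is a pair list, the
#'   row/column vocabularies are built in first-appearance order and duplicate
#'   pairs collapse to a single positive.
#' @examples
#' d <- PDADataset(cbind(c("p1", "p1", "p2"), c("d1", "d1", "d2")))
#' associationMatrix(d)
#' @export
PDADataset <- function(assoc, sequences = character(), dag = NULL) {
  if (!is.matrix(assoc) || !is.numeric(assoc)) {
    pairs <- as.matrix(assoc)
    storage.mode(pairs) <- "character"
    if (ncol(pairs) < 2L)
      stop("association pairs need two columns", call. = FALSE)
    pids <- unique(pairs[, 1L])
    dids <- unique(pairs[, 2L])
    A <- matrix(0, length(pids), length(dids), dimnames = list(pids, dids))
    A[cbind(match(pairs[, 1L], pids), match(pairs[, 2L], dids))] <- 1
    assoc <- A
  }
  storage.mode(assoc) <- "double"
  if (length(sequences)) sequences <- .normalizeSequences(sequences)
  new("PDADataset", assoc = assoc, sequences = sequences, dag = dag)
}

#' Read known piRNA-disease associations
#'
#' Reads a two-column tab-separated file of (piRNA id, disease id) pairs.
#' Duplicate pairs collapse to a single positive; identifier vocabularies are
#' built in first-appearance order, which fixes the row/column order of the
#' association matrix.
#'
#' @param path path to the TSV file (no header; extra columns ignored).
#' @param sequences,dag optional sequence map / disease DAG attached to the
#'   returned dataset.
#'
#' @return A [PDADataset-class].
#' @seealso [writeScores()], [PDADataset()]
#' @export
readAssociations <- function(path, sequences = character(), dag = NULL) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  if (!any(keep))
    stop(sprintf("association file '%s' is empty", path), call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  pairs <- matrix(character(), 0L, 2L)
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    f <- trimws(fields[[i]])
    if (length(f) < 2L || !nzchar(f[1L]) || !nzchar(f[2L]))
      stop(sprintf("malformed association line %d in '%s'", i, path),
           call. = FALSE)
    rows[[i]] <- f[1:2]
  }
  pairs <- do.call(rbind, rows[keep])
  PDADataset(pairs, sequences = sequences, dag = dag)
}

.normalizeSequences <- function(seqs) {
  out <- chartr("u", "T", chartr("U", "T", toupper(seqs)))
  bad <- grepl("[^ACGTN]", out)
  if (any(bad))
    stop(sprintf("sequence '%s' contains characters outside A,C,G,T,U,N",
                 names(out)[bad][1L]), call. = FALSE)
  if (anyDuplicated(names(out))) {
    for (id in unique(names(out)[duplicated(names(out))])) {
      v <- unique(out[names(out) == id])
      if (length(v) > 1L)
        stop(sprintf("conflicting sequences for id '%s'", id), call. = FALSE)
    }
    out <- out[!duplicated(names(out))]
  }
  out
}

#' Read piRNA sequences from FASTA
#'
#' Sequences are upper-cased and U is mapped to T so RNA and DNA records share
#' one alphabet for alignment. Duplicate ids carrying the same sequence are
#' collapsed; conflicting duplicates are an error. Identifiers are the first
#' whitespace-delimited token of each header.
#'
#' @param path FASTA file path.
#' @return Named character vector over the alphabet `A,C,G,T,N` (empty for an
#'   empty file).
#' @export
readPirnaFasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (!length(ss)) return(setNames(character(), character()))
  ids <- sub("\\s.*$", "", names(ss))
  .normalizeSequences(setNames(as.character(ss), ids))
}

#' Read a disease DAG from a child-parent edge list
#'
#' @param path TSV file of `child<TAB>parent` edges (no header). An empty file
#'   yields a DAG containing only `nodes`.
#' @param nodes additional (possibly isolated) node identifiers.
#' @return A validated, acyclic [DiseaseDAG-class]; a cycle is an error naming
#'   a node on it.
#' @export
readDiseaseDAG <- function(path, nodes = character()) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) return(DiseaseDAG(nodes = nodes))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(vapply(fields, function(f)
    length(f) < 2L || !nzchar(trimws(f[1L])) || !nzchar(trimws(f[2L])), TRUE))
  if (length(bad))
    stop(sprintf("malformed DAG edge line %d in '%s'", keep[bad[1L]], path),
         call. = FALSE)
  edges <- t(vapply(fields, function(f) trimws(f[1:2]), character(2)))
  DiseaseDAG(nodes = nodes, edges = edges)
}

#' Write association scores as TSV
#'
#' Rows are ordered by disease (vocabulary order), then descending score,
#' ties broken by piRNA id.
#'
#' @param scores M x N score matrix with id dimnames; all entries finite.
#' @param path output path.
#' @return Invisibly, the written data.frame with columns
#'   `pirna_id`, `disease_id`, `score`.
#' @export
writeScores <- function(scores, path) {
  stopifnot(is.matrix(scores))
  if (!all(is.finite(scores)))
    stop("scores contain non-finite values", call. = FALSE)
  df <- data.frame(
    pirna_id = rep(rownames(scores), times = ncol(scores)),
    disease_id = rep(colnames(scores), each = nrow(scores)),
    score = as.vector(scores), stringsAsFactors = FALSE)
  ord <- order(match(df$disease_id, colnames(scores)), -df$score, df$pirna_id)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Write a metrics report as JSON
#'
#' @param report a metrics report list (see [crossValidate()]) or any
#'   JSON-serializable list.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeMetrics <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Save / load a fitted model checkpoint
#'
#' Checkpoints are plain JSON: every weight matrix, the attention scalars,
#' hyper-parameters and seed, so a run can be reproduced or resumed anywhere.
#'
#' @param model a [PDAModel-class].
#' @param path checkpoint path (JSON).
#' @return `saveModel` invisibly returns `path`; `loadModel` returns the
#'   reconstructed [PDAModel-class].
#' @export
saveModel <- function(model, path) {
  payload <- list(
    gcnWeights = lapply(model@gcnWeights, unname),
    attention = model@attention,
    etgWeights = lapply(model@etgWeights, unname),
    etgBiases = lapply(model@etgBiases, unname),
    params = unclass(model@params),
    seed = model@seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  toMat <- function(m) if (is.matrix(m)) m else matrix(m, nrow = 1L)
  params <- do.call(pdaParams, x$params[setdiff(names(x$params), character())])
  new("PDAModel",
      gcnWeights = lapply(x$gcnWeights, toMat),
      attention = as.numeric(x$attention),
      etgWeights = lapply(x$etgWeights, toMat),
      etgBiases = if (length(x$etgBiases)) lapply(x$etgBiases, as.numeric)
                  else list(),
      params = params, seed = as.integer(x$seed))
}
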