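#' Generate clustered piRNA sequences
#'
#' Random sequences over A/C/G/T with one random motif per cluster implanted
#' at a random position, so piRNAs of the same cluster are detectably more
#' similar under global alignment than piRNAs of different clusters.
#'
#' @param n number of sequences (>= `nClusters`).
#' @param lengthRange integer range of sequence lengths (default 26-32,
#'   typical piRNA lengths).
#' @param nClusters number of planted clusters.
#' @param motifLen implanted motif length (must fit the shortest sequence).
#' @param seed integer seed.
#' @param ids sequence identifiers (default `pir-0001`...).
#' @return List: `sequences` (named character), `clusters` (named integer),
#'   `motifs` (per-cluster motif strings).
#' @export
genSequences <- function(n, lengthRange = c(26L, 32L), nClusters = 3L,
                         motifLen = 8L, seed = 1L,
                         ids = sprintf("pir-%04d", seq_len(n))) {
  stopifnot(n >= nClusters, nClusters >= 1L)
  if (motifLen > min(lengthRange))
    stop("motif longer than the shortest sequence", call. = FALSE)
  set.seed(.deriveSeed(seed, .streamOffsets[["sequences"]]))
  bases <- c("A", "C", "G", "T")
  motifs <- vapply(seq_len(nClusters), function(i)
    paste(sample(bases, motifLen, replace = TRUE), collapse = ""), "")
  clusters <- setNames(rep_len(seq_len(nClusters), n), ids)
  seqs <- vapply(seq_len(n), function(i) {
    len <- sample(seq(lengthRange[1L], lengthRange[2L]), 1L)
    s <- sample(bases, len, replace = TRUE)
    pos <- sample(len - motifLen + 1L, 1L)
    s[pos:(pos + motifLen - 1L)] <- strsplit(motifs[clusters[i]], "")[[1L]]
    paste(s, collapse = "")
  }, "")
  list(sequences = setNames(seqs, ids), clusters = clusters, motifs = motifs)
}

#' Generate a clustered disease DAG
#'
#' One root; each cluster hangs its diseases under its own chain of `depth`
#' internal hub nodes, so diseases of the same cluster share at least their
#' hub(s) and the root as common ancestors and score higher semantic
#' similarity within than between clusters.
#'
#' @param nDiseases number of disease leaves (>= `nClusters`).
#' @param nClusters number of planted clusters.
#' @param depth number of internal hub levels per cluster (>= 1).
#' @param seed integer seed (fixes the disease-to-cluster assignment).
#' @param ids disease identifiers (default `DIS01`...).
#' @return List: `dag` (a [DiseaseDAG-class]), `clusters` (named integer).
#' @export
genDAG <- function(nDiseases, nClusters = 3L, depth = 2L, seed = 1L,
                   ids = sprintf("DIS%02d", seq_len(nDiseases))) {
  stopifnot(nDiseases >= nClusters, nClusters >= 1L, depth >= 1L)
  set.seed(.deriveSeed(seed, .streamOffsets[["dag"]]))
  clusters <- setNames(sample(rep_len(seq_len(nClusters), nDiseases)), ids)
  edges <- list()
  for (cl in seq_len(nClusters)) {
    hubs <- sprintf("HUB%d_%d", cl, seq_len(depth))
    edges[[length(edges) + 1L]] <- cbind(hubs, c("ROOT", hubs[-depth]))
    leaves <- ids[clusters == cl]
    edges[[length(edges) + 1L]] <- cbind(leaves, hubs[depth])
  }
  list(dag = DiseaseDAG(edges = do.call(rbind, edges)), clusters = clusters)
}

#' Draw associations from a cluster-affinity table
#'
#' Each (piRNA, disease) pair is an independent Bernoulli draw with rate
#' `affinity[pirnaCluster, diseaseCluster]`. Optionally a fraction of the
#' drawn positives is withheld from the returned matrix and reported as
#' evaluation ground truth.
#'
#' @param pirnaClusters,diseaseClusters named integer cluster labels.
#' @param affinity matrix of Bernoulli rates in `[0, 1]`.
#' @param seed integer seed.
#' @param hideFraction fraction of drawn positives withheld (default 0).
#' @return List: `assoc` (binary matrix with id dimnames), `hidden`
#'   (integer matrix of withheld positive index pairs).
#' @export
genAssociations <- function(pirnaClusters, diseaseClusters, affinity,
                            seed = 1L, hideFraction = 0) {
  stopifnot(all(affinity >= 0), all(affinity <= 1),
            hideFraction >= 0, hideFraction < 1)
  set.seed(.deriveSeed(seed, .streamOffsets[["associations"]]))
  M <- length(pirnaClusters); N <- length(diseaseClusters)
  rates <- affinity[pirnaClusters, diseaseClusters, drop = FALSE]
  A <- matrix(rbinom(M * N, 1L, as.vector(rates)), M, N,
              dimnames = list(names(pirnaClusters), names(diseaseClusters)))
  hidden <- matrix(integer(), 0L, 2L,
                   dimnames = list(NULL, c("pirna", "disease")))
  if (hideFraction > 0 && any(A == 1)) {
    posIdx <- which(A == 1, arr.ind = TRUE)
    nHide <- floor(nrow(posIdx) * hideFraction)
    if (nHide > 0L) {
      pick <- sample(nrow(posIdx), nHide)
      hidden <- posIdx[pick, , drop = FALSE]
      dimnames(hidden) <- list(NULL, c("pirna", "disease"))
      A[hidden] <- 0L
    }
  }
  list(assoc = A, hidden = hidden)
}

#' Benchmark synthetic worlds
#'
#' Complete self-contained datasets with planted cluster structure. The
#' `small` preset (60 piRNAs x 8 diseases, 2 x 2 clusters) is sized for unit
#' tests; `default` (500 piRNAs x 20 diseases, 3 x 3 clusters, affinity 0.70
#' within / 0.002 off block, 20% of positives withheld) exercises the whole
#' pipeline on a planted signal strong enough to be recoverable: with
#' three-way blocks, held-out positives are statistically exchangeable with
#' within-block negatives, so the within-block rate bounds the attainable
#' AUC (see the methods vignette for the ceiling analysis behind these
#' rates).
#'
#' @param preset `"small"` or `"default"`.
#' @param seed integer seed; regeneration from the same seed and preset is
#'   bit-identical.
#' @return A [SyntheticWorld-class].
#' @examples
#' w <- benchmarkWorld("small", seed = 3)
#' syntheticDataset(w)
#' @export
benchmarkWorld <- function(preset = c("small", "default"), seed = 1L) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    small = list(nPirnas = 60L, nDiseases = 8L, nClusters = 2L,
                 within = 0.40, between = 0.05, hideFraction = 0,
                 depth = 2L, motifLen = 8L, lengthRange = c(26L, 32L)),
    default = list(nPirnas = 500L, nDiseases = 20L, nClusters = 3L,
                   within = 0.70, between = 0.002, hideFraction = 0.2,
                   depth = 2L, motifLen = 8L, lengthRange = c(26L, 32L)))
  sq <- genSequences(cfg$nPirnas, cfg$lengthRange, cfg$nClusters,
                     cfg$motifLen, seed)
  dg <- genDAG(cfg$nDiseases, cfg$nClusters, cfg$depth, seed)
  affinity <- matrix(cfg$between, cfg$nClusters, cfg$nClusters)
  diag(affinity) <- cfg$within
  as <- genAssociations(sq$clusters, dg$clusters, affinity, seed,
                        cfg$hideFraction)
  dataset <- PDADataset(as$assoc, sequences = sq$sequences, dag = dg$dag)
  new("SyntheticWorld", dataset = dataset,
      pirnaClusters = sq$clusters, diseaseClusters = dg$clusters,
      affinity = affinity, hiddenPositives = as$hidden,
      seed = as.integer(seed), genParams = cfg)
}

#' Write a synthetic world to disk
#'
#' Emits the three input files every pipeline stage reads — a FASTA of
#' sequences, a TSV of association pairs, a TSV of DAG edges — plus a JSON
#' file with the generation ground truth.
#'
#' @param world a [SyntheticWorld-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
writeWorld <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- syntheticDataset(world)
  paths <- c(fasta = file.path(dir, "pirna_sequences.fasta"),
             assoc = file.path(dir, "associations.tsv"),
             dag = file.path(dir, "disease_dag.tsv"),
             truth = file.path(dir, "truth.json"))
  seqs <- pirnaSequences(ds)
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), paths["fasta"])
  pp <- positivePairs(ds)
  writeLines(paste(pirnaIds(ds)[pp[, 1L]], diseaseIds(ds)[pp[, 2L]],
                   sep = "\t"), paths["assoc"])
  dag <- diseaseDAG(ds)
  edges <- do.call(rbind, lapply(names(dag@parents), function(ch) {
    if (length(dag@parents[[ch]])) cbind(ch, dag@parents[[ch]]) else NULL
  }))
  writeLines(paste(edges[, 1L], edges[, 2L], sep = "\t"), paths["dag"])
  hp <- hiddenPositives(world)
  jsonlite::write_json(list(
    seed = world@seed, params = world@genParams,
    affinity = world@affinity,
    pirnaClusters = as.list(pirnaClusters(world)),
    diseaseClusters = as.list(diseaseClusters(world)),
    hiddenPositives = data.frame(
      pirna_id = pirnaIds(ds)[hp[, 1L]],
      disease_id = diseaseIds(ds)[hp[, 2L]])),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
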