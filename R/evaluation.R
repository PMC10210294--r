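#' Split known positives into cross-validation folds
#'
#' Seeded shuffle followed by round-robin assignment, so fold sizes differ by
#' at most one (e.g. 5002 positives over 5 folds give sizes
#' 1001, 1001, 1000, 1000, 1000).
#'
#' @param positives matrix of positive pairs (rows), as from
#'   [positivePairs()].
#' @param k number of folds (default 5).
#' @param seed integer seed; the same seed always yields the same split.
#' @return List with `assignment` (fold id per positive row), `folds` (list of
#'   row-index vectors), `k`, `seed`.
#' @export
makeFolds <- function(positives, k = 5L, seed = 1L) {
  n <- nrow(positives)
  if (n < k)
    stop(sprintf("%d positives cannot fill %d folds", n, k), call. = FALSE)
  set.seed(.deriveSeed(seed, .streamOffsets[["foldSplit"]]))
  perm <- sample.int(n)
  assignment <- integer(n)
  assignment[perm] <- rep_len(seq_len(k), n)
  list(assignment = assignment,
       folds = split(seq_len(n), assignment), k = as.integer(k),
       seed = as.integer(seed))
}

#' Classification metrics for scored pairs
#'
#' AUC is computed by the midrank statistic (equivalent to the normalized
#' Mann-Whitney U, deterministic under ties); accuracy, recall and
#' specificity come from the confusion matrix at the given probability
#' threshold.
#'
#' @param posScores,negScores probability scores of the positive / negative
#'   pairs (both non-empty).
#' @param threshold decision threshold (default 0.5).
#' @return Named list: `auc`, `accuracy`, `recall`, `specificity`, `nPos`,
#'   `nNeg`, `threshold`.
#' @examples
#' computeMetrics(c(0.9, 0.4), c(0.6, 0.1))   # auc 0.75
#' @export
computeMetrics <- function(posScores, negScores, threshold = 0.5) {
  np <- length(posScores); nn <- length(negScores)
  if (np == 0L || nn == 0L)
    stop("need at least one positive and one negative score", call. = FALSE)
  r <- rank(c(posScores, negScores))
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
  tp <- sum(posScores >= threshold)
  tn <- sum(negScores < threshold)
  list(auc = auc,
       accuracy = (tp + tn) / (np + nn),
       recall = tp / np,
       specificity = tn / nn,
       nPos = np, nNeg = nn, threshold = threshold)
}

#' Training network for one cross-validation fold
#'
#' Masks the held-out test positives to zero in the association matrix and
#' recomputes everything downstream of it — both GIP kernels, the fused
#' similarities and the heterogeneous network — from the masked matrix, so no
#' information about the test pairs leaks into training. The sequence and
#' semantic similarity blocks do not depend on the association matrix and may
#' be passed in precomputed.
#'
#' @param dataset a [PDADataset-class] (full data).
#' @param testPairs matrix of held-out positive pairs (piRNA index, disease
#'   index rows).
#' @param params a [pdaParams()] list.
#' @param seqSim,semSim optional precomputed similarity blocks (see
#'   [similarityBundle()]).
#' @return List: `Atrain`, `bundle` (the fold's similarity bundle), `network`
#'   (a [HeteroNetwork-class]).
#' @export
foldNetwork <- function(dataset, testPairs, params = pdaParams(),
                        seqSim = NULL, semSim = NULL) {
  Atrain <- associationMatrix(dataset)
  Atrain[testPairs[, 1:2, drop = FALSE]] <- 0
  bundle <- similarityBundle(dataset, params, A = Atrain,
                             seqSim = seqSim, semSim = semSim)
  network <- buildHeteroNetwork(bundle$SPG, bundle$SDG, Atrain,
                                params$penalty)
  list(Atrain = Atrain, bundle = bundle, network = network)
}

#' Repeated five-fold cross-validation
#'
#' For each repeat and fold: the test positives are masked out of the
#' association matrix, the GIP kernels / fusions / heterogeneous network are
#' recomputed from the training matrix ([foldNetwork()]), a model is trained,
#' and the held-out positives are scored against the unknown pairs. Per-fold
#' AUC, accuracy, recall and specificity are reported together with their
#' grand means. Each repeat derives its own fold-split and training seeds from
#' `params$seed`, so the whole report is reproducible.
#'
#' @param dataset a [PDADataset-class].
#' @param params a [pdaParams()] list.
#' @param repeats number of independent repetitions of the 5-fold procedure.
#' @param k number of folds.
#' @param scorer optional override, mainly for testing the harness: a
#'   `function(Atrain, network, params)` returning an M x N probability
#'   matrix, used instead of training a model.
#' @param verbose print per-fold progress.
#' @return List of class `PDAMetrics`: `perFold` data.frame (`rep`, `fold`,
#'   `auc`, `accuracy`, `recall`, `specificity`, `nTest`), `summary` (grand
#'   means), `threshold`, `repeats`, `k`, `seed`.
#' @export
crossValidate <- function(dataset, params = pdaParams(), repeats = 1L,
                          k = 5L, scorer = NULL, verbose = FALSE) {
  A <- associationMatrix(dataset)
  positives <- positivePairs(dataset)
  unknown <- A == 0

  # A-independent similarity blocks, computed once
  base <- similarityBundle(dataset, params)
  rows <- list()
  for (r in seq_len(repeats)) {
    repSeed <- .deriveSeed(params$seed, .streamOffsets[["repeats"]] + r)
    split <- makeFolds(positives, k = k, seed = repSeed)
    for (f in seq_len(k)) {
      testPairs <- positives[split$folds[[f]], , drop = FALSE]
      fn <- foldNetwork(dataset, testPairs, params,
                        seqSim = base$SP, semSim = base$SD)
      foldParams <- params
      foldParams$seed <- .deriveSeed(repSeed, f)
      prob <- if (is.null(scorer)) {
        fit <- trainPDAModel(fn$network, foldParams)
        .sigmoid(.pdaForward(fit$model, inputGraph(fn$network),
                             fn$Atrain)$scores)
      } else {
        scorer(fn$Atrain, fn$network, foldParams)
      }
      posScores <- prob[testPairs[, 1:2, drop = FALSE]]
      negIdx <- which(unknown)
      if (params$negativeSet == "sampled_1to1") {
        set.seed(.deriveSeed(foldParams$seed,
                             .streamOffsets[["negatives"]]))
        negIdx <- sample(negIdx, min(length(posScores), length(negIdx)))
      }
      met <- computeMetrics(posScores, prob[negIdx], params$threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        rep = r, fold = f, auc = met$auc, accuracy = met$accuracy,
        recall = met$recall, specificity = met$specificity,
        nTest = met$nPos)
      if (verbose)
        message(sprintf("rep %d fold %d: AUC %.4f", r, f, met$auc))
    }
  }
  perFold <- do.call(rbind, rows)
  summary <- as.list(colMeans(perFold[c("auc", "accuracy", "recall",
                                        "specificity")]))
  structure(list(perFold = perFold, summary = summary,
                 threshold = params$threshold, repeats = repeats, k = k,
                 seed = params$seed),
            class = "PDAMetrics")
}

#' @export
print.PDAMetrics <- function(x, ...) {
  cat(sprintf("Cross-validation: %d repeat(s) x %d folds (seed %d)\n",
              x$repeats, x$k, x$seed))
  cat(sprintf("  mean AUC %.4f | accuracy %.4f | recall %.4f | specificity %.4f\n",
              x$summary$auc, x$summary$accuracy, x$summary$recall,
              x$summary$specificity))
  invisible(x)
}
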