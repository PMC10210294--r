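test_that("association reading collapses duplicates and orders vocabularies", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("p1\td1", "p1\td1", "p2\td2"), path)
  d <- readAssociations(path)
  expect_identical(pirnaIds(d), c("p1", "p2"))
  expect_identical(diseaseIds(d), c("d1", "d2"))
  expect_equal(positiveCount(d), 2)
  expect_equal(unname(associationMatrix(d)), matrix(c(1, 0, 0, 1), 2))

  writeLines("p1\td1", path)
  expect_equal(unname(associationMatrix(readAssociations(path))),
               matrix(1, 1, 1))
})

test_that("malformed and empty association files are rejected with context", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("p1\td1", "orphan"), path)
  expect_error(readAssociations(path), "line 2")
  writeLines(character(), path)
  expect_error(readAssociations(path), "empty")
})

test_that("positive and unknown pair counts always partition the grid", {
  path <- withr::local_tempfile(fileext = ".tsv")
  set.seed(11)
  for (i in 1:5) {
    np <- sample(3:20, 1)
    pairs <- cbind(paste0("p", sample(8, np, TRUE)),
                   paste0("d", sample(4, np, TRUE)))
    writeLines(paste(pairs[, 1], pairs[, 2], sep = "\t"), path)
    d <- readAssociations(path)
    A <- associationMatrix(d)
    expect_equal(positiveCount(d) + unknownCount(d), nrow(A) * ncol(A))
    expect_equal(positiveCount(d), nrow(unique(pairs)))
  }
})

test_that("reading a written association table reproduces the matrix exactly", {
  w <- smallWorld()
  dir <- withr::local_tempdir()
  paths <- writeWorld(w, dir)
  # a pair list carries only entities with at least one positive ...
  d1 <- readAssociations(paths[["assoc"]])
  A <- associationMatrix(syntheticDataset(w))
  expect_identical(associationMatrix(d1),
                   A[pirnaIds(d1), diseaseIds(d1)])
  # ... and re-reading a table's own written pairs is exactly idempotent
  again <- file.path(dir, "again.tsv")
  pp <- positivePairs(d1)
  writeLines(paste(pirnaIds(d1)[pp[, 1]], diseaseIds(d1)[pp[, 2]],
                   sep = "\t"), again)
  expect_identical(associationMatrix(readAssociations(again)),
                   associationMatrix(d1))
})

test_that("FASTA reading normalizes case and RNA alphabet", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "acgu", ">p2 some description", "UUGG"), path)
  seqs <- readPirnaFasta(path)
  expect_identical(seqs, c(p1 = "ACGT", p2 = "TTGG"))

  writeLines(character(), path)
  expect_length(readPirnaFasta(path), 0)

  writeLines(c(">p1", "ACGT", ">p1", "ACGT", ">p2", "GG"), path)
  expect_identical(readPirnaFasta(path), c(p1 = "ACGT", p2 = "GG"))

  writeLines(c(">p1", "ACGT", ">p1", "ACGA"), path)
  expect_error(readPirnaFasta(path), "conflicting")
})

test_that("DAG reading builds ancestor closures and rejects cycles", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("d1\troot", path)
  dag <- readDiseaseDAG(path)
  expect_setequal(ancestors(dag, "d1"), c("d1", "root"))

  writeLines(character(), path)
  expect_identical(ancestors(readDiseaseDAG(path, nodes = "d1"), "d1"), "d1")

  writeLines(c("d\tc", "c\tb", "b\ta"), path)
  expect_length(ancestors(readDiseaseDAG(path), "d"), 4)

  writeLines(c("a\tb", "b\tc", "c\ta"), path)
  expect_error(readDiseaseDAG(path), "cycle")
})

test_that("score files are ordered by disease, descending score, then id", {
  path <- withr::local_tempfile(fileext = ".tsv")
  s <- matrix(0.7, 1, 1, dimnames = list("p1", "d1"))
  df <- writeScores(s, path)
  expect_equal(nrow(df), 1)
  expect_equal(df$score, 0.7)

  s <- matrix(c(0.5, 0.5, 0.9, 0.1), 2, 2,
              dimnames = list(c("pB", "pA"), c("d1", "d2")))
  df <- writeScores(s, path)
  # equal scores within d1 break ties by piRNA id
  expect_identical(df$pirna_id[1:2], c("pA", "pB"))
  expect_identical(df$pirna_id[3:4], c("pB", "pA"))

  s[1, 1] <- NaN
  expect_error(writeScores(s, path), "non-finite")
})

test_that("metrics reports round-trip through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  rep <- list(auc = 1.0, accuracy = 0.5, recall = 0.25, specificity = 0.75)
  writeMetrics(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back[names(rep)], rep)
})

test_that("model checkpoints round-trip through JSON", {
  p <- pdaParams(embeddingDim = 4L, gcnLayers = 2L, epochs = 0L, seed = 9L)
  m <- newPDAModel(6, 3, p)
  path <- withr::local_tempfile(fileext = ".json")
  saveModel(m, path)
  m2 <- loadModel(path)
  expect_equal(m2@gcnWeights, lapply(m@gcnWeights, unname))
  expect_equal(m2@etgWeights, lapply(m@etgWeights, unname))
  expect_equal(m2@attention, m@attention)
  expect_equal(m2@params$embeddingDim, 4L)
})
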