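test_that("alignment scores match hand-checked cases", {
  expect_equal(nwScore("ACGT", "ACGT"), 4)
  expect_equal(nwScore("A", "T"), -1)   # one mismatch beats two gaps
  expect_equal(nwScore("ACGT", "AGT"), 2)
  expect_error(nwScore("", "ACGT"), "non-empty")
})

test_that("alignment scores agree with exhaustive enumeration", {
  set.seed(101)
  bases <- c("A", "C", "G", "T")
  for (i in 1:60) {
    a <- paste(sample(bases, sample(1:8, 1), TRUE), collapse = "")
    b <- paste(sample(bases, sample(1:8, 1), TRUE), collapse = "")
    sc <- sample(c(1, 2), 1)
    expect_equal(nwScore(a, b, sc, -sc, -1), bruteNW(a, b, sc, -sc, -1),
                 tolerance = 1e-12)
  }
})

test_that("alignment scores agree with Biostrings global alignment", {
  set.seed(55)
  bases <- c("A", "C", "G", "T")
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (i in 1:10) {
    a <- paste(sample(bases, sample(10:25, 1), TRUE), collapse = "")
    b <- paste(sample(bases, sample(10:25, 1), TRUE), collapse = "")
    ref <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = sub,
                                         gapOpening = 0, gapExtension = 1,
                                         scoreOnly = TRUE)
    expect_equal(nwScore(a, b), ref)
  }
})

test_that("min-max standardization maps to [0,1] and flags degeneracy", {
  expect_equal(minmaxStandardize(matrix(c(2, 6, 4, 8), 2)),
               matrix(c(0, 2/3, 1/3, 1), 2))
  expect_warning(z <- minmaxStandardize(matrix(5, 3, 3)), "degenerate")
  expect_equal(z, matrix(0, 3, 3))
  set.seed(2)
  m <- matrix(rnorm(25), 5)
  s <- minmaxStandardize(m)
  expect_equal(range(s), c(0, 1))
})

test_that("sequence similarity has unit diagonal and maximal identical pairs", {
  seqs <- c(a = "ACGTACGTAC", b = "ACGTACGTAC", c = "TTTTGGGGCC",
            d = "CAGTCGATCG")
  S <- pirnaSequenceSimilarity(seqs)
  expect_equal(unname(diag(S)), rep(1, 4))
  expect_equal(S, t(S))
  off <- S[upper.tri(S)]
  expect_equal(S["a", "b"], max(off))
  # a single sequence is a degenerate (constant) raw matrix, flagged
  expect_warning(one <- pirnaSequenceSimilarity(c(x = "ACGT")),
                 "degenerate")
  expect_equal(unname(one), matrix(1, 1, 1))
})

test_that("GIP kernel matches hand evaluation and is equivariant", {
  A <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("p1", "p2"), c("d1", "d2")))
  G <- gipKernel(A, "pirna")
  # phi = 1 / mean(1, 1) = 1; squared profile distance = 2
  expect_equal(G["p1", "p2"], exp(-2))
  expect_equal(unname(diag(G)), c(1, 1))

  set.seed(7)
  A <- matrix(rbinom(40, 1, 0.4), 8, 5,
              dimnames = list(paste0("p", 1:8), paste0("d", 1:5)))
  A[1, ] <- 1   # ensure nonzero profiles exist
  G <- gipKernel(A, "pirna")
  expect_equal(G, t(G))
  perm <- sample(8)
  Gp <- gipKernel(A[perm, ], "pirna")
  expect_equal(Gp, G[perm, perm])

  expect_error(gipKernel(matrix(0, 3, 3)), "bandwidth")
})

test_that("identical association profiles always score GIP similarity 1", {
  A <- matrix(c(1, 1, 0, 0, 1, 1), 2, 3, byrow = TRUE,
              dimnames = list(c("p1", "p2"), paste0("d", 1:3)))
  A[2, ] <- A[1, ]
  expect_equal(gipKernel(A, "pirna")["p1", "p2"], 1)
})

test_that("DAG contributions decay per layer and take the best path", {
  lone <- DiseaseDAG(nodes = "d")
  expect_equal(dagContributions(lone, "d"), c(d = 1))

  dag <- DiseaseDAG(edges = cbind("d", "parent"))
  expect_equal(dagContributions(dag, "d", 0.5), c(d = 1, parent = 0.5))

  # diamond: d -> m -> r and d -> r directly; r keeps max(0.5, 0.25)
  dag <- DiseaseDAG(edges = rbind(c("d", "m"), c("m", "r"), c("d", "r")))
  dv <- dagContributions(dag, "d", 0.5)
  expect_equal(dv[["r"]], 0.5)
  expect_error(dagContributions(dag, "absent"), "not in DAG")
})

test_that("semantic similarity matches hand evaluation", {
  dag <- DiseaseDAG(edges = rbind(c("d1", "r"), c("d2", "r")))
  expect_equal(semanticSimilarity(dag, "d1", "d1"), 1)
  # DV sums are 1.5 each; shared node r contributes 0.5 + 0.5
  expect_equal(semanticSimilarity(dag, "d1", "d2", 0.5), 1 / 3)

  disjoint <- DiseaseDAG(edges = rbind(c("d1", "r1"), c("d2", "r2")))
  expect_equal(semanticSimilarity(disjoint, "d1", "d2"), 0)
})

test_that("semantic similarity agrees with the path-enumeration oracle", {
  set.seed(303)
  for (i in 1:100) {
    parents <- randomParents(sample(3:12, 1))
    dag <- parentsToDAG(parents)
    picks <- sample(names(parents), 2)
    delta <- sample(c(0.25, 0.5, 0.8), 1)
    expect_equal(semanticSimilarity(dag, picks[1], picks[2], delta),
                 bruteSemantic(parents, picks[1], picks[2], delta),
                 tolerance = 1e-9)
    expect_setequal(ancestors(dag, picks[1]),
                    dfsAncestors(parents, picks[1]))
  }
})

test_that("fusion selects primary where available, GIP elsewhere", {
  primary <- matrix(0.9, 3, 3); diag(primary) <- 1
  gip <- matrix(0.2, 3, 3); diag(gip) <- 1
  expect_equal(fuseSimilarity(primary, gip), {
    out <- primary; dimnames(out) <- NULL; out
  })
  allFalse <- matrix(FALSE, 3, 3)
  f <- fuseSimilarity(primary, gip, allFalse)
  expect_equal(f[1, 2], 0.2)
  expect_equal(diag(f), rep(1, 3))

  set.seed(4)
  mask <- availabilityMask(paste0("p", 1:3), c("p1", "p3"))
  f <- fuseSimilarity(primary, gip, mask)
  for (i in 1:3) for (j in 1:3) {
    if (i == j) expect_equal(f[i, j], 1)
    else expect_equal(f[i, j], if (mask[i, j]) primary[i, j] else gip[i, j])
  }
  expect_error(fuseSimilarity(primary, gip[1:2, 1:2]), "shape")
})

test_that("all fused similarity matrices are symmetric, unit-diagonal, in [0,1]", {
  w <- smallWorld()
  b <- similarityBundle(syntheticDataset(w), pdaParams())
  for (nm in c("Gp", "SPG", "Gd", "SDG")) {
    m <- b[[nm]]
    expect_lt(max(abs(m - t(m))), 1e-9)
    expect_true(all(m >= 0 & m <= 1))
    expect_equal(unname(diag(m)), rep(1, nrow(m)))
  }
})
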