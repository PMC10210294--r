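test_that("initial embedding is the symmetric association block matrix", {
  expect_equal(initEmbedding(matrix(1, 1, 1)), matrix(c(0, 1, 1, 0), 2))
  expect_equal(initEmbedding(matrix(0, 2, 3)), matrix(0, 5, 5))
  set.seed(8)
  A <- matrix(rbinom(12, 1, 0.5), 4, 3)
  H0 <- initEmbedding(A)
  expect_equal(H0, t(H0))
  expect_equal(H0[1:4, 5:7], A)
  expect_equal(H0[1:4, 1:4], matrix(0, 4, 4))
})

test_that("a GCN layer equals its dense-matrix definition", {
  H <- matrix(c(1, 2, 0, 3), 2)
  expect_equal(gcnLayer(diag(2), H, diag(2)), H)
  expect_equal(gcnLayer(diag(2), H, matrix(0, 2, 2)), matrix(0, 2, 2))

  set.seed(9)
  B <- matrix(runif(25, 0.1, 1), 5); B <- (B + t(B)) / 2
  H <- matrix(rnorm(15), 5, 3)
  W <- matrix(rnorm(6), 3, 2)
  d <- rowSums(B)
  ref <- pmax(diag(1/sqrt(d)) %*% B %*% diag(1/sqrt(d)) %*% H %*% W, 0)
  expect_equal(gcnLayer(B, H, W), ref)
  expect_error(gcnLayer(B, H[1:3, ], W), "conformable")
})

test_that("attention combination is the weighted layer sum", {
  H1 <- matrix(1:6, 2)
  expect_equal(attentionCombine(list(H1), 1), H1)
  expect_equal(initAttention(2), c(1/3, 1/3))
  expect_equal(initAttention(3), rep(0.25, 3))

  set.seed(10)
  HL <- replicate(3, matrix(rnorm(8), 2), simplify = FALSE)
  a <- rnorm(3)
  ref <- 0 * HL[[1]]
  for (l in 1:3) for (i in seq_along(ref))
    ref[i] <- ref[i] + a[l] * HL[[l]][i]
  expect_equal(attentionCombine(HL, a), ref)
  expect_error(attentionCombine(HL[1:2], a), "one attention weight")
})

test_that("embedding split returns the piRNA and disease rows", {
  H <- matrix(1:35, 7, 5)
  sp <- splitEmbeddings(H, 4, 3)
  expect_equal(sp$HP, H[1:4, ])
  expect_equal(sp$HD, H[5:7, ])
  expect_equal(rbind(sp$HP, sp$HD), H)
  expect_error(splitEmbeddings(H, 4, 4), "M \\+ N")
})

test_that("the ETG decoder composes three maps with ReLU at each layer", {
  k <- 2
  Ws <- list(matrix(0, k, 2 * k), matrix(0, 2 * k, 4 * k),
             matrix(0, 4 * k, k))
  expect_equal(etgForward(matrix(0, 3, k), Ws), matrix(0, 3, k))

  # identity-like weights padded with zeros pass nonneg input through
  W1 <- matrix(0, k, 2 * k); W1[1, 1] <- 1; W1[2, 2] <- 1
  W2 <- matrix(0, 2 * k, 4 * k); W2[1, 1] <- 1; W2[2, 2] <- 1
  W3 <- matrix(0, 4 * k, k); W3[1, 1] <- 1; W3[2, 2] <- 1
  X <- matrix(c(1, 2, 3, 4), 2)
  expect_equal(etgForward(X, list(W1, W2, W3)), X)

  set.seed(12)
  Ws <- list(matrix(rnorm(8), 2, 4), matrix(rnorm(32), 4, 8),
             matrix(rnorm(16), 8, 2))
  X <- matrix(rnorm(10), 5, 2)
  ref <- X
  for (i in 1:3) ref <- pmax(ref %*% Ws[[i]], 0)
  expect_equal(etgForward(X, Ws), ref)
  refLin <- X %*% Ws[[1]] %*% Ws[[2]] %*% Ws[[3]]
  expect_equal(etgForward(X, Ws, activation = FALSE), refLin)
  expect_error(etgForward(X, Ws[c(2, 1, 3)]), "shape")
})

test_that("ETG parameter counts follow the closed form", {
  expect_equal(etgParamCount(1), 14)
  expect_equal(etgParamCount(4), 224)
  # enumeration oracle: count weight entries one by one
  k <- 4
  dims <- rbind(c(k, 2 * k), c(2 * k, 4 * k), c(4 * k, k))
  expect_equal(etgParamCount(k), sum(dims[, 1] * dims[, 2]))
  expect_equal(etgParamCount(16, bias = TRUE), 14 * 256 + 7 * 16)
})

test_that("cosine scoring matches the per-pair definition", {
  E <- matrix(c(1, 0, 1, 0, 1, 1), 3, 2, byrow = TRUE)
  HD <- matrix(c(2, 0, 0, 3), 2, 2, byrow = TRUE)
  S <- scorePairs(E, HD)
  expect_equal(S[1, 1], 1)   # identical direction
  expect_equal(S[1, 2], 0)   # orthogonal
  expect_equal(S[3, 1], 1 / sqrt(2))

  set.seed(13)
  E <- matrix(rnorm(6), 3, 2); HD <- matrix(rnorm(4), 2, 2)
  S <- scorePairs(E, HD)
  for (i in 1:3) for (j in 1:2) {
    ref <- sum(E[i, ] * HD[j, ]) /
      (sqrt(sum(E[i, ]^2)) * sqrt(sum(HD[j, ]^2)))
    expect_equal(S[i, j], ref)
  }
  expect_true(all(abs(S) <= 1 + 1e-12))
  expect_equal(scorePairs(E, HD, "dot"), E %*% t(HD))
  # zero rows score 0 rather than NaN
  E[1, ] <- 0
  expect_equal(scorePairs(E, HD)[1, ], c(0, 0))
})

test_that("the forward pass is deterministic and bounded", {
  w <- smallWorld()
  d <- syntheticDataset(w)
  A <- associationMatrix(d)
  b <- similarityBundle(d, pdaParams())
  net <- buildHeteroNetwork(b$SPG, b$SDG, A)
  p <- pdaParams(embeddingDim = 8L, epochs = 0L, seed = 4L)
  m <- newPDAModel(nrow(A), ncol(A), p)
  s1 <- predictAssociations(m, net)
  s2 <- predictAssociations(m, net)
  expect_identical(s1, s2)
  expect_true(all(abs(s1) <= 1 + 1e-12))
  prob <- predictAssociations(m, net, "probability")
  expect_true(all(prob > 0 & prob < 1))
})

test_that("candidate ranking sorts by score with id tie-breaks", {
  s <- matrix(c(0.3, 0.9, 0.1, 0.5, 0.5, 0.5), 3, 2,
              dimnames = list(c("p2", "p1", "p3"), c("d1", "d2")))
  expect_equal(rankCandidates(s, "d1", topK = 1)$pirna_id, "p1")
  expect_equal(rankCandidates(s, "d2")$pirna_id, c("p1", "p2", "p3"))
  set.seed(14)
  sv <- setNames(runif(8), paste0("p", 1:8))
  sm <- cbind(dX = sv)
  full <- rankCandidates(sm, "dX", topK = 8)
  expect_equal(full$score, sort(sv, decreasing = TRUE),
               ignore_attr = TRUE)
  # known positives can be excluded
  excl <- matrix(c(1, rep(0, 7)), 8, 1,
                 dimnames = list(paste0("p", 1:8), "dX"))
  expect_false("p1" %in% rankCandidates(sm, "dX", exclude = excl)$pirna_id)
  expect_error(rankCandidates(sm, "nope"), "unknown disease")
})
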