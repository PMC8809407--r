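test_that("rocAUC matches hand-derived values and handles edge cases", {
  expect_equal(rocAUC(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(rocAUC(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  expect_equal(rocAUC(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_error(rocAUC(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("prAUC matches hand-derived step curves", {
  expect_equal(prAUC(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(prAUC(c(0.9, 0.1, 0.2, 0.3), c(1, 0, 0, 0)), 1)
  expect_equal(prAUC(c(0.1, 0.9, 0.8, 0.7), c(1, 0, 0, 0)), 0.25)
  expect_error(prAUC(c(0.1, 0.2), c(0, 0)), "positive")
})

test_that("metric kernels agree with brute-force oracles on random vectors", {
  set.seed(42)
  for (i in seq_len(200)) {
    n <- sample(4:25, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))          # both classes present
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    expect_equal(rocAUC(scores, labels), bruteROC(scores, labels))
    expect_equal(prAUC(scores, labels), brutePR(scores, labels))
  }
})

test_that("rocAUC agrees with an independent library implementation", {
  set.seed(33)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))
    scores <- round(rnorm(n), 2)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(rocAUC(scores, labels), ref)
  }
})

test_that("rocAUC is rank-invariant and complements score negation", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(6:30, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- rnorm(n)  # continuous, ties almost surely absent
    expect_equal(rocAUC(scores, labels), rocAUC(exp(scores), labels))
    expect_equal(rocAUC(scores, labels) + rocAUC(-scores, labels), 1)
  }
})

test_that("tenfold split partitions positives into near-equal shared folds", {
  pos <- data.frame(drug = rep(1:5, 4), disease = rep(1:4, each = 5),
                    type = 1L)
  folds <- tenfoldSplit(pos, seed = 1)
  expect_length(folds, 10)
  expect_setequal(unlist(folds), seq_len(nrow(pos)))
  sizes <- lengths(folds)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_identical(folds, tenfoldSplit(pos, seed = 1))
  # triples of the same pair stay together
  pos2 <- rbind(pos, transform(pos, type = 2L))
  folds2 <- tenfoldSplit(pos2, seed = 4)
  key <- paste(pos2$drug, pos2$disease)
  for (fd in folds2) {
    inFold <- key %in% key[fd]
    expect_true(all(which(inFold) %in% fd))
  }
  expect_error(tenfoldSplit(pos[1:5, ], seed = 1), "at least")
})

test_that("class splits give one fold per class covering all triples", {
  pos <- data.frame(drug = sample(1:30), disease = sample(1:10, 30, TRUE),
                    type = sample(1:3, 30, TRUE))
  partition <- paste0("c", rep(1:15, each = 2))
  folds <- classSplit(pos, partition, "drug")
  expect_length(folds, 15)
  expect_setequal(unlist(folds), seq_len(nrow(pos)))
  for (cl in names(folds))
    expect_true(all(partition[pos$drug[folds[[cl]]]] == cl))

  expect_error(classSplit(pos, rep("c1", 30), "drug"), "single class")
  expect_error(classSplit(pos, partition[1:20], "drug"), "class label")
})

test_that("test negatives never overlap positives and honour the ratio", {
  a <- array(0L, c(2, 2, 3)); a[1, 1, 1] <- 1L
  at <- AssociationTensor(a)
  neg <- testNegatives(at, 1, 1)
  expect_equal(nrow(neg), 3)  # enumeration of the remaining type-1 cells
  expect_false(any(neg$drug == 1 & neg$disease == 1))

  set.seed(2)
  b <- array(rbinom(60, 1, 0.2), c(5, 4, 3))
  bt <- AssociationTensor(b)
  n5 <- testNegatives(bt, 5, 2, ratio = 1, seed = 3)
  expect_equal(nrow(n5), 5)
  expect_true(all(assocArray(bt)[cbind(n5$drug, n5$disease, n5$type)] == 0))

  full <- array(1L, c(2, 2, 3))
  expect_error(testNegatives(AssociationTensor(full), 1, 1), "dense")
})

test_that("permutation null preserves per-type counts, destroys placement", {
  set.seed(5)
  a <- array(rbinom(600, 1, 0.1), c(20, 10, 3))
  at <- AssociationTensor(a)
  pm <- permutationNull(at, seed = 7)
  for (k in 1:3)
    expect_equal(sum(assocArray(pm)[, , k]), sum(a[, , k]))
  expect_false(identical(assocArray(pm), assocArray(at)))
  expect_identical(assocArray(permutationNull(at, seed = 7)), assocArray(pm))
  zero <- AssociationTensor(array(0L, c(3, 3, 3)))
  expect_equal(sum(assocArray(permutationNull(zero, seed = 1))), 0)
})

test_that("experiment driver masks test positives from training", {
  # a perfectly separable toy tensor: KNN must score heldout positives 1
  a <- array(0L, c(6, 4, 3))
  a[1:3, 1, 1] <- 1L; a[1:3, 2, 1] <- 1L   # drug cluster 1
  a[4:6, 3, 1] <- 1L; a[4:6, 4, 1] <- 1L   # drug cluster 2
  at <- AssociationTensor(a)
  res <- runExperiment(at, methods = "drug_knn", scheme = "tenfold",
                       config = list(kDrug = 2), seed = 2)
  expect_equal(res$auc[res$type == "indication"], 1)
  expect_equal(res$aupr[res$type == "indication"], 1)
})
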