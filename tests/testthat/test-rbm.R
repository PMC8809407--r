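test_that("hidden and visible activations have closed-form special cases", {
  nv <- 3; m <- 4
  z <- zeroModel(nv, m)
  set.seed(1)
  view <- randomView(nv, c(1, 3))
  expect_equal(hiddenProb(z, view), rep(0.5, m))
  expect_equal(unname(visibleProb(z, rep(1, m))), matrix(0.5, nv, 3))

  # pre-activation ln 3 -> probability 3/4
  z2 <- zeroModel(nv, 1)
  z2@b <- log(3)
  empty <- drugView(AssociationTensor(array(0L, c(1, nv, 3))), 1)
  expect_equal(hiddenProb(z2, empty), 0.75)

  # single hidden unit, W = 2, a = -2, h = 1: exact cancellation
  z3 <- zeroModel(nv, 1)
  z3@W[, 1, ] <- 2; z3@a[] <- -2
  expect_true(all(visibleProb(z3, 1) == 0.5))

  expect_error(visibleProb(z, rep(1, m + 1)), "hidden units")
  expect_error(visibleProb(z, rep(1, m), diseases = nv + 1), "range")
})

test_that("free energy matches its closed form at zero parameters", {
  set.seed(2)
  for (m in c(1, 3, 5)) {
    z <- zeroModel(4, m)
    view <- randomView(4, sample(1:4, 2))
    expect_equal(freeEnergy(z, view), -m * log(2))
  }
  # linearity in the visible bias
  mod <- randomModel(4, 3)
  view <- randomView(4, c(2, 4))
  mod2 <- mod; mod2@a <- 2 * mod@a
  expect_equal(freeEnergy(mod2, view) - freeEnergy(mod, view),
               -sum(mod@a * view@v))
})

test_that("free-energy ratios reproduce exact probability ratios", {
  set.seed(3)
  mod <- randomModel(3, 3)
  view1 <- randomView(3, c(1, 2))
  v2 <- view1@v; v2[1, ] <- 1 - v2[1, ]
  view2 <- viewWithV(view1, v2)
  ratioFE <- exp(-freeEnergy(mod, view1)) / exp(-freeEnergy(mod, view2))
  ratioLL <- exp(exactLogLik(mod, view1)) / exp(exactLogLik(mod, view2))
  expect_equal(ratioFE, ratioLL, tolerance = 1e-9)
})

test_that("exact likelihood equals uniform closed forms at zero parameters", {
  z <- zeroModel(3, 2)
  set.seed(4)
  expect_equal(exactLogLik(z, randomView(3, 1)), log(1 / 8))
  expect_equal(exactLogLik(z, randomView(3, c(1, 3))), log(1 / 64))
  expect_error(exactLogLik(zeroModel(8, 2), randomView(8, 1:5)),
               "too large")
})

test_that("exact likelihood normalises and matches joint-state enumeration", {
  set.seed(5)
  for (rep in 1:5) {
    nv <- sample(2:3, 1); m <- sample(2:3, 1)
    mod <- randomModel(nv, m)
    obs <- sort(sample(nv, sample(1:2, 1)))
    view <- randomView(nv, obs)
    # free-energy route vs full (v, h) enumeration
    expect_equal(exactLogLik(mod, view), enumLogLik(mod, view),
                 tolerance = 1e-9)
    # probabilities over all visible configurations sum to one
    cfgs <- as.matrix(expand.grid(rep(list(0:1), 3 * length(obs))))
    tot <- sum(apply(cfgs, 1, function(cf) {
      v <- matrix(0, nv, 3); v[obs, ] <- matrix(cf, length(obs), 3)
      exp(exactLogLik(mod, viewWithV(view, v)))
    }))
    expect_equal(tot, 1, tolerance = 1e-9)
  }
})

test_that("hidden activations are invariant to consistent disease permutation", {
  set.seed(6)
  nv <- 5; m <- 3
  mod <- randomModel(nv, m)
  view <- randomView(nv, c(1, 2, 4))
  perm <- sample(nv)
  modP <- RBMModel(W = mod@W[perm, , , drop = FALSE],
                   a = mod@a[perm, , drop = FALSE], b = mod@b,
                   D = mod@D[perm, , drop = FALSE])
  viewP <- methods::new("DrugView", entity = 1L,
                        observed = as.integer(sort(match(view@observed, perm))),
                        v = view@v[perm, , drop = FALSE],
                        r = view@r[perm])
  expect_equal(hiddenProb(modP, viewP), hiddenProb(mod, view))
})

test_that("a zero learning rate leaves parameters untouched", {
  set.seed(7)
  mod <- randomModel(4, 3)
  view <- randomView(4, c(1, 3))
  out <- cdStep(mod, list(view), learningRate = 0)
  expect_equal(out@W, mod@W)
  expect_equal(out@a, mod@a)
  expect_equal(out@b, mod@b)
  expect_equal(out@D, mod@D)
  expect_error(cdStep(mod, list(), 0.1), "non-empty")
})

test_that("CD updates touch only parameters of observed diseases", {
  set.seed(8)
  nv <- 6
  mod <- randomModel(nv, 3)
  view <- randomView(nv, c(2, 5))
  out <- cdStep(mod, list(view), learningRate = 0.3)
  untouched <- setdiff(seq_len(nv), c(2, 5))
  expect_equal(out@W[untouched, , ], mod@W[untouched, , ])
  expect_equal(out@a[untouched, ], mod@a[untouched, ])
  expect_equal(out@D[untouched, ], mod@D[untouched, ])
  expect_false(isTRUE(all.equal(out@W[c(2, 5), , ], mod@W[c(2, 5), , ])))
})

test_that("training is deterministic, seed-sensitive and skips empty drugs", {
  set.seed(9)
  a <- array(rbinom(10 * 6 * 3, 1, 0.2), c(10, 6, 3))
  a[4, , ] <- 0L
  at <- AssociationTensor(a)
  m1 <- rbmTrain(at, m = 4, learningRate = 0.2, epochs = 3, seed = 11)
  m2 <- rbmTrain(at, m = 4, learningRate = 0.2, epochs = 3, seed = 11)
  expect_identical(m1@W, m2@W)
  expect_identical(m1@D, m2@D)
  m3 <- rbmTrain(at, m = 4, learningRate = 0.2, epochs = 3, seed = 12)
  expect_false(identical(m1@W, m3@W))

  init <- rbmTrain(at, m = 4, epochs = 0, seed = 11)
  expect_true(all(init@D == 0))
  expect_true(all(init@b == 0))

  expect_error(rbmTrain(AssociationTensor(array(0L, c(4, 3, 3))), m = 2),
               "no associations")
})

test_that("CD with shared weights ignores drug identity given the visit order", {
  # relabeling drug ids permutes rows of the tensor but, with the visit
  # order aligned to identities, every update sees the same view sequence
  # and the shared parameters must come out identical
  set.seed(10)
  a <- array(rbinom(8 * 5 * 3, 1, 0.3), c(8, 5, 3))
  a[rowSums(a) == 0, 1, 1] <- 1L       # ensure non-empty views
  at <- AssociationTensor(a)
  perm <- sample(8)
  atP <- AssociationTensor(a[perm, , , drop = FALSE])
  views1 <- lapply(1:8, function(d) drugView(at, d))
  views2 <- lapply(order(perm), function(d) drugView(atP, d))
  mod <- randomModel(5, 3, scale = 0.3)
  set.seed(77); out1 <- cdStep(mod, views1, learningRate = 0.3)
  set.seed(77); out2 <- cdStep(mod, views2, learningRate = 0.3)
  expect_equal(out1@W, out2@W)
  expect_equal(out1@a, out2@a)
  expect_equal(out1@b, out2@b)
  expect_equal(out1@D, out2@D)
})

test_that("prediction emits probabilities of the right shape", {
  set.seed(11)
  a <- array(rbinom(6 * 4 * 3, 1, 0.3), c(6, 4, 3))
  at <- AssociationTensor(a)
  z <- zeroModel(4, 3)
  expect_true(all(rbmPredict(z, drugView(at, 1)) == 0.5))
  mod <- rbmTrain(at, m = 3, learningRate = 0.2, epochs = 5, seed = 2)
  sc <- predictTensor(mod, at)
  expect_equal(dim(sc), c(6, 4, 3))
  expect_true(all(sc > 0 & sc < 1))
  # per-view prediction agrees with the vectorised path
  expect_equal(unname(rbmPredict(mod, drugView(at, 3))), unname(sc[3, , ]))
})

test_that("the flipped orientation swaps axes consistently", {
  set.seed(12)
  a <- array(rbinom(7 * 5 * 3, 1, 0.3), c(7, 5, 3))
  at <- AssociationTensor(a)
  flip <- AssociationTensor(aperm(a, c(2, 1, 3)))
  mf <- rbmTrain(at, m = 3, learningRate = 0.2, epochs = 4, seed = 3,
                 orientation = "drug_visible")
  md <- rbmTrain(flip, m = 3, learningRate = 0.2, epochs = 4, seed = 3,
                 orientation = "disease_visible")
  expect_equal(mf@W, md@W)
  expect_equal(nVisible(mf), 7)  # drugs are the visible entities
  sf <- predictTensor(mf, at)
  sd_ <- predictTensor(md, flip)
  expect_equal(sf, aperm(sd_, c(2, 1, 3)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(dim(sf), c(7, 5, 3))
})
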