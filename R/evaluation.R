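# Cross-validation schemes, negative handling, ROC/PR metrics, the
# degree-destroying permutation null, and the experiment driver that
# compares methods per phenotype type.

#' Tenfold split of the positive triples
#'
#' Randomly partitions the known associations into 10 near-equal folds.
#' Fold assignment is made per (drug, disease) pair: triples of different
#' phenotype types on the same pair always share a fold, so a pair under
#' test never has its sibling types in the training data (which the model
#' would otherwise partly reproduce rather than predict).
#'
#' @param positives data.frame of triples (\code{drug}, \code{disease},
#'   \code{type}).
#' @param seed Integer seed.
#' @param nFolds Number of folds (default 10).
#' @return List of \code{nFolds} integer vectors of row indices into
#'   \code{positives} (the test rows of each fold), with disjoint union
#'   equal to all rows.
#' @export
tenfoldSplit <- function(positives, seed = 1L, nFolds = 10L) {
  if (nrow(positives) < nFolds)
    stop(sprintf("need at least %d positives", nFolds))
  key <- paste(positives$drug, positives$disease)
  pairs <- unique(key)
  rng <- .seededRNG(seed)
  fold <- rng(function()
    sample(rep(seq_len(nFolds), length.out = length(pairs))))
  names(fold) <- pairs
  lapply(seq_len(nFolds), function(fd) which(fold[key] == fd))
}

#' Leave-one-class-out split
#'
#' One fold per annotation class (e.g. 15 ATC drug classes or 23 MeSH
#' disease classes): a triple is in fold c exactly when its partitioned
#' entity belongs to class c, so each test fold contains only entities the
#' training folds never saw.
#'
#' @param positives data.frame of triples.
#' @param partition Class label per entity id (as from
#'   [readClassPartition()] or [makeClassPartition()]).
#' @param axis \code{"drug"} or \code{"disease"}: which entity is
#'   partitioned.
#' @return Named list of integer index vectors, one per class.
#' @export
classSplit <- function(positives, partition, axis = c("drug", "disease")) {
  axis <- match.arg(axis)
  ids <- positives[[axis]]
  if (any(ids > length(partition)) || anyNA(partition[ids]))
    stop("every entity in the triples must have a class label")
  classes <- sort(unique(partition))
  folds <- lapply(classes, function(cl) which(partition[ids] == cl))
  names(folds) <- classes
  if (any(vapply(folds, length, 0L) == nrow(positives)))
    stop("a single class holds all positives; training set would be empty")
  folds
}

#' Sample evaluation negatives
#'
#' Negatives are unknown triples: same-type (drug, disease) cells that are
#' zero in the full tensor. By default all of them are used; a finite
#' \code{ratio} samples \code{ratio} negatives per test positive, uniformly
#' without replacement. Negatives never overlap any positive of the type.
#'
#' @param tensor The full [AssociationTensor-class].
#' @param nPositives Number of test positives (used when \code{ratio} is
#'   finite).
#' @param type Phenotype type index.
#' @param ratio Negatives per positive, or \code{"all"} (default).
#' @param seed Integer seed for the finite-ratio case.
#' @return data.frame of negative triples (\code{drug}, \code{disease},
#'   \code{type}).
#' @export
testNegatives <- function(tensor, nPositives, type, ratio = "all", seed = 1L) {
  X <- SummarizedExperiment::assay(tensor, type)
  zero <- which(X == 0L, arr.ind = TRUE)
  if (nrow(zero) == 0L)
    stop("type slice is fully dense; no negatives exist")
  if (!identical(ratio, "all")) {
    need <- ratio * nPositives
    if (need > nrow(zero))
      stop("not enough unknown triples for the requested ratio")
    rng <- .seededRNG(seed)
    zero <- zero[rng(function() sample.int(nrow(zero), need)), , drop = FALSE]
  }
  data.frame(drug = unname(zero[, 1]), disease = unname(zero[, 2]),
             type = type)
}

#' Area under the ROC curve
#'
#' Rank-based: equals the Mann-Whitney probability that a uniformly chosen
#' positive outscores a uniformly chosen negative, with ties counted one
#' half.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels, both classes present.
#' @return AUC in [0, 1].
#' @export
rocAUC <- function(scores, labels) {
  labels <- as.numeric(labels)
  nPos <- sum(labels == 1); nNeg <- sum(labels == 0)
  if (nPos == 0 || nNeg == 0)
    stop("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[labels == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Area under the precision-recall curve
#'
#' Step-wise summation over the descending-score sweep with tied scores
#' grouped: each distinct threshold contributes
#' (recall gain) x (precision at that threshold). No trapezoid
#' interpolation.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels with at least one positive.
#' @return AUPR in (0, 1].
#' @export
prAUC <- function(scores, labels) {
  labels <- as.numeric(labels)
  nPos <- sum(labels == 1)
  if (nPos == 0) stop("AUPR needs at least one positive")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE)  # end of each tie group
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / nPos
  sum(diff(c(0, rec)) * prec)
}

#' Degree-destroying permutation null
#'
#' Within each phenotype-type slice, replaces the set of known-association
#' cells by an equal-sized uniform random sample of cells: per-type density
#' is preserved exactly while all drug/disease degree structure is
#' destroyed. Methods trained on the permuted tensor should rank true
#' held-out associations no better than chance.
#'
#' @param tensor An [AssociationTensor-class].
#' @param seed Integer seed.
#' @return A permuted [AssociationTensor-class] of the same shape.
#' @export
permutationNull <- function(tensor, seed = 1L) {
  a <- assocArray(tensor)
  rng <- .seededRNG(seed)
  for (k in 1:3) {
    n1 <- sum(a[, , k])
    slice <- matrix(0L, dim(a)[1], dim(a)[2])
    if (n1 > 0)
      slice[rng(function() sample.int(length(slice), n1))] <- 1L
    a[, , k] <- slice
  }
  AssociationTensor(a, drugNames = rownames(tensor),
                    diseaseNames = colnames(tensor))
}

# Zero the test-positive cells out of a tensor (training view of a fold).
.maskPositives <- function(tensor, triples) {
  a <- assocArray(tensor)
  if (nrow(triples))
    a[cbind(triples$drug, triples$disease, triples$type)] <- 0L
  AssociationTensor(a, drugNames = rownames(tensor),
                    diseaseNames = colnames(tensor))
}

# Score a set of triples with each supported method, given the fold's
# training tensor. Returns a numeric vector per method.
.scoreTriples <- function(method, trainTensor, triples, config, seed) {
  n <- nrow(triples)
  switch(method,
    crbm = {
      cfg <- config$crbm %||% list()
      tt <- trainTensor
      if (!is.null(cfg$types)) {
        a <- assocArray(tt)
        drop <- setdiff(1:3, match(cfg$types, phenotypeTypes()))
        for (k in drop) a[, , k] <- 0L
        tt <- AssociationTensor(a)
      }
      model <- rbmTrain(tt,
                        m = cfg$m %||% 50L,
                        learningRate = cfg$learningRate %||% 0.5,
                        epochs = cfg$epochs %||% 100L,
                        cdSteps = cfg$cdSteps %||% 1L,
                        batchSize = cfg$batchSize %||% 10L,
                        initScale = cfg$initScale %||% 0.01,
                        seed = seed,
                        orientation = cfg$orientation %||% "disease_visible")
      sc <- predictTensor(model, tt)
      sc[cbind(triples$drug, triples$disease, triples$type)]
    },
    drug_knn = ,
    disease_knn = {
      axis <- if (method == "drug_knn") "drug" else "disease"
      k <- if (axis == "drug") config$kDrug %||% 6L else config$kDisease %||% 5L
      out <- numeric(n)
      for (type in unique(triples$type)) {
        rows <- which(triples$type == type)
        qcol <- if (axis == "drug") "drug" else "disease"
        ocol <- if (axis == "drug") "disease" else "drug"
        for (q in unique(triples[[qcol]][rows])) {
          rr <- rows[triples[[qcol]][rows] == q]
          sc <- suppressWarnings(
            knnPredict(trainTensor, q, type, k = k, axis = axis))
          out[rr] <- sc[triples[[ocol]][rr]]
        }
      }
      out
    },
    rf = ,
    gbt = {
      kind <- if (method == "rf") "random_forest" else "gradient_boosting"
      out <- numeric(n)
      trainPos <- assocPairs(trainTensor)
      rng <- .seededRNG(seed + 17L)
      for (type in unique(triples$type)) {
        pos <- trainPos[trainPos$type == type, , drop = FALSE]
        neg <- testNegatives(trainTensor, nrow(pos), type, ratio = 1L,
                             seed = rng(function() sample.int(2^30, 1)))
        feats <- rbind(
          .pairFeatureMatrix(trainTensor, pos$drug, pos$disease, type),
          .pairFeatureMatrix(trainTensor, neg$drug, neg$disease, type))
        lab <- c(rep(1, nrow(pos)), rep(0, nrow(neg)))
        fit <- fitTreeEnsemble(feats, lab, kind)
        rows <- which(triples$type == type)
        testF <- .pairFeatureMatrix(trainTensor, triples$drug[rows],
                                    triples$disease[rows], type)
        out[rows] <- fit$predictPairs(testF)
      }
      out
    },
    stop(sprintf("unknown method '%s'", method))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a cross-validated method comparison
#'
#' For every fold: the fold's test positives are zeroed out of the
#' training tensor, each method is fitted on the masked tensor, and the
#' test positives plus the negatives are scored. Scores are pooled across
#' folds and per-type AUC / AUPR computed on the pooled values.
#'
#' @param tensor The full [AssociationTensor-class].
#' @param methods Character vector from \code{"crbm"}, \code{"drug_knn"},
#'   \code{"disease_knn"}, \code{"rf"}, \code{"gbt"}.
#' @param scheme \code{"tenfold"}, \code{"leave_one_drug_class_out"} or
#'   \code{"leave_one_disease_class_out"}.
#' @param partition Class labels, required for the leave-one-class-out
#'   schemes.
#' @param negatives \code{"all"} (default) or a numeric negatives-per-
#'   positive ratio.
#' @param config Named list of per-method settings; \code{config$crbm} may
#'   set \code{m}, \code{learningRate}, \code{epochs}, \code{cdSteps},
#'   \code{batchSize}, \code{orientation} and \code{types} (phenotype
#'   types retained in the RBM's training input).
#' @param seed Integer seed governing fold assignment, negative sampling
#'   and model training.
#' @return data.frame with columns \code{method}, \code{type},
#'   \code{scheme}, \code{auc}, \code{aupr}.
#' @export
runExperiment <- function(tensor, methods = "crbm",
                          scheme = c("tenfold", "leave_one_drug_class_out",
                                     "leave_one_disease_class_out"),
                          partition = NULL, negatives = "all",
                          config = list(), seed = 1L) {
  scheme <- match.arg(scheme)
  positives <- assocPairs(tensor)
  folds <- switch(scheme,
    tenfold = tenfoldSplit(positives, seed = seed),
    leave_one_drug_class_out = classSplit(positives, partition, "drug"),
    leave_one_disease_class_out = classSplit(positives, partition, "disease"))
  ratio <- if (identical(negatives, "all")) "all" else negatives
  negByType <- lapply(1:3, function(k) {
    nPos <- sum(positives$type == k)
    if (nPos == 0) return(NULL)
    testNegatives(tensor, nPos, k, ratio = ratio, seed = seed + k)
  })
  pool <- list()
  for (fd in seq_along(folds)) {
    test <- positives[folds[[fd]], , drop = FALSE]
    if (nrow(test) == 0L) next
    trainTensor <- .maskPositives(tensor, test)
    negs <- do.call(rbind, negByType[unique(test$type)])
    eval <- rbind(test, negs)
    lab <- c(rep(1, nrow(test)), rep(0, nrow(negs)))
    for (meth in methods) {
      sc <- .scoreTriples(meth, trainTensor, eval,
                          config, seed = seed + 1000L * fd)
      pool[[length(pool) + 1L]] <-
        data.frame(method = meth, type = eval$type, label = lab, score = sc)
    }
  }
  pool <- do.call(rbind, pool)
  out <- do.call(rbind, lapply(split(pool, list(pool$method, pool$type),
                                     drop = TRUE), function(g) {
    data.frame(method = g$method[1], type = phenotypeTypes()[g$type[1]],
               scheme = scheme,
               auc = rocAUC(g$score, g$label),
               aupr = prAUC(g$score, g$label))
  }))
  rownames(out) <- NULL
  out[order(out$method, out$type), ]
}
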