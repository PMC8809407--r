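# Comparison methods: drug- and disease-based KNN with Jaccard similarity
# on binary association profiles, and random-forest / gradient-boosted-tree
# classifiers on concatenated profile features.

#' Jaccard index between two binary profiles
#'
#' With M11 the number of positions where both vectors are 1, M10 / M01
#' where exactly one is, returns M11 / (M01 + M10 + M11). Two all-zero
#' profiles have similarity 0 by convention.
#'
#' @param u,w Equal-length binary vectors.
#' @return A number in [0, 1].
#' @export
#' @examples
#' jaccardIndex(c(1, 1, 0, 0), c(1, 0, 1, 1))  # 1 / 4
jaccardIndex <- function(u, w) {
  if (length(u) != length(w))
    stop("profiles must have equal length")
  m11 <- sum(u == 1 & w == 1)
  denom <- sum(u == 1 | w == 1)
  if (denom == 0) return(0)
  m11 / denom
}

# All-pairs Jaccard between rows of a binary matrix; zero rows get 0.
.jaccardMatrix <- function(X) {
  inter <- tcrossprod(X)
  rs <- rowSums(X)
  union <- outer(rs, rs, "+") - inter
  J <- ifelse(union > 0, inter / union, 0)
  diag(J) <- ifelse(rs > 0, 1, 0)
  J
}

#' K-nearest-neighbour association scores
#'
#' For a query drug (axis \code{"drug"}), finds the k most Jaccard-similar
#' other drugs on their disease profile of the given phenotype type and
#' scores every disease as the mean of the neighbours' 0/1 association
#' bits; axis \code{"disease"} swaps the roles. Similarity ties are broken
#' in favour of the lower entity id. The grid-searched defaults on the
#' full-scale balanced data are k = 6 drug-based and k = 5 disease-based.
#'
#' @param tensor An [AssociationTensor-class] (training data; held-out
#'   associations must already be masked out).
#' @param query 1-based index of the query entity on \code{axis}.
#' @param type Phenotype type index (1 = indication, 2 = side effect,
#'   3 = contraindication).
#' @param k Number of neighbours; must be smaller than the axis size.
#' @param axis \code{"drug"} or \code{"disease"}.
#' @return Numeric score vector over the opposite axis, values in
#'   \{0, 1/k, ..., 1\}.
#' @export
knnPredict <- function(tensor, query, type, k = if (axis == "drug") 6L else 5L,
                       axis = c("drug", "disease")) {
  axis <- match.arg(axis)
  X <- SummarizedExperiment::assay(tensor, type)
  if (axis == "disease") X <- t(X)
  n <- nrow(X)
  if (query < 1L || query > n) stop("query index out of range")
  if (k >= n) stop("k must be smaller than the number of entities")
  if (sum(X[query, ]) == 0)
    warning("query has an empty profile; returning zero scores")
  prof <- X[query, ]
  inter <- drop(X %*% prof)
  union <- rowSums(X) + sum(prof) - inter
  sim <- ifelse(union > 0, inter / union, 0)
  cand <- setdiff(seq_len(n), query)
  nb <- cand[order(-sim[cand], cand)][seq_len(k)]
  colMeans(X[nb, , drop = FALSE])
}

#' Feature vector for one drug-disease pair
#'
#' Concatenates the drug's disease profile and the disease's drug profile
#' of the given type. The (drug, disease) cell itself is zeroed in both
#' halves so the feature vector never contains the pair's own label.
#'
#' @param tensor An [AssociationTensor-class].
#' @param drug,disease 1-based indices.
#' @param type Phenotype type index.
#' @return Numeric vector of length nDiseases + nDrugs.
#' @export
pairFeatures <- function(tensor, drug, disease, type) {
  X <- SummarizedExperiment::assay(tensor, type)
  if (drug < 1L || drug > nrow(X) || disease < 1L || disease > ncol(X))
    stop("index out of range")
  dProf <- as.numeric(X[drug, ]); dProf[disease] <- 0
  sProf <- as.numeric(X[, disease]); sProf[drug] <- 0
  c(dProf, sProf)
}

# Feature matrix for many pairs of one type, self-cells masked.
.pairFeatureMatrix <- function(tensor, drugs, diseases, type) {
  X <- SummarizedExperiment::assay(tensor, type)
  F1 <- X[drugs, , drop = FALSE]
  F2 <- t(X)[diseases, , drop = FALSE]
  F1[cbind(seq_along(drugs), diseases)] <- 0
  F2[cbind(seq_along(drugs), drugs)] <- 0
  cbind(F1, F2)
}

#' Fit a tree-ensemble classifier on pair features
#'
#' One binary classifier per phenotype type is the intended use. Random
#' forests use the library defaults; gradient boosting defaults to the
#' grid-searched optimum for this problem (gamma 0.25, learning rate 0.1,
#' max depth 5, no L2 penalty, positive-class weight 1) with 100 rounds.
#' If the training labels contain a single class the model degenerates to
#' a constant score with a warning.
#'
#' @param features Numeric matrix, one row per training pair.
#' @param labels 0/1 vector.
#' @param kind \code{"random_forest"} or \code{"gradient_boosting"}.
#' @param nrounds Boosting rounds (gradient boosting only).
#' @param ... Passed to the underlying fitting function.
#' @return An object with a \code{predictPairs(features)} element returning
#'   probability scores in [0, 1].
#' @export
fitTreeEnsemble <- function(features, labels,
                            kind = c("random_forest", "gradient_boosting"),
                            nrounds = 100L, ...) {
  kind <- match.arg(kind)
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2L) {
    warning("training labels contain a single class; constant scores")
    const <- if (length(labels)) mean(labels) else 0.5
    return(list(kind = kind, constant = const,
                predictPairs = function(f) rep(const, nrow(f))))
  }
  if (kind == "random_forest") {
    fit <- randomForest::randomForest(x = features, y = factor(labels), ...)
    list(kind = kind, fit = fit,
         predictPairs = function(f)
           as.numeric(predict(fit, f, type = "prob")[, "1"]))
  } else {
    fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", gamma = 0.25, eta = 0.1,
                    max_depth = 5, lambda = 0, scale_pos_weight = 1,
                    nthread = 1, ...),
      data = xgboost::xgb.DMatrix(features, label = labels, nthread = 1),
      nrounds = nrounds, verbose = 0)
    list(kind = kind, fit = fit,
         predictPairs = function(f)
           as.numeric(predict(fit, xgboost::xgb.DMatrix(f, nthread = 1))))
  }
}
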