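# Conditional RBM with per-drug visible layers and parameters shared across
# drugs. A drug's visible layer has three binary variables per associated
# disease (indication / side effect / contraindication bits); the binary
# indicator r of which diseases are associated at all enters as an observed
# conditioning vector that shifts hidden pre-activations through D.
#
# Internally parameters are kept flat: visible variable (disease i, type k)
# maps to row i + nVis * (k - 1), matching R's column-major vectorisation of
# an (nVis x 3) visible matrix. All hot paths are plain BLAS matrix products.

.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

.flatten <- function(model) {
  nv <- nVisible(model); m <- nHidden(model)
  list(W = matrix(aperm(model@W, c(1, 3, 2)), nv * 3L, m),
       a = as.vector(model@a), b = model@b, D = model@D,
       nv = nv, m = m)
}

.unflatten <- function(flat, orientation) {
  W <- aperm(array(flat$W, c(flat$nv, 3L, flat$m)), c(1, 3, 2))
  RBMModel(W = W, a = matrix(flat$a, flat$nv, 3L), b = flat$b, D = flat$D,
           orientation = orientation)
}

.zeroFlat <- function(nv, m, initScale = 0, aInit = numeric(nv * 3L)) {
  list(W = matrix(if (initScale > 0) rnorm(nv * 3L * m, sd = initScale) else 0,
                  nv * 3L, m),
       a = aInit, b = numeric(m), D = matrix(0, nv, m),
       nv = nv, m = m)
}

.checkView <- function(model, view) {
  if (nrow(view@v) != nVisible(model))
    stop(sprintf("view has %d visible entities but model expects %d",
                 nrow(view@v), nVisible(model)))
}

#' Hidden-unit activation probabilities
#'
#' Computes p(h_j = 1 | v, r) = logistic(b_j + sum_{i in O, k} v_ik W_ijk
#' + sum_i r_i D_ij): the data-dependent hidden activation used for both the
#' positive phase of contrastive divergence and mean-field prediction.
#'
#' @param model An [RBMModel-class].
#' @param view A [DrugView-class] with matching visible dimension.
#' @return Numeric vector of length \code{nHidden(model)}, entries in (0,1).
#' @export
hiddenProb <- function(model, view) {
  .checkView(model, view)
  f <- .flatten(model)
  pre <- f$b + drop(crossprod(f$W, as.vector(view@v))) +
    drop(crossprod(f$D, view@r))
  plogis(pre)
}

#' Visible-unit activation probabilities
#'
#' Computes p(v_ik = 1 | h) = logistic(a_ik + sum_j h_j W_ijk) for every
#' requested disease, including diseases outside the drug's observed set --
#' this down-pass over unobserved diseases is the prediction mechanism.
#' \code{hidden} may be a binary state or a mean-field probability vector.
#'
#' @param model An [RBMModel-class].
#' @param hidden Numeric vector of length \code{nHidden(model)}.
#' @param diseases Integer vector of visible-entity indices to score;
#'   defaults to all.
#' @return Numeric matrix (length(diseases) x 3) of probabilities.
#' @export
visibleProb <- function(model, hidden, diseases = seq_len(nVisible(model))) {
  if (length(hidden) != nHidden(model))
    stop("hidden vector length must equal the number of hidden units")
  if (any(diseases < 1L | diseases > nVisible(model)))
    stop("disease index out of range")
  f <- .flatten(model)
  p <- plogis(f$a + drop(f$W %*% hidden))
  matrix(p, f$nv, 3L)[diseases, , drop = FALSE]
}

#' Free energy of a visible configuration
#'
#' F(v) = -sum_{i in O, k} a_ik v_ik - sum_j softplus(b_j +
#' sum_{i in O, k} v_ik W_ijk + sum_i r_i D_ij), with the hidden layer
#' analytically summed out. The unnormalised marginal probability of a
#' visible configuration (given r) is proportional to exp(-F(v)).
#'
#' @param model An [RBMModel-class].
#' @param view A [DrugView-class].
#' @return A single number.
#' @export
freeEnergy <- function(model, view) {
  .checkView(model, view)
  f <- .flatten(model)
  vflat <- as.vector(view@v)
  pre <- f$b + drop(crossprod(f$W, vflat)) + drop(crossprod(f$D, view@r))
  -sum(f$a * vflat) - sum(.softplus(pre))
}

.logsumexp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

#' Exact log-likelihood by enumeration (small instances only)
#'
#' Normalises the free energy over every binary visible configuration on
#' the drug's observed block O x 3 (with r held fixed), giving
#' log p(v | r) exactly. Only feasible when the block has at most 12 bits
#' (4096 configurations); used as the independent oracle that contrastive
#' divergence is checked against.
#'
#' @param model An [RBMModel-class].
#' @param view A [DrugView-class] with \code{3 * length(view@observed) <= 12}.
#' @return log p(v | r), a single non-positive number.
#' @export
exactLogLik <- function(model, view) {
  .checkView(model, view)
  nBits <- 3L * length(view@observed)
  if (nBits > 12L)
    stop("visible configuration space too large for exact enumeration")
  f <- .flatten(model)
  blockIdx <- as.vector(outer(view@observed, (0:2) * f$nv, "+"))
  preBase <- f$b + drop(crossprod(f$D, view@r))
  if (nBits == 0L) return(0)
  configs <- as.matrix(expand.grid(rep(list(0:1), nBits)))
  aBlock <- f$a[blockIdx]
  Wblock <- f$W[blockIdx, , drop = FALSE]
  pre <- configs %*% Wblock
  negF <- drop(configs %*% aBlock) +
    rowSums(.softplus(sweep(pre, 2, preBase, "+")))
  logZ <- .logsumexp(negF)
  -freeEnergy(model, view) - logZ
}

# One CD update on flat parameters; V is (B x nv*3) data, R (B x nv) the
# conditioning indicators, M (B x nv*3) the visible mask replicating R over
# the three types. Negative-phase chains restart from the data; the final
# reconstruction uses probabilities (masked) rather than samples to lower
# gradient variance, intermediate steps sample.
.cdStepFlat <- function(f, V, R, M, learningRate, cdSteps = 1L) {
  B <- nrow(V)
  condPre <- R %*% f$D
  H0 <- plogis(sweep(V %*% f$W + condPre, 2, f$b, "+"))
  hs <- (matrix(runif(length(H0)), nrow(H0)) < H0) * 1
  for (s in seq_len(cdSteps)) {
    Pv <- plogis(sweep(tcrossprod(hs, f$W), 2, f$a, "+")) * M
    if (s < cdSteps) {
      Vk <- (matrix(runif(length(Pv)), nrow(Pv)) < Pv) * 1
    } else {
      Vk <- Pv
    }
    Hk <- plogis(sweep(Vk %*% f$W + condPre, 2, f$b, "+"))
    if (s < cdSteps)
      hs <- (matrix(runif(length(Hk)), nrow(Hk)) < Hk) * 1
  }
  lr <- learningRate / B
  f$W <- f$W + lr * (crossprod(V, H0) - crossprod(Vk, Hk))
  f$a <- f$a + lr * colSums(V - Vk)
  f$b <- f$b + lr * colSums(H0 - Hk)
  f$D <- f$D + lr * crossprod(R, H0 - Hk)
  f
}

#' One contrastive-divergence parameter update
#'
#' Positive phase uses the batch's data and exact hidden activations;
#' negative phase runs \code{cdSteps} alternating Gibbs steps restricted to
#' each drug's observed O x 3 visible block, with the conditioning vector r
#' held fixed. Gradients for W and a only touch rows of diseases observed
#' in the batch; D's gradient is r outer the hidden-statistic difference.
#' Updates are averaged over the batch and scaled by \code{learningRate}.
#' Uses R's current random-number stream (seed with \code{set.seed}).
#'
#' @param model An [RBMModel-class].
#' @param views Non-empty list of [DrugView-class] objects (a minibatch).
#' @param learningRate Step size.
#' @param cdSteps Number of Gibbs alternations (CD-k); default 1.
#' @return The updated [RBMModel-class].
#' @export
cdStep <- function(model, views, learningRate, cdSteps = 1L) {
  if (is(views, "DrugView")) views <- list(views)
  if (length(views) == 0L) stop("batch of views must be non-empty")
  for (vw in views) .checkView(model, vw)
  f <- .flatten(model)
  V <- t(vapply(views, function(vw) as.vector(vw@v), numeric(f$nv * 3L)))
  R <- t(vapply(views, function(vw) vw@r, numeric(f$nv)))
  M <- cbind(R, R, R)
  f <- .cdStepFlat(f, V, R, M, learningRate, cdSteps)
  .unflatten(f, model@orientation)
}

# Dense per-entity matrices for a whole tensor under a given orientation:
# V rows are entities owning an RBM (drugs by default), columns the
# flattened visible variables of the opposite axis.
.tensorMatrices <- function(tensor, orientation) {
  A <- assocArray(tensor)
  if (orientation == "drug_visible") A <- aperm(A, c(2, 1, 3))
  nEnt <- dim(A)[1]; nv <- dim(A)[2]
  V <- cbind(matrix(A[, , 1], nEnt, nv), matrix(A[, , 2], nEnt, nv),
             matrix(A[, , 3], nEnt, nv))
  R <- (matrix(A[, , 1] + A[, , 2] + A[, , 3], nEnt, nv) > 0) * 1
  list(V = V, R = R, nEnt = nEnt, nv = nv)
}

#' Train the conditional RBM on an association tensor
#'
#' Builds one view per drug (per disease under the flipped orientation),
#' initialises W from Normal(0, initScale), visible biases at the smoothed
#' empirical log-odds of each visible bit (so that units with little
#' training signal score at their marginal rate instead of 1/2), zero
#' hidden biases and zero conditional weights, then runs \code{epochs}
#' sweeps of contrastive divergence over shuffled minibatches. Entities
#' without any association are skipped. Deterministic given \code{seed};
#' the caller's RNG state is left untouched.
#'
#' Defaults (\code{m = 400}, \code{learningRate = 0.5},
#' \code{epochs = 300}) are the grid-search optimum for the full-scale
#' tensor; scale them down for desk-sized data.
#'
#' @param tensor An [AssociationTensor-class].
#' @param m Number of hidden units.
#' @param learningRate Step size.
#' @param epochs Number of sweeps over all entities.
#' @param cdSteps Gibbs alternations per update (CD-k).
#' @param batchSize Entities per minibatch.
#' @param initScale Standard deviation of the weight initialisation.
#' @param seed Integer seed.
#' @param orientation \code{"disease_visible"} (default: one RBM per drug,
#'   diseases as visible units) or \code{"drug_visible"} (one RBM per
#'   disease, drugs as visible units).
#' @return A trained [RBMModel-class].
#' @export
rbmTrain <- function(tensor, m = 400L, learningRate = 0.5, epochs = 300L,
                     cdSteps = 1L, batchSize = 10L, initScale = 0.01,
                     seed = 1L,
                     orientation = c("disease_visible", "drug_visible")) {
  orientation <- match.arg(orientation)
  tm <- .tensorMatrices(tensor, orientation)
  keep <- which(rowSums(tm$V) > 0)
  if (length(keep) == 0L)
    stop("tensor has no associations to train on")
  V <- tm$V[keep, , drop = FALSE]
  R <- tm$R[keep, , drop = FALSE]
  M <- cbind(R, R, R)
  aInit <- qlogis((colSums(V) + 1) / (nrow(V) + 2))
  rng <- .seededRNG(seed)
  f <- rng(function() .zeroFlat(tm$nv, m, initScale, aInit))
  if (epochs > 0) {
    rng(function() {
      for (e in seq_len(epochs)) {
        perm <- sample.int(nrow(V))
        starts <- seq(1L, length(perm), by = batchSize)
        for (s in starts) {
          idx <- perm[s:min(s + batchSize - 1L, length(perm))]
          f <<- .cdStepFlat(f, V[idx, , drop = FALSE], R[idx, , drop = FALSE],
                            M[idx, , drop = FALSE], learningRate, cdSteps)
        }
      }
    })
  }
  .unflatten(f, orientation)
}

#' Score all (disease, type) pairs for one drug view
#'
#' A single deterministic mean-field pass: hidden activations from the
#' observed data, then visible probabilities for every disease -- observed
#' or not. Output probabilities are the association scores.
#'
#' @param model A trained [RBMModel-class].
#' @param view A [DrugView-class].
#' @return Numeric matrix (nVisible x 3) of probabilities in (0, 1).
#' @export
rbmPredict <- function(model, view) {
  visibleProb(model, hiddenProb(model, view))
}

#' Score every (drug, disease, type) triple of a tensor
#'
#' Runs the mean-field pass for all entities at once. The returned array is
#' aligned with the input tensor regardless of the model's orientation.
#'
#' @param model A trained [RBMModel-class].
#' @param tensor The [AssociationTensor-class] supplying the observed views
#'   (typically the training tensor).
#' @return Numeric array (nDrugs, nDiseases, 3) of probabilities.
#' @export
predictTensor <- function(model, tensor) {
  tm <- .tensorMatrices(tensor, model@orientation)
  if (tm$nv != nVisible(model))
    stop("tensor does not match the model's visible dimension")
  f <- .flatten(model)
  H <- plogis(sweep(tm$V %*% f$W + tm$R %*% f$D, 2, f$b, "+"))
  S <- plogis(sweep(tcrossprod(H, f$W), 2, f$a, "+"))  # nEnt x nv*3
  out <- array(as.vector(S), c(tm$nEnt, tm$nv, 3L))
  if (model@orientation == "drug_visible") out <- aperm(out, c(2, 1, 3))
  dimnames(out) <- c(dimnames(SummarizedExperiment::assay(tensor, 1)),
                     list(phenotypeTypes()))
  out
}
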