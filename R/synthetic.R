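# Synthetic association tensors with planted latent structure and
# cross-type dependence, so that every method in the package can be
# exercised without any external data.

#' Configuration for the synthetic tensor generator
#'
#' Drugs and diseases get sparse binary latent factors over a shared pool
#' of dimensions; each phenotype type reads a subset of the pool, and the
#' three subsets overlap in a fraction \code{crossTypeCoupling} of their
#' dimensions, which is what makes side-effect / contraindication profiles
#' informative about indications. The per-pair association probability for
#' type k is
#' \code{plogis(qlogis(baseRate[k]) + signalStrength * <u_d, v_s>_k)},
#' followed by independent bit flips at \code{noiseFlipRate}.
#'
#' Defaults give a desk-scale fixture (200 x 100) with a strong planted
#' signal: around a thousand positives per type (per-type density around
#' 5-8 percent), the large majority of them generated by shared latent
#' structure rather than baseline noise.
#'
#' @param nDrugs,nDiseases Tensor dimensions.
#' @param nLatent Latent dimensions read by each type.
#' @param baseRate Length-3 baseline association probability per type.
#' @param signalStrength Log-odds added per shared active latent dimension.
#' @param crossTypeCoupling Fraction in [0, 1] of latent dimensions shared
#'   by all three types.
#' @param noiseFlipRate Probability of flipping each sampled bit.
#' @param pExtra Probability of each secondary latent activation (every
#'   entity also gets one dominant dimension).
#' @param seed Integer seed.
#' @return A \code{SynthConfig} list.
#' @export
synthConfig <- function(nDrugs = 200L, nDiseases = 100L, nLatent = 8L,
                        baseRate = c(0.002, 0.003, 0.0025),
                        signalStrength = 8, crossTypeCoupling = 0.5,
                        noiseFlipRate = 0, pExtra = 0.04, seed = 1L) {
  stopifnot(length(baseRate) == 3L, all(baseRate > 0), all(baseRate < 1),
            crossTypeCoupling >= 0, crossTypeCoupling <= 1,
            noiseFlipRate >= 0, noiseFlipRate <= 1,
            nLatent <= min(nDrugs, nDiseases))
  structure(list(nDrugs = nDrugs, nDiseases = nDiseases, nLatent = nLatent,
                 baseRate = baseRate, signalStrength = signalStrength,
                 crossTypeCoupling = crossTypeCoupling,
                 noiseFlipRate = noiseFlipRate, pExtra = pExtra,
                 seed = seed),
            class = "SynthConfig")
}

# Sparse binary factors: one dominant dimension each plus rare extras.
.sampleFactors <- function(n, pool, pExtra) {
  f <- matrix(rbinom(n * pool, 1, pExtra), n, pool)
  f[cbind(seq_len(n), sample.int(pool, n, replace = TRUE))] <- 1L
  f
}

#' Generate a synthetic association tensor
#'
#' @param config A [synthConfig()] list.
#' @return List with elements \code{tensor} (an
#'   [AssociationTensor-class]) and \code{truth} (drug/disease latent
#'   factors, the per-type latent dimension sets, and the pre-noise
#'   probability arrays).
#' @export
#' @examples
#' sim <- simulateTensor(synthConfig(nDrugs = 50, nDiseases = 30, seed = 7))
#' sim$tensor
simulateTensor <- function(config = synthConfig()) {
  stopifnot(inherits(config, "SynthConfig"))
  rng <- .seededRNG(config$seed)
  rng(function() {
    nShared <- round(config$crossTypeCoupling * config$nLatent)
    nPriv <- config$nLatent - nShared
    pool <- nShared + 3L * nPriv
    dims <- lapply(0:2, function(k) {
      c(seq_len(nShared),
        if (nPriv > 0) nShared + k * nPriv + seq_len(nPriv))
    })
    U <- .sampleFactors(config$nDrugs, pool, config$pExtra)
    V <- .sampleFactors(config$nDiseases, pool, config$pExtra)
    a <- array(0L, c(config$nDrugs, config$nDiseases, 3L))
    prob <- array(0, dim(a))
    for (k in 1:3) {
      dot <- tcrossprod(U[, dims[[k]], drop = FALSE],
                        V[, dims[[k]], drop = FALSE])
      p <- plogis(qlogis(config$baseRate[k]) + config$signalStrength * dot)
      bits <- matrix(rbinom(length(p), 1, p), nrow(p))
      if (config$noiseFlipRate > 0) {
        flip <- matrix(rbinom(length(p), 1, config$noiseFlipRate), nrow(p))
        bits <- abs(bits - flip)
      }
      a[, , k] <- bits
      prob[, , k] <- p
    }
    list(tensor = AssociationTensor(a),
         truth = list(drugFactors = U, diseaseFactors = V,
                      typeDims = dims, prob = prob))
  })
}

#' Build a class partition from planted latent structure
#'
#' Entities sharing a dominant latent dimension are grouped into a class,
#' mimicking annotation classes (ATC for drugs, MeSH for diseases) that
#' align with mechanism. Classes are merged or randomly split so that
#' exactly \code{nClasses} non-empty classes come out.
#'
#' @param truth The \code{truth} element returned by [simulateTensor()].
#' @param axis \code{"drug"} or \code{"disease"}.
#' @param nClasses Number of classes (at most the axis size).
#' @param seed Integer seed.
#' @return Character vector of class labels (\code{"c1"}, ...) indexed by
#'   entity id, with the axis as an attribute.
#' @export
makeClassPartition <- function(truth, axis = c("drug", "disease"),
                               nClasses = 15L, seed = 1L) {
  axis <- match.arg(axis)
  f <- if (axis == "drug") truth$drugFactors else truth$diseaseFactors
  n <- nrow(f)
  if (nClasses > n) stop("more classes than entities on the axis")
  dominant <- max.col(f, ties.method = "first")
  lab <- (dominant - 1L) %% nClasses + 1L
  rng <- .seededRNG(seed)
  rng(function() {
    empty <- setdiff(seq_len(nClasses), unique(lab))
    for (cl in empty) {
      big <- as.integer(names(which.max(table(lab))))
      donor <- which(lab == big)
      lab[sample(donor, max(1L, length(donor) %/% 2L))] <<- cl
    }
  })
  out <- paste0("c", lab)
  attr(out, "axis") <- axis
  out
}
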