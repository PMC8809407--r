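# Down-sampling that equalises association counts across the three
# phenotype types. Indication pairs are by far the rarest in the collected
# data, so they are all kept and the two denser types are sampled down to
# the indication count, restricted to a disease subset S anchored on the
# indication diseases.

#' Select the disease subset used for balancing
#'
#' A disease belongs to the subset S if it appears in at least one known
#' drug-indication pair, or if it is shared by at least two distinct
#' phenotype types (e.g. both a side effect and a contraindication of some
#' drugs).
#'
#' @param pairs data.frame of association triples with columns \code{drug},
#'   \code{disease}, \code{type} (type 1 = indication, 2 = side effect,
#'   3 = contraindication).
#' @return Sorted integer vector of disease ids in S.
#' @export
selectDiseaseSubset <- function(pairs) {
  stopifnot(all(c("drug", "disease", "type") %in% names(pairs)))
  indic <- unique(pairs$disease[pairs$type == 1L])
  typesPerDisease <- tapply(pairs$type, pairs$disease,
                            function(t) length(unique(t)))
  shared <- as.integer(names(typesPerDisease)[typesPerDisease >= 2L])
  s <- sort(unique(c(indic, shared)))
  if (length(s) == 0L)
    stop("no disease satisfies the subset criteria")
  s
}

#' Balance association counts across phenotype types
#'
#' Keeps every indication pair and uniformly down-samples, without
#' replacement, the side-effect and contraindication pairs whose disease
#' lies in the subset \code{s}, so that all three types end up with the
#' same number of associations: the smallest per-type count in the input.
#'
#' @param pairs data.frame of association triples (\code{drug},
#'   \code{disease}, \code{type}); duplicated triples are dropped first.
#' @param s Disease subset from [selectDiseaseSubset()]; computed from
#'   \code{pairs} when missing.
#' @param seed Integer seed making the down-sampling reproducible.
#' @return data.frame of retained triples with equal per-type counts.
#' @export
#' @examples
#' pairs <- data.frame(drug = c(1, 1, 2, 2, 3), disease = c(1, 2, 1, 2, 1),
#'                     type = c(1, 2, 2, 3, 3))
#' balanceAssociations(pairs, seed = 1)
balanceAssociations <- function(pairs, s = selectDiseaseSubset(pairs),
                                seed = 1L) {
  stopifnot(all(c("drug", "disease", "type") %in% names(pairs)))
  pairs <- unique(pairs[c("drug", "disease", "type")])
  counts <- vapply(1:3, function(k) sum(pairs$type == k), 0L)
  target <- min(counts)
  keep <- pairs[pairs$type == 1L, , drop = FALSE]
  rng <- .seededRNG(seed)
  for (k in 2:3) {
    sub <- pairs[pairs$type == k & pairs$disease %in% s, , drop = FALSE]
    if (nrow(sub) < target)
      stop(sprintf(
        "type '%s' has only %d pairs with disease in the subset; %d needed",
        phenotypeTypes()[k], nrow(sub), target))
    pick <- rng(function() sample.int(nrow(sub), target))
    keep <- rbind(keep, sub[sort(pick), , drop = FALSE])
  }
  rownames(keep) <- NULL
  keep
}

#' Apply balancing to a tensor
#'
#' Convenience wrapper: extracts the triple list from a tensor, balances
#' it, and rebuilds a tensor of the same shape containing only the
#' retained associations.
#'
#' @param tensor An [AssociationTensor-class].
#' @param seed Integer seed.
#' @return A balanced [AssociationTensor-class] of the same shape.
#' @export
balanceTensor <- function(tensor, seed = 1L) {
  pairs <- assocPairs(tensor)
  kept <- balanceAssociations(pairs, seed = seed)
  a <- array(0L, dim(assocArray(tensor)))
  a[cbind(kept$drug, kept$disease, kept$type)] <- 1L
  AssociationTensor(a, drugNames = rownames(tensor),
                    diseaseNames = colnames(tensor))
}

# Run `expr()` under a locally seeded RNG without disturbing the caller's
# RNG state. Returns a closure so successive draws continue one stream.
.seededRNG <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  function(expr) {
    outer <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (!is.null(outer)) assign(".Random.seed", outer, globalenv())
    })
    expr()
  }
}
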