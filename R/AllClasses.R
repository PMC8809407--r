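#' @import methods
#' @importFrom stats plogis qlogis rnorm runif rbinom predict
#' @importFrom utils read.delim write.table
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Phenotype type labels, in tensor slice order
#'
#' The third tensor axis is fixed to the three clinical phenotype types in
#' this order: slice 1 holds indications (diseases a drug treats), slice 2
#' side effects (conditions it can cause), slice 3 contraindications
#' (conditions under which it must not be used).
#'
#' @return Character vector of length 3.
#' @export
#' @examples
#' phenotypeTypes()
phenotypeTypes <- function() c("indication", "side_effect", "contraindication")

#' AssociationTensor: a three-type drug-disease association tensor
#'
#' An \linkS4class{SummarizedExperiment} holding a binary drugs x diseases x 3
#' association tensor as three binary assays named
#' \code{"indication"}, \code{"side_effect"} and \code{"contraindication"}.
#' Rows are drugs, columns are diseases. Every assay entry is 0 or 1;
#' \code{assay(x, k)[i, j] == 1} records a known association of type
#' \code{k} between drug \code{i} and disease \code{j}.
#'
#' @seealso [AssociationTensor()] to construct one from a 3-D array,
#'   [assocArray()] for the dense array view, [readTensor()] /
#'   [writeTensor()] for NPY serialisation.
#' @export
setClass("AssociationTensor", contains = "SummarizedExperiment")

.validAssociationTensor <- function(object) {
  msg <- NULL
  a <- SummarizedExperiment::assays(object)
  if (length(a) != 3L)
    msg <- c(msg, "exactly 3 assays are required (one per phenotype type)")
  if (!identical(SummarizedExperiment::assayNames(object), phenotypeTypes()))
    msg <- c(msg, sprintf("assay names must be (%s), in that order",
                          paste(phenotypeTypes(), collapse = ", ")))
  for (k in seq_along(a)) {
    v <- a[[k]]
    if (!is.numeric(v) || anyNA(v) || !all(v == 0L | v == 1L)) {
      msg <- c(msg, sprintf("assay %d has entries outside {0, 1}", k))
      break
    }
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("AssociationTensor", .validAssociationTensor)

#' Construct an AssociationTensor
#'
#' @param values Dense 3-D binary array with dimensions
#'   (drugs, diseases, 3), third axis ordered as [phenotypeTypes()];
#'   or a list of three binary drug x disease matrices in that order.
#' @param drugNames,diseaseNames Optional character vectors of row/column
#'   names; defaults are \code{drug1..drugN} / \code{disease1..diseaseM}.
#'
#' @return A validated [AssociationTensor-class] object.
#' @export
#' @examples
#' a <- array(0L, c(5, 4, 3))
#' a[1, 2, 1] <- 1L
#' at <- AssociationTensor(a)
#' nDrugs(at); nDiseases(at)
AssociationTensor <- function(values, drugNames = NULL, diseaseNames = NULL) {
  if (is.list(values)) {
    stopifnot(length(values) == 3L)
    values <- array(c(values[[1]], values[[2]], values[[3]]),
                    dim = c(dim(values[[1]]), 3L))
  }
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3-D array (drugs x diseases x types)")
  if (dim(values)[3] != 3L)
    stop("third dimension must have length 3 (indication, side_effect, contraindication)")
  storage.mode(values) <- "integer"
  if (is.null(drugNames))
    drugNames <- paste0("drug", seq_len(dim(values)[1]))
  if (is.null(diseaseNames))
    diseaseNames <- paste0("disease", seq_len(dim(values)[2]))
  asy <- lapply(1:3, function(k) {
    m <- values[, , k, drop = FALSE]
    dim(m) <- dim(values)[1:2]
    dimnames(m) <- list(drugNames, diseaseNames)
    m
  })
  names(asy) <- phenotypeTypes()
  methods::new("AssociationTensor",
               SummarizedExperiment::SummarizedExperiment(assays = asy))
}

#' @describeIn AssociationTensor number of drugs (rows)
#' @param x An AssociationTensor.
#' @export
nDrugs <- function(x) nrow(x)

#' @describeIn AssociationTensor number of diseases (columns)
#' @export
nDiseases <- function(x) ncol(x)

#' Dense array view of an association tensor
#'
#' @param x An [AssociationTensor-class].
#' @return Integer array of dimension (nDrugs, nDiseases, 3).
#' @export
assocArray <- function(x) {
  stopifnot(is(x, "AssociationTensor"))
  a <- array(0L, c(nrow(x), ncol(x), 3L),
             dimnames = c(dimnames(SummarizedExperiment::assay(x, 1L)),
                          list(phenotypeTypes())))
  for (k in 1:3) a[, , k] <- SummarizedExperiment::assay(x, k)
  a
}

#' Known associations as a triple table
#'
#' @param x An [AssociationTensor-class].
#' @return data.frame with columns \code{drug}, \code{disease}, \code{type}
#'   (1-based indices; type 1 = indication, 2 = side effect,
#'   3 = contraindication), one row per known association.
#' @export
assocPairs <- function(x) {
  out <- lapply(1:3, function(k) {
    idx <- which(SummarizedExperiment::assay(x, k) == 1L, arr.ind = TRUE)
    if (nrow(idx) == 0L)
      return(data.frame(drug = integer(), disease = integer(), type = integer()))
    data.frame(drug = unname(idx[, 1]), disease = unname(idx[, 2]), type = k)
  })
  do.call(rbind, out)
}

setMethod("show", "AssociationTensor", function(object) {
  cnt <- vapply(1:3, function(k) sum(SummarizedExperiment::assay(object, k)), 0)
  cat("AssociationTensor:", nrow(object), "drugs x", ncol(object),
      "diseases x 3 phenotype types\n")
  cat(sprintf("  known associations: %d indication, %d side_effect, %d contraindication\n",
              cnt[1], cnt[2], cnt[3]))
})

#' RBMModel: parameters of the conditional restricted Boltzmann machine
#'
#' One set of parameters is shared by all per-entity RBMs. Under the default
#' \code{"disease_visible"} orientation each drug has its own RBM whose
#' visible layer is that drug's associated diseases, three binary visible
#' variables per disease (one per phenotype type); under
#' \code{"drug_visible"} the axes swap and each disease has an RBM over its
#' associated drugs.
#'
#' @slot W numeric array (nVisible, m, 3): connection weight between visible
#'   variable (entity i, type k) and hidden unit j, shared across all
#'   per-entity RBMs.
#' @slot a numeric matrix (nVisible, 3): visible biases.
#' @slot b numeric vector (m): hidden biases.
#' @slot D numeric matrix (nVisible, m): conditional weights coupling the
#'   binary "has any known association" indicator vector r to the hidden
#'   units (an observed side channel that shifts hidden pre-activations).
#' @slot orientation \code{"disease_visible"} or \code{"drug_visible"}.
#' @export
setClass("RBMModel",
         representation(W = "array", a = "matrix", b = "numeric",
                        D = "matrix", orientation = "character"))

.validRBMModel <- function(object) {
  msg <- NULL
  dW <- dim(object@W)
  if (length(dW) != 3L || dW[3] != 3L)
    msg <- c(msg, "W must be a (nVisible, m, 3) array")
  else {
    if (!all(dim(object@a) == c(dW[1], 3L)))
      msg <- c(msg, "a must be (nVisible, 3)")
    if (length(object@b) != dW[2])
      msg <- c(msg, "b must have length m")
    if (!all(dim(object@D) == dW[1:2]))
      msg <- c(msg, "D must be (nVisible, m)")
  }
  if (!object@orientation %in% c("disease_visible", "drug_visible"))
    msg <- c(msg, "orientation must be 'disease_visible' or 'drug_visible'")
  if (is.null(msg) &&
      !all(is.finite(object@W)) || !all(is.finite(object@a)) ||
      !all(is.finite(object@b)) || !all(is.finite(object@D)))
    msg <- c(msg, "all parameters must be finite")
  if (is.null(msg)) TRUE else msg
}
setValidity("RBMModel", .validRBMModel)

#' Construct an RBMModel
#'
#' @param W (nVisible, m, 3) weight array.
#' @param a (nVisible, 3) visible-bias matrix.
#' @param b length-m hidden-bias vector.
#' @param D (nVisible, m) conditional-weight matrix.
#' @param orientation \code{"disease_visible"} (per-drug RBMs, default) or
#'   \code{"drug_visible"} (per-disease RBMs).
#' @return An [RBMModel-class].
#' @export
RBMModel <- function(W, a, b, D, orientation = "disease_visible") {
  methods::new("RBMModel", W = W, a = a, b = b, D = D,
               orientation = orientation)
}

#' @describeIn RBMModel number of hidden units
#' @param object An RBMModel.
#' @export
nHidden <- function(object) dim(object@W)[2]

#' @describeIn RBMModel number of visible entities (diseases under the
#'   default orientation)
#' @export
nVisible <- function(object) dim(object@W)[1]

setMethod("show", "RBMModel", function(object) {
  cat("RBMModel (conditional RBM, shared weights)\n")
  cat("  orientation:", object@orientation, "\n")
  cat("  visible entities:", nVisible(object), " hidden units:",
      nHidden(object), " types: 3\n")
})

#' DrugView: one entity's visible layer and conditioning indicator
#'
#' The per-drug view of the tensor that a single RBM sees: the set O of
#' diseases with at least one known association to the drug, the 3-bit
#' visible block over O, and the binary indicator vector r over all
#' diseases with \code{r[i] == 1} iff \code{i} is in O. Under the flipped
#' orientation the roles of drug and disease swap.
#'
#' @slot entity integer, index of the drug (or disease) this view belongs to.
#' @slot observed integer vector O of observed visible-entity indices.
#' @slot v numeric matrix (nVisible, 3) of visible bits; rows outside O are
#'   all zero.
#' @slot r numeric vector of length nVisible, the conditioning indicator.
#' @export
setClass("DrugView",
         representation(entity = "integer", observed = "integer",
                        v = "matrix", r = "numeric"))

.validDrugView <- function(object) {
  msg <- NULL
  n <- nrow(object@v)
  if (length(object@r) != n)
    msg <- c(msg, "r must have one entry per visible entity")
  if (ncol(object@v) != 3L)
    msg <- c(msg, "v must have 3 columns (one per phenotype type)")
  if (!all(object@v %in% c(0, 1)) || !all(object@r %in% c(0, 1)))
    msg <- c(msg, "v and r must be binary")
  inO <- which(object@r == 1)
  if (!identical(sort(inO), sort(as.integer(object@observed))))
    msg <- c(msg, "r[i] == 1 must hold exactly for i in the observed set")
  if (length(object@observed) && !all(rowSums(object@v)[object@observed] >= 1))
    msg <- c(msg, "every observed entity must carry at least one visible bit")
  if (n > 0 && length(object@observed) < n &&
      any(rowSums(object@v)[setdiff(seq_len(n), object@observed)] > 0))
    msg <- c(msg, "unobserved entities must have all-zero visible bits")
  if (is.null(msg)) TRUE else msg
}
setValidity("DrugView", .validDrugView)

setMethod("show", "DrugView", function(object) {
  cat("DrugView: entity", object@entity, "with", length(object@observed),
      "of", nrow(object@v), "visible entities observed,",
      sum(object@v), "visible bits set\n")
})

#' Extract one drug's view of the tensor
#'
#' Builds the visible layer of the per-drug RBM: the observed disease set
#' O = \{j : A[i, j, k] = 1 for some k\}, the binary visible block over
#' O x 3, and the indicator vector r. A drug with no associations yields an
#' empty observed set (callers typically skip such drugs during training).
#'
#' @param tensor An [AssociationTensor-class].
#' @param drug 1-based drug index.
#' @return A [DrugView-class].
#' @export
#' @examples
#' a <- array(0L, c(3, 4, 3)); a[1, 2, 2] <- a[1, 2, 3] <- 1L
#' v <- drugView(AssociationTensor(a), 1)
#' v@observed  # disease 2
#' v@v[2, ]    # (0, 1, 1): side effect and contraindication
drugView <- function(tensor, drug) {
  stopifnot(is(tensor, "AssociationTensor"))
  if (drug < 1L || drug > nrow(tensor))
    stop("drug index out of range")
  v <- vapply(1:3,
              function(k) as.numeric(SummarizedExperiment::assay(tensor, k)[drug, ]),
              numeric(ncol(tensor)))
  if (is.null(dim(v))) v <- matrix(v, ncol = 3L)
  obs <- which(rowSums(v) > 0)
  r <- as.numeric(rowSums(v) > 0)
  methods::new("DrugView", entity = as.integer(drug),
               observed = as.integer(obs), v = v, r = r)
}
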