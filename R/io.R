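# Readers and writers for the tensor, id<->name tables, class partitions and
# ranked-prediction files. External files use 1-based entity ids; so does
# everything in memory, so no index shifting happens anywhere.

#' Read an association tensor from an NPY file
#'
#' The file must hold a 3-D binary array of shape
#' (drugs, diseases, 3), with the third axis ordered as
#' indication, side effect, contraindication.
#'
#' @param path Path to the \code{.npy} file.
#' @return An [AssociationTensor-class].
#' @export
readTensor <- function(path) {
  a <- readNpy(path)
  if (is.null(dim(a)) || length(dim(a)) != 3L)
    stop("tensor file must hold a 3-D array")
  if (dim(a)[3] != 3L)
    stop(sprintf("last tensor dimension must be 3 phenotype types, got %d",
                 dim(a)[3]))
  if (!all(a == 0 | a == 1))
    stop("tensor entries must all be 0 or 1")
  AssociationTensor(a)
}

#' Write an association tensor to an NPY file
#'
#' @param tensor An [AssociationTensor-class].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeTensor <- function(tensor, path) {
  stopifnot(is(tensor, "AssociationTensor"))
  writeNpy(assocArray(tensor), path)
}

#' Read a drug or disease id/name table
#'
#' Tab-separated with a header; columns \code{id} and \code{name}, plus an
#' optional concept-identifier column (e.g. a UMLS CUI). Ids must be unique
#' and contiguous from 1, so that \code{id} indexes the matching tensor axis
#' directly.
#'
#' @param path Path to the TSV file.
#' @param axis \code{"drug"} or \code{"disease"} (recorded as an attribute).
#' @return data.frame with columns \code{id}, \code{name} (and any extra
#'   columns present), ordered by id.
#' @export
readEntityTable <- function(path, axis = c("drug", "disease")) {
  axis <- match.arg(axis)
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(tab) == 0L)
    stop(sprintf("entity table '%s' is empty", path))
  if (!all(c("id", "name") %in% names(tab)))
    stop("entity table must have 'id' and 'name' columns")
  tab <- tab[order(tab$id), , drop = FALSE]
  if (anyDuplicated(tab$id) || !identical(as.integer(tab$id), seq_len(nrow(tab))))
    stop("entity ids must be unique and contiguous from 1")
  rownames(tab) <- NULL
  attr(tab, "axis") <- axis
  tab
}

#' Read a class partition table
#'
#' Tab-separated with a header; columns \code{id} (1-based entity id) and
#' \code{class}. Used for leave-one-class-out cross-validation (e.g. 15 ATC
#' drug classes, 23 MeSH disease classes).
#'
#' @param path Path to the TSV file.
#' @param axis \code{"drug"} or \code{"disease"}.
#' @param n Number of entities on that axis (checked for full coverage).
#' @return Character vector of class labels indexed by entity id, with the
#'   axis stored as an attribute.
#' @export
readClassPartition <- function(path, axis = c("drug", "disease"), n = NULL) {
  axis <- match.arg(axis)
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("id", "class") %in% names(tab)))
    stop("class partition must have 'id' and 'class' columns")
  if (anyDuplicated(tab$id))
    stop("each entity must have exactly one class label")
  if (!is.null(n) && !setequal(tab$id, seq_len(n)))
    stop("every entity on the axis needs a class label")
  out <- tab$class[order(tab$id)]
  attr(out, "axis") <- axis
  out
}

#' Build ranked prediction records from a score array
#'
#' Pairs every (drug, disease, type) triple with its predicted probability
#' and a status flag telling whether the triple is a known association in
#' the input tensor (status = 1) or not (status = 0).
#'
#' @param scores Numeric array (nDrugs, nDiseases, 3) of probabilities.
#' @param tensor The input [AssociationTensor-class] the statuses refer to.
#' @return data.frame with columns \code{drug}, \code{disease}, \code{type},
#'   \code{score}, \code{status}, sorted by descending score within type.
#' @export
rankedPredictions <- function(scores, tensor) {
  stopifnot(is(tensor, "AssociationTensor"))
  if (!all(dim(scores) == c(nrow(tensor), ncol(tensor), 3L)))
    stop("scores must match the tensor dimensions")
  a <- assocArray(tensor)
  idx <- expand.grid(drug = seq_len(nrow(tensor)),
                     disease = seq_len(ncol(tensor)), type = 1:3)
  rec <- data.frame(idx, score = as.vector(scores), status = as.vector(a))
  rec <- rec[order(rec$type, -rec$score, rec$drug, rec$disease), ]
  rownames(rec) <- NULL
  rec
}

#' Write ranked predictions, one TSV per phenotype type
#'
#' Each file has exactly four tab-separated columns -- drug id, disease id,
#' prediction score, status -- sorted by descending score, no header.
#' Scores are serialised with six decimal places.
#'
#' @param records data.frame with columns \code{drug}, \code{disease},
#'   \code{type}, \code{score}, \code{status} (as from
#'   [rankedPredictions()]).
#' @param prefix Output path prefix; files are written as
#'   \code{<prefix>_<type>.tsv} for each type present in \code{records}.
#' @return Invisibly, the vector of file paths written.
#' @export
writeRankedPredictions <- function(records, prefix) {
  need <- c("drug", "disease", "type", "score", "status")
  if (!all(need %in% names(records)))
    stop("records must have columns drug, disease, type, score, status")
  if (any(records$score < 0 | records$score > 1))
    stop("scores must be probabilities in [0, 1]")
  if (!all(records$status %in% c(0, 1)))
    stop("status must be 0 or 1")
  paths <- character(0)
  for (k in sort(unique(records$type))) {
    sub <- records[records$type == k, , drop = FALSE]
    sub <- sub[order(-sub$score, sub$drug, sub$disease), , drop = FALSE]
    out <- data.frame(sub$drug, sub$disease, sprintf("%.6f", sub$score),
                      sub$status)
    p <- sprintf("%s_%s.tsv", prefix, phenotypeTypes()[k])
    write.table(out, p, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
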