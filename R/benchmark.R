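# Full-scale benchmark against the published association data. The real
# tensor (2141 drugs x 780 diseases x 3) is distributed as supplementary
# data and is not shipped with this package; point `tensorPath` at a local
# copy. Training the full-scale model (m = 400, 300 epochs, 2141 drugs)
# takes well over 15 minutes on one CPU, which is why this runs as an
# explicit benchmark entry point rather than inside the regular examples.

#' Reproduce the full-scale published benchmarks
#'
#' Loads the published association tensor, balances the three phenotype
#' types to equal counts, and reruns the cross-validated comparisons: the
#' conditional RBM against drug-based KNN (k = 6) and disease-based KNN
#' (k = 5) under tenfold cross-validation, optionally the
#' leave-one-drug-class-out scheme, and the flipped (drug-visible)
#' orientation under leave-one-disease-class-out.
#'
#' @param tensorPath Path to the full association tensor in NPY format
#'   (2141 x 780 x 3 for the published data).
#' @param drugClassPath,diseaseClassPath Optional TSV class partitions
#'   (id, class) enabling the leave-one-class-out schemes (15 ATC drug
#'   classes / 23 MeSH disease classes for the published data).
#' @param m,learningRate,epochs RBM settings; defaults are the published
#'   grid-search optimum.
#' @param negatives Negatives handling passed to [runExperiment()].
#' @param seed Integer seed.
#' @return data.frame of per-method, per-type AUC/AUPR rows across the
#'   schemes run.
#' @export
reproduceBenchmark <- function(tensorPath,
                               drugClassPath = NULL, diseaseClassPath = NULL,
                               m = 400L, learningRate = 0.5, epochs = 300L,
                               negatives = "all", seed = 1L) {
  if (!file.exists(tensorPath))
    stop(sprintf(paste0(
      "full association tensor not available at '%s'; download the ",
      "published supplementary NPY array and pass its path"), tensorPath))
  tensor <- readTensor(tensorPath)
  balanced <- balanceTensor(tensor, seed = seed)
  crbmCfg <- list(crbm = list(m = m, learningRate = learningRate,
                              epochs = epochs))
  out <- runExperiment(balanced,
                       methods = c("crbm", "drug_knn", "disease_knn"),
                       scheme = "tenfold", negatives = negatives,
                       config = crbmCfg, seed = seed)
  if (!is.null(drugClassPath)) {
    part <- readClassPartition(drugClassPath, "drug", nDrugs(balanced))
    out <- rbind(out, runExperiment(
      balanced, methods = c("crbm", "drug_knn", "disease_knn"),
      scheme = "leave_one_drug_class_out", partition = part,
      negatives = negatives, config = crbmCfg, seed = seed))
  }
  if (!is.null(diseaseClassPath)) {
    part <- readClassPartition(diseaseClassPath, "disease",
                               nDiseases(balanced))
    flipCfg <- list(crbm = c(crbmCfg$crbm, list(orientation = "drug_visible")))
    out <- rbind(out, runExperiment(
      balanced, methods = "crbm",
      scheme = "leave_one_disease_class_out", partition = part,
      negatives = negatives, config = flipCfg, seed = seed))
  }
  rownames(out) <- NULL
  out
}
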