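test_that("AssociationTensor validates shape, binarity and type order", {
  a <- array(0L, c(5, 4, 3))
  at <- AssociationTensor(a)
  expect_s4_class(at, "AssociationTensor")
  expect_equal(nDrugs(at), 5)
  expect_equal(nDiseases(at), 4)
  expect_equal(sum(assocArray(at)), 0)

  expect_error(AssociationTensor(array(0L, c(5, 4, 2))), "third dimension")
  bad <- array(0L, c(2, 2, 3)); bad[1, 1, 1] <- 2L
  expect_error(AssociationTensor(bad), "0")
})

test_that("tensor NPY round trip is bit exact and rejects malformed input", {
  set.seed(1)
  a <- array(rbinom(5 * 4 * 3, 1, 0.3), c(5, 4, 3))
  at <- AssociationTensor(a)
  path <- withr::local_tempfile(fileext = ".npy")
  writeTensor(at, path)
  back <- readTensor(path)
  expect_identical(assocArray(back), assocArray(at))

  p2 <- withr::local_tempfile(fileext = ".npy")
  writeNpy(array(0, c(5, 4, 2)), p2)
  expect_error(readTensor(p2), "phenotype types")
  writeNpy(array(2, c(2, 2, 3)), p2)
  expect_error(readTensor(p2), "0 or 1")
  writeNpy(matrix(0, 2, 2), p2)
  expect_error(readTensor(p2), "3-D")
  writeLines("not an npy file", p2)
  expect_error(readTensor(p2), "magic")
})

test_that("NPY reader handles numpy dtypes and C order", {
  # C-order stream written by hand with an int64 payload, shape (2, 3)
  path <- withr::local_tempfile(fileext = ".npy")
  hdr <- "{'descr': '<i8', 'fortran_order': False, 'shape': (2, 3), }"
  pad <- (16 - (10 + nchar(hdr) + 1) %% 16) %% 16
  hdr <- paste0(hdr, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"))), con)
  writeBin(c(1L, 0L), con, size = 1)
  writeBin(nchar(hdr), con, size = 2, endian = "little")
  writeBin(charToRaw(hdr), con)
  for (v in 0:5) writeBin(c(v, 0L), con, size = 4, endian = "little")
  close(con)
  x <- readNpy(path)
  expect_equal(dim(x), c(2, 3))
  expect_equal(x[1, ], c(0, 1, 2))  # row-major source
  expect_equal(x[2, ], c(3, 4, 5))
})

test_that("entity tables require contiguous unique 1-based ids", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tname", "1\tZoledronate", "2\tEstradiol"), path)
  tab <- readEntityTable(path, "drug")
  expect_equal(nrow(tab), 2)
  expect_equal(tab$name, c("Zoledronate", "Estradiol"))

  writeLines(c("id\tname", "1\ta", "3\tb"), path)
  expect_error(readEntityTable(path, "drug"), "contiguous")
  writeLines("id\tname", path)
  expect_error(readEntityTable(path, "drug"), "empty")
})

test_that("drugView extracts observed set, visible bits and indicator", {
  at <- tinyTensor()
  v1 <- drugView(at, 1)
  expect_equal(v1@observed, c(2L, 3L))
  expect_equal(v1@v[2, ], c(1, 0, 0))    # indication only
  expect_equal(v1@v[3, ], c(0, 1, 1))    # SE + CI together
  expect_equal(v1@r, c(0, 1, 1, 0))

  v5 <- drugView(at, 5)
  expect_length(v5@observed, 0)
  expect_true(all(v5@r == 0))
  expect_error(drugView(at, 6), "range")
})

test_that("observed sets partition the associated pairs", {
  set.seed(7)
  a <- array(rbinom(20 * 10 * 3, 1, 0.1), c(20, 10, 3))
  at <- AssociationTensor(a)
  total <- sum(vapply(seq_len(20), function(d)
    length(drugView(at, d)@observed), 0L))
  anyPair <- sum(apply(a, c(1, 2), max))
  expect_equal(total, anyPair)
})

test_that("ranked prediction files are sorted, 4-column, status-consistent", {
  at <- tinyTensor()
  set.seed(3)
  scores <- array(runif(5 * 4 * 3), c(5, 4, 3))
  rec <- rankedPredictions(scores, at)
  a <- assocArray(at)
  expect_true(all(rec$status == a[cbind(rec$drug, rec$disease, rec$type)]))

  prefix <- file.path(withr::local_tempdir(), "pred")
  paths <- writeRankedPredictions(rec, prefix)
  expect_length(paths, 3)
  for (p in paths) {
    tab <- read.delim(p, header = FALSE)
    expect_equal(ncol(tab), 4)
    expect_false(is.unsorted(rev(tab[[3]])))
  }

  bad <- rec; bad$score[1] <- 1.2
  expect_error(writeRankedPredictions(bad, prefix), "probabilities")
})

test_that("model checkpoints round trip through NPY + JSON sidecar", {
  set.seed(9)
  model <- randomModel(4, 3)
  prefix <- file.path(withr::local_tempdir(), "model")
  saveRBMModel(model, prefix, config = list(seed = 9))
  back <- loadRBMModel(prefix)
  expect_equal(back@W, model@W)
  expect_equal(back@a, model@a)
  expect_equal(back@b, model@b)
  expect_equal(back@D, model@D)
  expect_equal(back@orientation, model@orientation)
})
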