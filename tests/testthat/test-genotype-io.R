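test_that("dosage tables are read in both codings with missing cells flagged", {
  p012 <- writeTempLines(c("id,M1,M2", "L1,0,2", "L2,1,2"))
  G <- readGenotypeTable(p012, coding = "dosage012")
  expect_identical(dosages(G),
                   matrix(c(0, 1, 2, 2), 2, 2,
                          dimnames = list(c("L1", "L2"), c("M1", "M2"))))
  expect_false(any(missingMask(G)))

  p101 <- writeTempLines(c("id,M1,M2", "L1,-1,1", "L2,0,1"))
  G2 <- readGenotypeTable(p101, coding = "symmetric101")
  expect_identical(unname(dosages(G2)), matrix(c(0, 1, 2, 2), 2, 2))

  pna <- writeTempLines(c("id\tM1\tM2", "L1\tNA\t2", "L2\t1\t"))
  G3 <- readGenotypeTable(pna)
  expect_identical(unname(missingMask(G3)),
                   matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2))
  expect_identical(unname(dosages(G3)[2, 1]), 1)
})

test_that("malformed genotype tables are rejected with informative errors", {
  bad <- writeTempLines(c("id,M1,M2", "L1,0,x", "L2,1,2"))
  expect_error(readGenotypeTable(bad), "L1.*M2|M2.*L1")
  dup <- writeTempLines(c("id,M1,M2", "L1,0,1", "L1,1,2"))
  expect_error(readGenotypeTable(dup), "duplicate line")
  outr <- writeTempLines(c("id,M1,M2", "L1,0,3", "L2,1,2"))
  expect_error(readGenotypeTable(outr), "outside the declared coding")
  out101 <- writeTempLines(c("id,M1", "L1,2"))
  expect_error(readGenotypeTable(out101, coding = "symmetric101"),
               "outside the declared coding")
})

test_that("curation removes markers first, then lines, strictly above threshold", {
  d <- matrix(c(0, 1, 2, 0,
                NA, NA, 1, 2,
                2, 0, 1, 1), 4, 3)
  G <- toyGeno(d)  # marker 2 is 50% missing
  cur <- curateGenotypes(G)
  expect_identical(markerIds(cur), c("M1", "M3"))
  expect_identical(dim(cur), c(4L, 2L))

  # exactly at the threshold: retained ("more than" triggers removal)
  d10 <- matrix(0, 10, 2)
  d10[1, 1] <- NA
  G10 <- toyGeno(d10)
  expect_identical(dim(curateGenotypes(G10, maxMarkerMissing = 0.10,
                                       maxLineMissing = 0.5)),
                   c(10L, 2L))
  # just above the threshold: removed
  expect_identical(dim(curateGenotypes(G10, maxMarkerMissing = 0.09,
                                       maxLineMissing = 0.5)),
                   c(10L, 1L))

  # lines filtered on surviving markers only
  dl <- cbind(c(NA, NA, NA, 0), c(0, 1, 2, 0), c(0, NA, 1, 2))
  Gl <- toyGeno(dl)
  cur2 <- curateGenotypes(Gl, maxMarkerMissing = 0.5, maxLineMissing = 0.25)
  expect_identical(markerIds(cur2), c("M2", "M3"))
  expect_identical(lineIds(cur2), c("L1", "L3", "L4"))

  # no missing data: unchanged; and curation is idempotent
  Gc <- randomGeno(6, 5, seed = 3)
  expect_identical(dosages(curateGenotypes(Gc)), dosages(Gc))
  once <- curateGenotypes(Gl, maxMarkerMissing = 0.5, maxLineMissing = 0.25)
  twice <- curateGenotypes(once, maxMarkerMissing = 0.5, maxLineMissing = 0.25)
  expect_identical(dosages(twice), dosages(once))
  expect_identical(missingMask(twice), missingMask(once))

  allmiss <- toyGeno(matrix(NA_real_, 2, 2))
  expect_error(curateGenotypes(allmiss), "all markers")
})

test_that("population-mean imputation fills missing cells and preserves marker means", {
  G <- toyGeno(matrix(c(0, 2, NA, 2, 2, NA), 3, 2))
  imp <- imputePopulationMean(G)
  expect_equal(unname(dosages(imp)[3, ]), c(1, 2))
  # provenance kept
  expect_identical(unname(missingMask(imp)[3, ]), c(TRUE, TRUE))
  # marker means unchanged by imputation
  d <- dosages(G)
  expect_equal(colMeans(dosages(imp)), colMeans(d, na.rm = TRUE))
  # complete input returned as-is
  Gc <- randomGeno(5, 4, seed = 9)
  expect_identical(dosages(imputePopulationMean(Gc)), dosages(Gc))
  # fully missing marker: directed to curation
  Gm <- toyGeno(matrix(c(0, 1, NA, NA), 2, 2))
  expect_error(imputePopulationMean(Gm), "curateGenotypes")
})

test_that("square-matrix round trip is lossless beyond 12 significant digits", {
  set.seed(4)
  M <- matrix(rnorm(25), 5, 5)
  M <- M - mean(M)  # ensure negative entries survive
  ids <- paste0("L", 1:5)
  path <- tempfile()
  writeSquareMatrix(M, ids, path)
  M2 <- readSquareMatrix(path)
  expect_identical(rownames(M2), ids)
  expect_lt(max(abs(M2 - M)), 1e-12 * max(abs(M)))
  expect_true(any(M2 < 0))
  expect_error(writeSquareMatrix(matrix(0, 2, 3), c("a", "b"), tempfile()),
               "square")
  expect_error(writeSquareMatrix(diag(2), c("a", "b", "c"), tempfile()),
               "ids")
})

test_that("genotype write/read round trip preserves dosages, mask and ids", {
  G <- randomImputedGeno(8, 6, seed = 11)
  path <- tempfile()
  writeGenotypeTable(G, path)
  G2 <- readGenotypeTable(path)
  expect_equal(dosages(G2), dosages(G), tolerance = 1e-12)
  expect_identical(lineIds(G2), lineIds(G))
  # a matrix still carrying NAs round-trips its mask
  d <- dosages(randomGeno(4, 3, seed = 2))
  d[2, 2] <- NA
  Gna <- GenotypeMatrix(d)
  p2 <- tempfile()
  writeGenotypeTable(Gna, p2)
  expect_identical(missingMask(readGenotypeTable(p2)), missingMask(Gna))
})

test_that("phenotype tables parse into named vectors and reject bad input", {
  p <- writeTempLines(c("id,trait", "L1,1.5", "L2,-0.25"))
  y <- readPhenotypeTable(p)
  expect_equal(y, c(L1 = 1.5, L2 = -0.25))
  bad <- writeTempLines(c("id,trait", "L1,abc"))
  expect_error(readPhenotypeTable(bad), "L1")
  three <- writeTempLines(c("id,a,b", "L1,1,2"))
  expect_error(readPhenotypeTable(three), "two columns")
})
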