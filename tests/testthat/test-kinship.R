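test_that("centering produces zero-sum columns, frequencies and the pq denominator", {
  G <- toyGeno(matrix(c(0, 2, 2, 0), 2, 2))
  C <- centerGenotypes(G)
  expect_equal(alleleFreq(C), c(0.5, 0.5))
  expect_equal(unname(C@W), matrix(c(-1, 1, 1, -1), 2, 2))
  expect_equal(C@denom, 1)

  het <- centerGenotypes(toyGeno(matrix(1, 2, 2)))
  expect_equal(unname(het@W), matrix(0, 2, 2))

  mono <- centerGenotypes(toyGeno(cbind(c(2, 2), c(0, 2))))
  expect_equal(alleleFreq(mono)[1], 1)
  expect_equal(unname(mono@W[, 1]), c(0, 0))
  expect_equal(mono@denom, 2 * 0.5 * 0.5)  # monomorphic column contributes 0

  d <- matrix(c(0, NA, 2, 1), 2, 2)
  expect_error(centerGenotypes(toyGeno(d)), "imputePopulationMean")
})

test_that("sample covariance matches its definition and is symmetric", {
  W <- matrix(c(-1, 1, 1, -1), 2, 2)
  expect_equal(sampleCovariance(W), matrix(c(1, -1, -1, 1), 2, 2))
  expect_equal(sampleCovariance(matrix(0, 3, 4)), matrix(0, 3, 3))
  # duplicated rows give duplicated rows/cols
  set.seed(8)
  W2 <- rbind(a = rnorm(10), b = rnorm(10))
  W3 <- rbind(W2, W2[1, , drop = FALSE])
  S <- sampleCovariance(W3)
  expect_equal(S[1, ], S[3, ])
  expect_equal(S, t(S))
  # definition check against cov-style direct computation
  C <- centerGenotypes(randomGeno(6, 12, seed = 5))
  m <- ncol(C@W)
  direct <- tcrossprod(C@W) / m - tcrossprod(rowMeans(C@W))
  expect_equal(sampleCovariance(C), (direct + t(direct)) / 2, tolerance = 1e-12)
})

test_that("plain relationship matrix has mean diagonal 1+f and zero row sums", {
  G <- toyGeno(matrix(c(2, 0, 2, 0), 2, 2))
  A <- kinshipPlain(centerGenotypes(G))
  expect_equal(unname(relMatrix(A)), matrix(c(2, -2, -2, 2), 2, 2))
  expect_equal(inbreedingF(A), 1)

  het <- kinshipPlain(centerGenotypes(toyGeno(cbind(c(1, 1), c(0, 2)))))
  expect_equal(inbreedingF(het), mean(diag(relMatrix(het))) - 1)

  for (seed in 1:4) {
    G <- randomGeno(15, 30, seed = seed, inbred = seed %% 2 == 0)
    A <- relMatrix(kinshipPlain(centerGenotypes(G)))
    expect_lt(max(abs(rowSums(A))), 1e-9)
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(ev))  # PSD
    expect_lt(min(abs(ev)), 1e-8 * max(ev))  # centering null direction
  }

  allmono <- toyGeno(matrix(2, 3, 2))
  expect_error(kinshipPlain(centerGenotypes(allmono)), "monomorphic")
})

test_that("IBS matrix equals the allele-sharing fraction on homozygous panels", {
  same <- toyGeno(rbind(c(2, 0, 2), c(2, 0, 2)))
  expect_equal(unname(ibsMatrix(same)), matrix(1, 2, 2))
  opp <- toyGeno(rbind(c(2, 0, 2), c(0, 2, 0)))
  expect_equal(ibsMatrix(opp)[1, 2], 0)
  for (seed in 1:3) {
    G <- randomGeno(8, 40, seed = seed, inbred = TRUE)
    M <- ibsMatrix(G)
    X <- dosages(G)
    count <- matrix(0, 8, 8)
    for (i in 1:8) for (j in 1:8)
      count[i, j] <- mean(X[i, ] == X[j, ])
    expect_equal(unname(M), count, tolerance = 1e-12)
  }
})

test_that("per-locus, per-line and population inbreeding agree exactly", {
  hom <- toyGeno(cbind(c(0, 2), c(0, 2)))
  expect_equal(unname(inbreedingSummary(hom)@fk), c(1, 1))
  het <- toyGeno(cbind(c(1, 1), c(0, 2)))
  expect_equal(unname(inbreedingSummary(het)@fk[1]), -1)

  # all p = 1/2: phi simplifies to 2 * homozygous fraction - 1
  X <- rbind(c(0, 2, 1, 1), c(2, 0, 1, 1), c(1, 1, 0, 2), c(1, 1, 2, 0))
  ib <- inbreedingSummary(toyGeno(X))
  psi <- rowMeans(X != 1)
  expect_equal(unname(ib@phi), 2 * psi - 1)

  # monomorphic loci carry zero weight and f_k = 0
  Gm <- toyGeno(cbind(c(2, 2, 2), c(0, 1, 2)))
  ibm <- inbreedingSummary(Gm)
  expect_equal(unname(ibm@fk[1]), 0)
  expect_equal(unname(ibm@betak), c(0, 1))
  expect_error(inbreedingSummary(toyGeno(matrix(2, 2, 2))), "monomorphic")

  # triple identity on random integer and imputed real-valued panels
  for (seed in 1:5) {
    G <- if (seed %% 2) randomGeno(12, 25, seed = seed)
         else randomImputedGeno(12, 25, seed = seed)
    ib <- inbreedingSummary(G)
    A <- kinshipPlain(centerGenotypes(G))
    expect_equal(sum(ib@betak * ib@fk), mean(ib@phi), tolerance = 1e-10)
    expect_equal(inbreedingF(ib), inbreedingF(A), tolerance = 1e-10)
  }
})

test_that("eigenvalue CV and the shrinkage heuristic follow their closed forms", {
  expect_equal(eigenvalueCV(diag(3) * 2.5), 0)
  expect_equal(eigenvalueCV(diag(c(1, 3))), 0.5)
  expect_error(eigenvalueCV(diag(c(-1, -2))), "positive")
  expect_error(eigenvalueCV(matrix(c(1, 2, 0, 1), 2, 2)), "symmetric")

  expect_equal(heuristicIntensity(100, 100, 1), 1)
  expect_equal(heuristicIntensity(100, 200, 1),
               heuristicIntensity(100, 100, 1) / 2)
  expect_equal(heuristicIntensity(274, 384, 1.3), 0.422, tolerance = 0.01)
  expect_error(heuristicIntensity(10, 10, 0), "cv")
})

test_that("structured populations show higher eigenvalue CV than unstructured", {
  Gu <- simulatePopulation(80, 600, seed = 41)
  Gs <- simulatePopulation(80, 600, nSubpops = 2, divergence = 0.3, seed = 42)
  cvU <- eigenvalueCV(sampleCovariance(centerGenotypes(Gu)))
  cvS <- eigenvalueCV(sampleCovariance(centerGenotypes(Gs)))
  expect_gt(cvS, cvU)
})
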