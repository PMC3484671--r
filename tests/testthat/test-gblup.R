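test_that("profiled REML matches a dense grid search on the 6-line toy", {
  X <- rbind(c(2, 2, 0, 0), c(2, 0, 2, 0), c(0, 2, 2, 0),
             c(2, 2, 2, 2), c(0, 0, 0, 0), c(2, 0, 0, 2))
  G <- toyGeno(X)
  A <- kinshipPlain(centerGenotypes(G))
  y <- c(1.2, 0.6, 0.9, 2.0, -1.5, 0.1)
  names(y) <- lineIds(A)
  fit <- fitGBLUP(y, A)
  oracle <- remlOracleGrid(relMatrix(A), unname(y))
  expect_equal(fit@logREML, oracle$logREML, tolerance = 1e-6)
  if (!fit@boundary) {
    expect_equal(log10(fit@lambda), oracle$log10lambda, tolerance = 5e-3)
  }
  # dense evaluation at the fitted ratio can be no better than the optimum
  expect_gte(fit@logREML + 1e-8,
             denseREML(relMatrix(A), unname(y), fit@lambda))
})

test_that("noiseless phenotypes drive the residual variance to the boundary", {
  # a structured panel identifies the variance ratio cleanly, so the
  # noiseless limit lands on the sigmaE2 = 0 boundary and is flagged
  G <- simulatePopulation(80, 400, nSubpops = 3, divergence = 0.3, seed = 202)
  A <- estimateKinship(G, "plain")
  tr <- simulateTrait(A, 0, seed = 2)
  fit <- fitGBLUP(phenotypes(tr), A)
  expect_true(fit@boundary)
  expect_lt(fit@sigmaE2 / fit@sigma2, 1e-6)
  # GEBVs reproduce the centered phenotypes up to the null direction
  r <- phenotypes(tr) - fit@muHat
  expect_lt(max(abs(gebv(fit) - r)), 1e-3 * diff(range(r)))
})

test_that("an identity relationship matrix flags the unidentifiable ridge", {
  n <- 12
  A <- diag(n)
  dimnames(A) <- list(paste0("L", 1:n), paste0("L", 1:n))
  set.seed(2)
  y <- rnorm(n)
  names(y) <- rownames(A)
  fit <- fitGBLUP(y, A)
  expect_true(fit@boundary)
  # only the total variance is identified; it equals the sample variance
  expect_equal(fit@sigma2 + fit@sigmaE2, var(y), tolerance = 1e-6)
})

test_that("fits are invariant to phenotype location and equivariant to scale", {
  G <- randomGeno(15, 40, seed = 21)
  A <- kinshipPlain(centerGenotypes(G))
  tr <- simulateTrait(A, 1, seed = 5)
  y <- phenotypes(tr)
  fit <- fitGBLUP(y, A)

  shift <- fitGBLUP(y + 3.7, A)
  expect_equal(shift@muHat, fit@muHat + 3.7, tolerance = 1e-10)
  expect_equal(shift@sigma2, fit@sigma2, tolerance = 1e-10)
  expect_equal(shift@sigmaE2, fit@sigmaE2, tolerance = 1e-10)
  expect_equal(gebv(shift), gebv(fit), tolerance = 1e-10)

  s <- 2.5
  scaled <- fitGBLUP(s * y, A)
  expect_equal(scaled@sigma2, s^2 * fit@sigma2, tolerance = 1e-6)
  expect_equal(scaled@sigmaE2, s^2 * fit@sigmaE2, tolerance = 1e-6)
  expect_equal(gebv(scaled), s * gebv(fit), tolerance = 1e-6)
})

test_that("prediction reproduces training GEBVs and handles special targets", {
  G <- randomGeno(18, 50, seed = 33, inbred = TRUE)
  A <- kinshipPlain(centerGenotypes(G))
  tr <- simulateTrait(A, 2, seed = 6)
  ids <- lineIds(A)
  train <- ids[1:12]
  fit <- fitGBLUP(phenotypes(tr)[train], A, trainIds = train)

  expect_equal(predictGEBV(fit, A, train), gebv(fit), tolerance = 1e-12)
  expect_error(predictGEBV(fit, A, "nosuchline"), "unknown target")

  # a line unrelated to all training lines gets GEBV exactly 0
  M <- relMatrix(A)
  M["L18", train] <- 0
  M[train, "L18"] <- 0
  expect_equal(unname(predictGEBV(fit, M, "L18")), 0)

  # a duplicate of a training line (identical relationship row) matches it
  M2 <- relMatrix(A)
  M2["L17", train] <- M2["L1", train]
  expect_equal(unname(predictGEBV(fit, M2, "L17")),
               unname(gebv(fit)["L1"]), tolerance = 1e-12)
})

test_that("fit preconditions are enforced", {
  A <- diag(5)
  dimnames(A) <- list(paste0("L", 1:5), paste0("L", 1:5))
  y2 <- c(L1 = 1, L2 = 2)
  expect_error(fitGBLUP(y2, A), "3 training lines")
  yc <- setNames(rep(1, 5), rownames(A))
  expect_error(fitGBLUP(yc, A), "zero variance")
  yb <- setNames(rnorm(5), c("L1", "L2", "L3", "L4", "Lx"))
  expect_error(fitGBLUP(yb, A), "absent")
})

test_that("heritability estimators follow their closed forms", {
  expect_equal(heritabilityComponents(1, 1, 1), 2 / 3)
  expect_equal(heritabilityComponents(2, 0, -0.3), 1)
  expect_equal(heritabilityComponents(1, 1, 0), 1 / 2)
  expect_error(heritabilityComponents(0, 0, 0), "zero")
  expect_error(heritabilityComponents(1, 1, 2), "f must")

  # noiseless fit: regression heritability approaches 1
  G <- simulatePopulation(80, 400, nSubpops = 3, divergence = 0.3, seed = 202)
  A <- estimateKinship(G, "plain")
  tr <- simulateTrait(A, 0, seed = 2)
  fit <- fitGBLUP(phenotypes(tr), A)
  expect_equal(heritabilityRegression(fit), 1, tolerance = 1e-3)
  expect_equal(heritabilityRegression(fit), fit@h2Regression,
               tolerance = 1e-12)
})

test_that("accuracy is the Pearson correlation with its contract", {
  expect_equal(accuracy(1:5, 1:5), 1)
  expect_equal(accuracy(1:5, -(1:5)), -1)
  expect_equal(accuracy(c(1, 2, 3), c(1, 2, 4)), sqrt(27 / 28),
               tolerance = 1e-10)
  expect_error(accuracy(1:2, 1:2), "length")
  expect_error(accuracy(rep(1, 4), 1:4), "variance")
})
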