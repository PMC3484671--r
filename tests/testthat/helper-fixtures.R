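# Shared fixtures and independent oracles. Everything is generated in code;
# panels used by several test files are built once per session and memoized.

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(key, builder) {
  if (!exists(key, envir = .fixtureCache)) {
    assign(key, builder(), envir = .fixtureCache)
  }
  get(key, envir = .fixtureCache)
}

# small genotype matrix with explicit dimnames
toyGeno <- function(values, nLines = nrow(values)) {
  dimnames(values) <- list(paste0("L", seq_len(nrow(values))),
                           paste0("M", seq_len(ncol(values))))
  GenotypeMatrix(values)
}

# random complete genotype matrix (integer dosages)
randomGeno <- function(n, m, seed, inbred = FALSE) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.9)
  X <- if (inbred)
    2 * matrix(rbinom(n * m, 1, rep(p, each = n)), n, m)
  else
    matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  toyGeno(X)
}

# random genotype matrix with missing cells, imputed: exercises real dosages
randomImputedGeno <- function(n, m, seed, missFrac = 0.1) {
  G <- randomGeno(n, m, seed)
  set.seed(seed + 1)
  d <- dosages(G)
  miss <- matrix(runif(n * m) < missFrac, n, m)
  # keep at least one observed value per marker
  full <- colSums(!miss) == 0
  miss[1, full] <- FALSE
  d[miss] <- NA
  imputePopulationMean(GenotypeMatrix(d))
}

writeTempLines <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# Direct (definition-level) shrinkage-intensity numerator: loop over the
# per-column outer products instead of the squared-elements shortcut.
directIntensityNumerator <- function(Z) {
  Z <- Z - rowMeans(Z)
  m <- ncol(Z)
  S <- tcrossprod(Z) / m
  tot <- 0
  for (k in seq_len(m)) {
    D <- tcrossprod(Z[, k]) - S
    tot <- tot + sum(D * D)
  }
  tot
}

# Dense restricted log-likelihood of y ~ N(mu 1, sigma2 (K + lambda I)),
# profiled over mu and sigma2, evaluated by explicit solves -- no
# eigendecomposition, no code shared with fitGBLUP.
denseREML <- function(K, y, lambda) {
  n <- length(y)
  H <- K + diag(lambda, n)
  Hi <- solve(H)
  one <- rep(1, n)
  c11 <- drop(crossprod(one, Hi %*% one))
  mu <- drop(crossprod(one, Hi %*% y)) / c11
  r <- y - mu
  s2 <- drop(crossprod(r, Hi %*% r)) / (n - 1)
  ld <- determinant(H, logarithm = TRUE)$modulus
  -0.5 * ((n - 1) * (log(2 * pi * s2) + 1) + ld + log(c11))
}

# Grid-search REML oracle over log10(lambda) in [-6, 6]
remlOracleGrid <- function(K, y, step = 1e-3) {
  grid <- seq(-6, 6, by = step)
  ll <- vapply(grid, function(g) denseREML(K, y, 10^g), 0)
  best <- which.max(ll)
  list(log10lambda = grid[best], logREML = ll[best], grid = grid, ll = ll)
}

# Unstructured inbred benchmark panel shared by the acceptance tests
acceptancePanel <- function() {
  cachedFixture("panel3000", function() {
    G <- simulatePopulation(300, 3000, mating = "inbred", seed = 20120301)
    A <- estimateKinship(G, "plain")
    list(G = G, A = A)
  })
}
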