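# Experiment harnesses: benchmark shrinkage against marker density,
# population structure and heritability on simulated panels. All randomness
# flows from a single seed; per-replicate seeds are pre-drawn so nested calls
# (which set the RNG themselves) cannot perturb the stream.

.drawSeeds <- function(seed, k) {
  set.seed(seed)
  sample.int(.Machine$integer.max, k)
}

.se <- function(x) stats::sd(x) / sqrt(length(x))

#' Shrinkage scan: MSE and GEBV accuracy across intensities
#'
#' For each replicate, a random marker subset of size \code{mSub} is drawn
#' (uniformly, without replacement), the relationship matrix is re-estimated
#' at every intensity in \code{deltas}, and two criteria are recorded
#' against the full-marker matrix: the mean squared error
#' MSE = n^-2 ||A_sub(delta) - A_full||^2, and the GEBV accuracy from
#' training on a trait freshly simulated from A_full with noise variance
#' \code{sigmaE2} (all lines phenotyped; accuracy is the correlation of the
#' GEBVs with the true breeding values). The analytically optimal intensity
#' of each subset is recorded alongside.
#'
#' @param G complete \linkS4class{GenotypeMatrix} (the full panel).
#' @param mSub subset size (<= number of markers).
#' @param deltas intensity grid in [0, 1] (default 0 to 0.7 by 0.05).
#' @param nReps number of replicates (default 20).
#' @param sigmaE2 noise variance for the simulated training trait (default 3).
#' @param seed integer seed.
#' @return list with \code{table} (per-delta mean and SE of MSE and
#'   accuracy), \code{deltaAuto} (per-replicate optimal intensity),
#'   \code{mseArgminDelta} and \code{accArgmaxDelta} (grid argmin/argmax of
#'   the mean curves; ties broken toward the smaller delta).
#' @export
shrinkScan <- function(G, mSub, deltas = seq(0, 0.7, by = 0.05),
                       nReps = 20L, sigmaE2 = 3, seed = 1L) {
  stopifnot(is(G, "GenotypeMatrix"))
  m <- ncol(dosages(G))
  if (mSub > m) stop("mSub exceeds the number of markers")
  if (any(deltas < 0 | deltas > 1)) stop("deltas must lie in [0, 1]")
  Afull <- estimateKinship(G, "plain")
  Af <- relMatrix(Afull)
  n <- nrow(Af)
  seeds <- .drawSeeds(seed, 2L * nReps)
  mse <- acc <- matrix(NA_real_, nReps, length(deltas))
  deltaAuto <- numeric(nReps)
  for (r in seq_len(nReps)) {
    set.seed(seeds[r])
    sub <- sample.int(m, mSub)
    trait <- simulateTrait(Afull, sigmaE2, seed = seeds[nReps + r])
    Csub <- centerGenotypes(G[, sub])
    deltaAuto[r] <- shrinkDelta(shrinkageIntensity(Csub))
    for (j in seq_along(deltas)) {
      Astar <- relMatrix(kinshipShrunk(Csub, delta = deltas[j]))
      mse[r, j] <- mean((Astar - Af)^2)
      fit <- fitGBLUP(phenotypes(trait), Astar)
      acc[r, j] <- accuracy(gebv(fit), trueBV(trait))
    }
  }
  tab <- data.frame(delta = deltas,
                    mseMean = colMeans(mse), mseSE = apply(mse, 2L, .se),
                    accMean = colMeans(acc), accSE = apply(acc, 2L, .se))
  list(table = tab, deltaAuto = deltaAuto,
       mseArgminDelta = deltas[which.min(tab$mseMean)],
       accArgmaxDelta = deltas[which.max(tab$accMean)])
}

#' Optimal shrinkage intensity versus marker density
#'
#' Draws \code{nReps} random marker subsets at each size in \code{mList} and
#' reports the mean and standard error of the analytically optimal shrinkage
#' intensity. On typical panels the intensity falls toward zero as density
#' grows, and is uniformly smaller in structured populations (whose high
#' eigenvalue dispersion makes the sample covariance easier to estimate
#' relative to the target distance).
#'
#' @param G complete \linkS4class{GenotypeMatrix}.
#' @param mList marker counts, each <= the panel's marker number.
#' @param nReps replicates per count (default 20).
#' @param seed integer seed.
#' @return data.frame with columns m, deltaMean, deltaSE.
#' @export
intensityVsDensity <- function(G, mList, nReps = 20L, seed = 1L) {
  stopifnot(is(G, "GenotypeMatrix"))
  m <- ncol(dosages(G))
  if (any(mList > m)) stop("mList entries must not exceed the marker count")
  seeds <- .drawSeeds(seed, length(mList) * nReps)
  res <- matrix(NA_real_, nReps, length(mList))
  k <- 0L
  for (j in seq_along(mList)) {
    for (r in seq_len(nReps)) {
      k <- k + 1L
      set.seed(seeds[k])
      sub <- sample.int(m, mList[j])
      res[r, j] <- shrinkDelta(shrinkageIntensity(centerGenotypes(G[, sub])))
    }
  }
  data.frame(m = mList, deltaMean = colMeans(res),
             deltaSE = apply(res, 2L, .se))
}

#' GEBV accuracy versus phenotypic accuracy (heritability sweep)
#'
#' Repeatedly simulates traits with noise variance sigmaE2 = 2^u, u ~
#' uniform(-1, 7), from the full-marker relationship matrix, and compares
#' three predictors trained on all phenotypes: the full-marker matrix, a
#' random marker subset with optimal shrinkage, and the same subset without
#' shrinkage. Results are binned by realized phenotypic accuracy into
#' half-open bins [k/10 - 0.05, k/10 + 0.05) centered on multiples of 0.1.
#'
#' @param G complete \linkS4class{GenotypeMatrix}.
#' @param mSub subset size.
#' @param nSims number of simulations (>= 1).
#' @param seed integer seed.
#' @return list with \code{bins} (per-bin counts, means and SEs of the three
#'   accuracies and of the shrinkage gain, i.e. shrunk minus plain) and
#'   \code{sims} (one row per simulation). Empty bins appear with count 0 and
#'   NA values.
#' @export
accuracyVsHeritability <- function(G, mSub, nSims, seed = 1L) {
  stopifnot(is(G, "GenotypeMatrix"), nSims >= 1L)
  m <- ncol(dosages(G))
  if (mSub > m) stop("mSub exceeds the number of markers")
  Afull <- estimateKinship(G, "plain")
  seeds <- .drawSeeds(seed, 2L * nSims)
  sims <- data.frame(sigmaE2 = numeric(nSims), phenAcc = numeric(nSims),
                     accFull = numeric(nSims), accShrunk = numeric(nSims),
                     accPlain = numeric(nSims), deltaAuto = numeric(nSims))
  for (s in seq_len(nSims)) {
    set.seed(seeds[s])
    sigmaE2 <- 2^stats::runif(1, -1, 7)
    sub <- sample.int(m, mSub)
    trait <- simulateTrait(Afull, sigmaE2, seed = seeds[nSims + s])
    Csub <- centerGenotypes(G[, sub])
    Ashr <- kinshipShrunk(Csub, delta = "auto")
    Apln <- kinshipPlain(Csub)
    y <- phenotypes(trait)
    a <- trueBV(trait)
    sims$sigmaE2[s] <- sigmaE2
    sims$phenAcc[s] <- trait@phenAccuracy
    sims$accFull[s] <- accuracy(gebv(fitGBLUP(y, Afull)), a)
    sims$accShrunk[s] <- accuracy(gebv(fitGBLUP(y, Ashr)), a)
    sims$accPlain[s] <- accuracy(gebv(fitGBLUP(y, Apln)), a)
    sims$deltaAuto[s] <- shrinkDelta(Ashr)
  }
  centers <- seq(0, 1, by = 0.1)
  bin <- findInterval(sims$phenAcc, centers - 0.05)
  bins <- data.frame(binCenter = centers, count = 0L,
                     accFullMean = NA_real_, accFullSE = NA_real_,
                     accShrunkMean = NA_real_, accShrunkSE = NA_real_,
                     accPlainMean = NA_real_, accPlainSE = NA_real_,
                     gainMean = NA_real_, gainSE = NA_real_)
  for (k in seq_along(centers)) {
    idx <- which(bin == k)
    bins$count[k] <- length(idx)
    if (!length(idx)) next
    gain <- sims$accShrunk[idx] - sims$accPlain[idx]
    bins$accFullMean[k] <- mean(sims$accFull[idx])
    bins$accShrunkMean[k] <- mean(sims$accShrunk[idx])
    bins$accPlainMean[k] <- mean(sims$accPlain[idx])
    bins$gainMean[k] <- mean(gain)
    if (length(idx) > 1L) {
      bins$accFullSE[k] <- .se(sims$accFull[idx])
      bins$accShrunkSE[k] <- .se(sims$accShrunk[idx])
      bins$accPlainSE[k] <- .se(sims$accPlain[idx])
      bins$gainSE[k] <- .se(gain)
    }
  }
  list(bins = bins, sims = sims)
}

#' Holdout experiment: shrinkage for phenotyped versus unphenotyped lines
#'
#' Masks a random fraction of lines as unphenotyped, trains GBLUP on the rest
#' using a random marker subset estimated with and without shrinkage, and
#' reports GEBV accuracy against the true breeding values separately for the
#' phenotyped (training) and unphenotyped (test) lines. Shrinkage typically
#' raises training-line accuracy in unstructured populations but leaves
#' test-line accuracy essentially unchanged.
#'
#' @param G complete \linkS4class{GenotypeMatrix}.
#' @param trait a \linkS4class{TraitSim} simulated on the same lines.
#' @param testFraction fraction of lines masked per replicate, in (0, 0.5).
#' @param mSub marker subset size.
#' @param nReps number of replicates.
#' @param seed integer seed.
#' @return list with \code{reps} (one row per replicate: accuracies for
#'   train/test under shrunk/plain and the intensity used) and
#'   \code{summary} (means and SEs plus the paired mean differences).
#' @export
holdoutExperiment <- function(G, trait, testFraction, mSub, nReps = 20L,
                              seed = 1L) {
  stopifnot(is(G, "GenotypeMatrix"), is(trait, "TraitSim"))
  if (testFraction <= 0 || testFraction >= 0.5)
    stop("testFraction must lie strictly between 0 and 0.5")
  n <- nrow(dosages(G))
  m <- ncol(dosages(G))
  if (mSub > m) stop("mSub exceeds the number of markers")
  nTest <- round(testFraction * n)
  if (nTest < 3L) stop("test set must contain at least 3 lines")
  ids <- lineIds(G)
  y <- phenotypes(trait)
  a <- trueBV(trait)
  seeds <- .drawSeeds(seed, nReps)
  reps <- data.frame(accTrainShrunk = numeric(nReps),
                     accTrainPlain = numeric(nReps),
                     accTestShrunk = numeric(nReps),
                     accTestPlain = numeric(nReps),
                     deltaAuto = numeric(nReps))
  for (r in seq_len(nReps)) {
    set.seed(seeds[r])
    test <- sample(ids, nTest)
    train <- setdiff(ids, test)
    sub <- sample.int(m, mSub)
    Csub <- centerGenotypes(G[, sub])
    for (meth in c("Shrunk", "Plain")) {
      A <- if (meth == "Shrunk") kinshipShrunk(Csub, delta = "auto")
           else kinshipPlain(Csub)
      fit <- fitGBLUP(y[train], A, trainIds = train)
      reps[r, paste0("accTrain", meth)] <- accuracy(gebv(fit), a[train])
      reps[r, paste0("accTest", meth)] <-
        accuracy(predictGEBV(fit, A, test), a[test])
      if (meth == "Shrunk") reps$deltaAuto[r] <- shrinkDelta(A)
    }
  }
  summary <- data.frame(
    group = c("train", "test"),
    accShrunkMean = c(mean(reps$accTrainShrunk), mean(reps$accTestShrunk)),
    accShrunkSE = c(.se(reps$accTrainShrunk), .se(reps$accTestShrunk)),
    accPlainMean = c(mean(reps$accTrainPlain), mean(reps$accTestPlain)),
    accPlainSE = c(.se(reps$accTrainPlain), .se(reps$accTestPlain)),
    diffMean = c(mean(reps$accTrainShrunk - reps$accTrainPlain),
                 mean(reps$accTestShrunk - reps$accTestPlain)),
    diffSE = c(.se(reps$accTrainShrunk - reps$accTrainPlain),
               .se(reps$accTestShrunk - reps$accTestPlain)))
  list(reps = reps, summary = summary)
}
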