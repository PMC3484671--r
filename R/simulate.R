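#' Subset a GenotypeMatrix
#'
#' Standard two-index subsetting by line and marker (never drops dimensions).
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param i,j line and marker indices (integer, logical or character).
#' @param ... ignored.
#' @param drop ignored; dimensions are always kept.
#' @return a \linkS4class{GenotypeMatrix}.
#' @export
setMethod("[", signature(x = "GenotypeMatrix"),
          function(x, i, j, ..., drop = FALSE) {
            if (missing(i)) i <- seq_len(nrow(x@dosage))
            if (missing(j)) j <- seq_len(ncol(x@dosage))
            GenotypeMatrix(x@dosage[i, j, drop = FALSE],
                           x@missingMask[i, j, drop = FALSE])
          })

#' Subpopulation assignment used by the simulator
#'
#' Lines are assigned to subpopulations in contiguous blocks, partitioned as
#' evenly as possible.
#'
#' @param nLines number of lines.
#' @param nSubpops number of subpopulations.
#' @return integer vector of subpopulation labels, length nLines.
#' @export
subpopAssignment <- function(nLines, nSubpops) {
  sizes <- diff(round(seq(0, nLines, length.out = nSubpops + 1)))
  rep(seq_len(nSubpops), times = sizes)
}

#' Simulate a genotype panel with controllable structure and inbreeding
#'
#' Generates bi-allelic dosages for a panel of lines with two levels of
#' relatedness, both following the standard two-parameter drift model
#' (frequencies drawn from a Beta distribution with mean equal to the parent
#' frequency and variance F * p (1 - p)):
#' \itemize{
#'   \item between subpopulations, controlled by \code{divergence} -- this is
#'     what makes a panel "structured" (large first principal component,
#'     multimodal off-diagonal kinship);
#'   \item between families within each subpopulation, controlled by
#'     \code{familyDivergence} and \code{familySize} -- this reproduces the
#'     background relatedness of real breeding panels, where even
#'     populations with a first PC under 10 percent of the variance show an
#'     eigenvalue coefficient of variation well above 1. Family relatedness
#'     spreads over many principal components, so it raises the eigenvalue
#'     CV without creating "structure" in the first-PC sense.
#' }
#' Ancestral allele frequencies are drawn uniformly on [mafMin, 1 - mafMin].
#' Fully inbred lines are sampled as 2 * Bernoulli(p) (f near 1, as in
#' inbred crop panels); outbred lines as Binomial(2, p) (Hardy-Weinberg,
#' f near 0). Markers that end up with a panel-wide minor allele frequency
#' below mafMin are resampled (up to 1000 rounds). Fully deterministic under
#' \code{seed}.
#'
#' @param nLines number of lines.
#' @param nMarkers number of markers.
#' @param nSubpops number of subpopulations (>= 1, default 1).
#' @param divergence drift parameter in [0, 1) between subpopulations
#'   (default 0; ignored when nSubpops = 1).
#' @param mating \code{"inbred"} (fully homozygous lines) or
#'   \code{"outbred"} (Hardy-Weinberg sampling).
#' @param mafMin minimum panel-wide minor allele frequency (default 0.05).
#' @param familySize target number of lines per family (default 10).
#' @param familyDivergence drift parameter in [0, 1) between families within
#'   a subpopulation (0 disables the family level). For inbred panels the
#'   default 0.4 gives an eigenvalue CV near 1.3 with a first PC of a few
#'   percent, the profile of real inbred diversity panels. For outbred
#'   panels both gametes of a line are drawn from its family's frequencies,
#'   so the family divergence resurfaces as a Wahlund excess homozygosity of
#'   about the same size; the default drops to 0.03, matching the residual
#'   inbreeding seen in commercial outbred populations.
#' @param seed integer seed.
#' @return a complete \linkS4class{GenotypeMatrix}; lines of subpopulation k
#'   occupy the k-th contiguous block of rows (see [subpopAssignment()]),
#'   and families are contiguous within each block.
#' @export
simulatePopulation <- function(nLines, nMarkers, nSubpops = 1L,
                               divergence = 0, mating = c("inbred", "outbred"),
                               mafMin = 0.05, familySize = 10L,
                               familyDivergence = NULL, seed = 1L) {
  mating <- match.arg(mating)
  if (is.null(familyDivergence))
    familyDivergence <- if (mating == "inbred") 0.4 else 0.03
  if (nLines < 2L || nMarkers < 1L) stop("need at least 2 lines and 1 marker")
  if (mafMin <= 0 || mafMin > 0.5) stop("mafMin must lie in (0, 0.5]")
  if (divergence < 0 || divergence >= 1) stop("divergence must lie in [0, 1)")
  if (familyDivergence < 0 || familyDivergence >= 1)
    stop("familyDivergence must lie in [0, 1)")
  if (familySize < 1L) stop("familySize must be at least 1")
  set.seed(seed)
  sub <- subpopAssignment(nLines, nSubpops)
  # families nested within subpopulations, contiguous, as even as possible
  fam <- integer(nLines)
  nextFam <- 0L
  for (s in seq_len(nSubpops)) {
    rows <- which(sub == s)
    nFam <- max(1L, round(length(rows) / familySize))
    fam[rows] <- nextFam + subpopAssignment(length(rows), nFam)
    nextFam <- max(fam)
  }

  drawMarkers <- function(k) {
    panc <- stats::runif(k, mafMin, 1 - mafMin)
    X <- matrix(0, nLines, k)
    for (s in seq_len(nSubpops)) {
      if (nSubpops > 1L && divergence > 0) {
        ab <- (1 - divergence) / divergence
        ps <- stats::rbeta(k, panc * ab, (1 - panc) * ab)
      } else ps <- panc
      for (fm in unique(fam[sub == s])) {
        rows <- which(fam == fm)
        if (familyDivergence > 0) {
          abf <- (1 - familyDivergence) / familyDivergence
          pf <- stats::rbeta(k, ps * abf, (1 - ps) * abf)
        } else pf <- ps
        g <- if (mating == "inbred")
          2 * stats::rbinom(length(rows) * k, 1L, rep(pf, each = length(rows)))
        else
          stats::rbinom(length(rows) * k, 2L, rep(pf, each = length(rows)))
        X[rows, ] <- g
      }
    }
    X
  }

  X <- drawMarkers(nMarkers)
  for (round in seq_len(1000L)) {
    p <- colMeans(X) / 2
    bad <- which(pmin(p, 1 - p) < mafMin)
    if (!length(bad)) break
    X[, bad] <- drawMarkers(length(bad))
  }
  p <- colMeans(X) / 2
  if (any(pmin(p, 1 - p) < mafMin))
    stop("could not reach the requested minor allele frequency after 1000 ",
         "resampling rounds; relax mafMin or divergence")

  dimnames(X) <- list(sprintf("L%04d", seq_len(nLines)),
                      sprintf("M%05d", seq_len(nMarkers)))
  GenotypeMatrix(X)
}

#' True breeding values of a simulated trait
#'
#' @param x a \linkS4class{TraitSim}.
#' @return named numeric vector of true breeding values.
#' @export
setGeneric("trueBV", function(x) standardGeneric("trueBV"))

#' @describeIn trueBV for TraitSim
#' @export
setMethod("trueBV", "TraitSim", function(x) x@aTrue)

#' Phenotypes of a simulated trait
#'
#' @param x a \linkS4class{TraitSim}.
#' @return named numeric vector of phenotypes.
#' @export
phenotypes <- function(x) {
  stopifnot(is(x, "TraitSim"))
  x@y
}

setMethod("show", "TraitSim", function(object) {
  cat(sprintf("TraitSim: %d lines; sigmaE2 = %.3f; phenotypic accuracy = %.3f\n",
              length(object@y), object@sigmaE2, object@phenAccuracy))
})

#' Simulate a trait from a relationship matrix
#'
#' Draws true breeding values from the multivariate normal with covariance
#' equal to the relationship matrix (genetic variance 1). The matrix may be
#' singular (the plain estimator always is): eigenvalues are clipped below at
#' zero and the draw is made in the eigenbasis. Phenotypes are the breeding
#' values plus independent N(0, sigmaE2) noise and carry no fixed effect.
#'
#' @param A a \linkS4class{KinshipMatrix} or symmetric matrix, PSD within
#'   tolerance.
#' @param sigmaE2 residual variance (>= 0).
#' @param seed integer seed.
#' @return a \linkS4class{TraitSim} with the realized phenotypic accuracy
#'   (Pearson correlation between phenotype and true breeding value).
#' @export
simulateTrait <- function(A, sigmaE2, seed = 1L) {
  if (is(A, "KinshipMatrix")) A <- relMatrix(A)
  if (sigmaE2 < 0) stop("sigmaE2 must be non-negative")
  n <- nrow(A)
  eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  set.seed(seed)
  a <- drop(eg$vectors %*% (sqrt(lam) * stats::rnorm(n)))
  e <- if (sigmaE2 > 0) stats::rnorm(n, sd = sqrt(sigmaE2)) else numeric(n)
  y <- a + e
  names(a) <- names(y) <- rownames(A)
  acc <- if (sigmaE2 > 0) stats::cor(y, a) else 1
  new("TraitSim", aTrue = a, y = y, sigmaE2 = sigmaE2,
      phenAccuracy = acc, seed = as.integer(seed))
}
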