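#' @describeIn lineIds line IDs of a CenteredGenotypes
#' @export
setMethod("lineIds", "CenteredGenotypes", function(x) rownames(x@W))

#' @describeIn markerIds marker IDs of a CenteredGenotypes
#' @export
setMethod("markerIds", "CenteredGenotypes", function(x) colnames(x@W))

#' Allele frequencies of centered genotypes
#'
#' @param x a \linkS4class{CenteredGenotypes}.
#' @return numeric vector of per-marker allele frequencies.
#' @export
alleleFreq <- function(x) {
  stopifnot(is(x, "CenteredGenotypes"))
  x@p
}

setMethod("show", "CenteredGenotypes", function(object) {
  cat("CenteredGenotypes:", nrow(object@W), "lines x", ncol(object@W),
      "markers\n")
  cat(sprintf("  2*sum(p*q) = %.4f; polymorphic markers: %d\n",
              object@denom, sum(object@p > 0 & object@p < 1)))
})

#' @describeIn lineIds line IDs of a KinshipMatrix
#' @export
setMethod("lineIds", "KinshipMatrix", function(x) rownames(x@A))

#' @describeIn relMatrix relationship matrix slot
#' @export
setMethod("relMatrix", "KinshipMatrix", function(x) x@A)

#' @describeIn inbreedingF from the mean diagonal of A
#' @export
setMethod("inbreedingF", "KinshipMatrix", function(x) x@f)

#' @describeIn shrinkDelta intensity recorded on a KinshipMatrix
#' @export
setMethod("shrinkDelta", "KinshipMatrix", function(x) x@delta)

#' @export
setMethod("dim", "KinshipMatrix", function(x) dim(x@A))

setMethod("show", "KinshipMatrix", function(object) {
  cat(sprintf("KinshipMatrix (%s): %d lines\n", object@method, nrow(object@A)))
  cat(sprintf("  f = %.4f; mean diagonal = %.4f; delta = %.4f\n",
              object@f, 1 + object@f, object@delta))
})

#' Center a genotype matrix by allele frequency
#'
#' Computes W = X - 2p per marker column, where p_k is the allele frequency
#' estimated from the observed dosages (mean dosage / 2), plus the per-line
#' means of W and the denominator 2 * sum(p_k q_k) used to scale the
#' relationship matrix. Requires a complete matrix (impute first).
#'
#' @param G a complete \linkS4class{GenotypeMatrix}.
#' @return a \linkS4class{CenteredGenotypes}.
#' @export
centerGenotypes <- function(G) {
  stopifnot(is(G, "GenotypeMatrix"))
  X <- G@dosage
  if (anyNA(X))
    stop("genotypes contain missing values; run imputePopulationMean() first")
  p <- colMeans(X) / 2
  W <- sweep(X, 2L, 2 * p, "-")
  new("CenteredGenotypes", W = W, p = as.numeric(p),
      rowMeansW = rowMeans(W), denom = 2 * sum(p * (1 - p)))
}

#' @describeIn sampleCovariance for centered genotypes, using the stored row
#'   means
#' @export
setMethod("sampleCovariance", "CenteredGenotypes", function(x) {
  m <- ncol(x@W)
  S <- tcrossprod(x@W) / m - tcrossprod(x@rowMeansW)
  (S + t(S)) / 2
})

#' @describeIn sampleCovariance for a plain matrix of column observations
#' @export
setMethod("sampleCovariance", "matrix", function(x) {
  rm <- rowMeans(x)
  S <- tcrossprod(x) / ncol(x) - tcrossprod(rm)
  (S + t(S)) / 2
})

#' Plain realized relationship matrix
#'
#' The high-marker-density estimator A = W W' / (2 sum(p_k q_k)). Its mean
#' diagonal equals 1 + f, where f is the population inbreeding coefficient,
#' and all row sums are exactly zero because each column of W is centered, so
#' A is positive semidefinite with at least one zero eigenvalue.
#'
#' @param C a \linkS4class{CenteredGenotypes} with at least one polymorphic
#'   marker.
#' @param ids optional line IDs (defaults to those carried by C).
#' @return a \linkS4class{KinshipMatrix} with method "plain".
#' @export
kinshipPlain <- function(C, ids = lineIds(C)) {
  stopifnot(is(C, "CenteredGenotypes"))
  if (C@denom <= 0)
    stop("all markers are monomorphic: relationship matrix undefined")
  A <- tcrossprod(C@W) / C@denom
  A <- (A + t(A)) / 2
  dimnames(A) <- list(ids, ids)
  new("KinshipMatrix", A = A, method = "plain", delta = 0,
      f = mean(diag(A)) - 1)
}

#' Shrinkage estimator of the realized relationship matrix
#'
#' Shrinks the sample covariance of lines across loci toward the diagonal
#' target mean(diag(S)) I before rescaling into a relationship matrix:
#' A* = (delta mean(diag(S)) I + (1 - delta) S + rowMeans(W) rowMeans(W)') /
#' (2 mean(p_k q_k)). At delta = 0 this reproduces [kinshipPlain()] exactly;
#' the trace (hence the inbreeding coefficient) is identical for every delta
#' because the target preserves the total variance.
#'
#' @param C a \linkS4class{CenteredGenotypes}.
#' @param ids optional line IDs (defaults to those carried by C).
#' @param delta shrinkage intensity in [0, 1], or \code{"auto"} to use the
#'   analytically MSE-optimal intensity from [shrinkageIntensity()].
#' @return a \linkS4class{KinshipMatrix} with method "shrunk" and the
#'   intensity used recorded in its \code{delta} slot.
#' @export
kinshipShrunk <- function(C, ids = lineIds(C), delta = "auto") {
  stopifnot(is(C, "CenteredGenotypes"))
  if (C@denom <= 0)
    stop("all markers are monomorphic: relationship matrix undefined")
  if (identical(delta, "auto")) {
    delta <- shrinkDelta(shrinkageIntensity(C))
  } else {
    if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) ||
        delta < 0 || delta > 1)
      stop("delta must be a single value in [0, 1] or \"auto\"")
  }
  m <- ncol(C@W)
  S <- sampleCovariance(C)
  num <- (1 - delta) * S + tcrossprod(C@rowMeansW)
  diag(num) <- diag(num) + delta * mean(diag(S))
  A <- num / (C@denom / m)  # 2 * mean(p q) = denom / m
  A <- (A + t(A)) / 2
  dimnames(A) <- list(ids, ids)
  new("KinshipMatrix", A = A, method = "shrunk", delta = delta,
      f = mean(diag(A)) - 1)
}

#' Estimate a relationship matrix straight from genotypes
#'
#' Convenience wrapper: center a complete \linkS4class{GenotypeMatrix} and
#' apply the plain or shrinkage estimator.
#'
#' @param G a complete \linkS4class{GenotypeMatrix}.
#' @param method "plain" or "shrunk".
#' @param delta intensity in [0, 1] or "auto" (shrunk method only).
#' @return a \linkS4class{KinshipMatrix}.
#' @export
estimateKinship <- function(G, method = c("plain", "shrunk"), delta = "auto") {
  method <- match.arg(method)
  C <- centerGenotypes(G)
  if (method == "plain") kinshipPlain(C) else kinshipShrunk(C, delta = delta)
}

#' Heuristic shrinkage magnitude
#'
#' Order-of-magnitude heuristic delta ~ n / (m CV^2) for judging whether
#' shrinkage matters at a given panel size: when the line-to-marker ratio is
#' small compared with the squared coefficient of variation of the covariance
#' eigenvalues, shrinkage is negligible. Not clamped to [0, 1].
#'
#' @param n number of lines.
#' @param m number of markers.
#' @param cv coefficient of variation of the covariance eigenvalues (> 0).
#' @return scalar heuristic magnitude.
#' @export
heuristicIntensity <- function(n, m, cv) {
  if (n <= 0 || m <= 0) stop("n and m must be positive")
  if (cv <= 0) stop("cv must be positive")
  n / (m * cv^2)
}

#' Coefficient of variation of covariance eigenvalues
#'
#' CV = sd(lambda) / mean(lambda) over all eigenvalues of a symmetric
#' covariance matrix, with the population (n divisor) standard deviation.
#' High values indicate strong structure (a few dominant principal
#' components) and hence little need for shrinkage.
#'
#' @param S symmetric covariance matrix.
#' @return scalar CV.
#' @export
eigenvalueCV <- function(S) {
  if (is(S, "KinshipMatrix")) S <- relMatrix(S)
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
    stop("S must be symmetric")
  lam <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  mu <- mean(lam)
  if (mu <= 0) stop("mean eigenvalue must be positive")
  sqrt(mean((lam - mu)^2)) / mu
}

#' Identity-by-state matrix
#'
#' Mean probability that alleles drawn from two lines are identical in state,
#' computed from the symmetric {-1, 0, 1} coding as
#' (m^-1 X_sym X_sym' + J) / 2 with J the all-ones matrix. For fully
#' homozygous lines, entry (i, j) is the fraction of loci at which the two
#' lines carry the same genotype.
#'
#' @param G a complete \linkS4class{GenotypeMatrix}.
#' @return symmetric n x n matrix of IBS coefficients.
#' @export
ibsMatrix <- function(G) {
  stopifnot(is(G, "GenotypeMatrix"))
  X <- G@dosage
  if (anyNA(X)) stop("genotypes contain missing values; impute first")
  Xs <- X - 1
  M <- (tcrossprod(Xs) / ncol(Xs) + 1) / 2
  (M + t(M)) / 2
}
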