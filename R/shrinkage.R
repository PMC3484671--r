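#' @describeIn shrinkDelta clamped intensity of a diagnostics object
#' @export
setMethod("shrinkDelta", "ShrinkageDiagnostics", function(x) x@delta)

setMethod("show", "ShrinkageDiagnostics", function(object) {
  cat(sprintf("ShrinkageDiagnostics: n = %d\n", nrow(object@S)))
  cat(sprintf("  delta = %.4f (raw %.4f); target scale = %.4f\n",
              object@delta, object@deltaRaw, object@targetScale))
})

# Core computation on a plain matrix whose columns are the m replicate
# observations. Rows are adjusted to zero mean across columns first, per the
# estimator's zero-mean assumption.
.shrinkageIntensity <- function(Z) {
  if (!all(is.finite(Z))) stop("non-finite values in input")
  n <- nrow(Z)
  m <- ncol(Z)
  if (m < 2L)
    stop("at least 2 columns are required to estimate sampling variance")
  Z <- Z - rowMeans(Z)
  S <- tcrossprod(Z) / m
  S <- (S + t(S)) / 2
  Z2 <- Z * Z
  Gam <- tcrossprod(Z2) / m
  target <- mean(diag(S))
  # numerator of the intensity: m^-2 sum_k ||Z_k Z_k' - S||^2
  #                           = m^-1 sum_ij (Gamma_ij - S_ij^2)
  num <- sum(Gam - S * S) / m
  R <- S
  diag(R) <- diag(R) - target
  den <- sum(R * R)
  deltaRaw <- if (den > 0) num / den else 0
  new("ShrinkageDiagnostics", S = S, deltaRaw = deltaRaw,
      delta = min(1, max(0, deltaRaw)), targetScale = target,
      numerator = num, denominator = den)
}

#' @describeIn shrinkageIntensity for centered genotypes (rows additionally
#'   adjusted to zero mean across markers)
#' @export
setMethod("shrinkageIntensity", "CenteredGenotypes",
          function(x) .shrinkageIntensity(x@W))

#' @describeIn shrinkageIntensity for a plain matrix of column observations
#' @export
setMethod("shrinkageIntensity", "matrix",
          function(x) .shrinkageIntensity(x))

#' Shrunk covariance estimate from diagnostics
#'
#' Assembles delta * mean(diag(S)) I + (1 - delta) * S from a
#' \linkS4class{ShrinkageDiagnostics} object, at the recorded intensity or an
#' override. The diagonal target preserves the estimated total variance, so
#' the trace is identical at every delta.
#'
#' @param diag_ a \linkS4class{ShrinkageDiagnostics}.
#' @param delta optional intensity override in [0, 1].
#' @return symmetric covariance matrix estimate.
#' @export
shrunkCovariance <- function(diag_, delta = shrinkDelta(diag_)) {
  stopifnot(is(diag_, "ShrinkageDiagnostics"))
  if (delta < 0 || delta > 1) stop("delta must lie in [0, 1]")
  out <- (1 - delta) * diag_@S
  diag(out) <- diag(out) + delta * diag_@targetScale
  out
}
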