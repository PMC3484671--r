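#' @describeIn gebv GEBVs of the training lines
#' @export
setMethod("gebv", "GBLUPFit", function(x) x@gebv)

#' @describeIn varComponents genetic and residual variance estimates
#' @export
setMethod("varComponents", "GBLUPFit",
          function(x) c(sigma2 = x@sigma2, sigmaE2 = x@sigmaE2))

setMethod("show", "GBLUPFit", function(object) {
  cat(sprintf("GBLUPFit: %d training lines%s\n", length(object@trainIds),
              if (object@boundary) " [boundary/ridge]" else ""))
  cat(sprintf("  mu = %.4f; sigma2 = %.4f; sigmaE2 = %.4f (lambda = %.4g)\n",
              object@muHat, object@sigma2, object@sigmaE2, object@lambda))
  cat(sprintf("  logREML = %.4f; h2 (regression) = %.4f; h2 (components) = %.4f\n",
              object@logREML, object@h2Regression, object@h2Components))
})

# bounds of the profiled log variance ratio: lambda in [1e-8, 1e8]
.LOGLAM_LO <- -18.4
.LOGLAM_HI <- 18.4

# Restricted log-likelihood of y ~ N(mu 1, sigma2 (K + lambda I)) profiled
# over mu and sigma2, expressed in the eigenbasis of the training kinship.
# d: eigenvalues, yt/u1: rotated phenotypes and intercept column.
.remlProfile <- function(loglam, d, yt, u1, n) {
  lam <- exp(loglam)
  w <- 1 / (d + lam)
  c11 <- sum(w * u1 * u1)
  mu <- sum(w * u1 * yt) / c11
  rt <- yt - mu * u1
  q <- sum(w * rt * rt)
  s2 <- q / (n - 1)
  ll <- -0.5 * ((n - 1) * (log(2 * pi * s2) + 1) +
                  sum(log(d + lam)) + log(c11))
  list(ll = ll, mu = mu, s2 = s2, rt = rt, w = w)
}

# Analytic derivative of the profiled restricted log-likelihood with respect
# to lambda (envelope theorem over the profiled mu and sigma2), used to pin
# the optimum to machine precision after the grid stage.
.remlScore <- function(loglam, d, yt, u1, n) {
  lam <- exp(loglam)
  w <- 1 / (d + lam)
  c11 <- sum(w * u1 * u1)
  mu <- sum(w * u1 * yt) / c11
  rt <- yt - mu * u1
  q <- sum(w * rt * rt)
  -0.5 * (-(n - 1) * sum(w * w * rt * rt) / q + sum(w) -
            sum(w * w * u1 * u1) / c11)
}

#' Fit GBLUP by REML with a profiled variance ratio
#'
#' Fits the mixed model y = mu 1 + a + e, a ~ N(0, sigma2 A), e ~ N(0,
#' sigmaE2 I), on the training lines by restricted maximum likelihood. After
#' one eigendecomposition of the training block of A, the restricted
#' likelihood is profiled over the ratio lambda = sigmaE2 / sigma2: a coarse
#' 64-point grid on log lambda in [-18.4, 18.4] brackets the maximum, which
#' is then pinned by root-finding on the analytic score (falling back to
#' golden-section when the score is numerically flat), so the phenotypic
#' covariance inverse is never formed explicitly. A singular A (the plain estimator always has a zero
#' eigenvalue) poses no problem: eigenvalues below 1e-10 of the largest are
#' treated as exactly zero, i.e. directions with no genetic variance.
#'
#' When the optimum sits at a search boundary or the profiled likelihood is
#' flat (e.g. A proportional to I, where only sigma2 + sigmaE2 is
#' identified), the fit is returned with its \code{boundary} flag set rather
#' than erroring.
#'
#' @param y named numeric vector of phenotypes for the training lines.
#' @param A a \linkS4class{KinshipMatrix} (or bare symmetric matrix with line
#'   IDs) covering at least the training lines.
#' @param trainIds lines to train on; defaults to \code{names(y)}. \code{y}
#'   must be in this order or named so it can be aligned.
#' @return a \linkS4class{GBLUPFit}.
#' @seealso [predictGEBV()], [heritabilityRegression()],
#'   [heritabilityComponents()]
#' @export
fitGBLUP <- function(y, A, trainIds = names(y)) {
  f <- NA_real_
  if (is(A, "KinshipMatrix")) {
    f <- A@f
    A <- relMatrix(A)
  } else {
    f <- mean(diag(A)) - 1
  }
  if (is.null(trainIds)) stop("y must be named or trainIds supplied")
  if (!all(trainIds %in% rownames(A)))
    stop("training IDs absent from the relationship matrix: ",
         paste(setdiff(trainIds, rownames(A)), collapse = ", "))
  if (!is.null(names(y))) y <- y[trainIds]
  n <- length(trainIds)
  if (n < 3L) stop("at least 3 training lines are required")
  if (length(y) != n || !all(is.finite(y))) stop("y must be finite, one value per training line")
  if (stats::var(y) <= 0) stop("phenotypes have zero variance")

  K <- A[trainIds, trainIds, drop = FALSE]
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  d <- eg$values
  dmax <- max(d, 0)
  d[d < 1e-10 * dmax] <- 0
  U <- eg$vectors
  yt <- drop(crossprod(U, y))
  u1 <- drop(crossprod(U, rep(1, n)))

  grid <- seq(.LOGLAM_LO, .LOGLAM_HI, length.out = 64L)
  llg <- vapply(grid, function(g) .remlProfile(g, d, yt, u1, n)$ll, 0)
  best <- which.max(llg)
  flat <- (max(llg) - min(llg)) < 1e-6
  boundary <- flat
  if (best == 1L || best == length(grid) || flat) {
    loglam <- grid[best]
    boundary <- TRUE
  } else {
    # the maximum is bracketed by the neighbouring grid points; locate the
    # zero of the score there to machine precision
    lo <- grid[best - 1L]
    hi <- grid[best + 1L]
    slo <- .remlScore(lo, d, yt, u1, n)
    shi <- .remlScore(hi, d, yt, u1, n)
    if (is.finite(slo) && is.finite(shi) && slo > 0 && shi < 0) {
      loglam <- stats::uniroot(.remlScore, c(lo, hi), d = d, yt = yt,
                               u1 = u1, n = n, tol = 1e-12)$root
    } else {
      # score does not change sign (numerically flat optimum): fall back to
      # golden-section on the likelihood itself
      opt <- stats::optimize(function(g) .remlProfile(g, d, yt, u1, n)$ll,
                             interval = c(lo, hi), maximum = TRUE,
                             tol = 1e-10)
      loglam <- opt$maximum
    }
  }
  sol <- .remlProfile(loglam, d, yt, u1, n)

  lam <- exp(loglam)
  sigma2 <- sol$s2
  sigmaE2 <- lam * sigma2
  a <- drop(U %*% (d * sol$w * sol$rt))
  names(a) <- trainIds
  vres <- drop(U %*% (sol$w * sol$rt))
  names(vres) <- trainIds
  r <- y - sol$mu
  h2reg <- sum(a * r) / sum(r * r)
  # marker-subset estimates of f can overshoot 1 slightly; clamp for the
  # closed-form heritability
  h2comp <- heritabilityComponents(sigma2, sigmaE2, min(1, max(-1, f)))
  yy <- as.numeric(y)
  names(yy) <- trainIds
  new("GBLUPFit", muHat = sol$mu, sigma2 = sigma2, sigmaE2 = sigmaE2,
      lambda = lam, gebv = a, logREML = sol$ll, h2Regression = h2reg,
      h2Components = h2comp, trainIds = as.character(trainIds),
      boundary = boundary, y = yy, vres = vres)
}

#' Predict breeding values for arbitrary lines
#'
#' GEBVs for any lines in the relationship matrix, phenotyped or not, via the
#' cross-covariance rows: a_target = sigma2 A[target, train] V^-1 (y - mu 1).
#' For the training lines this reproduces the fit's stored GEBVs exactly; a
#' line with an all-zero relationship row to the training set gets GEBV 0.
#'
#' @param fit a \linkS4class{GBLUPFit} from [fitGBLUP()] on the same A.
#' @param A the \linkS4class{KinshipMatrix} (or bare matrix) used for the fit.
#' @param targetIds lines to predict; defaults to all lines in A.
#' @return named numeric vector of GEBVs for the target lines.
#' @export
predictGEBV <- function(fit, A, targetIds = NULL) {
  stopifnot(is(fit, "GBLUPFit"))
  if (is(A, "KinshipMatrix")) A <- relMatrix(A)
  if (is.null(targetIds)) targetIds <- rownames(A)
  unknown <- setdiff(targetIds, rownames(A))
  if (length(unknown))
    stop("unknown target IDs: ", paste(unknown, collapse = ", "))
  a <- drop(A[targetIds, fit@trainIds, drop = FALSE] %*% fit@vres)
  names(a) <- targetIds
  a
}

#' Heritability from the breeding-value regression
#'
#' Plug-in estimator h2 = a' (y - mu 1) / ||y - mu 1||^2 using the fitted
#' GEBVs and intercept: the slope of the regression of predicted breeding
#' value on phenotype, matching the parent-offspring definition of
#' narrow-sense heritability.
#'
#' @param fit a \linkS4class{GBLUPFit}.
#' @param y phenotypes aligned with the fit's training lines; defaults to the
#'   phenotypes stored on the fit.
#' @return scalar heritability estimate.
#' @export
heritabilityRegression <- function(fit, y = fit@y) {
  stopifnot(is(fit, "GBLUPFit"))
  if (!is.null(names(y))) y <- y[fit@trainIds]
  r <- y - fit@muHat
  ss <- sum(r * r)
  if (ss <= 0) stop("phenotypes have zero variance")
  sum(fit@gebv * r) / ss
}

#' Heritability from variance components
#'
#' Large-population closed form E[h2] = sigma2 (1 + f) / (sigma2 (1 + f) +
#' sigmaE2). The (1 + f) factor arises because the additive genetic variance
#' of the current population exceeds the relationship-matrix scale parameter
#' sigma2 by that factor in (partially) inbred populations.
#'
#' @param sigma2 genetic variance component (>= 0).
#' @param sigmaE2 residual variance component (>= 0).
#' @param f population inbreeding coefficient in [-1, 1].
#' @return scalar heritability.
#' @export
heritabilityComponents <- function(sigma2, sigmaE2, f) {
  if (sigma2 < 0 || sigmaE2 < 0) stop("variance components must be >= 0")
  if (sigma2 == 0 && sigmaE2 == 0) stop("both variance components are zero")
  if (is.na(f) || f < -1 - 1e-8 || f > 1 + 1e-8) stop("f must lie in [-1, 1]")
  f <- min(1, max(-1, f))  # absorb floating-point overshoot at the ends
  sigma2 * (1 + f) / (sigma2 * (1 + f) + sigmaE2)
}

#' Prediction accuracy
#'
#' Pearson correlation between two vectors, e.g. GEBVs and true (or
#' progeny-test-estimated) breeding values.
#'
#' @param x,y numeric vectors of equal length >= 3 with positive variance.
#' @return scalar correlation in [-1, 1].
#' @export
accuracy <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3")
  if (stats::var(x) <= 0 || stats::var(y) <= 0)
    stop("zero variance input")
  stats::cor(x, y)
}
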