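#' @import methods
NULL

#' GenotypeMatrix: bi-allelic dosage matrix with missing-data provenance
#'
#' Container for an n x m matrix of allele dosages (lines in rows, markers in
#' columns), coded as the count of the counted allele: 0/1/2 for observed
#' genotypes, real values in [0, 2] after population-mean imputation. Cells
#' that were missing in the source data are NA in \code{dosage} until
#' imputation; \code{missingMask} records which cells were originally missing
#' regardless of imputation, so downstream summaries can report how much of
#' the matrix is inferred.
#'
#' @slot dosage numeric matrix with unique rownames (line IDs) and colnames
#'   (marker IDs); non-missing entries lie in [0, 2].
#' @slot missingMask logical matrix of the same dimension; TRUE marks cells
#'   that were missing in the input.
#'
#' @seealso [readGenotypeTable()], [curateGenotypes()],
#'   [imputePopulationMean()], [centerGenotypes()]
#' @export
setClass("GenotypeMatrix",
         representation(dosage = "matrix", missingMask = "matrix"))

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosage
  mk <- object@missingMask
  msg <- character()
  if (!is.numeric(d)) msg <- c(msg, "dosage must be a numeric matrix")
  if (!is.logical(mk)) msg <- c(msg, "missingMask must be a logical matrix")
  if (!identical(dim(d), dim(mk)))
    msg <- c(msg, "dosage and missingMask dimensions differ")
  if (is.null(rownames(d)) || is.null(colnames(d)))
    msg <- c(msg, "dosage must carry line IDs (rownames) and marker IDs (colnames)")
  else {
    if (anyDuplicated(rownames(d))) msg <- c(msg, "duplicate line IDs")
    if (anyDuplicated(colnames(d))) msg <- c(msg, "duplicate marker IDs")
  }
  obs <- d[!is.na(d)]
  if (length(obs) && (min(obs) < 0 || max(obs) > 2))
    msg <- c(msg, "observed dosages must lie in [0, 2]")
  if (length(msg)) msg else TRUE
})

#' CenteredGenotypes: column-centered dosages and allele frequencies
#'
#' The centered genotype matrix W = X - 2p (each marker column centered by
#' twice its allele frequency), together with the allele frequencies p, the
#' per-line means of W across markers, and the scaling denominator
#' 2 * sum(p * q) used by the relationship-matrix estimators. Every column of
#' W sums to zero by construction, which is what makes the plain relationship
#' matrix row-sum-zero and positive semidefinite with a zero eigenvalue.
#'
#' @slot W numeric matrix (lines x markers) with dimnames.
#' @slot p numeric vector of allele frequencies in [0, 1], one per marker.
#' @slot rowMeansW numeric vector, mean of W across markers for each line.
#' @slot denom scalar, 2 * sum(p_k * (1 - p_k)).
#'
#' @seealso [centerGenotypes()], [kinshipPlain()], [kinshipShrunk()]
#' @export
setClass("CenteredGenotypes",
         representation(W = "matrix", p = "numeric",
                        rowMeansW = "numeric", denom = "numeric"))

setValidity("CenteredGenotypes", function(object) {
  msg <- character()
  if (length(object@p) != ncol(object@W))
    msg <- c(msg, "length(p) must equal ncol(W)")
  if (length(object@rowMeansW) != nrow(object@W))
    msg <- c(msg, "length(rowMeansW) must equal nrow(W)")
  if (length(object@denom) != 1 || object@denom < 0)
    msg <- c(msg, "denom must be a non-negative scalar")
  if (length(object@p) && (min(object@p) < 0 || max(object@p) > 1))
    msg <- c(msg, "allele frequencies must lie in [0, 1]")
  cs <- colSums(object@W)
  if (length(cs) && max(abs(cs)) > 1e-9 * max(1, nrow(object@W)))
    msg <- c(msg, "columns of W must sum to zero")
  if (length(msg)) msg else TRUE
})

#' ShrinkageDiagnostics: optimal-intensity computation trace
#'
#' Intermediate quantities behind the analytically MSE-optimal shrinkage
#' intensity for the covariance of lines across loci: the sample covariance S
#' of the row-centered data, the unclamped and clamped intensity, the scale
#' of the diagonal target, and the numerator / denominator of the intensity
#' ratio. Kept so that diagnostic output can show how close a panel is to the
#' no-shrinkage regime.
#'
#' @slot S numeric n x n sample covariance matrix.
#' @slot deltaRaw unclamped intensity (can exceed [0, 1]).
#' @slot delta intensity clamped to [0, 1].
#' @slot targetScale mean diagonal of S (the scale of the target).
#' @slot numerator estimation-variance term (numerator of the intensity).
#' @slot denominator squared distance from S to the target.
#' @export
setClass("ShrinkageDiagnostics",
         representation(S = "matrix", deltaRaw = "numeric", delta = "numeric",
                        targetScale = "numeric", numerator = "numeric",
                        denominator = "numeric"))

setValidity("ShrinkageDiagnostics", function(object) {
  msg <- character()
  if (object@delta < 0 || object@delta > 1)
    msg <- c(msg, "delta must lie in [0, 1]")
  if (nrow(object@S) != ncol(object@S)) msg <- c(msg, "S must be square")
  if (max(abs(object@S - t(object@S))) > 1e-9)
    msg <- c(msg, "S must be symmetric")
  if (length(msg)) msg else TRUE
})

#' KinshipMatrix: realized (IBS) relationship matrix with provenance
#'
#' The marker-estimated additive relationship matrix A, scaled so that the
#' mean diagonal element equals 1 + f, where f is the inbreeding coefficient
#' of the current population. Records whether the plain or the shrinkage
#' estimator produced it, and at which intensity.
#'
#' @slot A symmetric numeric matrix with line IDs as dimnames.
#' @slot method "plain" or "shrunk".
#' @slot delta shrinkage intensity used (0 for plain).
#' @slot f population inbreeding coefficient, mean(diag(A)) - 1.
#'
#' @seealso [kinshipPlain()], [kinshipShrunk()], [fitGBLUP()]
#' @export
setClass("KinshipMatrix",
         representation(A = "matrix", method = "character",
                        delta = "numeric", f = "numeric"))

setValidity("KinshipMatrix", function(object) {
  msg <- character()
  A <- object@A
  if (nrow(A) != ncol(A)) msg <- c(msg, "A must be square")
  if (is.null(rownames(A)) || anyDuplicated(rownames(A)))
    msg <- c(msg, "A must carry unique line IDs")
  if (nrow(A) && max(abs(A - t(A))) > 1e-9)
    msg <- c(msg, "A must be symmetric (max asymmetry < 1e-9)")
  if (!object@method %in% c("plain", "shrunk"))
    msg <- c(msg, "method must be 'plain' or 'shrunk'")
  if (object@delta < 0 || object@delta > 1)
    msg <- c(msg, "delta must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' InbreedingSummary: marker-based inbreeding at locus, line and population level
#'
#' Per-locus inbreeding coefficients f_k (the intra-individual gametic
#' correlation), their weights beta_k proportional to p_k q_k, per-individual
#' coefficients phi_i (excess homozygosity relative to the current
#' population), and the population coefficient f. The three levels are tied
#' by an exact identity: f = sum(beta_k f_k) = mean(phi_i) = mean(diag(A)) - 1.
#'
#' @slot fk per-locus coefficients (0 at monomorphic loci).
#' @slot betak locus weights, proportional to p_k q_k, summing to 1 over
#'   polymorphic loci (0 at monomorphic loci).
#' @slot phi per-individual coefficients.
#' @slot f population inbreeding coefficient.
#' @export
setClass("InbreedingSummary",
         representation(fk = "numeric", betak = "numeric",
                        phi = "numeric", f = "numeric"))

setValidity("InbreedingSummary", function(object) {
  msg <- character()
  if (length(object@fk) != length(object@betak))
    msg <- c(msg, "fk and betak lengths differ")
  bs <- sum(object@betak)
  if (length(object@betak) && bs > 0 && abs(bs - 1) > 1e-8)
    msg <- c(msg, "betak must sum to 1 over polymorphic loci")
  if (length(msg)) msg else TRUE
})

#' GBLUPFit: REML variance components and breeding-value predictions
#'
#' Result of fitting y = mu * 1 + a + e with a ~ N(0, sigma2 * A) and
#' e ~ N(0, sigmaE2 * I) by restricted maximum likelihood, profiling the
#' variance ratio lambda = sigmaE2 / sigma2 on the spectrum of the training
#' block of A. Carries the BLUE of the intercept, both variance components,
#' the GEBVs of the training lines, the restricted log-likelihood at the
#' optimum, and two heritability estimators (regression-based and
#' components-based).
#'
#' @slot muHat BLUE of the fixed intercept.
#' @slot sigma2 genetic variance component (>= 0).
#' @slot sigmaE2 residual variance component (>= 0).
#' @slot lambda ratio sigmaE2 / sigma2 at the REML optimum.
#' @slot gebv named vector of predicted breeding values for training lines.
#' @slot logREML restricted log-likelihood at the optimum.
#' @slot h2Regression heritability from the breeding-value-on-phenotype
#'   regression plug-in.
#' @slot h2Components heritability from variance components and f,
#'   sigma2 (1 + f) / (sigma2 (1 + f) + sigmaE2).
#' @slot trainIds line IDs with phenotypes.
#' @slot boundary TRUE when the REML optimum sat on the search boundary or
#'   the profiled likelihood was flat (e.g. A close to I, where only the sum
#'   of the two components is identified).
#' @slot y training phenotypes (named, in trainIds order).
#' @slot vres solve(V, y - mu 1) up to the sigma2 scale; used for prediction
#'   of unphenotyped lines.
#' @export
setClass("GBLUPFit",
         representation(muHat = "numeric", sigma2 = "numeric",
                        sigmaE2 = "numeric", lambda = "numeric",
                        gebv = "numeric", logREML = "numeric",
                        h2Regression = "numeric", h2Components = "numeric",
                        trainIds = "character", boundary = "logical",
                        y = "numeric", vres = "numeric"))

setValidity("GBLUPFit", function(object) {
  msg <- character()
  if (object@sigma2 < 0 || object@sigmaE2 < 0)
    msg <- c(msg, "variance components must be non-negative")
  n <- length(object@trainIds)
  if (length(object@gebv) != n || length(object@y) != n ||
      length(object@vres) != n)
    msg <- c(msg, "gebv, y and vres must align with trainIds")
  if (length(msg)) msg else TRUE
})

#' TraitSim: simulated breeding values and phenotypes
#'
#' A single simulated trait: true breeding values drawn from the (possibly
#' singular) multivariate normal with covariance equal to a relationship
#' matrix (genetic variance 1), phenotypes formed by adding independent
#' Gaussian noise, and the realized phenotypic accuracy, i.e. the Pearson
#' correlation between phenotype and true breeding value.
#'
#' @slot aTrue named vector of true breeding values.
#' @slot y named vector of phenotypes (y = aTrue + e; no fixed effect).
#' @slot sigmaE2 residual variance used.
#' @slot phenAccuracy realized cor(y, aTrue).
#' @slot seed integer seed the draw was made under.
#' @export
setClass("TraitSim",
         representation(aTrue = "numeric", y = "numeric",
                        sigmaE2 = "numeric", phenAccuracy = "numeric",
                        seed = "integer"))

setValidity("TraitSim", function(object) {
  msg <- character()
  if (length(object@aTrue) != length(object@y))
    msg <- c(msg, "aTrue and y lengths differ")
  if (object@sigmaE2 < 0) msg <- c(msg, "sigmaE2 must be non-negative")
  if (length(msg)) msg else TRUE
})
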