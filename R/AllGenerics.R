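#' Dosage matrix of a GenotypeMatrix
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @return numeric matrix of allele dosages (lines x markers); NA where
#'   missing and not yet imputed.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' Missing-data mask
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @return logical matrix; TRUE where the input cell was missing.
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' Line identifiers
#'
#' @param x a \linkS4class{GenotypeMatrix}, \linkS4class{CenteredGenotypes}
#'   or \linkS4class{KinshipMatrix}.
#' @return character vector of line IDs.
#' @export
setGeneric("lineIds", function(x) standardGeneric("lineIds"))

#' Marker identifiers
#'
#' @param x a \linkS4class{GenotypeMatrix} or \linkS4class{CenteredGenotypes}.
#' @return character vector of marker IDs.
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))

#' Relationship matrix of a KinshipMatrix object
#'
#' @param x a \linkS4class{KinshipMatrix}.
#' @return the symmetric numeric matrix A with line IDs as dimnames.
#' @export
setGeneric("relMatrix", function(x) standardGeneric("relMatrix"))

#' Population inbreeding coefficient
#'
#' For a \linkS4class{KinshipMatrix} this is mean(diag(A)) - 1; for an
#' \linkS4class{InbreedingSummary} it is the weighted locus average, which is
#' identical by construction.
#'
#' @param x a \linkS4class{KinshipMatrix} or \linkS4class{InbreedingSummary}.
#' @return scalar inbreeding coefficient f.
#' @export
setGeneric("inbreedingF", function(x) standardGeneric("inbreedingF"))

#' Shrinkage intensity recorded on an object
#'
#' @param x a \linkS4class{KinshipMatrix} or
#'   \linkS4class{ShrinkageDiagnostics}.
#' @return scalar intensity in [0, 1].
#' @export
setGeneric("shrinkDelta", function(x) standardGeneric("shrinkDelta"))

#' Genomic estimated breeding values of a fit
#'
#' @param x a \linkS4class{GBLUPFit}.
#' @return named numeric vector of GEBVs for the training lines.
#' @export
setGeneric("gebv", function(x) standardGeneric("gebv"))

#' REML variance components of a fit
#'
#' @param x a \linkS4class{GBLUPFit}.
#' @return named numeric vector c(sigma2 = ..., sigmaE2 = ...).
#' @export
setGeneric("varComponents", function(x) standardGeneric("varComponents"))

#' Sample covariance of lines across loci
#'
#' Treats marker columns as replicate observations of an n-variate random
#' variable and returns the n x n sample covariance
#' S = m^-1 W W' - rowMeans(W) rowMeans(W)'.
#'
#' @param x a \linkS4class{CenteredGenotypes} or a numeric matrix whose
#'   columns are the replicate observations.
#' @return symmetric n x n numeric matrix.
#' @export
setGeneric("sampleCovariance", function(x) standardGeneric("sampleCovariance"))

#' MSE-optimal shrinkage intensity
#'
#' Analytic intensity minimizing the expected squared Frobenius error of the
#' shrunk covariance of lines across loci, clamped to [0, 1]. For genotype
#' data the rows are first adjusted to zero mean across markers.
#'
#' @param x a \linkS4class{CenteredGenotypes} or a numeric matrix whose
#'   columns are replicate observations of a zero-mean variable.
#' @return a \linkS4class{ShrinkageDiagnostics} object.
#' @export
setGeneric("shrinkageIntensity",
           function(x) standardGeneric("shrinkageIntensity"))
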