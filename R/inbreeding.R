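#' @describeIn inbreedingF weighted locus average of an InbreedingSummary
#' @export
setMethod("inbreedingF", "InbreedingSummary", function(x) x@f)

setMethod("show", "InbreedingSummary", function(object) {
  cat(sprintf("InbreedingSummary: %d loci, %d individuals\n",
              length(object@fk), length(object@phi)))
  cat(sprintf("  f = %.4f; phi range [%.4f, %.4f]\n", object@f,
              min(object@phi), max(object@phi)))
})

#' Marker-based inbreeding coefficients
#'
#' Computes the identity-in-state inbreeding coefficients implied by the
#' realized relationship matrix, at three levels:
#' \itemize{
#'   \item per locus, f_k: the intra-individual gametic correlation. At a
#'     fully homozygous locus f_k = 1; under universal heterozygosity
#'     f_k = -1; Hardy-Weinberg proportions give f_k = 0. Monomorphic loci
#'     are assigned f_k = 0 with weight 0.
#'   \item per individual, phi_i = sum_k (X_ik - 2 p_k)^2 / (2 sum_j p_j q_j)
#'     - 1, the excess homozygosity of line i relative to the current
#'     population. When all allele frequencies equal 1/2 this simplifies to
#'     2 psi - 1 with psi the line's homozygous fraction.
#'   \item population, f = sum_k beta_k f_k with weights
#'     beta_k = p_k q_k / sum_j p_j q_j.
#' }
#' The three are tied by an exact identity, f = sum(beta_k f_k) =
#' mean(phi_i) = mean(diag(A)) - 1, which holds to machine precision for any
#' real-valued dosages (including mean-imputed ones): f_k is evaluated as
#' n^-1 sum_i (X_ik - 2 p_k)^2 / (2 p_k q_k) - 1, which coincides with the
#' gametic-correlation definition at integer dosages {0, 1, 2} and extends it
#' continuously in between.
#'
#' @param G a complete \linkS4class{GenotypeMatrix}.
#' @return an \linkS4class{InbreedingSummary}.
#' @export
inbreedingSummary <- function(G) {
  stopifnot(is(G, "GenotypeMatrix"))
  X <- G@dosage
  if (anyNA(X)) stop("genotypes contain missing values; impute first")
  n <- nrow(X)
  p <- colMeans(X) / 2
  pq <- p * (1 - p)
  poly <- pq > 0
  if (!any(poly)) stop("all loci are monomorphic: inbreeding undefined")
  W2 <- sweep(X, 2L, 2 * p, "-")^2
  css <- colSums(W2)  # sum_i (X_ik - 2 p_k)^2 per locus
  fk <- numeric(length(p))
  fk[poly] <- css[poly] / (2 * n * pq[poly]) - 1
  betak <- numeric(length(p))
  betak[poly] <- pq[poly] / sum(pq[poly])
  denom <- 2 * sum(pq)
  phi <- rowSums(W2) / denom - 1
  names(phi) <- rownames(X)
  names(fk) <- names(betak) <- colnames(X)
  new("InbreedingSummary", fk = fk, betak = betak, phi = phi,
      f = sum(betak * fk))
}
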