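#' Construct a GenotypeMatrix
#'
#' @param dosage numeric matrix of allele dosages with line IDs as rownames
#'   and marker IDs as colnames; NA marks missing cells.
#' @param missingMask optional logical matrix; defaults to \code{is.na(dosage)}.
#' @return a \linkS4class{GenotypeMatrix}.
#' @examples
#' x <- matrix(c(0, 1, 2, 2), 2, 2,
#'             dimnames = list(c("L1", "L2"), c("M1", "M2")))
#' GenotypeMatrix(x)
#' @export
GenotypeMatrix <- function(dosage, missingMask = is.na(dosage)) {
  storage.mode(dosage) <- "double"
  dimnames(missingMask) <- dimnames(dosage)
  new("GenotypeMatrix", dosage = dosage, missingMask = missingMask)
}

#' @describeIn dosages dosage matrix of a GenotypeMatrix
#' @export
setMethod("dosages", "GenotypeMatrix", function(x) x@dosage)

#' @describeIn missingMask mask of a GenotypeMatrix
#' @export
setMethod("missingMask", "GenotypeMatrix", function(x) x@missingMask)

#' @describeIn lineIds line IDs of a GenotypeMatrix
#' @export
setMethod("lineIds", "GenotypeMatrix", function(x) rownames(x@dosage))

#' @describeIn markerIds marker IDs of a GenotypeMatrix
#' @export
setMethod("markerIds", "GenotypeMatrix", function(x) colnames(x@dosage))

#' @export
setMethod("dim", "GenotypeMatrix", function(x) dim(x@dosage))

setMethod("show", "GenotypeMatrix", function(object) {
  d <- dim(object@dosage)
  nmiss <- sum(object@missingMask)
  cat("GenotypeMatrix:", d[1], "lines x", d[2], "markers\n")
  cat(sprintf("  missing cells: %d (%.2f%%)%s\n", nmiss,
              100 * nmiss / max(1, prod(d)),
              if (nmiss > 0 && !anyNA(object@dosage)) ", imputed" else ""))
})

.detectSep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("file is empty: ", path)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

.readDelimited <- function(path) {
  sep <- .detectSep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          row.names = NULL, quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE,
                          na.strings = character(0))
  if (ncol(df) < 2L)
    stop("expected at least two columns (IDs plus data) in ", path)
  df
}

#' Read a delimited genotype table
#'
#' Reads an n x m genotype table from delimited text (comma or tab,
#' auto-detected). The first column holds line IDs and the header row holds
#' marker IDs. Two dosage codings are accepted: \code{"dosage012"} (counted
#' allele copies, the canonical internal coding) and \code{"symmetric101"}
#' ({-1, 0, 1}, shifted to {0, 1, 2} on input). Cells equal to
#' \code{missingToken} or empty are flagged missing. Values may be fractional
#' (e.g. from prior mean imputation) but must lie within the declared
#' coding's range.
#'
#' @param path path to the delimited text file.
#' @param coding \code{"dosage012"} or \code{"symmetric101"}.
#' @param missingToken string marking missing cells (default \code{"NA"});
#'   empty cells are always treated as missing.
#' @return a \linkS4class{GenotypeMatrix} in canonical {0, 1, 2} dosage
#'   coding, with the missing cells flagged in the mask.
#' @export
readGenotypeTable <- function(path, coding = c("dosage012", "symmetric101"),
                              missingToken = "NA") {
  coding <- match.arg(coding)
  df <- .readDelimited(path)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate line IDs: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  markers <- colnames(df)[-1L]
  if (anyDuplicated(markers))
    stop("duplicate marker IDs: ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "))
  cells <- as.matrix(df[, -1L, drop = FALSE])
  miss <- cells == missingToken | cells == ""
  vals <- suppressWarnings(as.numeric(cells))
  bad <- which(is.na(vals) & !miss)
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(cells)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(cells)) + 1L
    stop(sprintf("unparseable cell '%s' at line '%s', marker '%s'",
                 cells[bad[1L]], ids[i], markers[j]))
  }
  rng <- if (coding == "dosage012") c(0, 2) else c(-1, 1)
  out <- which(!is.na(vals) & (vals < rng[1L] | vals > rng[2L]))
  if (length(out)) {
    i <- ((out[1L] - 1L) %% nrow(cells)) + 1L
    j <- ((out[1L] - 1L) %/% nrow(cells)) + 1L
    stop(sprintf(
      "value %s at line '%s', marker '%s' outside the declared coding %s",
      cells[out[1L]], ids[i], markers[j], coding))
  }
  if (coding == "symmetric101") vals <- vals + 1
  vals[miss] <- NA_real_
  m <- matrix(vals, nrow = nrow(cells), ncol = ncol(cells),
              dimnames = list(ids, markers))
  GenotypeMatrix(m, matrix(miss, nrow(cells), ncol(cells)))
}

#' Curate a genotype matrix by missing-data thresholds
#'
#' Removes markers with a missing fraction strictly greater than
#' \code{maxMarkerMissing}, then lines whose missing fraction over the
#' surviving markers is strictly greater than \code{maxLineMissing}. Both
#' passes are computed once (no iteration) and survivor order is preserved.
#' A marker or line sitting exactly at the threshold is retained.
#'
#' @param G a \linkS4class{GenotypeMatrix}.
#' @param maxMarkerMissing maximum tolerated missing fraction per marker
#'   (default 0.10).
#' @param maxLineMissing maximum tolerated missing fraction per line over the
#'   surviving markers (default 0.15).
#' @return the curated \linkS4class{GenotypeMatrix}.
#' @export
curateGenotypes <- function(G, maxMarkerMissing = 0.10, maxLineMissing = 0.15) {
  stopifnot(is(G, "GenotypeMatrix"))
  mk <- G@missingMask | is.na(G@dosage)
  keepM <- colMeans(mk) <= maxMarkerMissing
  if (!any(keepM)) stop("curation removed all markers")
  mk2 <- mk[, keepM, drop = FALSE]
  keepL <- rowMeans(mk2) <= maxLineMissing
  if (!any(keepL)) stop("curation removed all lines")
  GenotypeMatrix(G@dosage[keepL, keepM, drop = FALSE],
                 G@missingMask[keepL, keepM, drop = FALSE])
}

#' Impute missing dosages with the per-marker population mean
#'
#' Replaces each missing cell with the mean dosage of its marker's
#' non-missing values. The missing mask is kept for provenance. Note that
#' mean imputation can introduce low levels of apparent heterozygosity in
#' fully inbred panels (a marker column like c(0, 2, NA) is imputed to 1),
#' pulling the estimated inbreeding coefficient slightly below 1.
#'
#' @param G a \linkS4class{GenotypeMatrix}; every marker must have at least
#'   one observed value (curate first otherwise).
#' @return a complete \linkS4class{GenotypeMatrix} with real-valued dosages.
#' @export
imputePopulationMean <- function(G) {
  stopifnot(is(G, "GenotypeMatrix"))
  d <- G@dosage
  if (!anyNA(d)) return(G)
  nObs <- colSums(!is.na(d))
  if (any(nObs == 0L))
    stop("marker(s) with no observed values: ",
         paste(colnames(d)[nObs == 0L], collapse = ", "),
         "; run curateGenotypes() first")
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- mu[idx[, 2L]]
  GenotypeMatrix(d, G@missingMask)
}

#' Write a square matrix as delimited text
#'
#' Writes a square matrix with IDs on both axes as tab-delimited text: a
#' header line \code{id<TAB>ids...} followed by one row per line. Values are
#' printed with 15 significant digits so a read/write round trip is lossless
#' well beyond 12 significant digits. Signs are preserved as-is (no
#' clamping).
#'
#' @param M square numeric matrix.
#' @param ids character vector of row/column identifiers, length nrow(M).
#' @param path output file path.
#' @return invisibly, the path.
#' @seealso [readSquareMatrix()]
#' @export
writeSquareMatrix <- function(M, ids, path) {
  if (is(M, "KinshipMatrix")) {
    if (missing(ids)) ids <- lineIds(M)
    M <- relMatrix(M)
  }
  if (nrow(M) != ncol(M)) stop("M must be square")
  if (length(ids) != nrow(M)) stop("ids length must match nrow(M)")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", ids), collapse = "\t"), con)
  body <- apply(M, 1L, function(r)
    paste(format(r, digits = 15, scientific = FALSE, trim = TRUE),
          collapse = "\t"))
  writeLines(paste(ids, body, sep = "\t"), con)
  invisible(path)
}

#' Write a genotype table as delimited text
#'
#' Inverse of [readGenotypeTable()] for the canonical {0, 1, 2} coding:
#' tab-delimited, header row of marker IDs behind an \code{id} column, one
#' row per line. Missing (non-imputed) cells are written as \code{NA}.
#'
#' @param G a \linkS4class{GenotypeMatrix}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeGenotypeTable <- function(G, path) {
  stopifnot(is(G, "GenotypeMatrix"))
  d <- G@dosage
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(d)), collapse = "\t"), con)
  body <- apply(d, 1L, function(r)
    paste(ifelse(is.na(r), "NA",
                 format(r, digits = 15, scientific = FALSE, trim = TRUE)),
          collapse = "\t"))
  writeLines(paste(rownames(d), body, sep = "\t"), con)
  invisible(path)
}

#' Read a square delimited matrix written by writeSquareMatrix
#'
#' @param path path to the delimited file (comma or tab auto-detected).
#' @return numeric matrix with the IDs as dimnames.
#' @export
readSquareMatrix <- function(path) {
  df <- .readDelimited(path)
  ids <- df[[1L]]
  M <- matrix(suppressWarnings(as.numeric(as.matrix(df[, -1L, drop = FALSE]))),
              nrow = nrow(df), dimnames = list(ids, colnames(df)[-1L]))
  if (nrow(M) != ncol(M)) stop("matrix in ", path, " is not square")
  if (anyNA(M)) stop("non-numeric cells in ", path)
  M
}

#' Read a two-column phenotype table
#'
#' Expects delimited text with a header and two columns: line ID and a
#' numeric trait value.
#'
#' @param path path to the file.
#' @return named numeric vector of phenotypes.
#' @export
readPhenotypeTable <- function(path) {
  df <- .readDelimited(path)
  if (ncol(df) != 2L) stop("phenotype file must have exactly two columns")
  y <- suppressWarnings(as.numeric(df[[2L]]))
  if (anyNA(y)) {
    bad <- df[[1L]][which(is.na(y))[1L]]
    stop("non-numeric phenotype for line '", bad, "'")
  }
  names(y) <- df[[1L]]
  if (anyDuplicated(names(y))) stop("duplicate line IDs in phenotype file")
  y
}
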