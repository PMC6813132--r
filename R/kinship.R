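## Genetic relatedness matrix utilities.

#' Standardize a genetic relatedness matrix
#'
#' Rescales a kinship/GRM matrix so that the mean of its diagonal elements
#' equals one (`trace(K)/n == 1`). Under this normalization the ratio
#' `sigma_g2 / (sigma_g2 + sigma_u2 + sigma_e2/2)` of the fitted variance
#' components is interpretable as the approximate background heritability of
#' the latent logit-methylation. The operation is idempotent.
#'
#' @param K square symmetric numeric matrix (optionally with id dimnames).
#' @param tol symmetry tolerance.
#' @return the rescaled matrix, dimnames preserved.
#' @examples
#' standardizeKinship(2 * diag(3))
#' @export
standardizeKinship <- function(K, tol = 1e-8) {
  if (!is.matrix(K) || nrow(K) != ncol(K)) {
    stop("invalid kinship: K must be a square matrix")
  }
  if (nrow(K) < 2L) stop("invalid kinship: need n >= 2")
  if (max(abs(K - t(K))) > tol) {
    stop("invalid kinship: K must be symmetric")
  }
  tr <- sum(diag(K))
  if (tr <= 0) stop("invalid kinship: trace must be positive")
  K * (nrow(K) / tr)
}

#' Repair a kinship matrix to positive semi-definiteness
#'
#' Eigenvalues below `-tol` trigger clipping at zero; tiny negative
#' eigenvalues within tolerance are clipped silently. A valid (PSD)
#' covariance is required by the penalized quasi-likelihood fit.
#'
#' @param K square symmetric matrix.
#' @param tol eigenvalue tolerance below which values are clipped to zero.
#' @return a PSD matrix (symmetrized).
#' @export
makeKinshipPSD <- function(K, tol = 1e-8) {
  K <- (K + t(K)) / 2
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) >= 0) return(K)
  v <- pmax(e$values, 0)
  out <- e$vectors %*% (v * t(e$vectors))
  dimnames(out) <- dimnames(K)
  (out + t(out)) / 2
}

#' Centered genetic relatedness matrix from dosages
#'
#' Computes `K = Xc Xc' / p` from an n-by-p matrix of allele dosages, where
#' `Xc` is the column-centered dosage matrix, then standardizes so the mean
#' diagonal equals one (see [standardizeKinship()]). Monomorphic SNPs are
#' dropped.
#'
#' @param dosage n-by-p numeric matrix of genotypes coded 0/1/2.
#' @return standardized n-by-n GRM with rownames from `dosage` rownames.
#' @export
grmFromDosage <- function(dosage) {
  keep <- apply(dosage, 2L, function(x) var(x) > 0)
  X <- scale(dosage[, keep, drop = FALSE], center = TRUE, scale = FALSE)
  K <- tcrossprod(X) / ncol(X)
  dimnames(K) <- list(rownames(dosage), rownames(dosage))
  standardizeKinship(K)
}

#' Read a kinship matrix from a whitespace-delimited file
#'
#' The file is a square numeric matrix, optionally preceded by a first row
#' of individual identifiers. Without a header, identifiers must be supplied
#' via `ids` (e.g. taken from the counts file order).
#'
#' @param path file path.
#' @param ids identifiers to use when the file has no header row.
#' @return symmetric numeric matrix with id dimnames, standardized via
#'   [standardizeKinship()].
#' @export
readKinship <- function(path, ids = NULL) {
  first <- strsplit(trimws(readLines(path, n = 1L)), "\\s+")[[1]]
  header <- all(is.na(suppressWarnings(as.numeric(first))))
  tab <- utils::read.table(path, header = FALSE, skip = as.integer(header))
  K <- as.matrix(tab)
  if (header) {
    ids <- first
  } else if (is.null(ids)) {
    ids <- paste0("ind", seq_len(nrow(K)))
  }
  if (length(ids) != nrow(K) || nrow(K) != ncol(K)) {
    stop("invalid kinship: dimensions do not match the ids")
  }
  dimnames(K) <- list(ids, ids)
  standardizeKinship(K)
}

#' Write a kinship matrix with an id header row
#'
#' @param K matrix with id dimnames.
#' @param path output path.
#' @export
writeKinship <- function(K, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(rownames(K), collapse = "\t"), con)
  utils::write.table(format(K, digits = 12, trim = TRUE), con,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}
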