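## Readers and writers for the long-format pair counts TSV, the results
## table, and covariate handling.

pairTsvHeader <- c("pair_id", "snp_id", "cpg_id", "individual_id",
                   "genotype", "y_total", "r_total",
                   "y_ref", "r_ref", "y_alt", "r_alt")

#' Read SNP-CpG pair counts from a long-format TSV
#'
#' One row per (pair, individual). Required columns (exact header):
#' `pair_id, snp_id, cpg_id, individual_id, genotype, y_total, r_total,
#' y_ref, r_ref, y_alt, r_alt`; the four allele columns are `NA` for
#' homozygotes. Optional columns `chrom`, `pos_snp`, `pos_cpg` (1-based)
#' are kept as pair metadata. Rows violating the count invariants
#' (`y > r`, allele sums not matching the totals, unknown genotype codes)
#' are rejected individually with a logged reason; more than 10% rejected
#' rows is a file-level error.
#'
#' @param path TSV file path.
#' @return named list of [PairCounts-class] objects; attribute `rejected`
#'   is a `data.frame` of dropped rows and reasons.
#' @export
readPairsTSV <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(pairTsvHeader %in% names(tab))) {
    stop("pairs TSV is missing required columns: ",
         paste(setdiff(pairTsvHeader, names(tab)), collapse = ", "))
  }
  reasons <- character(nrow(tab))
  g <- tab$genotype
  bad <- !(g %in% c(0, 1, 2))
  reasons[bad & reasons == ""] <- "unknown genotype code"
  bad2 <- is.na(tab$r_total) | is.na(tab$y_total) |
    tab$y_total < 0 | tab$y_total > tab$r_total
  reasons[bad2 & reasons == ""] <- "count invariant violated (y_total)"
  hasAll <- !is.na(tab$r_ref) & !is.na(tab$r_alt)
  badAll <- hasAll & (
    is.na(tab$y_ref) | is.na(tab$y_alt) |
    tab$y_ref < 0 | tab$y_ref > tab$r_ref |
    tab$y_alt < 0 | tab$y_alt > tab$r_alt |
    (tab$y_ref + tab$y_alt) != tab$y_total |
    (tab$r_ref + tab$r_alt) != tab$r_total)
  reasons[badAll & reasons == ""] <- "allele counts inconsistent with totals"
  badHet <- hasAll & !badAll & g != 1
  reasons[badHet & reasons == ""] <- "allele counts on a homozygote"
  drop <- reasons != ""
  if (mean(drop) > 0.10) {
    stop(sprintf("more than 10%% of rows rejected (%d of %d)",
                 sum(drop), nrow(tab)))
  }
  rejected <- cbind(tab[drop, , drop = FALSE], reason = reasons[drop])
  keep <- tab[!drop, , drop = FALSE]
  out <- lapply(split(keep, keep$pair_id), function(d) {
    n <- nrow(d)
    yA <- as.matrix(d[, c("y_ref", "y_alt")])
    rA <- as.matrix(d[, c("r_ref", "r_alt")])
    meta <- list()
    for (cc in c("chrom", "pos_snp", "pos_cpg")) {
      if (cc %in% names(d)) meta[[cc]] <- d[[cc]][1]
    }
    PairCounts(d$pair_id[1], ids = d$individual_id,
               genotype = d$genotype, yTotal = d$y_total,
               rTotal = d$r_total, yAllele = yA, rAllele = rA,
               snpId = as.character(d$snp_id[1]),
               cpgId = as.character(d$cpg_id[1]), meta = meta)
  })
  attr(out, "rejected") <- rejected
  out
}

#' Write pairs to the long-format TSV
#'
#' Inverse of [readPairsTSV()]; round trips are lossless.
#'
#' @param pairs list of [PairCounts-class] objects.
#' @param path output path.
#' @export
writePairsTSV <- function(pairs, path) {
  rows <- lapply(pairs, function(pc) {
    d <- data.frame(
      pair_id = pc@pairId,
      snp_id = if (length(pc@snpId)) pc@snpId else NA,
      cpg_id = if (length(pc@cpgId)) pc@cpgId else NA,
      individual_id = pc@ids, genotype = pc@genotype,
      y_total = pc@yTotal, r_total = pc@rTotal,
      y_ref = pc@yAllele[, 1], r_ref = pc@rAllele[, 1],
      y_alt = pc@yAllele[, 2], r_alt = pc@rAllele[, 2])
    for (cc in c("chrom", "pos_snp", "pos_cpg")) {
      if (!is.null(pc@meta[[cc]])) d[[cc]] <- pc@meta[[cc]]
    }
    d
  })
  common <- Reduce(intersect, lapply(rows, names))
  rows <- lapply(rows, function(d) d[common])
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
}

#' Write a results table to TSV
#'
#' One row per pair with the shared results schema of [fitPair()]; missing
#' values are written as `"NA"`.
#'
#' @param results `data.frame` from [fitStudy()].
#' @param path output path.
#' @export
writeResultsTSV <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}

#' Residualize a genotype dosage on covariates
#'
#' Least-squares regression of the dosage on an intercept plus the numeric
#' covariate columns (age, sex, methylation principal components, ...).
#' The residual replaces the dosage in downstream fits; on allele rows the
#' covariate becomes `x_il - fitted_i / 2`, which preserves the
#' within-heterozygote allele contrast of exactly 1. Missing covariate
#' values are imputed by the column mean (flagged); collinear columns are
#' dropped with a warning.
#'
#' @param genotype named dosage vector (names = individual ids), or plain
#'   vector in covariate-table order.
#' @param covariates `data.frame` with an `individual_id` column and
#'   numeric covariates, or a plain numeric matrix/data.frame in genotype
#'   order.
#' @return list with `residual` and `fitted` (both named like `genotype`)
#'   and `imputed` (logical: was any covariate value imputed?).
#' @export
residualizeGenotype <- function(genotype, covariates) {
  covariates <- as.data.frame(covariates)
  if ("individual_id" %in% names(covariates)) {
    if (is.null(names(genotype))) {
      stop("genotype must be named to match covariates by individual_id")
    }
    idx <- match(names(genotype), covariates$individual_id)
    if (anyNA(idx)) stop("covariates missing for some individuals")
    covariates <- covariates[idx, setdiff(names(covariates),
                                          "individual_id"), drop = FALSE]
  }
  C <- as.matrix(covariates)
  storage.mode(C) <- "double"
  imputed <- FALSE
  for (j in seq_len(ncol(C))) {
    if (anyNA(C[, j])) {
      C[is.na(C[, j]), j] <- mean(C[, j], na.rm = TRUE)
      imputed <- TRUE
    }
  }
  n <- length(genotype)
  if (n <= ncol(C) + 1L) stop("need n > number of covariates + 1")
  fit <- lm(genotype ~ C)
  if (anyNA(coef(fit))) {
    warning("collinear covariate column(s) dropped")
  }
  res <- list(residual = setNames(unname(resid(fit)), names(genotype)),
              fitted = setNames(unname(fitted(fit)), names(genotype)),
              imputed = imputed)
  if (imputed) warning("missing covariate values imputed by column mean")
  res
}
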