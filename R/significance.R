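## Permutation-based empirical null, empirical FDR, and truth-based power.

#' Permute genotype labels across sample units
#'
#' Builds the joint design for a pair ([buildDesign()]), treats each
#' heterozygote allele as one sample unit and each homozygote (or het
#' without allele data) as one unit, and permutes the genotype covariate
#' labels across units while leaving the counts untouched. The multiset of
#' labels is preserved by construction. This is the default strategy for
#' constructing an empirical null, applicable at any sample size.
#'
#' @param pc a [PairCounts-class] object.
#' @param B number of permutations (default 10).
#' @param fittedCovariate optional fitted dosage, see [buildDesign()].
#' @return list of `B` permuted design `data.frame`s, each directly
#'   fittable by [fitPQL()].
#' @export
permuteLabels <- function(pc, B = 10L, fittedCovariate = NULL) {
  des <- buildDesign(pc, "joint", fittedCovariate = fittedCovariate)
  lapply(seq_len(B), function(b) {
    d <- des
    d$x <- sample(d$x)
    d
  })
}

#' Permute counts across individuals (alternative strategy)
#'
#' Permutes the individual-level count pairs `(y_i, r_i)` across
#' individuals while genotypes stay in place; for individuals who are
#' heterozygous, the allele split is then redrawn read-by-read with
#' probability 1/2: methylated reads `y1 ~ Bin(y, 1/2)` and unmethylated
#' reads `(r - y)_1 ~ Bin(r - y, 1/2)` independently, so the per-allele
#' counts always sum back to the individual totals. Recommended for larger
#' samples (roughly n > 150); at small n the label permutation is safer.
#'
#' @param pc a [PairCounts-class] object.
#' @param B number of permutations (default 10).
#' @return list of `B` permuted [PairCounts-class] objects.
#' @export
permuteCountsAlt <- function(pc, B = 10L) {
  pc <- dropUninformative(pc)
  n <- length(pc@ids)
  lapply(seq_len(B), function(b) {
    perm <- sample.int(n)
    y <- pc@yTotal[perm]; r <- pc@rTotal[perm]
    yA <- matrix(NA_real_, n, 2); rA <- matrix(NA_real_, n, 2)
    het <- which(pc@genotype == 1)
    if (length(het)) {
      y1 <- rbinom(length(het), y[het], 0.5)
      u1 <- rbinom(length(het), r[het] - y[het], 0.5)
      yA[het, ] <- cbind(y1, y[het] - y1)
      rA[het, ] <- cbind(y1 + u1, (y[het] - y1) + (r[het] - y[het] - u1))
    }
    PairCounts(pc@pairId, ids = pc@ids, genotype = pc@genotype,
               yTotal = y, rTotal = r, yAllele = yA, rAllele = rA,
               snpId = pc@snpId, cpgId = pc@cpgId, meta = pc@meta)
  })
}

#' Empirical false discovery rate from permuted p-values
#'
#' For each candidate threshold `t`,
#' `fdr_hat(t) = (mean permuted count <= t) / max(1, observed count <= t)`,
#' with the permuted null pooled across pairs and permutations. The
#' estimate is forced monotone non-decreasing in `t` (step-up), and
#' discoveries at level `alpha` are all pairs with `p <= t*`, where `t*`
#' is the largest threshold with `fdr_hat(t*) <= alpha`.
#'
#' @param pObs observed p-values (one per pair).
#' @param pPerm matrix of permuted p-values, one row per permutation
#'   (columns = pairs), or a vector for a single permutation.
#' @param alpha FDR level used to report discoveries.
#' @param thresholds candidate thresholds; defaults to the sorted observed
#'   p-values.
#' @return `data.frame` of class `"FdrTable"` with columns `threshold`,
#'   `n_observed`, `mean_n_permuted`, `fdr_hat`; attributes `discoveries`
#'   (logical per pair at `alpha`), `alpha`, `tstar`, and `B`.
#' @examples
#' empiricalFdr(c(0.001, 0.2), rbind(c(0.05, 0.5)), alpha = 0.05)
#' @export
empiricalFdr <- function(pObs, pPerm, alpha = 0.05, thresholds = NULL) {
  if (is.vector(pPerm)) pPerm <- matrix(pPerm, nrow = 1L)
  pObs <- pObs[!is.na(pObs)]
  B <- nrow(pPerm)
  pp <- sort(as.vector(pPerm[!is.na(pPerm)]))
  if (is.null(thresholds)) thresholds <- sort(unique(pObs))
  so <- sort(pObs)
  nObs <- findInterval(thresholds, so)
  nPerm <- findInterval(thresholds, pp) / B
  fdr <- nPerm / pmax(1, nObs)
  fdr <- cummax(fdr)   # step-up: monotone non-decreasing in t
  tab <- data.frame(threshold = thresholds, n_observed = nObs,
                    mean_n_permuted = nPerm, fdr_hat = fdr)
  ok <- which(fdr <= alpha)
  tstar <- if (length(ok)) thresholds[max(ok)] else -Inf
  attr(tab, "discoveries") <- pObs <= tstar
  attr(tab, "alpha") <- alpha
  attr(tab, "tstar") <- tstar
  attr(tab, "B") <- B
  class(tab) <- c("FdrTable", "data.frame")
  tab
}

#' Power at a known-truth false discovery proportion
#'
#' Pools p-values across simulated sites (and replicates), sorts them
#' ascending, and finds the largest rank `K` at which the realized false
#' discovery proportion - the fraction of null sites among the top `K` -
#' does not exceed `alpha`. Tied p-values enter together at the larger
#' rank. Power is the fraction of all true sites ranked in the top `K`.
#'
#' @param p p-values, pooled across replicates.
#' @param truth logical flags: is each site a true mQTL?
#' @param alpha target false discovery proportion.
#' @return power in `[0, 1]`.
#' @export
powerAtFdr <- function(p, truth, alpha = 0.05) {
  keep <- !is.na(p)
  p <- p[keep]; truth <- as.logical(truth[keep])
  nTrue <- sum(truth)
  if (nTrue == 0L) stop("power undefined: no true sites")
  o <- order(p)
  ps <- p[o]; ts <- truth[o]
  cumFalse <- cumsum(!ts)
  k <- seq_along(ps)
  fdp <- cumFalse / k
  ## ties enter together: only ranks that close a tie group are eligible
  groupEnd <- c(ps[-1] != ps[-length(ps)], TRUE)
  ok <- which(fdp <= alpha & groupEnd)
  if (!length(ok)) return(0)
  K <- max(ok)
  sum(ts[seq_len(K)]) / nTrue
}
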