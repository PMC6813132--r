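## Quality-control filters for SNP-CpG pairs.

#' Filter SNP-CpG pairs by the standard QC rules
#'
#' Applies five exclusion rules to each pair (per-individual methylation
#' level computed as `y_total / r_total` over measured individuals, i.e.
#' those with `r_total > 0` and a genotype call):
#' \enumerate{
#'   \item measured in fewer than `minIndividuals` individuals;
#'   \item methylation level below `levelLow` or above `levelHigh` in at
#'     least `levelProp` of measured individuals (near-constant sites carry
#'     little signal);
#'   \item mean read depth below `minMeanDepth`;
#'   \item SNP minor allele frequency below `minMaf` among measured
#'     individuals;
#'   \item apparent reference/alternate methylation difference larger than
#'     `maxAlleleDiff`, computed as the absolute difference of the mean
#'     per-allele methylation ratios across heterozygotes with allele data
#'     (a guard against allele-specific mapping bias).
#' }
#' The filter is order-independent and idempotent.
#'
#' @param pairs list of [PairCounts-class] objects.
#' @param minIndividuals,levelLow,levelHigh,levelProp,minMeanDepth,minMaf,maxAlleleDiff
#'   rule thresholds; defaults 20, 0.10, 0.90, 0.90, 5, 0.05 and 0.6.
#' @return list of retained pairs; attribute `report` is a `data.frame`
#'   with per-rule exclusion counts, attribute `excluded` maps pair ids to
#'   the first rule that removed them.
#' @export
qcFilter <- function(pairs, minIndividuals = 20L, levelLow = 0.10,
                     levelHigh = 0.90, levelProp = 0.90, minMeanDepth = 5,
                     minMaf = 0.05, maxAlleleDiff = 0.6) {
  ruleNames <- c("few_individuals", "extreme_levels", "low_depth",
                 "low_maf", "allele_difference")
  firstRule <- vapply(pairs, function(pc) {
    keep <- !is.na(pc@genotype) & pc@rTotal > 0
    nMeas <- sum(keep)
    if (nMeas < minIndividuals) return("few_individuals")
    lev <- pc@yTotal[keep] / pc@rTotal[keep]
    if (mean(lev < levelLow | lev > levelHigh) >= levelProp) {
      return("extreme_levels")
    }
    if (mean(pc@rTotal[keep]) < minMeanDepth) return("low_depth")
    af <- mean(pc@genotype[keep]) / 2
    if (min(af, 1 - af) < minMaf) return("low_maf")
    hasAll <- hasAlleleData(pc) & keep
    if (any(hasAll)) {
      refRatio <- mean(pc@yAllele[hasAll, 1] /
                         pmax(pc@rAllele[hasAll, 1], 1))
      altRatio <- mean(pc@yAllele[hasAll, 2] /
                         pmax(pc@rAllele[hasAll, 2], 1))
      if (abs(refRatio - altRatio) > maxAlleleDiff) {
        return("allele_difference")
      }
    }
    ""
  }, character(1))
  kept <- pairs[firstRule == ""]
  report <- data.frame(
    rule = ruleNames,
    n_excluded = vapply(ruleNames, function(r) sum(firstRule == r),
                        integer(1)))
  excl <- firstRule[firstRule != ""]
  names(excl) <- vapply(pairs, pairId, character(1))[firstRule != ""]
  attr(kept, "report") <- report
  attr(kept, "excluded") <- excl
  kept
}
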