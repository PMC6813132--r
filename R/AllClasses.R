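#' @import methods
#' @importFrom stats var plogis qlogis pchisq rbinom rnorm runif rbeta rnbinom
#'   dbinom pbeta optim optimize glm binomial coef lm resid fitted fisher.test
#'   setNames qnorm quantile p.adjust sd convolve
NULL

## -------------------------------------------------------------------------
## PairCounts: observed counts and genotypes for one SNP-CpG pair
## -------------------------------------------------------------------------

#' Per-pair methylation counts and genotypes
#'
#' A `PairCounts` object holds, for a single SNP-CpG pair, the per-individual
#' methylated and total read counts together with the SNP genotype
#' (0/1/2 copies of the alternate allele). For heterozygotes whose reads can
#' be assigned to an allele, the per-allele methylated/total counts are kept
#' in two-column matrices (reference allele first, alternate second); allele
#' entries are `NA` for homozygotes and for heterozygotes lacking
#' phase-assignable reads.
#'
#' Invariants enforced by the validity method: `0 <= y <= r` everywhere, and
#' wherever allele counts are present they sum to the individual totals.
#'
#' @slot pairId single identifier for the SNP-CpG pair.
#' @slot snpId,cpgId optional SNP / CpG identifiers.
#' @slot ids character vector of individual identifiers.
#' @slot genotype numeric vector, copies of the alternate allele (0, 1, 2 or
#'   `NA`).
#' @slot yTotal,rTotal numeric vectors of methylated / total read counts per
#'   individual.
#' @slot yAllele,rAllele n-by-2 numeric matrices of per-allele counts
#'   (columns `ref`, `alt`); rows are `NA` unless the individual is a
#'   heterozygote with allele-resolved reads.
#' @slot meta list of optional metadata (e.g. `chrom`, `posSnp`, `posCpg`,
#'   1-based coordinates).
#'
#' @export
setClass("PairCounts",
  representation(
    pairId   = "character",
    snpId    = "character",
    cpgId    = "character",
    ids      = "character",
    genotype = "numeric",
    yTotal   = "numeric",
    rTotal   = "numeric",
    yAllele  = "matrix",
    rAllele  = "matrix",
    meta     = "list"
  )
)

setValidity("PairCounts", function(object) {
  n <- length(object@ids)
  msg <- character()
  if (length(object@pairId) != 1L) msg <- c(msg, "pairId must be length 1")
  for (s in c("genotype", "yTotal", "rTotal")) {
    if (length(slot(object, s)) != n) {
      msg <- c(msg, sprintf("%s must have one entry per individual", s))
    }
  }
  if (!all(dim(object@yAllele) == c(n, 2L)) ||
      !all(dim(object@rAllele) == c(n, 2L))) {
    msg <- c(msg, "yAllele and rAllele must be n-by-2 matrices")
  }
  g <- object@genotype
  if (!all(is.na(g) | g %in% c(0, 1, 2))) {
    msg <- c(msg, "genotype entries must be 0, 1, 2 or NA")
  }
  if (any(object@yTotal < 0 | object@rTotal < 0 |
          object@yTotal > object@rTotal, na.rm = TRUE)) {
    msg <- c(msg, "need 0 <= yTotal <= rTotal")
  }
  if (length(msg)) return(msg)
  hasAll <- !is.na(object@rAllele[, 1L])
  if (any(hasAll & (is.na(g) | g != 1))) {
    msg <- c(msg, "allele-level counts are only allowed for heterozygotes")
  }
  if (any(hasAll)) {
    ya <- object@yAllele[hasAll, , drop = FALSE]
    ra <- object@rAllele[hasAll, , drop = FALSE]
    if (any(is.na(ya)) || any(ya < 0) || any(ya > ra)) {
      msg <- c(msg, "need 0 <= yAllele <= rAllele for allele rows")
    } else {
      if (any(rowSums(ya) != object@yTotal[hasAll]) ||
          any(rowSums(ra) != object@rTotal[hasAll])) {
        msg <- c(msg, "allele counts must sum to the individual totals")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PairCounts object
#'
#' @param pairId pair identifier.
#' @param ids individual identifiers; defaults to `ind1..indn`.
#' @param genotype copies of the alternate allele per individual (0/1/2/NA).
#' @param yTotal,rTotal methylated / total read counts per individual.
#' @param yAllele,rAllele optional n-by-2 matrices of per-allele counts
#'   (columns ref, alt) for heterozygotes; default all-`NA`.
#' @param snpId,cpgId optional identifiers.
#' @param meta optional metadata list (`chrom`, `posSnp`, `posCpg`, ...).
#' @return a validated [PairCounts-class] object.
#' @examples
#' pc <- PairCounts("p1", genotype = c(0, 1, 2),
#'                  yTotal = c(2, 5, 9), rTotal = c(10, 10, 10))
#' nHet(pc)
#' @export
PairCounts <- function(pairId, ids = NULL, genotype, yTotal, rTotal,
                       yAllele = NULL, rAllele = NULL,
                       snpId = character(), cpgId = character(),
                       meta = list()) {
  n <- length(genotype)
  if (is.null(ids)) ids <- paste0("ind", seq_len(n))
  blank <- matrix(NA_real_, n, 2L, dimnames = list(NULL, c("ref", "alt")))
  if (is.null(yAllele)) yAllele <- blank
  if (is.null(rAllele)) rAllele <- blank
  dimnames(yAllele) <- dimnames(rAllele) <- list(NULL, c("ref", "alt"))
  new("PairCounts", pairId = as.character(pairId), snpId = snpId,
      cpgId = cpgId, ids = as.character(ids),
      genotype = as.numeric(genotype),
      yTotal = as.numeric(yTotal), rTotal = as.numeric(rTotal),
      yAllele = yAllele, rAllele = rAllele, meta = meta)
}

#' @describeIn PairCounts pair identifier accessor.
#' @param object,x a `PairCounts` object.
#' @export
setGeneric("pairId", function(object) standardGeneric("pairId"))

#' @rdname PairCounts
#' @export
setMethod("pairId", "PairCounts", function(object) object@pairId)

#' @describeIn PairCounts genotype vector accessor (named by individual).
#' @export
setGeneric("genotypes", function(object) standardGeneric("genotypes"))

#' @rdname PairCounts
#' @export
setMethod("genotypes", "PairCounts",
          function(object) setNames(object@genotype, object@ids))

#' @describeIn PairCounts number of heterozygotes (genotype == 1).
#' @export
setGeneric("nHet", function(object) standardGeneric("nHet"))

#' @rdname PairCounts
#' @export
setMethod("nHet", "PairCounts",
          function(object) sum(object@genotype == 1, na.rm = TRUE))

#' @describeIn PairCounts which individuals carry allele-resolved counts.
#' @export
setGeneric("hasAlleleData", function(object) standardGeneric("hasAlleleData"))

#' @rdname PairCounts
#' @export
setMethod("hasAlleleData", "PairCounts",
          function(object) !is.na(object@rAllele[, 1L]))

setMethod("show", "PairCounts", function(object) {
  n <- length(object@ids)
  cat("PairCounts '", object@pairId, "': ", n, " individuals (",
      nHet(object), " het, ", sum(hasAlleleData(object)),
      " with allele-resolved reads)\n", sep = "")
  cat("  median total depth: ",
      stats::median(object@rTotal[object@rTotal > 0]), "\n", sep = "")
})

#' @rdname PairCounts
#' @export
setMethod("length", "PairCounts", function(x) length(x@ids))

#' Drop non-informative individuals from a pair
#'
#' Individuals with a total read count of zero (or a missing genotype) carry
#' no information for the model and are removed before fitting.
#'
#' @param pc a [PairCounts-class] object.
#' @return a `PairCounts` object restricted to informative individuals.
#' @export
dropUninformative <- function(pc) {
  keep <- !is.na(pc@genotype) & !is.na(pc@rTotal) & pc@rTotal > 0
  if (all(keep)) return(pc)
  new("PairCounts", pairId = pc@pairId, snpId = pc@snpId, cpgId = pc@cpgId,
      ids = pc@ids[keep], genotype = pc@genotype[keep],
      yTotal = pc@yTotal[keep], rTotal = pc@rTotal[keep],
      yAllele = pc@yAllele[keep, , drop = FALSE],
      rAllele = pc@rAllele[keep, , drop = FALSE], meta = pc@meta)
}

## -------------------------------------------------------------------------
## SimConfig: the simulation knobs
## -------------------------------------------------------------------------

#' Simulation configuration
#'
#' Holds the knobs of the bisulfite-sequencing simulation: sample size,
#' background heritability of the latent logit-methylation, total
#' over-dispersion variance, shared-environment proportion, SNP minor allele
#' frequency bin, negative-binomial read-depth parameters, baseline
#' methylation level, genotype effect size (proportion of latent variance
#' explained), and study layout. Defaults are the baseline study conditions:
#' n = 100, h2 = 0.3, pi0 = 0.5, MAF = 0.3, rho = 0, TR = 20, phi = 3,
#' sigma2 = 0.7, PVE = 0.1, with a Beta(10, 10) allele read split.
#'
#' @slot n sample size.
#' @slot h2 background heritability of the latent variable, in `[0, 1)`.
#' @slot sigma2 total over-dispersion variance on the logit scale.
#' @slot rho proportion of environmental variance shared between the two
#'   alleles of an individual, in `[0, 1]`.
#' @slot maf minor allele frequency bin center; supported bins are centered
#'   on 0.1 (0.05-0.15), 0.3 (0.25-0.35) and 0.5 (0.45-0.50).
#' @slot tr mean of the negative-binomial total read count.
#' @slot phi negative-binomial dispersion (variance `tr + tr^2 / phi`).
#' @slot pi0 baseline methylation proportion.
#' @slot pve proportion of latent variance explained by the focal SNP for
#'   true mQTL sites; `pve + h2 < 1`.
#' @slot nSites number of SNP-CpG pairs per study.
#' @slot propTrue fraction of pairs simulated with a nonzero SNP effect.
#' @slot betaShape1,betaShape2 shape parameters of the Beta allele-split
#'   distribution for total reads.
#' @slot nSnps number of SNPs used to build the genetic relatedness matrix.
#' @slot seed RNG seed (`NA` = use the current RNG state).
#' @export
setClass("SimConfig",
  representation(
    n = "numeric", h2 = "numeric", sigma2 = "numeric", rho = "numeric",
    maf = "numeric", tr = "numeric", phi = "numeric", pi0 = "numeric",
    pve = "numeric", nSites = "numeric", propTrue = "numeric",
    betaShape1 = "numeric", betaShape2 = "numeric", nSnps = "numeric",
    seed = "numeric"
  ),
  prototype(
    n = 100, h2 = 0.3, sigma2 = 0.7, rho = 0, maf = 0.3, tr = 20, phi = 3,
    pi0 = 0.5, pve = 0.1, nSites = 1000, propTrue = 0.1,
    betaShape1 = 10, betaShape2 = 10, nSnps = 2000, seed = NA_real_
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@h2 < 0 || object@h2 >= 1) msg <- c(msg, "h2 must be in [0, 1)")
  if (object@rho < 0 || object@rho > 1) msg <- c(msg, "rho must be in [0, 1]")
  if (object@pve < 0 || object@pve >= 1) msg <- c(msg, "pve must be in [0, 1)")
  if (object@pve + object@h2 >= 1) msg <- c(msg, "need pve + h2 < 1")
  if (object@sigma2 < 0) msg <- c(msg, "sigma2 must be non-negative")
  if (object@tr <= 0 || object@phi <= 0) {
    msg <- c(msg, "tr and phi must be positive")
  }
  if (object@pi0 <= 0 || object@pi0 >= 1) {
    msg <- c(msg, "pi0 must be in (0, 1)")
  }
  ok <- vapply(list(c(0.05, 0.15), c(0.25, 0.35), c(0.45, 0.50)),
               function(b) object@maf >= b[1] && object@maf <= b[2],
               logical(1))
  if (!any(ok)) {
    msg <- c(msg,
      "maf must fall in a supported bin: 0.05-0.15, 0.25-0.35, 0.45-0.50")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' @param ... slot values overriding the baseline defaults; see
#'   [SimConfig-class].
#' @return a validated `SimConfig` object.
#' @examples
#' cfg <- simConfig(n = 100, nSites = 50, seed = 1)
#' geneticVarianceCoefficient(cfg)
#' @export
simConfig <- function(...) new("SimConfig", ...)

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: n =", object@n, " h2 =", object@h2,
      " sigma2 =", object@sigma2, " rho =", object@rho, "\n",
      "  maf =", object@maf, " TR =", object@tr, " phi =", object@phi,
      " pi0 =", object@pi0, " pve =", object@pve, "\n",
      "  sites =", object@nSites, " (propTrue =", object@propTrue, ")\n")
})

#' Minor allele frequency bin for a configuration
#'
#' @param cfg a [SimConfig-class] object.
#' @return numeric length-2 vector `(lower, upper)` of the MAF bin the
#'   configured center falls in.
#' @export
mafBin <- function(cfg) {
  bins <- list(c(0.05, 0.15), c(0.25, 0.35), c(0.45, 0.50))
  for (b in bins) if (cfg@maf >= b[1] && cfg@maf <= b[2]) return(b)
  stop("maf outside the supported bins")
}
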