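## The allele-level binomial model and the homozygote collapse.
##
## For each allele l of individual i the methylated count follows
##   y_il ~ Bin(r_il, pi_il),  logit(pi_il) = mu + x_il * beta + g_i + u_i + e_il
## with a polygenic effect g ~ MVN(0, sigma_g2 * K), an individual-level
## environmental effect u_i ~ N(0, sigma_u2) shared by the two alleles, and
## an allele-level residual e_il ~ N(0, sigma_e2). Allele counts are only
## observed in heterozygotes; homozygotes contribute the summed counts.

#' Linear predictor of the allele-level model
#'
#' `lambda = mu + x * beta + g + u + e`; the methylation probability is
#' `plogis(lambda)`.
#'
#' @param mu intercept (logit of the baseline methylation level).
#' @param beta per-allele genotype effect.
#' @param x allele-scale genotype covariate (0/1 on allele rows,
#'   genotype/2 on collapsed rows).
#' @param g,u,e random-effect values (polygenic, individual environment,
#'   allele residual).
#' @return the linear predictor value(s).
#' @export
linearPredictor <- function(mu, beta, x, g = 0, u = 0, e = 0) {
  mu + x * beta + g + u + e
}

#' Exact distribution of the summed count in a homozygote
#'
#' In homozygotes only the totals `y = y1 + y2`, `r = r1 + r2` are observed.
#' Marginalizing the unobserved allele split with `r1 ~ Bin(r, 1/2)` (both
#' alleles equally likely to be sequenced) and independent allele models
#' `y_l ~ Bin(r_l, pi_l)` gives
#' `P(y | r) = sum_{r1} sum_{y1} Bin(y1; r1, pi1) Bin(y - y1; r - r1, pi2)
#' Bin(r1; r, 1/2)`, evaluated here by full enumeration.
#'
#' @param y methylated count (scalar or vector; the full pmf is returned when
#'   `y` is `NULL`).
#' @param r total read count (enumeration guarded at `r <= 10000`; cost is
#'   quadratic in `r`).
#' @param pi1,pi2 allele methylation probabilities.
#' @return probability (vector) `P(y | r, pi1, pi2)`; with `y = NULL`, the
#'   pmf over `0:r`.
#' @examples
#' exactHomozygotePmf(1, 2, 0.5, 0.5)  # reduces to Bin(2, 0.5)
#' @export
exactHomozygotePmf <- function(y = NULL, r, pi1, pi2) {
  if (r < 0 || r != round(r)) stop("r must be a non-negative integer")
  if (r > 10000) stop("r too large for exact enumeration (guard: r <= 10000)")
  full <- numeric(r + 1L)
  ## P(y1 given r1) and P(y - y1 given r - r1): convolution per r1 split
  pr1 <- dbinom(0:r, r, 0.5)
  for (r1 in 0:r) {
    p1 <- dbinom(0:r1, r1, pi1)            # y1 = 0..r1
    p2 <- dbinom(0:(r - r1), r - r1, pi2)  # y2 = 0..r-r1
    conv <- convolve(p1, rev(p2), type = "open")  # pmf of y1+y2 over 0..r
    full <- full + pr1[r1 + 1L] * conv
  }
  full <- pmax(full, 0)
  if (is.null(y)) return(full)
  if (any(y < 0 | y > r)) stop("domain error: need 0 <= y <= r")
  full[y + 1L]
}

#' Collapse a homozygote to a single approximate binomial row
#'
#' The exact summed-count distribution ([exactHomozygotePmf()]) has no
#' analytic form, so homozygotes (and heterozygotes without allele-resolved
#' reads) are represented by one binomial observation. Conditional on the
#' two allele probabilities, `Bin(r, (pi1 + pi2)/2)` matches the exact
#' distribution in both mean and variance (the allele-split
#' `Bin(r, 1/2)` contributes exactly the variance a single binomial with the
#' averaged probability carries). On the linear-predictor scale, averaging
#' two independent allele residuals halves the residual variance, so the
#' collapsed row uses a residual scale of 1/2 on `sigma_e2` - the same
#' `sigma_e2 / 2` that appears in the background-heritability denominator.
#'
#' @param genotype homozygous genotype (0 or 2); heterozygous input is a
#'   contract violation.
#' @param y,r summed methylated / total read counts.
#' @param individual index (or id) of the individual the row belongs to.
#' @return one design row (a one-row `data.frame` with columns `individual`,
#'   `x`, `y`, `r`, `scale`): covariate `x = genotype / 2`, residual scale
#'   1/2.
#' @export
collapseHomozygote <- function(genotype, y, r, individual = 1L) {
  if (is.na(genotype) || genotype == 1) {
    stop("collapseHomozygote requires a homozygous genotype")
  }
  data.frame(individual = individual, x = genotype / 2,
             y = y, r = r, scale = 0.5)
}

#' Build the model design rows for a pair
#'
#' Converts a [PairCounts-class] object into the row layout consumed by
#' [fitPQL()]. Three layouts are supported:
#' \describe{
#'   \item{`joint`}{two allele rows (`x` = 0 for the reference allele, 1 for
#'     the alternate; residual scale 1) for each heterozygote with
#'     allele-resolved reads, plus one collapsed row (`x = genotype/2`,
#'     residual scale 1/2) for every homozygote and for heterozygotes
#'     without allele data.}
#'   \item{`individual`}{one collapsed row per individual (heterozygote
#'     covariate 0.5) - the non-allele-specific binomial mixed model.}
#'   \item{`allele`}{allele rows for heterozygotes only; requires at least
#'     `minHet` heterozygotes with allele data.}
#' }
#' Rows with zero total reads are dropped. When `fittedCovariate` is given
#' (per-individual fitted values from regressing the dosage on covariates,
#' see [residualizeGenotype()]), allele-row covariates become
#' `x - fitted/2` and collapsed-row covariates `(genotype - fitted)/2`, so
#' the within-heterozygote allele contrast of 1 is preserved.
#'
#' @param pc a [PairCounts-class] object.
#' @param method one of `"joint"`, `"individual"`, `"allele"`.
#' @param minHet minimum heterozygote count for the allele-only layout.
#' @param fittedCovariate optional per-individual fitted dosage values
#'   (named by individual id, or in `pc` order).
#' @return `data.frame` with columns `individual` (id), `x`, `y`, `r`,
#'   `scale`, plus attribute `note` flagging collapsed heterozygotes.
#' @export
buildDesign <- function(pc, method = c("joint", "individual", "allele"),
                        minHet = 5L, fittedCovariate = NULL) {
  method <- match.arg(method)
  pc <- dropUninformative(pc)
  n <- length(pc@ids)
  g <- pc@genotype
  fit <- rep(0, n)
  if (!is.null(fittedCovariate)) {
    fit <- if (!is.null(names(fittedCovariate))) {
      unname(fittedCovariate[pc@ids])
    } else fittedCovariate
    if (length(fit) != n || anyNA(fit)) {
      stop("fittedCovariate must cover every informative individual")
    }
  }
  hasAll <- hasAlleleData(pc)
  note <- ""
  useAllele <- if (method == "individual") rep(FALSE, n) else g == 1 & hasAll
  ia <- which(useAllele)
  ic <- if (method == "allele") integer() else which(!useAllele)
  if (method == "joint" && any(g[ic] == 1)) {
    note <- "het_without_allele_data_collapsed"
  }
  out <- data.frame(
    individual = c(rep(pc@ids[ia], each = 2L), pc@ids[ic]),
    x = c(rep(c(0, 1), length(ia)) - rep(fit[ia], each = 2L) / 2,
          (g[ic] - fit[ic]) / 2),
    y = c(as.vector(t(pc@yAllele[ia, , drop = FALSE])), pc@yTotal[ic]),
    r = c(as.vector(t(pc@rAllele[ia, , drop = FALSE])), pc@rTotal[ic]),
    scale = c(rep(1, 2L * length(ia)), rep(0.5, length(ic))))
  if (method == "allele" && length(ia) < minHet) {
    stop(sprintf(
      "insufficient heterozygotes: %d with allele data (need >= %d)",
      length(ia), minHet))
  }
  out <- out[out$r > 0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "note") <- note
  out
}
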