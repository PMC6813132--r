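## Simulation engine for power and calibration studies.
##
## Per SNP-CpG pair, allele-level latent methylation follows
##   logit(pi_il) = logit(pi0) + x_il * beta + g_i + u_i + e_il,
## with g ~ MVN(0, c(h2, rho, sigma2) * K), and per individual the pair
## (u_i + e_i1, u_i + e_i2) drawn from a bivariate normal with diagonal
## (1 - pve - h2) * sigma2 and off-diagonal rho * (1 - pve - h2) * sigma2.
## Total reads are negative binomial with mean TR and dispersion phi, split
## between the two alleles with a Beta(a, b)-distributed proportion.
## Heterozygotes keep allele-level counts; homozygotes are collapsed to the
## summed counts.

#' Simulate synthetic genotypes and their relatedness matrix
#'
#' Genotypes are drawn per SNP as `Binomial(2, f)` with `f` uniform in the
#' configured MAF bin (unrelated individuals). The genetic relatedness
#' matrix is the centered GRM of the dosages, standardized so the mean
#' diagonal equals one.
#'
#' @param n number of individuals.
#' @param p number of SNPs (at least 100).
#' @param maf MAF bin center (bins 0.05-0.15, 0.25-0.35, 0.45-0.50).
#' @return list with `dosage` (n-by-p matrix, rownames `ind1..indn`) and
#'   `K` (standardized GRM).
#' @export
simulateGenotypes <- function(n, p, maf = 0.3) {
  if (p < 100L) stop("need p >= 100 SNPs for a stable relatedness matrix")
  bin <- mafBin(simConfig(maf = maf))
  f <- runif(p, bin[1], bin[2])
  dosage <- vapply(f, function(fr) rbinom(n, 2L, fr), numeric(n))
  rownames(dosage) <- paste0("ind", seq_len(n))
  list(dosage = dosage, K = grmFromDosage(dosage))
}

#' Simulate total read counts and their allele split
#'
#' `r_i ~ NB(mean = TR, dispersion = phi)` (variance `TR + TR^2/phi`);
#' the proportion of reads on the first allele is `q_i ~ Beta(a, b)`
#' (default `Beta(10, 10)`, symmetric around 0.5 with 93.6% of its mass in
#' (0.3, 0.7)); `r_i1 ~ Bin(r_i, q_i)` and `r_i2 = r_i - r_i1`.
#'
#' @param cfg a [SimConfig-class] object (uses `tr`, `phi`, `betaShape1`,
#'   `betaShape2`).
#' @param n number of individuals (default `cfg@n`).
#' @return list with vectors `r`, `r1`, `r2`, `q`.
#' @export
simulateReads <- function(cfg, n = cfg@n) {
  r <- rnbinom(n, size = cfg@phi, mu = cfg@tr)
  q <- rbeta(n, cfg@betaShape1, cfg@betaShape2)
  r1 <- rbinom(n, r, q)
  list(r = r, r1 = r1, r2 = r - r1, q = q)
}

#' Genetic-variance coefficient of the simulation
#'
#' The polygenic effect is drawn with covariance `c * K` where
#' `c = (1 + rho) * h2 * sigma2 / (2 + (rho - 1) * h2)`, calibrated so the
#' background heritability of the simulated latent variable is `h2`.
#'
#' @param cfg a [SimConfig-class] object.
#' @return the scalar coefficient `c`.
#' @examples
#' geneticVarianceCoefficient(simConfig())  # 0.3/1.7 * 0.7
#' @export
geneticVarianceCoefficient <- function(cfg) {
  (1 + cfg@rho) * cfg@h2 * cfg@sigma2 / (2 + (cfg@rho - 1) * cfg@h2)
}

#' Simulate per-individual environmental effects
#'
#' Draws, for each individual, the summed environment-plus-residual values
#' of the two alleles `(u_i + e_i1, u_i + e_i2)` from a bivariate normal
#' with variance `(1 - pve - h2) * sigma2` per component and correlation
#' `rho`. For null sites (no SNP effect) call with `pve = 0` so the total
#' latent variance stays consistent.
#'
#' @param cfg a [SimConfig-class] object.
#' @param n number of individuals.
#' @param pve variance share of the focal SNP to subtract (default
#'   `cfg@pve`).
#' @return n-by-2 matrix, one row per individual.
#' @export
simulateEnvEffects <- function(cfg, n = cfg@n, pve = cfg@pve) {
  v <- (1 - pve - cfg@h2) * cfg@sigma2
  if (v < 0) stop("need pve + h2 < 1")
  ## bivariate normal via shared + independent parts
  shared <- rnorm(n, 0, sqrt(cfg@rho * v))
  indep1 <- rnorm(n, 0, sqrt((1 - cfg@rho) * v))
  indep2 <- rnorm(n, 0, sqrt((1 - cfg@rho) * v))
  cbind(shared + indep1, shared + indep2)
}

#' Effect-size variance from the target PVE
#'
#' `sigma_b2 = PVE * sigma2 / ((1 - PVE) * V(x))` with `V` the sample
#' variance of the genotype dosage vector; per-site effects are drawn as
#' `beta ~ N(0, sigma_b2)` so that the focal SNP explains the configured
#' proportion of latent variance on average.
#'
#' @param cfg a [SimConfig-class] object.
#' @param x genotype dosage vector.
#' @param pve optional override of `cfg@pve`.
#' @return the scalar `sigma_b2`.
#' @export
sigmaBFromPve <- function(cfg, x, pve = cfg@pve) {
  vx <- var(x)
  if (is.na(vx) || vx <= 0) stop("monomorphic genotype: V(x) must be > 0")
  pve * cfg@sigma2 / ((1 - pve) * vx)
}

#' Simulate one SNP-CpG pair
#'
#' Draws the polygenic effects, environmental effects, effect size (0 for
#' null sites), read depths and allele-level methylated counts, then
#' packages the result as a [PairCounts-class] object: heterozygotes keep
#' their allele-resolved counts, homozygotes are collapsed, and individuals
#' with zero total reads are dropped. For heterozygotes the alternate
#' allele is assigned to either read pool with equal probability.
#'
#' @param cfg a [SimConfig-class] object.
#' @param x genotype dosage vector (length `cfg@n`).
#' @param K standardized relatedness matrix (rownames = individual ids), or
#'   `NULL` for independent individuals.
#' @param isMqtl logical; simulate a true SNP effect?
#' @param pairId identifier for the resulting pair.
#' @param g optional pre-drawn polygenic effects (length `n`), e.g. to
#'   share one draw across sites.
#' @return a `PairCounts` object with attributes `truth` (list: `isMqtl`,
#'   `beta`) and `latent` (list of the latent components `g`, `ue`,
#'   `xAllele`, `lambda` for diagnostics, full length `n`).
#' @export
simulateSite <- function(cfg, x, K = NULL, isMqtl = FALSE, pairId = "pair1",
                         g = NULL) {
  n <- length(x)
  ids <- if (!is.null(K)) rownames(K) else paste0("ind", seq_len(n))
  if (is.null(g)) {
    cc <- geneticVarianceCoefficient(cfg)
    if (cc == 0) {
      g <- numeric(n)
    } else if (is.null(K)) {
      g <- rnorm(n, 0, sqrt(cc))
    } else {
      ch <- chol(makeKinshipPSD(K) + diag(1e-10, n))
      g <- drop(crossprod(ch, rnorm(n))) * sqrt(cc)
    }
  }
  beta <- 0
  pve <- 0
  if (isMqtl) {
    beta <- rnorm(1, 0, sqrt(sigmaBFromPve(cfg, x)))
    pve <- cfg@pve
  }
  ue <- simulateEnvEffects(cfg, n, pve = pve)
  ## allele genotype codes: hom ref (0,0), hom alt (1,1); hets get the alt
  ## allele on a random side
  xa <- cbind(as.numeric(x >= 1), as.numeric(x == 2))
  het <- which(x == 1)
  flip <- het[runif(length(het)) < 0.5]
  xa[flip, ] <- xa[flip, c(2, 1), drop = FALSE]
  reads <- simulateReads(cfg, n)
  lam <- qlogis(cfg@pi0) + beta * xa + g + ue
  y1 <- rbinom(n, reads$r1, plogis(lam[, 1]))
  y2 <- rbinom(n, reads$r2, plogis(lam[, 2]))

  yA <- matrix(NA_real_, n, 2); rA <- matrix(NA_real_, n, 2)
  if (length(het)) {
    ## column 1 = reference allele, column 2 = alternate
    refFirst <- xa[het, 1] == 0
    yA[het, 1] <- ifelse(refFirst, y1[het], y2[het])
    yA[het, 2] <- ifelse(refFirst, y2[het], y1[het])
    rA[het, 1] <- ifelse(refFirst, reads$r1[het], reads$r2[het])
    rA[het, 2] <- ifelse(refFirst, reads$r2[het], reads$r1[het])
  }
  pc <- PairCounts(pairId, ids = ids, genotype = x,
                   yTotal = y1 + y2, rTotal = reads$r,
                   yAllele = yA, rAllele = rA)
  pc <- dropUninformative(pc)
  attr(pc, "truth") <- list(isMqtl = isMqtl, beta = beta)
  attr(pc, "latent") <- list(g = g, ue = ue, xAllele = xa, lambda = lam)
  pc
}

#' Simulate a full study of SNP-CpG pairs
#'
#' Generates a genotype panel and its relatedness matrix once, then one
#' fresh genotype column per site from the configured MAF bin, and
#' simulates `cfg@nSites` pairs of which a `cfg@propTrue` fraction carry a
#' true SNP effect. Reproducible when `cfg@seed` is set.
#'
#' @param cfg a [SimConfig-class] object.
#' @param keepLatent keep per-site latent diagnostics (memory-heavy for
#'   large studies)?
#' @return list with `pairs` (list of [PairCounts-class]), `truth`
#'   (`data.frame`: `pair_id`, `is_mqtl`, `beta_true`), `K`, and `cfg`.
#' @export
simulateStudy <- function(cfg, keepLatent = FALSE) {
  if (!is.na(cfg@seed)) set.seed(cfg@seed)
  geno <- simulateGenotypes(cfg@n, cfg@nSnps, cfg@maf)
  K <- geno$K
  bin <- mafBin(cfg)
  nTrue <- round(cfg@nSites * cfg@propTrue)
  isMqtl <- seq_len(cfg@nSites) <= nTrue
  cc <- geneticVarianceCoefficient(cfg)
  chK <- if (cc > 0) chol(makeKinshipPSD(K) + diag(1e-10, cfg@n)) else NULL
  pairs <- vector("list", cfg@nSites)
  for (s in seq_len(cfg@nSites)) {
    repeat {
      f <- runif(1, bin[1], bin[2])
      x <- rbinom(cfg@n, 2L, f)
      if (var(x) > 0) break
    }
    g <- if (cc > 0) drop(crossprod(chK, rnorm(cfg@n))) * sqrt(cc)
         else numeric(cfg@n)
    pc <- simulateSite(cfg, x, K, isMqtl = isMqtl[s],
                       pairId = sprintf("pair%05d", s), g = g)
    if (!keepLatent) attr(pc, "latent") <- NULL
    pairs[[s]] <- pc
  }
  truth <- data.frame(
    pair_id = vapply(pairs, pairId, character(1)),
    is_mqtl = isMqtl,
    beta_true = vapply(pairs, function(p) attr(p, "truth")$beta, numeric(1)))
  list(pairs = pairs, truth = truth, K = K, cfg = cfg)
}
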