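# Shared fixture builders (all fixtures are generated in code).

# A small deterministic pair: genotypes 0/1/2, one het with allele data.
makeTinyPair <- function() {
  PairCounts("tiny", genotype = c(0, 1, 2),
             yTotal = c(2, 5, 9), rTotal = c(10, 10, 10),
             yAllele = rbind(c(NA, NA), c(2, 3), c(NA, NA)),
             rAllele = rbind(c(NA, NA), c(6, 4), c(NA, NA)))
}

# Pure binomial pair (no over-dispersion): y ~ Bin(r, plogis(mu + x*beta))
# with allele-level draws for heterozygotes.
makeBinomialPair <- function(n = 80, mu = 0, beta = 1, f = 0.4,
                             depth = 30) {
  g <- rbinom(n, 2, f)
  while (var(g) == 0) g <- rbinom(n, 2, f)
  r1 <- rbinom(n, depth, 0.5)
  r2 <- depth - r1
  x1 <- as.numeric(g >= 1)  # alt on side 1 for het and hom-alt
  x2 <- as.numeric(g == 2)
  y1 <- rbinom(n, r1, plogis(mu + beta * x1))
  y2 <- rbinom(n, r2, plogis(mu + beta * x2))
  het <- g == 1
  yA <- matrix(NA_real_, n, 2); rA <- matrix(NA_real_, n, 2)
  # column 1 = reference allele (x = 0) = side 2 for hets as coded above
  yA[het, ] <- cbind(y2[het], y1[het])
  rA[het, ] <- cbind(r2[het], r1[het])
  PairCounts("binom", genotype = g, yTotal = y1 + y2,
             rTotal = r1 + r2, yAllele = yA, rAllele = rA)
}

# Brute-force triple-loop oracle for the summed-count distribution of a
# homozygote (independent of the package implementation).
bruteHomozygotePmf <- function(y, r, pi1, pi2) {
  total <- 0
  for (r1 in 0:r) {
    for (y1 in 0:r1) {
      y2 <- y - y1
      if (y2 < 0 || y2 > r - r1) next
      total <- total + dbinom(r1, r, 0.5) * dbinom(y1, r1, pi1) *
        dbinom(y2, r - r1, pi2)
    }
  }
  total
}
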