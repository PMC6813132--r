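test_that("linear predictor is the additive logit-scale sum", {
  expect_equal(linearPredictor(0, 0, x = 1), 0)
  expect_equal(plogis(linearPredictor(0, 0, x = 1)), 0.5)
  expect_equal(linearPredictor(qlogis(0.5), 1, x = 1), 1)
  expect_equal(plogis(linearPredictor(0, 1, x = 1)), 0.7310586,
               tolerance = 1e-6)
  expect_equal(linearPredictor(-2, 1, x = 0.5, g = 0.3, u = -0.1, e = 0.2),
               -1.1)
})

test_that("exact homozygote pmf matches brute-force enumeration and MC", {
  # frozen value from the triple-loop oracle (helper-fixtures.R)
  expect_equal(exactHomozygotePmf(2, 3, 0.2, 0.8),
               bruteHomozygotePmf(2, 3, 0.2, 0.8), tolerance = 1e-12)
  for (y in 0:5) {
    expect_equal(exactHomozygotePmf(y, 5, 0.3, 0.9),
                 bruteHomozygotePmf(y, 5, 0.3, 0.9), tolerance = 1e-12)
  }
  # allele-choice symmetry: one read, one fully methylated allele
  expect_equal(exactHomozygotePmf(1, 1, 1, 0), 0.5)
  # Monte-Carlo cross-check of the (y=2, r=3) case, 1e6 draws
  set.seed(11)
  nmc <- 1e6
  r1 <- rbinom(nmc, 3, 0.5)
  ymc <- rbinom(nmc, r1, 0.2) + rbinom(nmc, 3 - r1, 0.8)
  expect_equal(exactHomozygotePmf(2, 3, 0.2, 0.8), mean(ymc == 2),
               tolerance = 5e-3)
  expect_error(exactHomozygotePmf(4, 3, 0.5, 0.5), "domain")
})

test_that("exact pmf normalizes, collapses at equal probabilities, and has
           the linear mean", {
  for (r in c(1, 5, 17, 30)) {
    for (p in list(c(0.5, 0.5), c(0.1, 0.9), c(0.33, 0.71))) {
      pmf <- exactHomozygotePmf(NULL, r, p[1], p[2])
      expect_equal(sum(pmf), 1, tolerance = 1e-10)
      expect_equal(sum((0:r) * pmf), r * (p[1] + p[2]) / 2,
                   tolerance = 1e-10)
    }
    # analytic collapse: pi1 == pi2 reduces to a plain binomial
    pmf <- exactHomozygotePmf(NULL, r, 0.37, 0.37)
    expect_equal(pmf, dbinom(0:r, r, 0.37), tolerance = 1e-12)
  }
})

test_that("averaged-probability binomial matches the exact summed-count
           moments", {
  # conditional on the two allele probabilities, Bin(r, (pi1+pi2)/2)
  # reproduces the mean and variance of the exact distribution
  for (r in c(5, 20, 50)) {
    for (p in list(c(0.1, 0.5), c(0.5, 0.9), c(0.2, 0.8))) {
      pmf <- exactHomozygotePmf(NULL, r, p[1], p[2])
      pbar <- mean(p)
      m1 <- sum((0:r) * pmf)
      v1 <- sum((0:r)^2 * pmf) - m1^2
      expect_equal(m1, r * pbar, tolerance = 1e-9)
      expect_equal(v1, r * pbar * (1 - pbar), tolerance = 1e-8)
    }
  }
})

test_that("collapsed homozygote row carries the halved residual scale", {
  row <- collapseHomozygote(2, y = 7, r = 10, individual = 3L)
  expect_equal(row$x, 1)
  expect_equal(row$scale, 0.5)
  expect_equal(collapseHomozygote(0, 2, 10)$x, 0)
  expect_error(collapseHomozygote(1, 5, 10), "homozygous")
})

test_that("collapsed-row marginal agrees with the exact allele-level model", {
  # Exact model: e1, e2 ~ N(0, sigma_e2), reads split Bin(r, 1/2).
  # Collapsed observation: Bin(r, pbar) with pbar the averaged allele
  # probability (the averaged residual carries variance sigma_e2 / 2 on
  # the logit scale, the collapsed row's residual scale). sigma_e2 = 0
  # forces exact agreement; otherwise mean exact and variance within 5%
  # of the Monte-Carlo variance of the exact allele-level model.
  nmc <- 1e6
  for (case in list(list(r = 20, pi0 = 0.5, se2 = 0.7),
                    list(r = 50, pi0 = 0.1, se2 = 0.7),
                    list(r = 35, pi0 = 0.9, se2 = 1.0))) {
    eta <- qlogis(case$pi0); r <- case$r
    set.seed(101)
    e1 <- rnorm(nmc, 0, sqrt(case$se2))
    e2 <- rnorm(nmc, 0, sqrt(case$se2))
    r1 <- rbinom(nmc, r, 0.5)
    yEx <- rbinom(nmc, r1, plogis(eta + e1)) +
      rbinom(nmc, r - r1, plogis(eta + e2))
    yAp <- rbinom(nmc, r, (plogis(eta + e1) + plogis(eta + e2)) / 2)
    expect_equal(mean(yAp), mean(yEx), tolerance = 0.005)
    expect_equal(var(yAp), var(yEx), tolerance = 0.05)
  }
  # no allele-level noise: collapsed model is exactly binomial
  pmf0 <- exactHomozygotePmf(NULL, 12, 0.42, 0.42)
  expect_equal(pmf0, dbinom(0:12, 12, 0.42), tolerance = 1e-12)
})

test_that("design construction follows the layout counting rules", {
  pc <- makeTinyPair()
  joint <- buildDesign(pc, "joint")
  expect_equal(nrow(joint), 4L)          # 1 + 2 + 1 rows
  expect_equal(sort(joint$scale), c(0.5, 0.5, 1, 1))
  indiv <- buildDesign(pc, "individual")
  expect_equal(nrow(indiv), 3L)
  expect_equal(sort(indiv$x), c(0, 0.5, 1))
  # allele rows: het contributes exactly one x = 1 row
  expect_equal(sum(joint$x == 1 & joint$scale == 1), 1L)

  # four heterozygotes are not enough for the allele-only layout
  g <- c(1, 1, 1, 1, 0, 0)
  yA <- matrix(NA_real_, 6, 2); rA <- matrix(NA_real_, 6, 2)
  yA[1:4, ] <- 2; rA[1:4, ] <- 5
  pc4 <- PairCounts("hets4", genotype = g, yTotal = c(rep(4, 4), 3, 3),
                    rTotal = c(rep(10, 4), 8, 8), yAllele = yA,
                    rAllele = rA)
  expect_error(buildDesign(pc4, "allele"), "insufficient heterozygotes")
})

test_that("zero-depth rows and individuals are dropped before fitting", {
  pc <- PairCounts("z", genotype = c(0, 1, 2, 2),
                   yTotal = c(2, 5, 0, 4), rTotal = c(10, 10, 0, 9))
  expect_equal(length(dropUninformative(pc)), 3L)
  d <- buildDesign(pc, "individual")
  expect_equal(nrow(d), 3L)
})

test_that("PairCounts validity enforces the count invariants", {
  expect_error(PairCounts("bad", genotype = c(0, 1), yTotal = c(5, 2),
                          rTotal = c(4, 10)), "yTotal")
  yA <- rbind(c(NA, NA), c(2, 2)); rA <- rbind(c(NA, NA), c(5, 4))
  expect_error(PairCounts("bad2", genotype = c(0, 1), yTotal = c(1, 5),
                          rTotal = c(4, 9), yAllele = yA, rAllele = rA),
               "sum")
  expect_error(PairCounts("bad3", genotype = c(0, 3), yTotal = c(1, 1),
                          rTotal = c(4, 4)), "genotype")
})
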