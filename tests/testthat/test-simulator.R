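test_that("genetic-variance coefficient follows the printed formula", {
  expect_equal(geneticVarianceCoefficient(simConfig(h2 = 0)), 0)
  expect_equal(geneticVarianceCoefficient(simConfig()),
               0.3 / 1.7 * 0.7, tolerance = 1e-12)
  # frozen direct evaluation: (1+0.9)*0.6*0.7 / (2 + (0.9-1)*0.6)
  expect_equal(geneticVarianceCoefficient(simConfig(h2 = 0.6, rho = 0.9)),
               0.798 / 1.94, tolerance = 1e-12)
})

test_that("effect-size variance follows the PVE relation", {
  cfg <- simConfig()
  x <- c(rep(0, 5), rep(1, 5), rep(2, 5))
  expect_equal(sigmaBFromPve(cfg, x, pve = 0), 0)
  v <- var(x)
  expect_equal(sigmaBFromPve(cfg, x), 0.1 * 0.7 / (0.9 * v))
  # doubling V(x) halves sigma_b2
  x2 <- x * sqrt(2)
  expect_equal(sigmaBFromPve(cfg, x2), sigmaBFromPve(cfg, x) / 2,
               tolerance = 1e-12)
  # spot value from the formula at V(x) = 0.5
  xh <- c(0, 1) # var 0.5
  expect_equal(sigmaBFromPve(cfg, xh), 0.07 / (0.9 * 0.5))
  expect_error(sigmaBFromPve(cfg, rep(1, 10)), "monomorphic")
})

test_that("allele-split distribution has the documented shape", {
  # Beta(10,10) mass on (0.3, 0.7): analytic incomplete beta
  expect_equal(pbeta(0.7, 10, 10) - pbeta(0.3, 10, 10), 0.936,
               tolerance = 2e-3)
  set.seed(41)
  cfg <- simConfig()
  rd <- simulateReads(cfg, n = 1e5)
  expect_equal(mean(rd$r), 20, tolerance = 0.01)
  expect_equal(var(rd$r), 20 + 400 / 3, tolerance = 0.05)
  expect_equal(mean(rd$q), 0.5, tolerance = 5e-3)
  expect_true(all(rd$r1 + rd$r2 == rd$r))
})

test_that("genotype simulation hits the MAF bin and het fraction", {
  set.seed(42)
  geno <- simulateGenotypes(150, 2000, maf = 0.3)
  f <- colMeans(geno$dosage) / 2
  maf <- pmin(f, 1 - f)
  # per-SNP sample MAF stays near the bin (binomial sampling error)
  expect_gt(mean(maf >= 0.20 & maf <= 0.40), 0.99)
  # expected heterozygote fraction at MAF 0.3 is 2*0.3*0.7 = 42%
  hetFrac <- mean(geno$dosage == 1)
  expect_equal(hetFrac, 0.42, tolerance = 0.02)
  expect_equal(mean(diag(geno$K)), 1, tolerance = 1e-12)
  expect_error(simulateGenotypes(50, 1000, maf = 0.2), "bin")
  expect_error(simulateGenotypes(50, 50), "p >= 100")
})

test_that("environmental effects have the configured covariance", {
  set.seed(43)
  cfg <- simConfig()
  ue <- simulateEnvEffects(cfg, n = 1e5)
  expect_equal(var(ue[, 1]), (1 - 0.1 - 0.3) * 0.7, tolerance = 0.02)
  expect_lt(abs(cor(ue[, 1], ue[, 2])), 0.02)          # rho = 0
  cfgR <- simConfig(rho = 1)
  ueR <- simulateEnvEffects(cfgR, n = 1000)
  expect_equal(ueR[, 1], ueR[, 2], tolerance = 1e-12)  # rho = 1
  cfg9 <- simConfig(rho = 0.9)
  ue9 <- simulateEnvEffects(cfg9, n = 1e5)
  expect_equal(cor(ue9[, 1], ue9[, 2]), 0.9, tolerance = 0.01)
})

test_that("simulated sites satisfy the count identities and allele coding", {
  set.seed(44)
  cfg <- simConfig(n = 80, nSnps = 200)
  x <- rbinom(80, 2, 0.3)
  pc <- simulateSite(cfg, x, K = NULL, isMqtl = TRUE)
  expect_true(validObject(pc))
  hasAll <- hasAlleleData(pc)
  expect_true(all(pc@genotype[hasAll] == 1))
  d <- buildDesign(pc, "joint")
  # every het with allele data contributes exactly one x = 1 allele row
  alleleRows <- d[d$scale == 1, ]
  byInd <- tapply(alleleRows$x, alleleRows$individual, sum)
  expect_true(all(byInd %in% c(0, 1)))  # one alt row unless depth dropped one
  # pure-binomial limit: mean ratio near pi0
  cfg0 <- simConfig(h2 = 0, pve = 0, sigma2 = 1e-8, propTrue = 0)
  pc0 <- simulateSite(cfg0, rbinom(100, 2, 0.3), isMqtl = FALSE)
  expect_equal(sum(pc0@yTotal) / sum(pc0@rTotal), 0.5, tolerance = 0.03)
})

test_that("study simulation is reproducible and respects the truth split", {
  cfg <- simConfig(n = 40, nSites = 30, seed = 99, nSnps = 150)
  s1 <- simulateStudy(cfg)
  s2 <- simulateStudy(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$pairs[[7]]@yTotal, s2$pairs[[7]]@yTotal)
  expect_equal(sum(s1$truth$is_mqtl), 3)
  expect_true(all(s1$truth$beta_true[!s1$truth$is_mqtl] == 0))
  cfg0 <- simConfig(n = 40, nSites = 10, seed = 1, propTrue = 0,
                    nSnps = 150)
  s0 <- simulateStudy(cfg0)
  expect_true(all(s0$truth$beta_true == 0))
})

test_that("latent variance decomposition matches the target background
           heritability", {
  # Background heritability of the latent variable: share of var(g) in
  # var(g) + var(u) + var(e)/2 + var(x * beta) (dosage scale), averaged
  # over sites. Validates the genetic-variance coefficient end-to-end.
  set.seed(46)
  for (pars in list(c(h2 = 0.3, rho = 0), c(h2 = 0.6, rho = 0),
                    c(h2 = 0.3, rho = 0.9))) {
    cfg <- simConfig(n = 200, h2 = pars["h2"], rho = pars["rho"],
                     nSnps = 200)
    num <- den <- 0
    for (s in 1:300) {
      x <- rbinom(cfg@n, 2, 0.3)
      if (var(x) == 0) next
      pc <- simulateSite(cfg, x, K = NULL, isMqtl = TRUE)
      lat <- attr(pc, "latent")
      vg <- var(lat$g)
      ue <- lat$ue
      vu <- cfg@rho * (1 - cfg@pve - cfg@h2) * cfg@sigma2
      ve <- var(c(ue[, 1], ue[, 2])) - vu
      bt <- attr(pc, "truth")$beta
      num <- num + vg
      den <- den + vg + vu + ve / 2 + bt^2 * var(x)
    }
    expect_lt(abs(num / den - unname(pars["h2"])), 0.03)
  }
})
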