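test_that("empirical FDR reproduces the hand-enumerated micro-example", {
  # p_obs = (0.001, 0.2); one permutation p = (0.05, 0.5)
  tab <- empiricalFdr(c(0.001, 0.2), rbind(c(0.05, 0.5)), alpha = 0.05,
                      thresholds = c(0.01, 0.2))
  expect_equal(tab$fdr_hat[tab$threshold == 0.01], 0)    # 0 permuted / 1 obs
  expect_equal(tab$n_observed, c(1, 2))
  expect_equal(tab$mean_n_permuted, c(0, 1))
  expect_equal(tab$fdr_hat[2], 0.5)
  expect_equal(sum(attr(tab, "discoveries")), 1L)
})

test_that("empirical FDR behaves at the extremes", {
  set.seed(51)
  # observed values far below every permuted value: fdr 0, all discovered
  tab <- empiricalFdr(runif(50, 0, 1e-4), matrix(runif(500, 0.5, 1), 10),
                      alpha = 0.05)
  expect_true(all(tab$fdr_hat == 0))
  expect_true(all(attr(tab, "discoveries")))
  # observed exchangeable with permuted: fdr near 1 everywhere
  pObs <- runif(2000)
  pPerm <- matrix(runif(2000 * 10), nrow = 10)
  tab2 <- empiricalFdr(pObs, pPerm)
  mid <- tab2$threshold > 0.05 & tab2$threshold < 0.95
  expect_gt(min(tab2$fdr_hat[mid]), 0.85)
  # monotone non-decreasing in the threshold
  expect_true(all(diff(tab2$fdr_hat) >= 0))
  # invariant to reordering pairs and permutations
  o <- sample(length(pObs))
  tab3 <- empiricalFdr(pObs[o], pPerm[sample(10), o])
  expect_equal(tab3$fdr_hat, tab2$fdr_hat)
})

test_that("known-truth power behaves at the extremes and is monotone in
           alpha", {
  # perfect separation: power 1 at any alpha
  p <- c(rep(1e-6, 10), runif(90, 0.2, 1))
  truth <- c(rep(TRUE, 10), rep(FALSE, 90))
  expect_equal(powerAtFdr(p, truth, 0.01), 1)
  # uniform p for everything: essentially nothing is recoverable
  set.seed(52)
  p2 <- runif(1000)
  truth2 <- c(rep(TRUE, 100), rep(FALSE, 900))
  expect_lt(powerAtFdr(p2, truth2, 0.05), 0.1)
  # monotone in alpha
  set.seed(53)
  p3 <- c(rbeta(100, 0.2, 1), runif(900))
  truth3 <- c(rep(TRUE, 100), rep(FALSE, 900))
  alphas <- c(0.01, 0.05, 0.1, 0.2)
  pw <- vapply(alphas, function(a) powerAtFdr(p3, truth3, a), numeric(1))
  expect_true(all(diff(pw) >= 0))
  expect_error(powerAtFdr(runif(10), rep(FALSE, 10)), "no true sites")
})

test_that("label permutation preserves the covariate multiset", {
  set.seed(54)
  pc <- makeBinomialPair(n = 40, mu = 0, beta = 1)
  des <- buildDesign(pc, "joint")
  perms <- permuteLabels(pc, B = 5)
  expect_length(perms, 5L)
  for (d in perms) {
    expect_equal(sort(d$x), sort(des$x))
    expect_equal(d$y, des$y)   # counts untouched
    expect_equal(d$r, des$r)
    # permuted designs are fittable
  }
  f <- fitPQL(perms[[1]], K = NULL)
  expect_true(is.finite(f$pvalue))
})

test_that("count permutation conserves totals and redraws allele splits", {
  set.seed(55)
  pc <- makeBinomialPair(n = 60, mu = 0.4, beta = 0.8)
  perms <- permuteCountsAlt(pc, B = 4)
  for (pp in perms) {
    expect_true(validObject(pp))
    expect_equal(sort(pp@yTotal), sort(pc@yTotal))
    expect_equal(sort(pp@rTotal), sort(pc@rTotal))
    expect_equal(pp@genotype, pc@genotype)  # genotypes stay in place
    hasAll <- hasAlleleData(pp)
    expect_equal(rowSums(pp@yAllele[hasAll, , drop = FALSE]),
                 pp@yTotal[hasAll])
    expect_equal(rowSums(pp@rAllele[hasAll, , drop = FALSE]),
                 pp@rTotal[hasAll])
  }
})

test_that("permuted null p-values are exchangeable with observed ones
           under the global null", {
  set.seed(56)
  cfg <- simConfig(n = 60, nSites = 60, propTrue = 0, nSnps = 200,
                   seed = 56)
  st <- simulateStudy(cfg)
  pObs <- pPerm <- numeric(length(st$pairs))
  for (i in seq_along(st$pairs)) {
    pObs[i] <- fitPair(st$pairs[[i]], st$K, "joint")$pvalue
    d <- permuteLabels(st$pairs[[i]], B = 1)[[1]]
    pPerm[i] <- fitPQL(d, st$K)$pvalue
  }
  ks <- suppressWarnings(stats::ks.test(pObs, pPerm))
  expect_gt(ks$p.value, 0.01)
})
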