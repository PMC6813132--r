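---
title: "ASM-assisted mQTL mapping with binomial mixed models"
author: "asmQTL package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ASM-assisted mQTL mapping with binomial mixed models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmQTL)
```

## The problem

In bisulfite-sequencing studies (RRBS or WGBS), methylation at a CpG site
is observed as a pair of counts per individual: the number of methylated
reads $y_i$ out of $r_i$ total reads. Methylation quantitative trait locus
(mQTL) mapping asks whether a nearby SNP genotype is associated with the
methylation level. When the SNP and the CpG are covered by the same reads
(or phasing is available), heterozygous individuals additionally yield
*allele-specific* counts $(y_{il}, r_{il})$, $l = 1, 2$ — and a cis-acting
variant should produce both a genotype effect across individuals and an
allele effect within heterozygotes. Using the two sources jointly is the
point of this package.

## The model

For allele $l$ of individual $i$,

$$y_{il} \sim \mathrm{Bin}(r_{il}, \pi_{il}), \qquad
\mathrm{logit}(\pi_{il}) = \mu + x_{il}\beta + g_i + u_i + e_{il},$$

where $x_{il} \in \{0, 1\}$ codes the allele (reference/alternate),
$\beta$ is the per-allele genotype effect shared by the allele-specific
and individual-level channels (the equal-effect-size assumption that
holds for cis effects), $g \sim \mathrm{MVN}(0, \sigma_g^2 K)$ is a
polygenic effect with known relatedness matrix $K$,
$u_i \sim N(0, \sigma_u^2)$ is an individual-level environmental effect
shared by the two alleles, and $e_{il} \sim N(0, \sigma_e^2)$ is an
allele-level residual. The three random effects model over-dispersion and
sample non-independence. $K$ is standardized so that
$\mathrm{tr}(K)/n = 1$, under which

$$h^2 = \frac{\sigma_g^2}{\sigma_g^2 + \sigma_u^2 + \tfrac12\sigma_e^2}$$

is interpretable as the approximate background heritability of the latent
logit-methylation (the $\tfrac12$ arises because an individual-level
average of two allele residuals carries variance $\sigma_e^2/2$).

### Collapsing homozygotes

Allele counts are unobservable in homozygotes; only the sums
$(y_i, r_i)$ are seen. The exact distribution of $y_i$ marginalizes the
read split, assumed $r_{i1} \sim \mathrm{Bin}(r_i, 1/2)$ (both alleles
equally likely to be sequenced), and is implemented by full enumeration
in `exactHomozygotePmf()`. It has no analytic form, so fitting uses an
approximation: a single binomial observation with the *averaged* allele
probability, $y_i \sim \mathrm{Bin}(r_i, (\pi_{i1}+\pi_{i2})/2)$. A short
calculation shows this matches the exact compound distribution in both
mean and variance, *exactly*, conditional on $(\pi_{i1}, \pi_{i2})$:
the binomial read split contributes precisely the extra variance that
the averaged probability absorbs. On the linear-predictor scale the
averaged residual $(e_{i1}+e_{i2})/2$ has variance $\sigma_e^2/2$, which
is why collapsed design rows carry a residual scale of $1/2$ — and why
$\tfrac12\sigma_e^2$ appears in the $h^2$ denominator. A fully
independent logit-scale residual with variance $\sigma_e^2/2$ is *not*
equivalent: Monte-Carlo checks show its marginal count variance deviates
by ~10% at extreme methylation levels, so the averaged-probability
construction is the one documented and tested.

### Estimators

`buildDesign()` produces three layouts consumed by `fitPQL()`:

* **joint** — allele rows for heterozygotes with allele-resolved reads
  (x = 0/1, residual scale 1) plus collapsed rows for homozygotes and
  unphased heterozygotes (x = genotype/2, scale 1/2). This is the
  full ASM-assisted estimator.
* **individual** — collapsed rows for everyone (heterozygote covariate
  0.5): the non-allele-specific binomial mixed model.
* **allele** — heterozygote allele rows only (requires at least 5
  heterozygotes); the pure ASM analysis, in which each individual serves
  as its own control for $g_i$ and $u_i$.

Baselines with the same input/output contract: `fitBetaBinomial()`
(per-site beta-binomial ML on the collapsed counts — over-dispersion
without relatedness) and `fitLmmMvalues()` (REML linear mixed model on
M-values $\log_2\frac{y+0.5}{r-y+0.5}$ — the normalized-data approach;
the 0.5 offset is the standard half-count continuity correction).

### Fitting and testing

`fitPQL()` uses penalized quasi-likelihood: the binomial likelihood is
linearized into a working response $z = \eta + (y - r\pi)/(r\pi(1-\pi))$
with weights $w = r\pi(1-\pi)$, and the variance components of
$V = \sigma_g^2 Z K Z^\top + \sigma_u^2 Z Z^\top + \sigma_e^2 D + W^{-1}$
are updated by average-information REML, alternating with GLS updates of
$(\mu, \beta)$ until the maximum parameter change falls below `tol`
(default `1e-5`, `maxIter` 200). When every individual contributes a
single row (the individual layout), $\sigma_u^2$ and $\sigma_e^2$ are not
separately identifiable and $u$ is folded into $e$. Components are kept
in $[10^{-6}, 100]$; fitted probabilities are clamped to
$[10^{-6}, 1-10^{-6}]$ so boundary counts ($y = 0$ or $y = r$) cannot
produce infinite working responses. Initialization: $(\mu, \beta)$ from a
binomial GLM, components at $0.1$. Monomorphic covariates and other
recoverable failures yield an `NA` row with a reason code from
`fitPair()` rather than an error, so study-scale batch runs continue.

The null hypothesis $\beta = 0$ is assessed with a Wald statistic
$(\hat\beta/\widehat{se})^2$. By default the p-value uses a *t* reference
with Satterthwaite degrees of freedom derived from the AI-REML
covariance of the variance components. The motivation is empirical as
well as standard small-sample practice: on 2,500 simulated null-only
baseline sites, the plug-in $\chi^2_1$ reference gave a tail fraction
$P(p < 10^{-3}) \approx 0.0020$ for the joint model where $0.0010$ is
nominal, and the Satterthwaite reference halved that inflation. Far-tail
calibration is what drives discovery ordering at low false discovery
rates, so this choice matters more than the 0.05-level error rate (which
both references control). The plain $\chi^2_1$ mapping remains available
(`pReference = "chisq"`, or `waldTest()`).

## The simulator

`simulateStudy()` generates complete studies without any external data,
emulating a population-scale bisulfite experiment:

* **Genotypes** — `Binomial(2, f)` per SNP with $f$ uniform in a MAF bin
  (bins centered at 0.1, 0.3, 0.5); the relatedness matrix is the
  centered, standardized GRM of a 2,000-SNP panel. Individuals are
  unrelated, so $K$ is near identity — the kinship code path is
  exercised, but power statements are validated under near-identity
  relatedness only.
* **Read depths** — total reads $r_i \sim \mathrm{NB}$ with mean `TR`
  (default 20) and dispersion `phi` (default 3, variance
  $TR + TR^2/\phi$), split between alleles with
  $q_i \sim \mathrm{Beta}(10, 10)$ (93.5% of splits fall in (0.3, 0.7)).
* **Latent methylation** — $g$ drawn with covariance
  $c\,K$, $c = (1+\rho)h^2\sigma^2 / (2 + (\rho-1)h^2)$; per individual
  $(u_i + e_{i1}, u_i + e_{i2})$ bivariate normal with per-component
  variance $(1 - \mathrm{PVE} - h^2)\sigma^2$ and correlation $\rho$
  (for null sites the PVE term is zero, keeping total variance
  consistent); for true mQTL sites
  $\beta \sim N(0, \mathrm{PVE}\,\sigma^2 / ((1-\mathrm{PVE}) V(x)))$
  with $V(x)$ the sample variance of the dosage vector.
* **Counts** — $y_{il} \sim \mathrm{Bin}(r_{il}, \pi_{il})$;
  heterozygotes keep allele-level counts, homozygotes are collapsed, and
  zero-depth individuals are dropped.

Defaults are the baseline study conditions ($n = 100$, $h^2 = 0.3$,
$\pi_0 = 0.5$, MAF bin 0.3, $\rho = 0$, TR = 20, $\phi = 3$,
$\sigma^2 = 0.7$, PVE = 0.1, 10% true sites). A property test verifies
the variance bookkeeping end-to-end: across simulated sites, the share of
$\mathrm{var}(g)$ in
$\mathrm{var}(g) + \sigma_u^2 + \tfrac12\sigma_e^2 + \mathrm{var}(x\beta)$
recovers the configured $h^2$ within 0.03. Note the printed genetic
coefficient and the $h^2$ ratio excluding the focal-SNP term are mutually
consistent only when the focal term is included in the denominator; the
package implements both formulas verbatim and measures the decomposition
rather than guessing.

What the simulator does *not* emulate: linkage disequilibrium between
sites (each site draws a fresh SNP), related individuals, allele-specific
mapping bias (the read split is symmetric by construction), bimodal
genome-wide methylation landscapes (each site has a single $\pi_0$), and
covariate structure. Passing power tests therefore speak to the
estimators under idealized sampling, not to artefact robustness on real
data — the QC filters (`qcFilter()`) exist precisely because real data
violate these idealizations.

## Significance without distributional trust

Because per-site asymptotic calibration degrades at high $h^2$, small
$n$, or low MAF, discovery calls should use a permutation-derived
empirical null (`empiricalFdr()`): the empirical FDR at threshold $t$ is
the mean permuted discovery count divided by the observed count, made
monotone in $t$, with the permuted p-values pooled across pairs — the
aggregate empirical-null construction. Two permutation schemes are
provided: `permuteLabels()` permutes genotype labels across sample units
(heterozygote alleles and homozygotes), valid at any $n$ and the default
($B = 10$); `permuteCountsAlt()` permutes count pairs across individuals
and redraws heterozygote allele splits read-by-read with probability
1/2 — preferable only for larger samples (roughly $n > 150$). For
simulation studies with known truth, `powerAtFdr()` reports power at a
realized false-discovery proportion, with tied p-values entering
together at the larger rank.

## Worked example

```{r example, eval = FALSE}
cfg <- simConfig(n = 100, nSites = 200, seed = 42)
st <- simulateStudy(cfg)
res <- fitStudy(st$pairs, st$K, method = "joint")
head(res[, c("pair_id", "beta", "se", "pvalue", "h2", "converged")])
powerAtFdr(res$pvalue, st$truth$is_mqtl, alpha = 0.05)
```

## Numerical and design choices

* Kinship matrices are repaired to positive semi-definiteness by
  clipping negative eigenvalues at zero — PQL requires a valid
  covariance.
* Heterozygotes without phase-assignable reads are collapsed like
  homozygotes (with covariate 0.5) and flagged in the output, rather
  than dropped; they still contribute individual-level information.
* The genotype covariate is coded on the allele scale everywhere
  (allele rows 0/1, collapsed rows genotype/2) so that $\beta$ is a
  per-allele effect common to both channels.
* Covariates are removed from the *genotype* (least-squares
  residualization, `residualizeGenotype()`), not from the counts; on
  allele rows the covariate becomes $x_{il} - \widehat{x}_i/2$, which
  preserves the within-heterozygote contrast of exactly 1. Count-model
  likelihoods with covariates in the mean are less stable, and the
  residualization sidesteps that.
* QC defaults follow standard sequencing-study practice: at least 20
  measured individuals, not ≥90% of individuals outside the 10–90%
  methylation range, mean depth ≥5, MAF ≥0.05, and a guard against
  allele-specific mapping bias excluding pairs whose mean
  reference/alternate methylation ratios differ by more than 0.6
  (computed across heterozygotes with allele data; configurable).
* CpG context uses BED half-open island intervals; a CpG exactly
  2,000 bp from an island edge is shore, 2,001–4,000 bp is shelf
  (boundaries inclusive at the outer edge).
* Study sizes in the test-suite power checks are 2,000 pairs per
  scenario with 10% true sites — large enough that power estimates
  carry a Monte-Carlo standard error of a few percentage points, small
  enough for routine re-runs.

## Known limitations

* The known-FDR power of the joint estimator at these study conditions
  is information-limited: an oracle given the latent logit-methylation
  directly (infinite depth) and the true variance components attains
  roughly twice the count-based power but no more. The package reports
  what its own statistics achieve; the orderings among estimators are
  the robust, reproducible part, while absolute power levels depend
  strongly on the genotype and relatedness structure being simulated
  (unrelated individuals here).
* PQL attenuates both $\hat\beta$ and the variance components by
  roughly 10–20% at depths around 10–20 reads; rankings (and hence
  FDR-controlled discovery) are largely unaffected, but absolute effect
  sizes should be read with that bias in mind.
* Only adjacent (same-read or phased) SNP-CpG pairs are analyzable;
  distant pairs in unphased data are out of scope, as are
  imprinting-specific models and 5hmC/5mC distinction.
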