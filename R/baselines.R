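## Baseline estimators: beta-binomial regression on the collapsed counts and
## a linear mixed model on M-values. Both consume the same PairCounts input
## and emit the same results schema as the binomial mixed model, so the
## estimators are drop-in comparable.

#' M-values from methylated/total counts
#'
#' `M = log2((y + offset) / (r - y + offset))`, the variance-stabilizing
#' log-ratio transform of methylation proportions. The half-count offset
#' (default 0.5) keeps the value finite at `y = 0` and `y = r`.
#'
#' @param y,r methylated / total read counts (`r > 0` required; individuals
#'   with zero depth are excluded upstream).
#' @param offset continuity-correction added to both counts.
#' @return numeric vector of M-values.
#' @examples
#' mValues(5, 10)   # 0 at a 50% methylation level
#' @export
mValues <- function(y, r, offset = 0.5) {
  if (any(r <= 0)) stop("mValues requires r > 0 (exclude zero-depth rows)")
  log2((y + offset) / (r - y + offset))
}

#' Linear mixed model on M-values
#'
#' REML fit of `M = mu + x * beta + g + eps` with `g ~ MVN(0, sigma_g2 K)`
#' and i.i.d. residuals, via the spectral decomposition of `K` and a
#' one-dimensional profile-REML optimization over the variance ratio. Wald
#' test on the genotype effect. This is the standard normalized-data
#' approach to mQTL mapping, included for comparison with the count models.
#'
#' @param pc a [PairCounts-class] object.
#' @param K standardized kinship matrix (id dimnames), or `NULL` for an
#'   identity relatedness.
#' @param offset M-value offset, see [mValues()].
#' @param fittedCovariate optional per-individual fitted dosage from
#'   [residualizeGenotype()].
#' @return a fit list (class `"pqlFit"` schema: `mu`, `beta`, `se`, `wald`,
#'   `pvalue`, `vc`, `h2`, `nIndividuals`, `nHet`, `converged`, `nIter`,
#'   `note`). `vc` reports `sigma_g2` and the residual variance in
#'   `sigma_e2`; `h2` is the narrow-sense ratio `sigma_g2 / (sigma_g2 +
#'   sigma_e2)` on the M-value scale.
#' @export
fitLmmMvalues <- function(pc, K = NULL, offset = 0.5,
                          fittedCovariate = NULL) {
  pc <- dropUninformative(pc)
  n <- length(pc@ids)
  if (n < 10L) stop("too few individuals for the M-value LMM (need >= 10)")
  g <- pc@genotype
  fit <- rep(0, n)
  if (!is.null(fittedCovariate)) {
    fit <- if (!is.null(names(fittedCovariate))) {
      unname(fittedCovariate[pc@ids])
    } else fittedCovariate
  }
  x <- (g - fit) / 2
  if (var(x) == 0) stop("degenerate design: monomorphic genotype")
  m <- mValues(pc@yTotal, pc@rTotal, offset)
  Ks <- if (is.null(K)) diag(n) else K[pc@ids, pc@ids, drop = FALSE]
  e <- eigen(Ks, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  Ut <- t(e$vectors)
  yr <- drop(Ut %*% m)
  Xr <- Ut %*% cbind(1, x)
  p <- 2L
  ## profile REML over delta = sigma_e2 / sigma_g2 on the log scale
  remlNegLL <- function(logDelta) {
    wv <- 1 / (lam + exp(logDelta))
    XtWX <- crossprod(Xr * wv, Xr)
    b <- solve(XtWX, crossprod(Xr * wv, yr))
    rss <- sum(wv * (yr - drop(Xr %*% b))^2)
    0.5 * ((n - p) * log(rss) - sum(log(wv)) +
             determinant(XtWX, logarithm = TRUE)$modulus)
  }
  opt <- optimize(remlNegLL, c(-12, 12))
  delta <- exp(opt$minimum)
  wv <- 1 / (lam + delta)
  XtWX <- crossprod(Xr * wv, Xr)
  XtWXi <- solve(XtWX)
  b <- drop(XtWXi %*% crossprod(Xr * wv, yr))
  rss <- sum(wv * (yr - drop(Xr %*% b))^2)
  sg2 <- rss / (n - p)
  se2 <- sg2 * delta
  se <- sqrt(sg2 * XtWXi[2, 2])
  wald <- (b[2] / se)^2
  structure(list(
    mu = unname(b[1]), beta = unname(b[2]), se = unname(se), wald = unname(wald),
    pvalue = pchisq(wald, 1, lower.tail = FALSE),
    vc = c(sigma_g2 = sg2, sigma_u2 = NA_real_, sigma_e2 = se2),
    h2 = sg2 / (sg2 + se2), nIndividuals = n, nHet = nHet(pc),
    converged = TRUE, nIter = 1L, note = ""
  ), class = "pqlFit")
}

#' Beta-binomial regression on the collapsed counts
#'
#' Per-site maximum likelihood for `y_i ~ BetaBin(r_i; p_i, rhoBB)` with
#' mean `p_i = plogis(mu + x_i * beta)` and a single intra-class
#' over-dispersion parameter `rhoBB` in (0, 1) (optimized on the logit
#' scale). The Wald test on `beta` uses the observed-information standard
#' error from the numerical Hessian at the optimum. When the
#' over-dispersion estimate collapses to the lower boundary, the model is
#' refit as a plain binomial GLM and flagged.
#'
#' @param pc a [PairCounts-class] object.
#' @param fittedCovariate optional per-individual fitted dosage from
#'   [residualizeGenotype()].
#' @return a fit list in the shared schema (see [fitLmmMvalues()]); element
#'   `logLik` carries the maximized log-likelihood and `rhoBB` the
#'   over-dispersion estimate.
#' @export
fitBetaBinomial <- function(pc, fittedCovariate = NULL) {
  pc <- dropUninformative(pc)
  n <- length(pc@ids)
  if (n < 10L) stop("too few individuals for beta-binomial fit (need >= 10)")
  g <- pc@genotype
  fit <- rep(0, n)
  if (!is.null(fittedCovariate)) {
    fit <- if (!is.null(names(fittedCovariate))) {
      unname(fittedCovariate[pc@ids])
    } else fittedCovariate
  }
  x <- (g - fit) / 2
  if (var(x) == 0) stop("degenerate design: monomorphic genotype")
  y <- pc@yTotal; r <- pc@rTotal

  negLL <- function(par) {
    p <- pmin(pmax(plogis(par[1] + par[2] * x), 1e-8), 1 - 1e-8)
    rho <- pmin(pmax(plogis(par[3]), 1e-10), 1 - 1e-10)
    s <- (1 - rho) / rho
    a <- p * s; b <- (1 - p) * s
    -sum(lchoose(r, y) + lbeta(y + a, r - y + b) - lbeta(a, b))
  }
  glm0 <- suppressWarnings(glm(cbind(y, r - y) ~ x, family = binomial()))
  start <- c(unname(coef(glm0)), qlogis(0.05))
  if (anyNA(start)) start[is.na(start)] <- 0
  opt <- tryCatch(
    optim(start, negLL, method = "BFGS", hessian = TRUE,
          control = list(maxit = 500)),
    error = function(e) NULL)
  boundary <- is.null(opt) || plogis(opt$par[3]) < 1e-4 ||
    !all(is.finite(opt$par))
  if (boundary) {
    ## no over-dispersion: plain binomial GLM
    sm <- summary(glm0)$coefficients
    b <- unname(coef(glm0))
    se <- sm["x", "Std. Error"]
    wald <- (b[2] / se)^2
    return(structure(list(
      mu = b[1], beta = b[2], se = se, wald = wald,
      pvalue = pchisq(wald, 1, lower.tail = FALSE),
      vc = c(sigma_g2 = NA_real_, sigma_u2 = NA_real_, sigma_e2 = NA_real_),
      h2 = NA_real_, nIndividuals = n, nHet = nHet(pc),
      converged = TRUE, nIter = 1L, rhoBB = 0,
      logLik = as.numeric(stats::logLik(glm0)),
      note = "boundary_overdispersion_binomial_refit"
    ), class = "pqlFit"))
  }
  covm <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  if (is.null(covm) || covm[2, 2] <= 0) {
    stop("degenerate fit: singular observed information")
  }
  se <- sqrt(covm[2, 2])
  wald <- (opt$par[2] / se)^2
  structure(list(
    mu = opt$par[1], beta = opt$par[2], se = se, wald = wald,
    pvalue = pchisq(wald, 1, lower.tail = FALSE),
    vc = c(sigma_g2 = NA_real_, sigma_u2 = NA_real_, sigma_e2 = NA_real_),
    h2 = NA_real_, nIndividuals = n, nHet = nHet(pc),
    converged = opt$convergence == 0, nIter = opt$counts[1],
    rhoBB = plogis(opt$par[3]), logLik = -opt$value,
    note = if (opt$convergence == 0) "" else "optimizer_not_converged"
  ), class = "pqlFit")
}
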