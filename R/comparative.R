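# Phylogeny-aware statistics.  The central model is the phylogenetic
# linear mixed model y = X beta + g + e, with g ~ N(0, sigma2_g K) for
# a Brownian-motion kinship matrix K derived from the tree and
# e ~ N(0, sigma2_e I).  Everything is fitted by full maximum
# likelihood (not REML) so that AIC, chi-square LRTs and
# likelihood-ratio R-squared all consume comparable total
# log-likelihoods.

#' Brownian-motion covariance matrix from a tree
#'
#' C[i, j] is the branch-length path from the root to the most recent
#' common ancestor of tips i and j; the diagonal equals the root-to-tip
#' lengths.  The `"correlation"` convention rescales C by its largest
#' diagonal entry, which is the form used as a kinship matrix.
#'
#' @param tree rooted `ape::phylo` with branch lengths.
#' @param convention `"covariance"` or `"correlation"`.
#' @return symmetric positive semi-definite matrix with tip labels as
#'   dimnames.
#' @export
#' @examples
#' bmCovariance(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
bmCovariance <- function(tree, convention = c("covariance", "correlation")) {
  convention <- match.arg(convention)
  assertPhylogram(tree)
  C <- ape::vcv(tree)
  if (convention == "correlation") C <- C / max(diag(C))
  C
}

# Shared GLS core: beta-hat, ML sigma2, log-likelihood for fixed C.
glsCore <- function(y, X, C) {
  n <- length(y)
  ch <- tryCatch(chol(C), error = function(e)
    stopf("covariance matrix is not positive definite: %s", conditionMessage(e)))
  Xs <- backsolve(ch, X, transpose = TRUE)
  ys <- backsolve(ch, y, transpose = TRUE)
  XtX <- crossprod(Xs)
  if (rcond(XtX) < 1e-12) stopf("design matrix is rank deficient")
  beta <- solve(XtX, crossprod(Xs, ys))
  r <- ys - Xs %*% beta
  sigma2 <- sum(r^2) / n
  logDetC <- 2 * sum(log(diag(ch)))
  ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + logDetC + n)
  list(beta = drop(beta), sigma2 = sigma2, logLik = ll,
       vcovBeta = sigma2 * solve(XtX))
}

#' Phylogenetic generalized least squares
#'
#' GLS estimates beta = (X' C^-1 X)^-1 X' C^-1 y with ML error variance
#' and Gaussian log-likelihood; a Wald chi-square ANOVA is reported for
#' each non-intercept term of the design (identified through the
#' `assign` attribute that [stats::model.matrix()] leaves on `X`).
#'
#' @param y numeric response (species order must match `C`).
#' @param X design matrix, full rank; ideally from `model.matrix()` so
#'   term blocks are known.
#' @param C phylogenetic covariance from [bmCovariance()] (any positive
#'   definite matrix works; `C = diag(n)` reduces to OLS).
#' @return list with `beta`, `sigma2`, `logLik`, `vcovBeta` and
#'   `anova` (data.frame: term, waldChisq, df, p).
#' @export
pglsFit <- function(y, X, C) {
  stopifnot(length(y) == nrow(X), nrow(C) == length(y))
  fit <- glsCore(y, X, C)
  assign <- attr(X, "assign")
  anovaTab <- NULL
  if (!is.null(assign)) {
    terms <- setdiff(unique(assign), 0L)
    anovaTab <- do.call(rbind, lapply(terms, function(tm) {
      j <- which(assign == tm)
      b <- fit$beta[j]
      W <- drop(t(b) %*% solve(fit$vcovBeta[j, j, drop = FALSE], b))
      data.frame(term = tm, waldChisq = W, df = length(j),
                 p = pchisq(W, length(j), lower.tail = FALSE))
    }))
  }
  c(fit, list(anova = anovaTab))
}

#' Fit the kinship phylogenetic linear mixed model by ML
#'
#' Fits y = X beta + g + e with g ~ N(0, sigma2_g K), e ~ N(0,
#' sigma2_e I) via eigendecomposition of K and 1-D profile likelihood
#' over the variance ratio.  The response is expected on the natural
#' log scale (log brl) as used throughout the analyses.  The parameter
#' count is the number of fixed effects plus two variance components,
#' so the null intercept-only model has DF 3, adding a 3-level factor
#' gives 5, a 5-level factor 7, and both 9.
#'
#' @param y numeric response (natural-log branch lengths).
#' @param X design matrix with intercept (from `model.matrix()`).
#' @param K positive semi-definite kinship matrix in the same species
#'   order, e.g. `bmCovariance(tree, "correlation")`.
#' @param label optional model label stored in the fit.
#' @return a [PhyloModelFit-class].
#' @export
plmmFit <- function(y, X, K, label = "y ~ X + RE") {
  n <- length(y)
  stopifnot(nrow(X) == n, all(dim(K) == n))
  if (!isSymmetric(unname(K), tol = 1e-8)) stopf("K must be symmetric")
  eig <- eigen(K, symmetric = TRUE)
  if (min(eig$values) < -1e-8 * max(eig$values))
    stopf("K is not positive semi-definite")
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)

  profile <- function(logLambda) {
    lambda <- exp(logLambda)       # sigma2_g / sigma2_e
    w <- 1 / (lambda * d + 1)
    Xw <- Xt * w
    XtWX <- crossprod(Xt, Xw)
    if (rcond(XtWX) < 1e-14) return(list(nll = Inf))
    beta <- solve(XtWX, crossprod(Xw, yt))
    r <- yt - Xt %*% beta
    sigmaE2 <- sum(w * r^2) / n
    ll <- -0.5 * (n * log(2 * pi) + n * log(sigmaE2) +
                    sum(log(lambda * d + 1)) + n)
    list(nll = -ll, beta = drop(beta), sigmaE2 = sigmaE2,
         vcovBeta = sigmaE2 * solve(XtWX), lambda = lambda)
  }
  # the profile need not be unimodal over the wide lambda range, so
  # scan a coarse grid first and refine around the best point
  lo <- -25; hi <- 25
  grid <- seq(lo, hi, by = 0.5)
  nllGrid <- vapply(grid, function(l) profile(l)$nll, numeric(1))
  iBest <- which.min(nllGrid)
  opt <- optimize(function(l) profile(l)$nll,
                  interval = c(grid[max(1L, iBest - 1L)],
                               grid[min(length(grid), iBest + 1L)]),
                  tol = 1e-8)
  best <- if (min(nllGrid) < opt$objective) grid[iBest] else opt$minimum
  sol <- profile(best)
  if (!is.finite(sol$nll)) stopf("design matrix is rank deficient")
  boundary <- best <= lo + 1e-3 || best >= hi - 1e-3
  betaNames <- colnames(X)
  if (is.null(betaNames)) betaNames <- paste0("b", seq_along(sol$beta))
  df <- ncol(X) + 2L
  ll <- -sol$nll
  new("PhyloModelFit",
      beta = setNames(sol$beta, betaNames),
      se = setNames(sqrt(diag(sol$vcovBeta)), betaNames),
      sigmaG2 = sol$lambda * sol$sigmaE2, sigmaE2 = sol$sigmaE2,
      logLik = ll, df = df, aic = 2 * df - 2 * ll, n = as.integer(n),
      boundary = boundary, label = label)
}

#' Akaike information criterion with the model-table DF convention
#'
#' AIC = 2 DF - 2 logLik, where DF counts fixed effects plus the two
#' variance components.
#'
#' @param fit a [PhyloModelFit-class], or a numeric log-likelihood
#'   (then `df` must be given).
#' @param df parameter count when `fit` is numeric.
#' @return numeric AIC.
#' @export
#' @examples
#' modelAIC(-12964, df = 5)  # 25938
modelAIC <- function(fit, df = NULL) {
  if (is(fit, "PhyloModelFit")) return(fit@aic)
  stopifnot(is.numeric(fit), !is.null(df))
  2 * df - 2 * fit
}

#' Likelihood-ratio R-squared
#'
#' Raw form 1 - exp(-(2/n) (llFull - llNull)); the optional Nagelkerke
#' adjustment divides by the maximum attainable value
#' 1 - exp((2/n) llNull).  The raw form is the default.
#'
#' @param llFull,llNull ML log-likelihoods of the nested models.
#' @param n number of observations.
#' @param adjusted apply the Nagelkerke rescaling.
#' @return R-squared in [0, 1).
#' @export
#' @examples
#' lrRSquared(-11381, -15466, n = 10906)  # ~0.527
lrRSquared <- function(llFull, llNull, n, adjusted = FALSE) {
  if (n <= 0) stopf("n must be positive")
  if (llFull < llNull) warnf("llFull < llNull; negative R2")
  r2 <- 1 - exp(-(2 / n) * (llFull - llNull))
  if (adjusted) r2 <- r2 / (1 - exp((2 / n) * llNull))
  r2
}

#' Chi-square likelihood-ratio test of nested model fits
#'
#' @param fitAlt,fitNull nested [PhyloModelFit-class] objects on the
#'   same data, or numeric log-likelihoods when `dfAlt`/`dfNull` given.
#' @param dfAlt,dfNull parameter counts for the numeric interface.
#' @return list with `lambda` (2 * delta logLik), `df`, `p`.  P-values
#'   below the double-precision floor are reported as 0.
#' @export
#' @examples
#' likelihoodRatioTest(-12964, -15466, dfAlt = 5, dfNull = 3)
likelihoodRatioTest <- function(fitAlt, fitNull, dfAlt = NULL, dfNull = NULL) {
  if (is(fitAlt, "PhyloModelFit")) {
    if (fitAlt@n != fitNull@n) stopf("fits are not on the same data (n differs)")
    llA <- fitAlt@logLik; llN <- fitNull@logLik
    dfAlt <- fitAlt@df; dfNull <- fitNull@df
  } else {
    llA <- fitAlt; llN <- fitNull
  }
  ddf <- dfAlt - dfNull
  if (ddf < 1) stopf("models are not nested: DF_alt must exceed DF_null")
  lambda <- 2 * (llA - llN)
  if (lambda < -1e-6) warnf("negative LR statistic (%.3g); optimizer noise?", lambda)
  lambda <- max(lambda, 0)
  list(lambda = lambda, df = ddf,
       p = pchisq(lambda, ddf, lower.tail = FALSE))
}

# --- Tukey HSD with compact letters ----------------------------------

# Piepho-style insert-and-absorb compact letter display: groups share a
# letter iff they are not significantly different.
compactLetters <- function(groups, sigPairs) {
  sets <- list(groups)
  for (r in seq_len(nrow(sigPairs))) {
    a <- sigPairs[r, 1]; b <- sigPairs[r, 2]
    for (i in seq_along(sets)) {
      s <- sets[[i]]
      if (a %in% s && b %in% s) {
        sets[[i]] <- setdiff(s, a)
        sets[[length(sets) + 1L]] <- setdiff(s, b)
      }
    }
    # absorb subsets
    keep <- rep(TRUE, length(sets))
    for (i in seq_along(sets)) for (j in seq_along(sets))
      if (i != j && keep[i] && keep[j] && all(sets[[i]] %in% sets[[j]]) &&
          length(sets[[i]]) < length(sets[[j]]))
        keep[i] <- FALSE
    keep[duplicated(vapply(sets, paste, character(1), collapse = "\r"))] <- FALSE
    sets <- sets[keep]
  }
  sets <- sets[vapply(sets, length, integer(1)) > 0L]
  sets <- sets[order(vapply(sets, function(s) min(match(s, groups)), numeric(1)))]
  lab <- setNames(rep("", length(groups)), groups)
  for (i in seq_along(sets))
    for (g in sets[[i]]) lab[g] <- paste0(lab[g], letters[i])
  lab
}

#' Tukey HSD pairwise comparisons with compact letter display
#'
#' One-way ANOVA pooled error, Tukey-Kramer studentized-range p-values
#' for unequal group sizes, significance letters at `alpha`, and
#' Cohen's d per pair.
#'
#' @param values numeric response.
#' @param groups group labels, same length as `values`.
#' @param alpha family-wise significance level.
#' @param dThresholds effect-size magnitude thresholds passed to
#'   [cohensD()].
#' @return list with `pairs` (data.frame: group1, group2, diff, q, p,
#'   significant, d, magnitude), `letters` (named by group, ordered by
#'   decreasing mean), `groupMeans`, `mse`, `dfError`.  Groups with
#'   fewer than 2 members are excluded with a warning.
#' @export
tukeyPairwise <- function(values, groups, alpha = 0.05,
                          dThresholds = NULL) {
  g <- as.character(groups)
  sizes <- table(g)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warnf("excluding group(s) with < 2 members: %s",
          paste(small, collapse = ", "))
    keep <- !g %in% small
    values <- values[keep]; g <- g[keep]
  }
  lev <- names(sort(tapply(values, g, mean), decreasing = TRUE))
  if (length(lev) < 2L) stopf("need at least 2 groups with >= 2 members")
  ni <- table(g)[lev]
  mi <- tapply(values, g, mean)[lev]
  N <- length(values); k <- length(lev)
  dfe <- N - k
  mse <- sum(tapply(values, g, function(v) sum((v - mean(v))^2))) / dfe
  cmb <- utils::combn(lev, 2L)
  pairs <- do.call(rbind, apply(cmb, 2L, function(pr) {
    a <- pr[1]; b <- pr[2]
    sed <- sqrt(mse / 2 * (1 / ni[a] + 1 / ni[b]))
    qstat <- if (sed == 0) 0 else abs(mi[a] - mi[b]) / sed
    p <- if (sed == 0 && mi[a] != mi[b]) 0 else
      ptukey(qstat, k, dfe, lower.tail = FALSE)
    dd <- cohensD(values[g == a], values[g == b], thresholds = dThresholds)
    data.frame(group1 = a, group2 = b, diff = unname(mi[a] - mi[b]),
               q = unname(qstat), p = unname(p), significant = p < alpha,
               d = dd$d, magnitude = dd$magnitude, stringsAsFactors = FALSE)
  }))
  sig <- as.matrix(pairs[pairs$significant, c("group1", "group2")])
  letters_ <- compactLetters(lev, sig)
  list(pairs = pairs, letters = letters_, groupMeans = mi, mse = mse,
       dfError = dfe, alpha = alpha)
}

#' Cohen's d with magnitude label
#'
#' Standardized mean difference using the pooled (n-1 weighted)
#' standard deviation.  Default magnitude thresholds follow
#' Sawilowsky: 0.2 small, 0.5 medium, 0.8 large, 1.2 very large,
#' 2.0 huge.
#'
#' @param group1,group2 numeric vectors (>= 2 members each).
#' @param thresholds named numeric vector of lower bounds per label;
#'   `NULL` for the default scale.
#' @return list with `d` (signed) and `magnitude` (label for |d|).
#'   Zero pooled sd with unequal means yields d = Inf and a flag.
#' @export
#' @examples cohensD(rnorm(20, 2), rnorm(20))$magnitude
cohensD <- function(group1, group2, thresholds = NULL) {
  if (length(group1) < 2L || length(group2) < 2L)
    stopf("both groups need >= 2 members")
  if (is.null(thresholds))
    thresholds <- c(negligible = 0, small = 0.2, medium = 0.5, large = 0.8,
                    "very large" = 1.2, huge = 2.0)
  n1 <- length(group1); n2 <- length(group2)
  sp <- sqrt(((n1 - 1) * var(group1) + (n2 - 1) * var(group2)) / (n1 + n2 - 2))
  md <- mean(group1) - mean(group2)
  infinite <- sp == 0 && md != 0
  d <- if (sp == 0) (if (md == 0) 0 else sign(md) * Inf) else md / sp
  thresholds <- sort(thresholds)
  mag <- names(thresholds)[max(which(abs(d) >= thresholds))]
  if (abs(d) < min(thresholds)) mag <- names(thresholds)[1]
  list(d = unname(d), magnitude = mag, degenerate = infinite)
}

#' Power of a two-sided two-sample t-test
#'
#' Uses the noncentral t distribution with noncentrality
#' d * sqrt(n1 n2 / (n1 + n2)).
#'
#' @param d true standardized effect size (>= 0).
#' @param n1,n2 group sizes (>= 2).
#' @param alpha significance level.
#' @return power in (0, 1); equals `alpha` at d = 0.
#' @export
#' @examples powerTwoSample(0.5, 64, 64)  # ~0.80
powerTwoSample <- function(d, n1, n2, alpha = 0.05) {
  stopifnot(d >= 0, n1 >= 2, n2 >= 2)
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tc <- qt(1 - alpha / 2, df)
  pt(-tc, df, ncp) + pt(tc, df, ncp, lower.tail = FALSE)
}
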