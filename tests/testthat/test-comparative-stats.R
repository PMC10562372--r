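# Phylogeny-aware statistics: BM covariance, PGLS, the kinship mixed
# model, LR R-squared, AIC, LRT, Tukey HSD, Cohen's d, power.

test_that("BM covariance equals shared root-to-MRCA path lengths", {
  C <- bmCovariance(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
  expect_equal(unname(C), rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 2)))
  C0 <- bmCovariance(ape::read.tree(text = "((A:1,B:1):1e-12,C:1);"))
  expect_equal(unname(C0["A", "B"]), 0, tolerance = 1e-10)
  # diagonal is the root-to-tip length; correlation scales max diag to 1
  tr <- withr::with_seed(2, ape::rtree(15))
  expect_equal(diag(bmCovariance(tr)),
               brl(rootToTipLengths(tr))[colnames(bmCovariance(tr))])
  expect_equal(max(diag(bmCovariance(tr, "correlation"))), 1)
})

test_that("PGLS with identity covariance reduces to OLS", {
  set.seed(11)
  n <- 20
  X <- model.matrix(~ gl(2, 10))
  y <- rnorm(n) + 0.8 * (as.numeric(gl(2, 10)) - 1)
  fit <- pglsFit(y, X, diag(n))
  ols <- lm(y ~ gl(2, 10))
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(fit$logLik, as.numeric(logLik(ols)), tolerance = 1e-8)
})

test_that("PGLS matches the brute-force GLS formula and nlme::gls", {
  tr <- sampleYuleTree(12, seed = 3)   # corBrownian assumes ultrametry
  C <- bmCovariance(tr)
  set.seed(4)
  g <- factor(sample(c("a", "b"), 12, replace = TRUE))
  X <- model.matrix(~ g)
  y <- drop(t(chol(C)) %*% rnorm(12)) + 2 * (g == "b")
  fit <- pglsFit(y, X, C)
  expect_equal(unname(fit$beta), unname(bruteGls(y, X, C)), tolerance = 1e-10)
  d <- data.frame(y = y, g = g, sp = colnames(C))
  gfit <- nlme::gls(y ~ g, data = d, method = "ML",
                    correlation = ape::corBrownian(1, tr, form = ~sp))
  expect_equal(unname(fit$beta), unname(coef(gfit)), tolerance = 1e-6)
  expect_equal(fit$logLik, as.numeric(logLik(gfit)), tolerance = 1e-6)
  # intercept-only closed form on a 3-species tree
  tr3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C3 <- bmCovariance(tr3)
  y3 <- c(1.2, 0.8, 3.0)
  one <- matrix(1, 3, 1)
  b0 <- drop(solve(t(one) %*% solve(C3) %*% one) %*%
               t(one) %*% solve(C3) %*% y3)
  expect_equal(unname(pglsFit(y3, one, C3)$beta), b0, tolerance = 1e-12)
  expect_error(pglsFit(y3, cbind(one, one), C3), "rank")
})

test_that("PGLS Wald ANOVA flags a real factor effect", {
  tr <- sampleYuleTree(40, seed = 6)
  C <- bmCovariance(tr)
  set.seed(7)
  g <- factor(rep(c("a", "b"), each = 20))
  X <- model.matrix(~ g)
  y <- drop(t(chol(C / max(C))) %*% rnorm(40)) * 0.1 + 3 * (g == "b")
  fit <- pglsFit(y, X, C / max(C))
  expect_lt(fit$anova$p[1], 1e-6)
  expect_identical(fit$anova$df[1], 1L)
})

test_that("mixed-model DF convention counts fixed effects plus two", {
  set.seed(8)
  n <- 45
  tr <- sampleYuleTree(n, seed = 8)
  K <- bmCovariance(tr, "correlation")
  y <- rnorm(n) + 2
  lht <- factor(sample(LHT_LEVELS, n, replace = TRUE))
  loc <- factor(sample(LOC_LEVELS, n, replace = TRUE))
  X0 <- matrix(1, n, dimnames = list(NULL, "(Intercept)"))
  expect_identical(plmmFit(y, X0, K)@df, 3L)
  expect_identical(plmmFit(y, model.matrix(~loc), K)@df, 5L)
  expect_identical(plmmFit(y, model.matrix(~lht), K)@df, 7L)
  expect_identical(plmmFit(y, model.matrix(~lht + loc), K)@df, 9L)
  f <- plmmFit(y, model.matrix(~loc), K)
  expect_equal(f@aic, 2 * f@df - 2 * f@logLik)
})

test_that("mixed-model likelihood matches the dense grid-search oracle", {
  for (seed in c(1, 2)) {
    n <- 7
    tr <- sampleYuleTree(n, seed = seed)
    K <- bmCovariance(tr, "correlation")
    set.seed(seed + 100)
    g <- rep(c(0, 1), length.out = n)
    X <- cbind(1, g)
    colnames(X) <- c("(Intercept)", "g")
    y <- drop(t(chol(K + diag(n) * 0.3)) %*% rnorm(n)) + 1.5 * g
    fit <- plmmFit(y, X, K)
    oracle <- gridSearchPlmmLogLik(y, X, K)
    expect_equal(fit@logLik, oracle, tolerance = 1e-4)
    expect_gte(fit@logLik, oracle - 1e-4)
  }
})

test_that("without phylogenetic signal the mixed model collapses to OLS", {
  n <- 40
  tr <- sampleYuleTree(n, seed = 12)
  K <- bmCovariance(tr, "correlation")
  set.seed(13)
  y <- rnorm(n)     # iid: sigma2_g = 0 truth
  X <- matrix(1, n, dimnames = list(NULL, "(Intercept)"))
  fit <- plmmFit(y, X, K)
  ols <- lm(y ~ 1)
  expect_equal(fit@logLik, as.numeric(logLik(ols)), tolerance = 1e-4)
  # K = I: the variance split is unidentifiable but the likelihood
  # still equals the OLS maximum
  fitI <- plmmFit(y, X, diag(n))
  expect_equal(fitI@logLik, as.numeric(logLik(ols)), tolerance = 1e-6)
})

test_that("AIC bookkeeping is exact", {
  expect_equal(modelAIC(-12964, df = 5), 25938)
  expect_equal(modelAIC(-13487, df = 5), 26984)
  expect_equal(modelAIC(0, df = 0), 0)
})

test_that("LR R-squared follows the closed form and is monotone", {
  expect_equal(lrRSquared(-10, -10, 50), 0)
  expect_equal(lrRSquared(-1272, -1719, 1212), 0.52174, tolerance = 2e-4)
  r <- vapply(seq(-1719, -1500, by = 25), lrRSquared, numeric(1),
              llNull = -1719, n = 1212)
  expect_true(all(diff(r) > 0))
  adj <- lrRSquared(-1272, -1719, 1212, adjusted = TRUE)
  expect_gt(adj, lrRSquared(-1272, -1719, 1212))
  expect_error(lrRSquared(-1, -2, 0), "positive")
})

test_that("likelihood-ratio tests use the chi-square upper tail", {
  out <- likelihoodRatioTest(-12964, -15466, dfAlt = 5, dfNull = 3)
  expect_equal(out$lambda, 5004)
  expect_identical(out$p, 0)
  same <- likelihoodRatioTest(-10, -10, dfAlt = 4, dfNull = 3)
  expect_equal(same$lambda, 0)
  expect_equal(same$p, 1)
  borderline <- likelihoodRatioTest(-10, -10 - 3.841 / 2, dfAlt = 4,
                                    dfNull = 3)
  expect_equal(borderline$p, 0.05, tolerance = 1e-3)
  expect_error(likelihoodRatioTest(-1, -2, dfAlt = 3, dfNull = 3), "nested")
})

test_that("Tukey HSD p-values agree with stats::TukeyHSD on unbalanced data", {
  set.seed(20)
  v <- c(rnorm(8, 0), rnorm(12, 1.1), rnorm(6, 2.4))
  g <- rep(c("a", "b", "c"), c(8, 12, 6))
  ours <- tukeyPairwise(v, g)
  ref <- stats::TukeyHSD(aov(v ~ factor(g)))$`factor(g)`
  for (i in seq_len(nrow(ours$pairs))) {
    pr <- ours$pairs[i, ]
    key <- paste(sort(c(pr$group1, pr$group2), decreasing = TRUE),
                 collapse = "-")
    expect_equal(pr$p, ref[key, "p adj"], tolerance = 1e-8)
  }
})

test_that("Tukey letters partition groups by significance", {
  # identical groups share a letter with p = 1
  same <- tukeyPairwise(rep(c(1, 2), 4), rep(c("a", "b"), each = 4))
  expect_equal(same$pairs$p, ptukey(same$pairs$q, 2, 6, lower.tail = FALSE))
  flat <- tukeyPairwise(c(1, 2, 1, 2), rep(c("a", "b"), each = 2))
  expect_equal(flat$pairs$p, 1)
  expect_identical(unname(flat$letters), c("a", "a"))
  # well-separated groups get distinct letters
  set.seed(21)
  v <- c(rnorm(10, 0), rnorm(10, 10), rnorm(10, 20))
  g <- rep(c("g1", "g2", "g3"), each = 10)
  sep <- tukeyPairwise(v, g)
  expect_true(all(sep$pairs$p < 0.05))
  expect_identical(sort(unname(sep$letters)), c("a", "b", "c"))
  # letters are a valid clique cover of the non-significance graph
  for (seed in 1:6) {
    set.seed(seed + 300)
    k <- sample(3:5, 1)
    v <- rnorm(k * 7, mean = rep(runif(k, 0, 3), each = 7))
    g <- rep(letters[1:k], each = 7)
    out <- tukeyPairwise(v, g)
    for (i in seq_len(nrow(out$pairs))) {
      share <- any(strsplit(out$letters[out$pairs$group1[i]], "")[[1]] %in%
                     strsplit(out$letters[out$pairs$group2[i]], "")[[1]])
      expect_identical(share, out$pairs$p[i] >= 0.05)
    }
  }
  expect_warning(tukeyPairwise(c(1, 2, 3, 4, 9), c("a", "a", "b", "b", "c")),
                 "excluding")
})

test_that("Cohen's d is the pooled standardized difference", {
  expect_equal(cohensD(c(1, 2, 3), c(1, 2, 3))$d, 0)
  g1 <- c(-0.5, 0.5); g2 <- c(-0.5, 0.5) + sqrt(0.5)
  expect_equal(cohensD(g2, g1)$d, 1.0)
  g3 <- c(-0.5, 0.5) + 2.3 * sqrt(0.5)
  out <- cohensD(g3, g1)
  expect_equal(out$d, 2.3)
  expect_identical(out$magnitude, "huge")
  expect_identical(cohensD(c(1, 2), c(1.4, 1.6))$magnitude, "negligible")
  deg <- cohensD(c(1, 1), c(2, 2))
  expect_true(is.infinite(deg$d) && deg$degenerate)
})

test_that("two-sample power follows the noncentral t", {
  expect_equal(powerTwoSample(0, 10, 10), 0.05, tolerance = 1e-10)
  expect_equal(powerTwoSample(0.5, 64, 64), 0.8015, tolerance = 1e-3)
  expect_equal(powerTwoSample(0.5, 64, 64),
               power.t.test(n = 64, delta = 0.5, sd = 1)$power,
               tolerance = 1e-4)
  grid <- vapply(seq(0.2, 2, by = 0.2), powerTwoSample, numeric(1),
                 n1 = 20, n2 = 30)
  expect_true(all(diff(grid) > 0))
})
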