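# Independent oracles.  These deliberately avoid the package's
# computational paths: matrix exponentials come from Matrix::expm,
# likelihoods from explicit enumeration or dense multivariate-normal
# densities, and GLS from the textbook closed form with solve().

# Brute-force Mk likelihood: sum over all internal-node state
# assignments of prior(root) * prod over edges of P(t)[parent, child].
enumMkLogLik <- function(tree, tipStates, model) {
  k <- length(model@states)
  nt <- ape::Ntip(tree)
  nn <- tree$Nnode
  tipIdx <- match(as.character(tipStates[tree$tip.label]), model@states)
  Pt <- lapply(tree$edge.length, function(t)
    as.matrix(Matrix::expm(model@Q * t)))
  total <- 0
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nn)))
  for (r in seq_len(nrow(grid))) {
    assign <- c(tipIdx, grid[r, ])
    lik <- model@rootPrior[assign[nt + 1L]]
    for (e in seq_len(nrow(tree$edge)))
      lik <- lik * Pt[[e]][assign[tree$edge[e, 1L]], assign[tree$edge[e, 2L]]]
    total <- total + lik
  }
  log(total)
}

# Brute-force marginal probability of each state at one node.
enumMkNodeMarginal <- function(tree, tipStates, model, node) {
  k <- length(model@states)
  nt <- ape::Ntip(tree)
  nn <- tree$Nnode
  tipIdx <- match(as.character(tipStates[tree$tip.label]), model@states)
  Pt <- lapply(tree$edge.length, function(t)
    as.matrix(Matrix::expm(model@Q * t)))
  joint <- numeric(k)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nn)))
  for (r in seq_len(nrow(grid))) {
    assign <- c(tipIdx, grid[r, ])
    lik <- model@rootPrior[assign[nt + 1L]]
    for (e in seq_len(nrow(tree$edge)))
      lik <- lik * Pt[[e]][assign[tree$edge[e, 1L]], assign[tree$edge[e, 2L]]]
    joint[assign[node]] <- joint[assign[node]] + lik
  }
  joint / sum(joint)
}

# Textbook GLS estimate.
bruteGls <- function(y, X, C) {
  Ci <- solve(C)
  drop(solve(t(X) %*% Ci %*% X) %*% t(X) %*% Ci %*% y)
}

# Dense MVN log-density of y ~ N(X beta, s2g K + s2e I) with beta the
# GLS estimate at that variance pair.
denseMvnLogLik <- function(y, X, K, s2g, s2e) {
  n <- length(y)
  V <- s2g * K + s2e * diag(n)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  Ci <- chol2inv(ch)
  XtCiX <- t(X) %*% Ci %*% X
  if (rcond(XtCiX) < 1e-14) return(-Inf)
  beta <- solve(XtCiX, t(X) %*% Ci %*% y)
  r <- y - X %*% beta
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) + drop(t(r) %*% Ci %*% r))
}

# Iteratively refined grid search over the two variance components.
gridSearchPlmmLogLik <- function(y, X, K) {
  vy <- var(y)
  lo <- log(vy) - 12; hi <- log(vy) + 4
  best <- -Inf
  cg <- ce <- (lo + hi) / 2
  width <- (hi - lo) / 2
  for (round in 1:4) {
    gGrid <- c(-Inf, seq(cg - width, cg + width, length.out = 21))
    eGrid <- seq(ce - width, ce + width, length.out = 21)
    for (lg in gGrid) for (le in eGrid) {
      ll <- denseMvnLogLik(y, X, K, exp(lg), exp(le))
      if (ll > best) { best <- ll; cg <- if (is.finite(lg)) lg else cg; ce <- le }
    }
    width <- width / 6
  }
  best
}
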