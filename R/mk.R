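# Mk (k-state continuous-time Markov) models on a rooted tree:
# Felsenstein pruning for the tip-data likelihood, ML rate estimation,
# marginal ancestral state reconstruction, and transition bookkeeping
# used to count independent origins of a state (e.g. endoparasitism).

#' Construct an Mk model
#'
#' @param states state labels (length k >= 2).
#' @param rates single transition rate (`equal_rates`) or a vector of
#'   k*(k-1) off-diagonal rates filled row-wise (`all_rates_different`).
#' @param parameterization `"equal_rates"` or `"all_rates_different"`.
#' @param rootPrior probability vector over states; default uniform.
#' @return an [MkModel-class].
#' @export
#' @examples MkModel(c("L", "H"), rates = 0.1)
MkModel <- function(states, rates,
                    parameterization = c("equal_rates", "all_rates_different"),
                    rootPrior = rep(1 / length(states), length(states))) {
  parameterization <- match.arg(parameterization)
  k <- length(states)
  stopifnot(k >= 2L, all(rates >= 0))
  Q <- matrix(0, k, k, dimnames = list(states, states))
  if (parameterization == "equal_rates") {
    stopifnot(length(rates) == 1L)
    Q[] <- rates
  } else {
    stopifnot(length(rates) == k * (k - 1L))
    r <- 0L
    for (i in seq_len(k)) for (j in seq_len(k)) if (i != j) {
      r <- r + 1L
      Q[i, j] <- rates[r]
    }
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  new("MkModel", states = states, Q = Q,
      parameterization = parameterization, rootPrior = rootPrior)
}

# exp(Q t); closed form for the equal-rates generator, series-free
# eigen/scaling for the general case.
transitionMatrix <- function(Q, t) {
  k <- nrow(Q)
  off <- Q[row(Q) != col(Q)]
  if (max(off) - min(off) <= 1e-12 * max(off, 1e-300)) {
    q <- off[1]
    e <- exp(-k * q * t)
    P <- matrix((1 - e) / k, k, k)
    diag(P) <- (1 - e) / k + e
    return(P)
  }
  P <- as.matrix(Matrix::expm(Q * t))
  P[P < 0] <- 0
  P / rowSums(P)
}

# Coerce tip states (named character/factor/integer) to indices in
# model@states, erroring on unlabelled leaves.
tipStateIndex <- function(tree, tipStates, states) {
  if (is.null(names(tipStates)))
    stopf("tipStates must be named by tip label")
  missing <- setdiff(tree$tip.label, names(tipStates))
  if (length(missing))
    stopf("leaf without state: %s", paste(head(missing, 10), collapse = ", "))
  x <- tipStates[tree$tip.label]
  idx <- match(as.character(x), states)
  if (any(is.na(idx)))
    stopf("tip state(s) outside model states: %s",
          paste(unique(as.character(x)[is.na(idx)]), collapse = ", "))
  idx
}

# Post-order pruning pass.  Returns per-node scaled partial
# likelihoods, per-edge messages, and the log-likelihood.
pruneMk <- function(tree, tipStates, model) {
  assertPhylogram(tree)
  states <- model@states
  k <- length(states)
  nt <- ape::Ntip(tree)
  nn <- tree$Nnode
  idx <- tipStateIndex(tree, tipStates, states)
  tr <- ape::reorder.phylo(tree, "postorder")
  L <- matrix(1, nt + nn, k)
  L[seq_len(nt), ] <- 0
  L[cbind(seq_len(nt), idx)] <- 1
  msg <- matrix(NA_real_, nrow(tr$edge), k)  # message child -> parent
  logScale <- 0
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1L]
    child <- tr$edge[e, 2L]
    P <- transitionMatrix(model@Q, tr$edge.length[e])
    m <- as.vector(P %*% L[child, ])
    s <- sum(m)
    if (s <= 0) return(list(logLik = -Inf))
    msg[e, ] <- m / s
    logScale <- logScale + log(s)
    L[parent, ] <- L[parent, ] * msg[e, ]
  }
  root <- nt + 1L
  lik <- sum(model@rootPrior * L[root, ])
  list(L = L, msg = msg, edge = tr$edge, edge.length = tr$edge.length,
       logLik = log(lik) + logScale, root = root, nt = nt, k = k)
}

#' Mk log-likelihood of tip data
#'
#' Computes the probability of the observed tip states under `model` by
#' post-order pruning with per-branch transition matrices exp(Q t);
#' the root is integrated against the model's root prior.
#'
#' @param tree rooted `ape::phylo` with branch lengths.
#' @param tipStates named vector (tip label -> state label).
#' @param model an [MkModel-class].
#' @return log-likelihood (<= 0).
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' mkLogLikelihood(tr, c(A = "L", B = "L", C = "H"), MkModel(c("L", "H"), 0.1))
mkLogLikelihood <- function(tree, tipStates, model) {
  pruneMk(tree, tipStates, model)$logLik
}

#' Fit an Mk model by maximum likelihood
#'
#' Transition rate(s) maximizing [mkLogLikelihood()], found by bounded
#' 1-D optimization on the log-rate scale (`equal_rates`) or L-BFGS-B
#' over all log off-diagonal rates (`all_rates_different`).  The fit is
#' deterministic: fixed start, fixed tolerance.  With fewer than two
#' distinct tip states the rate is unidentifiable and a boundary fit at
#' the lower rate bound is returned with a warning.
#'
#' @inheritParams mkLogLikelihood
#' @param states state labels; defaults to the sorted unique tip states.
#' @param parameterization `"equal_rates"` or `"all_rates_different"`.
#' @param rootPrior root state prior; default uniform.
#' @return an [MkModel-class] with attributes `logLik` and `boundary`.
#' @export
fitMkModel <- function(tree, tipStates,
                       states = sort(unique(as.character(tipStates))),
                       parameterization = c("equal_rates", "all_rates_different"),
                       rootPrior = rep(1 / length(states), length(states))) {
  parameterization <- match.arg(parameterization)
  k <- length(states)
  lower <- -18; upper <- 9
  if (length(unique(as.character(tipStates[tree$tip.label]))) < 2L) {
    warnf("fewer than two distinct tip states; returning boundary fit")
    m <- MkModel(states, rates = if (parameterization == "equal_rates") exp(lower)
                 else rep(exp(lower), k * (k - 1L)),
                 parameterization = parameterization, rootPrior = rootPrior)
    attr(m, "logLik") <- mkLogLikelihood(tree, tipStates, m)
    attr(m, "boundary") <- TRUE
    return(m)
  }
  if (parameterization == "equal_rates") {
    f <- function(lq) -mkLogLikelihood(tree, tipStates,
                                       MkModel(states, exp(lq),
                                               rootPrior = rootPrior))
    opt <- optimize(f, interval = c(lower, upper), tol = 1e-8)
    rates <- exp(opt$minimum)
    ll <- -opt$objective
    boundary <- opt$minimum < lower + 1e-3 || opt$minimum > upper - 1e-3
  } else {
    f <- function(lq) -mkLogLikelihood(tree, tipStates,
                                       MkModel(states, exp(lq),
                                               parameterization = "all_rates_different",
                                               rootPrior = rootPrior))
    start <- rep(log(max(1e-6, k / sum(tree$edge.length))), k * (k - 1L))
    opt <- optim(start, f, method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = 500))
    if (opt$convergence != 0)
      stopf("Mk optimizer failed to converge: %s", opt$message)
    rates <- exp(opt$par)
    ll <- -opt$value
    boundary <- any(opt$par < lower + 1e-3 | opt$par > upper - 1e-3)
  }
  m <- MkModel(states, rates, parameterization = parameterization,
               rootPrior = rootPrior)
  attr(m, "logLik") <- ll
  attr(m, "boundary") <- boundary
  m
}

#' Marginal ancestral state probabilities
#'
#' Combines the post-order (pruning) partial likelihoods with a
#' pre-order pass so that every node's marginal conditions on all tip
#' data; the root uses the model's root prior.
#'
#' @inheritParams mkLogLikelihood
#' @return an [AncestralReconstruction-class].
#' @export
marginalAncestralStates <- function(tree, tipStates, model) {
  pr <- pruneMk(tree, tipStates, model)
  if (!is.finite(pr$logLik)) stopf("tip data have zero likelihood under model")
  nt <- pr$nt; k <- pr$k
  nNodes <- nt + tree$Nnode
  G <- matrix(NA_real_, nNodes, k)
  G[pr$root, ] <- model@rootPrior
  edgeOrder <- rev(seq_len(nrow(pr$edge)))  # postorder reversed = preorder
  childrenOf <- split(seq_len(nrow(pr$edge)), pr$edge[, 1L])
  for (e in edgeOrder) {
    parent <- pr$edge[e, 1L]
    child <- pr$edge[e, 2L]
    sibs <- setdiff(childrenOf[[as.character(parent)]], e)
    H <- G[parent, ]
    for (s in sibs) H <- H * pr$msg[s, ]
    P <- transitionMatrix(model@Q, pr$edge.length[e])
    G[child, ] <- as.vector(H %*% P)
    G[child, ] <- G[child, ] / sum(G[child, ])
  }
  marg <- G * pr$L
  marg <- marg / rowSums(marg)
  colnames(marg) <- model@states
  new("AncestralReconstruction", tree = tree, marginals = marg,
      model = model, logLik = pr$logLik)
}

#' Assign a state to every node from its marginals
#'
#' Each node receives its maximum-marginal state.  Ties (within
#' `tol`) are broken toward the parent's assigned state when it is
#' among the tied states; root ties take the first state.
#'
#' @param recon an [AncestralReconstruction-class].
#' @param tol probability tolerance defining a tie.
#' @return character vector of states, indexed by ape node number
#'   (tips first, then internal nodes).
#' @export
assignNodeStates <- function(recon, tol = 1e-9) {
  tree <- recon@tree
  m <- recon@marginals
  states <- recon@model@states
  nt <- ape::Ntip(tree)
  out <- character(nrow(m))
  tr <- ape::reorder.phylo(tree, "postorder")
  root <- nt + 1L
  tied <- function(i) which(m[i, ] >= max(m[i, ]) - tol)
  rootTie <- tied(root)
  out[root] <- states[rootTie[1L]]
  for (e in rev(seq_len(nrow(tr$edge)))) {   # preorder
    parent <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
    tc <- tied(child)
    pState <- match(out[parent], states)
    out[child] <- states[if (pState %in% tc) pState else tc[1L]]
  }
  out
}

#' Count independent origins of a focal state
#'
#' An origin is an edge whose parent is not in the focal state while
#' its child is; a root already in the focal state counts as one
#' additional origin.  As assignments are max-marginal point estimates,
#' the weakest marginal probability along each origin edge is reported
#' as a confidence caveat.
#'
#' @param tree rooted `ape::phylo`.
#' @param nodeStates character vector indexed by node number (tips and
#'   internal nodes), e.g. from [assignNodeStates()].
#' @param focal the focal state label.
#' @param recon optional [AncestralReconstruction-class] used for the
#'   confidence column.
#' @return list with `count`, `originEdges` (two-column matrix of
#'   parent/child node numbers; a focal root appears as a (0, root)
#'   row) and `minMarginal` per origin (NA without `recon`).
#' @export
countStateOrigins <- function(tree, nodeStates, focal, recon = NULL) {
  checkNodeStates(tree, nodeStates)
  root <- ape::Ntip(tree) + 1L
  pa <- nodeStates[tree$edge[, 1L]]
  ch <- nodeStates[tree$edge[, 2L]]
  hit <- which(pa != focal & ch == focal)
  edges <- tree$edge[hit, , drop = FALSE]
  if (nodeStates[root] == focal) edges <- rbind(c(0L, root), edges)
  conf <- rep(NA_real_, nrow(edges))
  if (!is.null(recon)) {
    si <- match(focal, recon@model@states)
    conf <- apply(edges, 1L, function(e)
      min(recon@marginals[e[e > 0], si]))
  }
  list(count = nrow(edges), originEdges = edges, minMarginal = conf)
}

#' Parent-to-child state transition matrix
#'
#' @inheritParams countStateOrigins
#' @param states optional state ordering for the matrix.
#' @return k x k integer matrix; entry (i, j) counts edges with parent
#'   state i and child state j; the diagonal is zero.
#' @export
countTransitions <- function(tree, nodeStates,
                             states = sort(unique(nodeStates))) {
  checkNodeStates(tree, nodeStates)
  k <- length(states)
  out <- matrix(0L, k, k, dimnames = list(states, states))
  pa <- nodeStates[tree$edge[, 1L]]
  ch <- nodeStates[tree$edge[, 2L]]
  chg <- which(pa != ch)
  for (e in chg) out[pa[e], ch[e]] <- out[pa[e], ch[e]] + 1L
  out
}

checkNodeStates <- function(tree, nodeStates) {
  n <- ape::Ntip(tree) + tree$Nnode
  if (length(nodeStates) != n || any(is.na(nodeStates)))
    stopf("nodeStates must assign a non-NA state to all %d nodes", n)
  invisible(TRUE)
}
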