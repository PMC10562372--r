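# Mk likelihood, ML rate fitting, marginal reconstruction, and
# origin/transition bookkeeping.

test_that("pruning likelihood matches enumeration on random small trees", {
  for (seed in 1:10) {
    k <- if (seed %% 2) 2L else 3L
    fx <- randomStateTree(nTips = 3L + seed %% 4L, k = k, seed = seed)
    q <- withr::with_seed(seed, runif(1, 0.05, 1.5))
    model <- MkModel(fx$states, q)
    expect_equal(mkLogLikelihood(fx$tree, fx$tipStates, model),
                 enumMkLogLik(fx$tree, fx$tipStates, model),
                 tolerance = 1e-9)
  }
  # all-rates-different generator through the same oracle
  fx <- randomStateTree(5, 3, seed = 99)
  model <- MkModel(fx$states, rates = c(0.2, 0.4, 0.1, 0.6, 0.3, 0.5),
                   parameterization = "all_rates_different")
  expect_equal(mkLogLikelihood(fx$tree, fx$tipStates, model),
               enumMkLogLik(fx$tree, fx$tipStates, model), tolerance = 1e-9)
})

test_that("zero-rate and saturation limits behave analytically", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  m0 <- MkModel(c("0", "1"), 1e-12)
  expect_equal(mkLogLikelihood(tr, c(A = "0", B = "0"), m0), log(0.5),
               tolerance = 1e-6)
  # saturation: tips become independent draws from the uniform stationary
  mInf <- MkModel(c("0", "1"), 500)
  expect_equal(mkLogLikelihood(tr, c(A = "0", B = "1"), mInf),
               2 * log(0.5), tolerance = 1e-6)
  expect_error(mkLogLikelihood(tr, c(A = "0"), m0), "leaf without state")
})

test_that("likelihood is invariant to leaf ordering", {
  fx <- randomStateTree(6, 2, seed = 3)
  model <- MkModel(fx$states, 0.4)
  ll <- mkLogLikelihood(fx$tree, fx$tipStates, model)
  perm <- sample(names(fx$tipStates))
  expect_equal(mkLogLikelihood(fx$tree, fx$tipStates[perm], model), ll)
})

test_that("ML rate fitting recovers a simulated rate and matches phytools", {
  tr <- sampleYuleTree(200, seed = 1)
  h <- simulateMkStates(tr, MkModel(c("0", "1"), 0.5)@Q, "0", seed = 2)
  fit <- fitMkModel(tr, h$tipStates)
  q <- fit@Q[1, 2]
  expect_gt(q, 0.25)
  expect_lt(q, 0.75)
  pf <- phytools::fitMk(tr, h$tipStates, model = "ER", pi = "equal")
  expect_equal(attr(fit, "logLik"), as.numeric(stats::logLik(pf)),
               tolerance = 1e-4)
  expect_equal(q, pf$rates, tolerance = 1e-3)
})

test_that("nested Mk parameterizations order their likelihoods", {
  fx <- randomStateTree(12, 2, seed = 21)
  er <- fitMkModel(fx$tree, fx$tipStates)
  ard <- fitMkModel(fx$tree, fx$tipStates,
                    parameterization = "all_rates_different")
  expect_gte(attr(ard, "logLik"), attr(er, "logLik") - 1e-6)
})

test_that("single-state data yield a boundary fit with warning", {
  tr <- sampleYuleTree(10, seed = 8)
  states <- setNames(rep("L", 10), tr$tip.label)
  expect_warning(fit <- fitMkModel(tr, states, states = c("L", "H")),
                 "boundary")
  expect_true(attr(fit, "boundary"))
})

test_that("marginal reconstructions match enumeration and sum to one", {
  fx <- randomStateTree(4, 2, seed = 13)
  model <- MkModel(fx$states, 0.3)
  rec <- marginalAncestralStates(fx$tree, fx$tipStates, model)
  expect_true(all(abs(rowSums(rec@marginals) - 1) < 1e-9))
  nt <- ape::Ntip(fx$tree)
  for (node in (nt + 1L):(nt + fx$tree$Nnode)) {
    expect_equal(unname(rec@marginals[node, ]),
                 enumMkNodeMarginal(fx$tree, fx$tipStates, model, node),
                 tolerance = 1e-9)
  }
})

test_that("state-symmetric data give an uninformative root", {
  tr <- ape::read.tree(text = "((A:1,B:1):0.5,(C:1,D:1):0.5);")
  rec <- marginalAncestralStates(tr, c(A = "0", B = "0", C = "1", D = "1"),
                                 MkModel(c("0", "1"), 0.2))
  expect_equal(unname(rec@marginals[5, ]), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("uniform slow-evolving tips pin the root state", {
  tr <- sampleYuleTree(20, seed = 17)
  states <- setNames(rep("L", 20), tr$tip.label)
  rec <- marginalAncestralStates(tr, states, MkModel(c("L", "H"), 1e-3))
  expect_gt(rec@marginals[21, "L"], 0.999)
})

test_that("node state assignment breaks ties toward the parent", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:1);")
  model <- MkModel(c("0", "1"), 0.1)
  # hand-built marginals: root certain of state 1, inner node tied
  marg <- rbind(c(1, 0), c(1, 0), c(0, 1),
                c(0.001, 0.999), c(0.5, 0.5))
  rec <- new("AncestralReconstruction", tree = tr, marginals = marg,
             model = model, logLik = -1)
  st <- assignNodeStates(rec)
  expect_identical(st[4], "1")
  expect_identical(st[5], "1")     # tie resolved to parent state
  # root tie goes to the first state
  marg2 <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0.5, 0.5), c(0.9, 0.1))
  rec2 <- new("AncestralReconstruction", tree = tr, marginals = marg2,
              model = model, logLik = -1)
  expect_identical(assignNodeStates(rec2)[4], "0")
  # clear argmax ignores the parent
  expect_identical(assignNodeStates(rec)[1], "0")
})

test_that("origin counting finds clades and focal roots", {
  tr <- ape::read.tree(text = "(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,F:1):1);")
  nt <- 6L
  # nodes: 7 root, 8 = (AB,CD) ancestor, 9 = AB, 10 = CD, 11 = EF
  statesOneClade <- c("E", "E", "F", "F", "F", "F",  # tips A..F
                      "F", "F", "E", "F", "F")
  out <- countStateOrigins(tr, statesOneClade, "E")
  expect_identical(out$count, 1L)
  statesTwoClades <- c("E", "E", "F", "F", "E", "E",
                       "F", "F", "E", "F", "E")
  out2 <- countStateOrigins(tr, statesTwoClades, "E")
  expect_identical(out2$count, 2L)
  allF <- rep("F", 11)
  expect_identical(countStateOrigins(tr, allF, "E")$count, 0L)
  # focal root counts as an origin
  allE <- rep("E", 11)
  expect_identical(countStateOrigins(tr, allE, "E")$count, 1L)
  expect_error(countStateOrigins(tr, c("E", "F"), "E"), "11 nodes")
})

test_that("transition matrix counts state-changing edges", {
  tr <- ape::read.tree(text = "(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,F:1):1);")
  states <- c("E", "E", "F", "F", "F", "L",
              "F", "F", "E", "F", "F")
  tm <- countTransitions(tr, states)
  expect_identical(tm["F", "E"], 1L)   # edge 8 -> 9
  expect_identical(tm["F", "L"], 1L)   # edge 11 -> F tip
  expect_identical(sum(tm), 2L)
  expect_true(all(diag(tm) == 0L))
  uniform <- countTransitions(tr, rep("F", 11), states = c("E", "F"))
  expect_true(all(uniform == 0L))
})

test_that("origin and transition bookkeeping agree", {
  for (seed in 1:5) {
    fx <- randomStateTree(8, 2, seed = 40 + seed)
    states <- withr::with_seed(seed,
      sample(fx$states, 8 + fx$tree$Nnode, replace = TRUE))
    focal <- fx$states[1]
    tm <- countTransitions(fx$tree, states, states = fx$states)
    org <- countStateOrigins(fx$tree, states, focal)
    root <- ape::Ntip(fx$tree) + 1L
    expect_identical(org$count,
                     sum(tm[, focal]) + as.integer(states[root] == focal))
  }
})
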