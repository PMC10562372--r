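# Seeded synthetic-data generator.  It emulates the statistical
# structure the comparative analysis assumes: an ultrametric Yule
# chronogram, discrete trait histories evolved under Mk models (deeply
# conserved, a handful of transitions per tree, as for parasitism and
# locomotory capacity in real data), a phylogram whose branch lengths
# are time x state-dependent rate multiplier x lognormal noise, and
# toy GenBank records exercising the duplicate-resolution pipeline.

#' Construct a simulation recipe
#'
#' See [SimulationConfig-class] for the meaning of each field.  The
#' life-history multipliers default to the ratios of the empirical
#' category mean branch lengths (F 1.0, MP 1.05, Parasitoid 1.44,
#' EctoP 2.34, EndoP 3.82); Mk rates default to 4 expected transitions
#' per tree; every state must reach `minStateFrac` of the tips
#' (default 2%, the order of the rarer empirical categories).
#'
#' @param nTips,birthRate tree size and Yule speciation rate.
#' @param lhtStates,locStates,rootLht,rootLoc trait vocabularies and
#'   root states.
#' @param mkRateLht,mkRateLoc Mk rates (`NA` = 4*birthRate/(nTips-1)).
#' @param multipliers named per-life-history-state rate multipliers.
#' @param baseRate,noiseSd substitution rate in the reference state and
#'   lognormal branch-segment noise sd.
#' @param minStateFrac minimum tip fraction per state.
#' @param duplicateFraction,stopFraction,translTable toy-record knobs.
#' @param seed integer seed.
#' @return a [SimulationConfig-class].
#' @export
#' @examples SimulationConfig(nTips = 50, seed = 7)
SimulationConfig <- function(nTips = 200, birthRate = 1,
                             lhtStates = c("F", "MP", "Parasitoid", "EctoP", "EndoP"),
                             locStates = c("H", "I", "L"),
                             rootLht = "F", rootLoc = "L",
                             mkRateLht = NA_real_, mkRateLoc = NA_real_,
                             multipliers = c(F = 1, MP = 1.05, Parasitoid = 1.44,
                                             EctoP = 2.34, EndoP = 3.82),
                             baseRate = 1, noiseSd = 0.3,
                             minStateFrac = 0.02,
                             duplicateFraction = 0.2, stopFraction = 0.5,
                             translTable = 5, seed = 1) {
  if (is.na(mkRateLht)) mkRateLht <- 4 * birthRate / (nTips - 1)
  if (is.na(mkRateLoc)) mkRateLoc <- 4 * birthRate / (nTips - 1)
  new("SimulationConfig", nTips = as.integer(nTips), birthRate = birthRate,
      lhtStates = lhtStates, locStates = locStates, rootLht = rootLht,
      rootLoc = rootLoc, mkRateLht = mkRateLht, mkRateLoc = mkRateLoc,
      multipliers = multipliers, baseRate = baseRate, noiseSd = noiseSd,
      minStateFrac = minStateFrac, duplicateFraction = duplicateFraction,
      stopFraction = stopFraction, translTable = as.integer(translTable),
      seed = as.integer(seed))
}

#' Simulate a Yule (pure-birth) chronogram
#'
#' @param nTips number of leaves (>= 2).
#' @param birthRate speciation rate.
#' @param seed optional seed; the same seed yields an identical tree.
#' @return rooted binary ultrametric `ape::phylo` with tip labels
#'   `t1..tn`.
#' @export
sampleYuleTree <- function(nTips, birthRate = 1, seed = NULL) {
  if (nTips < 2L) stopf("nTips must be >= 2")
  withSeed(seed, {
    tr <- ape::rphylo(nTips, birth = birthRate, death = 0)
    tr$tip.label <- paste0("t", seq_len(nTips))
    tr
  })
}

#' Evolve a discrete character along a tree
#'
#' States change by exponential waiting times under the generator `Q`
#' along every branch, root state given.  The full history (per-branch
#' state segments and events) is retained as simulation truth.
#'
#' @param tree rooted `ape::phylo` with branch lengths.
#' @param Q generator matrix with state dimnames, or an
#'   [MkModel-class].
#' @param rootState state label at the root.
#' @param seed optional seed.
#' @return list: `tipStates` (named by tip label), `nodeStates`
#'   (by ape node number), `segments` (per edge, data.frame with
#'   `state`, `duration`), `nEvents`.
#' @export
simulateMkStates <- function(tree, Q, rootState, seed = NULL) {
  assertPhylogram(tree)
  if (is(Q, "MkModel")) Q <- Q@Q
  states <- rownames(Q)
  stopifnot(!is.null(states), rootState %in% states)
  withSeed(seed, {
    nt <- ape::Ntip(tree)
    nodeStates <- character(nt + tree$Nnode)
    nodeStates[nt + 1L] <- rootState
    tr <- ape::reorder.phylo(tree, "postorder")
    nEdge <- nrow(tr$edge)
    segments <- vector("list", nEdge)
    nEvents <- 0L
    exitRates <- -diag(Q)
    # With equal exit rates the event process is state-independent, so
    # per-edge event counts can be drawn in one vectorized Poisson pass.
    erPath <- max(exitRates) - min(exitRates) <= 1e-12 * max(exitRates, 1e-300)
    counts <- if (erPath) stats::rpois(nEdge, exitRates[1L] * tr$edge.length)
              else rep(NA_integer_, nEdge)
    for (e in rev(seq_len(nEdge))) {   # preorder
      s <- nodeStates[tr$edge[e, 1L]]
      len <- tr$edge.length[e]
      if (erPath) {
        nc <- counts[e]
        if (nc == 0L) {
          segments[[e]] <- fastSegs(s, len)
        } else {
          times <- sort(runif(nc, 0, len))
          segState <- character(nc + 1L)
          segState[1L] <- s
          for (j in seq_len(nc)) {
            probs <- Q[segState[j], ]; probs[segState[j]] <- 0
            segState[j + 1L] <- sample(states, 1L, prob = probs)
          }
          segments[[e]] <- fastSegs(segState, diff(c(0, times, len)))
          s <- segState[nc + 1L]
          nEvents <- nEvents + nc
        }
      } else {
        t0 <- 0
        segState <- character(); segDur <- numeric()
        repeat {
          rate <- -Q[s, s]
          wait <- if (rate > 0) rexp(1L, rate) else Inf
          if (t0 + wait >= len) {
            segState <- c(segState, s); segDur <- c(segDur, len - t0)
            break
          }
          segState <- c(segState, s); segDur <- c(segDur, wait)
          t0 <- t0 + wait
          probs <- Q[s, ]; probs[s] <- 0
          s <- sample(states, 1L, prob = probs)
          nEvents <- nEvents + 1L
        }
        segments[[e]] <- fastSegs(segState, segDur)
      }
      nodeStates[tr$edge[e, 2L]] <- s
    }
    list(tipStates = setNames(nodeStates[seq_len(nt)], tree$tip.label),
         nodeStates = nodeStates,
         segments = segments, edge = tr$edge, nEvents = nEvents)
  })
}

#' Turn a chronogram into a phylogram with state-dependent rates
#'
#' Each branch's new length is the sum over its state segments of
#' duration x baseRate x multiplier(state) x exp(eps) with
#' eps ~ N(0, noiseSd^2) drawn independently per segment.
#'
#' @param chronogram rooted ultrametric `ape::phylo`.
#' @param history output of [simulateMkStates()] on the same tree.
#' @param multipliers named positive multipliers, one per state.
#' @param noiseSd lognormal noise sd (0 = deterministic transform).
#' @param baseRate substitutions/site per unit time in a state with
#'   multiplier 1.
#' @param seed optional seed.
#' @return an `ape::phylo` phylogram sharing the topology.
#' @export
simulatePhylogram <- function(chronogram, history, multipliers,
                              noiseSd = 0, baseRate = 1, seed = NULL) {
  stopifnot(all(multipliers > 0))
  withSeed(seed, {
    tr <- ape::reorder.phylo(chronogram, "postorder")
    newLen <- numeric(nrow(tr$edge))
    for (e in seq_len(nrow(tr$edge))) {
      seg <- history$segments[[e]]
      if (is.null(seg)) stopf("missing state segments for edge %d", e)
      m <- multipliers[seg$state]
      if (any(is.na(m)))
        stopf("segment state without multiplier: %s",
              paste(setdiff(seg$state, names(multipliers)), collapse = ", "))
      eps <- if (noiseSd > 0) rnorm(nrow(seg), 0, noiseSd) else numeric(nrow(seg))
      newLen[e] <- sum(seg$duration * baseRate * m * exp(eps))
    }
    tr$edge.length <- newLen
    tr
  })
}

# Redraw a trait history until every state covers >= minTips tips.
conditionedMkHistory <- function(tree, states, rate, rootState, minTips,
                                 maxTries = 5000L) {
  Q <- MkModel(states, rate)@Q
  for (i in seq_len(maxTries)) {
    h <- simulateMkStates(tree, Q, rootState)
    counts <- table(factor(h$tipStates, levels = states))
    if (all(counts >= minTips)) return(h)
  }
  warnf("trait history conditioning not met after %d tries; using last draw",
        maxTries)
  h
}

# Label tips by the clade they belong to at a given fraction of the
# tree height (used to fabricate phylum/class/order levels).
cladeLabels <- function(tree, frac, prefix) {
  nt <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  h <- frac * max(depth)
  tipsUnder <- vector("list", nt + tree$Nnode)
  tr <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nt)) tipsUnder[[i]] <- i
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]; c_ <- tr$edge[e, 2L]
    tipsUnder[[p]] <- c(tipsUnder[[p]], tipsUnder[[c_]])
  }
  lab <- character(nt)
  grp <- 0L
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]; c_ <- tr$edge[e, 2L]
    if (depth[p] <= h && depth[c_] > h) {
      grp <- grp + 1L
      lab[tipsUnder[[c_]]] <- sprintf("%s%02d", prefix, grp)
    }
  }
  lab[lab == ""] <- sprintf("%s%02d", prefix, 0L)  # root-adjacent leftovers
  setNames(lab, tree$tip.label)
}

#' Generate a complete benchmark dataset
#'
#' Composes [sampleYuleTree()], conditioned [simulateMkStates()] for
#' the life-history and locomotory traits, and [simulatePhylogram()],
#' and assembles a [TraitTable-class] with fabricated clade-based
#' taxonomy.  Endoparasite tips are forced into locomotory category L,
#' mirroring the empirical constraint.  Everything is deterministic
#' under `config@seed`.
#'
#' @param config a [SimulationConfig-class].
#' @param records also simulate toy GenBank records (for up to 24
#'   species) via [simulateMitogenomeRecords()].
#' @return a [SimulatedDataset-class].
#' @export
makeBenchmarkDataset <- function(config, records = FALSE) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  withSeed(config@seed, {
    chron <- sampleYuleTree(config@nTips, config@birthRate)
    minTips <- max(2L, ceiling(config@minStateFrac * config@nTips))
    lht <- conditionedMkHistory(chron, config@lhtStates, config@mkRateLht,
                                config@rootLht, minTips)
    loc <- conditionedMkHistory(chron, config@locStates, config@mkRateLoc,
                                config@rootLoc, minTips)
    phylo <- simulatePhylogram(chron, lht, config@multipliers,
                               noiseSd = config@noiseSd,
                               baseRate = config@baseRate)
    locTip <- loc$tipStates
    if ("EndoP" %in% config@lhtStates && "L" %in% config@locStates)
      locTip[lht$tipStates == "EndoP"] <- "L"
    traits <- TraitTable(data.frame(
      species = chron$tip.label,
      lht = unname(lht$tipStates[chron$tip.label]),
      loc = unname(locTip[chron$tip.label]),
      phylum = unname(cladeLabels(chron, 0.15, "Phylum")[chron$tip.label]),
      class = unname(cladeLabels(chron, 0.45, "Class")[chron$tip.label]),
      order = unname(cladeLabels(chron, 0.70, "Order")[chron$tip.label]),
      basis = "simulated", stringsAsFactors = FALSE))
    gb <- if (records)
      simulateMitogenomeRecords(min(config@nTips, 24L),
                                duplicateFraction = config@duplicateFraction,
                                stopFraction = config@stopFraction,
                                translTable = config@translTable)
    else list(text = character(), truth = list())
    truth <- list(multipliers = config@multipliers,
                  baseRate = config@baseRate, noiseSd = config@noiseSd,
                  mkRateLht = config@mkRateLht, mkRateLoc = config@mkRateLoc,
                  lhtNodeStates = lht$nodeStates, locNodeStates = loc$nodeStates,
                  lhtHistory = lht, locHistory = loc,
                  records = gb$truth)
    new("SimulatedDataset", chronogram = chron, phylogram = phylo,
        traits = traits, truth = truth, records = gb$text)
  })
}

#' Write a simulated dataset to standard-format files
#'
#' @param dataset a [SimulatedDataset-class].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(chronogram = file.path(dir, "chronogram.nwk"),
             phylogram = file.path(dir, "phylogram.nwk"),
             traits = file.path(dir, "traits.tsv"),
             truth = file.path(dir, "truth.json"))
  ape::write.tree(dataset@chronogram, paths["chronogram"])
  ape::write.tree(dataset@phylogram, paths["phylogram"])
  writeTraitTable(dataset@traits, paths["traits"])
  tr <- dataset@truth
  slim <- list(multipliers = as.list(tr$multipliers), baseRate = tr$baseRate,
               noiseSd = tr$noiseSd, mkRateLht = tr$mkRateLht,
               mkRateLoc = tr$mkRateLoc, lhtNodeStates = tr$lhtNodeStates,
               locNodeStates = tr$locNodeStates)
  jsonlite::write_json(slim, paths["truth"], auto_unbox = TRUE, digits = NA)
  if (length(dataset@records)) {
    paths["records"] <- file.path(dir, "records.gb")
    writeLines(dataset@records, paths["records"])
  }
  invisible(paths)
}
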