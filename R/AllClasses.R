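setOldClass("phylo")

#' MitogenomeRecord: one parsed mitogenome flatfile entry
#'
#' Container for a single GenBank-style mitogenome record.  Features are
#' held as a data.frame with one row per CDS: columns `gene` (raw or
#' canonical symbol), `canonical` (logical: is the symbol one of the 13
#' mitochondrial protein-coding genes), `start`, `end` (1-based
#' inclusive), `strand` (`"+"`/`"-"`), `translTable` (NCBI genetic-code
#' id) and `sequence` (nucleotides already in coding orientation, i.e.
#' reverse-complemented for minus-strand CDS).
#'
#' @slot accession single accession string.
#' @slot organism organism binomial as given in the record.
#' @slot taxonomy ordered lineage, most inclusive rank (phylum) first;
#'   does not include the species itself.
#' @slot features data.frame of CDS features (see Description).
#' @slot isAnnotated `FALSE` when the entry carried no feature table.
#' @exportClass MitogenomeRecord
setClass("MitogenomeRecord",
  representation(
    accession = "character",
    organism = "character",
    taxonomy = "character",
    features = "data.frame",
    isAnnotated = "logical"
  ),
  prototype(
    accession = NA_character_, organism = NA_character_,
    taxonomy = character(), features = emptyFeatureTable(),
    isAnnotated = FALSE
  )
)

setValidity("MitogenomeRecord", function(object) {
  msg <- character()
  if (length(object@accession) != 1L) msg <- c(msg, "accession must be length 1")
  f <- object@features
  need <- c("gene", "canonical", "start", "end", "strand", "translTable", "sequence")
  if (!all(need %in% names(f))) {
    msg <- c(msg, paste0("features lacks columns: ",
                         paste(setdiff(need, names(f)), collapse = ", ")))
  } else if (nrow(f)) {
    if (any(f$start > f$end)) msg <- c(msg, "feature with start > end")
    if (!all(f$strand %in% c("+", "-"))) msg <- c(msg, "strand must be '+' or '-'")
  }
  if (object@isAnnotated && length(object@taxonomy) == 0L)
    msg <- c(msg, "annotated record must carry a taxonomy")
  if (length(msg)) msg else TRUE
})

#' RateTable: per-species root-to-tip branch lengths
#'
#' One evolutionary-rate proxy (`brl`, the root-to-tip branch length of
#' the phylogram, substitutions/site) per species.
#'
#' @slot brl named numeric vector, names are species identifiers.
#' @exportClass RateTable
setClass("RateTable", representation(brl = "numeric"))

setValidity("RateTable", function(object) {
  x <- object@brl
  msg <- character()
  if (is.null(names(x)) || anyDuplicated(names(x)) || any(!nzchar(names(x))))
    msg <- c(msg, "brl must have unique non-empty species names")
  if (length(x) && (any(!is.finite(x)) || any(x < 0)))
    msg <- c(msg, "brl values must be finite and non-negative")
  if (length(msg)) msg else TRUE
})

#' TraitTable: life-history and locomotory classifications
#'
#' Species-level discrete classifications plus taxonomy.  Columns:
#' `species`, `lht` (one of F, EndoP, EctoP, Parasitoid, MP), `loc`
#' (H, I, L), `phylum`, `class`, `order`, `excluded` (logical),
#' `reason`, `basis` (free-text provenance, never computed on).
#'
#' @slot data the underlying data.frame.
#' @exportClass TraitTable
setClass("TraitTable", representation(data = "data.frame"))

setValidity("TraitTable", function(object) {
  d <- object@data
  need <- c("species", "lht", "loc", "phylum", "class", "order",
            "excluded", "reason", "basis")
  msg <- character()
  if (!all(need %in% names(d)))
    msg <- c(msg, paste0("missing columns: ",
                         paste(setdiff(need, names(d)), collapse = ", ")))
  else {
    if (anyDuplicated(d$species)) msg <- c(msg, "duplicated species")
    if (!is.logical(d$excluded)) msg <- c(msg, "excluded must be logical")
  }
  if (length(msg)) msg else TRUE
})

#' MkModel: continuous-time Markov model for a discrete character
#'
#' @slot states state labels, length k.
#' @slot Q k x k generator; rows sum to zero, off-diagonals >= 0.
#' @slot parameterization `"equal_rates"` or `"all_rates_different"`.
#' @slot rootPrior probability vector over states (sums to 1).
#' @exportClass MkModel
setClass("MkModel",
  representation(states = "character", Q = "matrix",
                 parameterization = "character", rootPrior = "numeric"))

setValidity("MkModel", function(object) {
  k <- length(object@states)
  Q <- object@Q
  msg <- character()
  if (!all(dim(Q) == c(k, k))) msg <- c(msg, "Q must be k x k")
  else {
    if (any(Q[row(Q) != col(Q)] < 0)) msg <- c(msg, "off-diagonal Q entries must be >= 0")
    if (any(abs(rowSums(Q)) > 1e-8 * max(1, max(abs(Q)))))
      msg <- c(msg, "Q rows must sum to 0")
  }
  if (length(object@rootPrior) != k || abs(sum(object@rootPrior) - 1) > 1e-8)
    msg <- c(msg, "rootPrior must be a length-k probability vector")
  if (!object@parameterization %in% c("equal_rates", "all_rates_different"))
    msg <- c(msg, "unknown parameterization")
  if (length(msg)) msg else TRUE
})

#' AncestralReconstruction: marginal ancestral state probabilities
#'
#' @slot tree the rooted phylogram the reconstruction was computed on.
#' @slot marginals (Ntip + Nnode) x k matrix of marginal state
#'   probabilities, rows indexed like `ape` node numbers.
#' @slot model the [MkModel-class] used.
#' @slot logLik log-likelihood of the tip data under the model.
#' @exportClass AncestralReconstruction
setClass("AncestralReconstruction",
  representation(tree = "phylo", marginals = "matrix",
                 model = "MkModel", logLik = "numeric"))

setValidity("AncestralReconstruction", function(object) {
  m <- object@marginals
  if (any(abs(rowSums(m) - 1) > 1e-9))
    return("marginal probabilities must sum to 1 at every node")
  TRUE
})

#' PhyloModelFit: ML fit of the kinship phylogenetic linear mixed model
#'
#' The model is y = X beta + g + e with g ~ N(0, sigmaG2 * K) for a
#' tree-derived kinship matrix K and e ~ N(0, sigmaE2 * I), fitted by
#' maximum likelihood.  `df` follows the bookkeeping used for model
#' comparison tables: number of fixed effects (incl. intercept) + 2
#' variance components.
#'
#' @slot beta named fixed-effect estimates (treatment coding).
#' @slot se standard errors of `beta`.
#' @slot sigmaG2 phylogenetic variance component.
#' @slot sigmaE2 residual variance component.
#' @slot logLik maximized ML log-likelihood.
#' @slot df parameter count (fixed effects + 2).
#' @slot aic 2 * df - 2 * logLik.
#' @slot n number of species.
#' @slot boundary TRUE when the variance-ratio optimizer stopped at a
#'   search boundary (e.g. sigmaG2 ~ 0: phylogenetic signal
#'   unidentifiable).
#' @slot label human-readable model formula label.
#' @exportClass PhyloModelFit
setClass("PhyloModelFit",
  representation(beta = "numeric", se = "numeric", sigmaG2 = "numeric",
                 sigmaE2 = "numeric", logLik = "numeric", df = "integer",
                 aic = "numeric", n = "integer", boundary = "logical",
                 label = "character"))

setValidity("PhyloModelFit", function(object) {
  msg <- character()
  if (object@sigmaG2 < 0 || object@sigmaE2 < 0)
    msg <- c(msg, "variance components must be non-negative")
  if (abs(object@aic - (2 * object@df - 2 * object@logLik)) > 1e-6)
    msg <- c(msg, "aic must equal 2*df - 2*logLik")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: recipe for a synthetic comparative dataset
#'
#' Defaults emulate the empirical study conditions: deeply conserved
#' clade-level traits (about four expected state transitions per tree),
#' every category reaching at least 8% of tips, and life-history rate
#' multipliers equal to the ratios of the reported category mean branch
#' lengths (F 1.0, MP 1.05, Parasitoid 1.44, EctoP 2.34, EndoP 3.82).
#'
#' @slot nTips number of species in the tree.
#' @slot birthRate Yule speciation rate (per unit time).
#' @slot lhtStates,locStates category labels for the two traits.
#' @slot rootLht,rootLoc root states.
#' @slot mkRateLht,mkRateLoc Mk transition rates; `NA` means the
#'   default 4 * birthRate / (nTips - 1), i.e. ~4 expected transitions.
#' @slot multipliers per-life-history-state branch-rate multipliers.
#' @slot baseRate substitutions/site per unit time in the baseline state.
#' @slot noiseSd sd of the lognormal branch-segment rate noise.
#' @slot minStateFrac minimum fraction of tips required in every trait
#'   state (trait histories are redrawn until satisfied).
#' @slot duplicateFraction,stopFraction,translTable toy mitogenome
#'   record generation: fraction of species with a duplicated gene, and
#'   fraction of those duplicates carrying internal stop codons.
#' @slot seed integer seed fixing every draw.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(nTips = "integer", birthRate = "numeric",
                 lhtStates = "character", locStates = "character",
                 rootLht = "character", rootLoc = "character",
                 mkRateLht = "numeric", mkRateLoc = "numeric",
                 multipliers = "numeric", baseRate = "numeric",
                 noiseSd = "numeric", minStateFrac = "numeric",
                 duplicateFraction = "numeric", stopFraction = "numeric",
                 translTable = "integer", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nTips < 2L) msg <- c(msg, "nTips must be >= 2")
  if (object@birthRate <= 0) msg <- c(msg, "birthRate must be > 0")
  if (any(object@multipliers <= 0)) msg <- c(msg, "multipliers must be > 0")
  if (!setequal(names(object@multipliers), object@lhtStates))
    msg <- c(msg, "multipliers must be named by lhtStates")
  if (!object@rootLht %in% object@lhtStates) msg <- c(msg, "rootLht not in lhtStates")
  if (!object@rootLoc %in% object@locStates) msg <- c(msg, "rootLoc not in locStates")
  if (object@duplicateFraction < 0 || object@duplicateFraction > 1 ||
      object@stopFraction < 0 || object@stopFraction > 1)
    msg <- c(msg, "fractions must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' SimulatedDataset: a complete synthetic comparative dataset
#'
#' @slot chronogram ultrametric Yule tree (time units).
#' @slot phylogram same topology, branch lengths in expected
#'   substitutions/site after state-dependent rate multipliers and
#'   lognormal noise.
#' @slot traits the [TraitTable-class] covering every tip.
#' @slot truth list with the generating parameters, node states and
#'   per-branch state histories needed to score recovery.
#' @slot records toy GenBank flatfile text (`character(0)` when records
#'   were not simulated).
#' @exportClass SimulatedDataset
setClass("SimulatedDataset",
  representation(chronogram = "phylo", phylogram = "phylo",
                 traits = "TraitTable", truth = "list",
                 records = "character"))
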