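#' @name accessors
#' @title Accessors for mitoRates classes
#'
#' @description `brl()` returns the named vector of root-to-tip branch
#' lengths of a [RateTable-class]; `traitData()` the underlying
#' data.frame of a [TraitTable-class] (excluded species included; use
#' [activeSpecies()] for the analysis set).
#'
#' @param x a RateTable or TraitTable.
#' @return `brl()`: named numeric; `traitData()`: data.frame;
#'   `activeSpecies()`: character vector of non-excluded species.
#' @aliases brl traitData activeSpecies
#' @examples
#' rt <- rootToTipLengths(ape::read.tree(text = "((A:1,B:3):0.5,C:2);"))
#' brl(rt)
NULL

#' @rdname accessors
#' @export
setGeneric("brl", function(x) standardGeneric("brl"))

#' @rdname accessors
#' @export
setMethod("brl", "RateTable", function(x) x@brl)

#' @rdname accessors
#' @export
setGeneric("traitData", function(x) standardGeneric("traitData"))

#' @rdname accessors
#' @export
setMethod("traitData", "TraitTable", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("activeSpecies", function(x) standardGeneric("activeSpecies"))

#' @rdname accessors
#' @export
setMethod("activeSpecies", "TraitTable",
          function(x) x@data$species[!x@data$excluded])

#' @rdname accessors
#' @param row.names,optional unused, present for generic compatibility.
#' @param ... unused.
NULL

#' Display methods
#'
#' Compact console summaries for the package's S4 classes.
#'
#' @param object the object to display.
#' @return invisibly, `NULL`; called for the side effect of printing.
#' @name show-methods
#' @keywords internal
NULL

#' @rdname show-methods
#' @export
setMethod("show", "MitogenomeRecord", function(object) {
  cat("MitogenomeRecord", object@accession, "-", object@organism, "\n")
  cat("  ", nrow(object@features), "CDS feature(s);",
      if (object@isAnnotated) "annotated" else "UNANNOTATED", "\n")
  pcg <- object@features$gene[object@features$canonical]
  if (length(pcg)) cat("  PCGs:", paste(sort(unique(pcg)), collapse = " "), "\n")
})

#' @rdname show-methods
#' @export
setMethod("show", "RateTable", function(object) {
  x <- object@brl
  cat("RateTable with", length(x), "species\n")
  cat(sprintf("  brl: mean %.4g, range [%.4g, %.4g]\n",
              mean(x), min(x), max(x)))
})

#' @rdname show-methods
#' @export
setMethod("show", "TraitTable", function(object) {
  d <- object@data
  cat("TraitTable:", nrow(d), "species (", sum(d$excluded), "excluded )\n")
  cat("  LHT:", paste(names(table(d$lht)), table(d$lht), collapse = ", "), "\n")
  cat("  LOC:", paste(names(table(d$loc)), table(d$loc), collapse = ", "), "\n")
})

#' @rdname show-methods
#' @export
setMethod("show", "MkModel", function(object) {
  cat("MkModel (", object@parameterization, ") on states:",
      paste(object@states, collapse = ", "), "\n")
  cat("  off-diagonal rate(s):",
      paste(signif(unique(object@Q[row(object@Q) != col(object@Q)]), 4),
            collapse = ", "), "\n")
})

#' @rdname show-methods
#' @export
setMethod("show", "AncestralReconstruction", function(object) {
  cat("AncestralReconstruction over", nrow(object@marginals), "nodes,",
      ncol(object@marginals), "states; logLik =",
      format(object@logLik, digits = 6), "\n")
  root <- ape::Ntip(object@tree) + 1L
  cat("  root marginals:",
      paste(sprintf("%s=%.4f", object@model@states, object@marginals[root, ]),
            collapse = " "), "\n")
})

#' @rdname show-methods
#' @export
setMethod("show", "PhyloModelFit", function(object) {
  cat("PhyloModelFit:", object@label, " (n =", object@n, ")\n")
  cat(sprintf("  logLik %.3f  DF %d  AIC %.3f%s\n", object@logLik,
              object@df, object@aic,
              if (object@boundary) "  [boundary]" else ""))
  cat(sprintf("  sigma2_g %.4g  sigma2_e %.4g\n", object@sigmaG2, object@sigmaE2))
  print(round(cbind(Estimate = object@beta, SE = object@se), 4))
})

#' @rdname show-methods
#' @export
setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nTips, "tips, seed", object@seed, "\n")
  cat("  multipliers:",
      paste(sprintf("%s=%.3g", names(object@multipliers), object@multipliers),
            collapse = " "), "\n")
})

#' @rdname show-methods
#' @export
setMethod("show", "SimulatedDataset", function(object) {
  cat("SimulatedDataset:", ape::Ntip(object@phylogram), "tips;",
      length(object@records), "line(s) of toy GenBank text\n")
})

#' @describeIn accessors coerce a RateTable to a two-column data.frame.
#' @export
setMethod("as.data.frame", "RateTable", function(x, ...) {
  data.frame(species = names(x@brl), brl = unname(x@brl),
             stringsAsFactors = FALSE)
})

#' @describeIn accessors coerce a TraitTable to its data.frame.
#' @export
setMethod("as.data.frame", "TraitTable", function(x, ...) x@data)

#' Extract model coefficients / log-likelihood from a PhyloModelFit
#'
#' @param object a [PhyloModelFit-class].
#' @param ... ignored.
#' @return `coef()`: named numeric vector of fixed effects; `logLik()`:
#'   an object of class "logLik" with the model's parameter count as df.
#' @export
setMethod("coef", "PhyloModelFit", function(object, ...) object@beta)

#' @rdname coef-PhyloModelFit-method
#' @export
setMethod("logLik", "PhyloModelFit", function(object, ...) {
  structure(object@logLik, df = object@df, nobs = object@n, class = "logLik")
})
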