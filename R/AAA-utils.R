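# Internal helpers shared across modules.  This file sorts first so the
# class prototypes in AllClasses.R can use emptyFeatureTable().

emptyFeatureTable <- function() {
  data.frame(gene = character(), canonical = logical(),
             start = integer(), end = integer(), strand = character(),
             translTable = integer(), sequence = character(),
             stringsAsFactors = FALSE)
}

# Run expr under a fixed seed without disturbing the caller's RNG
# state; seed = NULL uses (and advances) the current stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Rooted-with-lengths check used by everything consuming a phylogram.
assertPhylogram <- function(tree, what = "tree") {
  if (!inherits(tree, "phylo")) stopf("%s must be an ape 'phylo' object", what)
  if (!ape::is.rooted(tree)) stopf("%s must be rooted", what)
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge))
    stopf("%s must carry a branch length on every edge", what)
  if (any(!is.finite(tree$edge.length))) stopf("%s has non-finite branch lengths", what)
  if (any(tree$edge.length < 0)) stopf("%s has negative branch lengths", what)
  if (anyDuplicated(tree$tip.label)) stopf("%s has duplicated tip labels", what)
  invisible(tree)
}

# Minimal-overhead data.frame constructor for per-edge state segments
# (called hundreds of thousands of times during conditioned draws).
fastSegs <- function(state, duration) {
  structure(list(state = state, duration = duration),
            class = "data.frame", row.names = seq_along(state))
}
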