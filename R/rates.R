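# Root-to-tip branch lengths as per-species rate proxies.  On a
# phylogram whose tips are contemporaneous taxa, the root-to-tip path
# length (brl) measures the expected number of substitutions per site
# accumulated by that lineage, i.e. its average molecular rate.

#' Root-to-tip branch lengths
#'
#' Sums branch lengths along the unique root-to-leaf path of a rooted
#' phylogram for every leaf.
#'
#' @param tree a rooted `ape::phylo` with a branch length on every edge.
#' @return a [RateTable-class].
#' @export
#' @examples
#' brl(rootToTipLengths(ape::read.tree(text = "((A:1,B:3):0.5,C:2);")))
rootToTipLengths <- function(tree) {
  assertPhylogram(tree)
  depth <- ape::node.depth.edgelength(tree)   # root = 0
  new("RateTable", brl = setNames(depth[seq_len(ape::Ntip(tree))],
                                  tree$tip.label))
}

#' Long-branch threshold: twice the mean branch length
#'
#' @param rates a [RateTable-class] or named numeric vector of brl.
#' @return list with `threshold` (2 x mean brl), `meanBrl`, and
#'   `exceeders` (species above the threshold).
#' @export
#' @examples
#' longBranchThreshold(setNames(c(1, 2, 3), c("a", "b", "c")))
longBranchThreshold <- function(rates) {
  x <- if (is(rates, "RateTable")) brl(rates) else rates
  if (!length(x)) stopf("rate table is empty")
  thr <- 2 * mean(x)
  list(threshold = thr, meanBrl = mean(x),
       exceeders = names(x)[x > thr])
}

#' Flag outliers by the 1.5 x IQR boxplot rule
#'
#' Quartiles are Tukey hinges (the convention of boxplot statistics);
#' a value is flagged when it lies below Q1 - k*IQR or above
#' Q3 + k*IQR.
#'
#' @param values numeric vector, length >= 4.
#' @param k fence multiplier (default 1.5).
#' @return logical vector of flags, same length and names as `values`.
#' @export
#' @examples flagOutliersIQR(c(1, 2, 3, 4, 100))
flagOutliersIQR <- function(values, k = 1.5) {
  if (length(values) < 4L) stopf("need at least 4 values")
  if (any(!is.finite(values))) stopf("values must be finite")
  f <- fivenum(values)
  q1 <- f[2]; q3 <- f[4]
  iqr <- q3 - q1
  values < q1 - k * iqr | values > q3 + k * iqr
}

#' Per-category summary of branch lengths
#'
#' @param rates a [RateTable-class] or named numeric vector.
#' @param labels named character vector: species -> category.  Every
#'   species in `rates` must be labelled.
#' @return data.frame with columns category, n, mean, sd (sd is NA for
#'   singleton categories).
#' @export
groupSummary <- function(rates, labels) {
  x <- if (is(rates, "RateTable")) brl(rates) else rates
  missing <- setdiff(names(x), names(labels))
  if (length(missing))
    stopf("unlabelled species: %s", paste(head(missing, 10), collapse = ", "))
  g <- factor(labels[names(x)])
  out <- data.frame(
    category = levels(g),
    n = as.integer(table(g)),
    mean = as.numeric(tapply(x, g, mean)),
    sd = as.numeric(tapply(x, g, function(v) if (length(v) > 1L) sd(v) else NA_real_)),
    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Correlation between two rate tables
#'
#' Pearson correlation of brl over the species shared by two trees'
#' rate tables; used to check robustness of root-to-tip lengths to the
#' tree-building protocol.
#'
#' @param a,b [RateTable-class] objects (or named numeric vectors).
#' @return Pearson r, with attribute `nShared`.
#' @export
rateVectorCorrelation <- function(a, b) {
  xa <- if (is(a, "RateTable")) brl(a) else a
  xb <- if (is(b, "RateTable")) brl(b) else b
  shared <- intersect(names(xa), names(xb))
  if (length(shared) < 3L) stopf("fewer than 3 shared species")
  r <- cor(xa[shared], xb[shared])
  attr(r, "nShared") <- length(shared)
  r
}

#' Write a rate table (with outlier flags) to TSV
#'
#' @param rates a [RateTable-class].
#' @param file output path.
#' @param k fence multiplier passed to [flagOutliersIQR()].
#' @return invisibly, the data.frame written.
#' @export
writeRateTable <- function(rates, file, k = 1.5) {
  d <- as.data.frame(rates)
  d$outlier <- if (nrow(d) >= 4L) flagOutliersIQR(d$brl, k) else FALSE
  write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(d)
}
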