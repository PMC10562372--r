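# Fixture builders shared across test files.  Everything is generated
# in code; no binary fixtures.

# Minimal record constructor mirroring the parser output.
makeFeature <- function(gene, start, end, sequence, strand = "+",
                        translTable = 5L) {
  data.frame(gene = gene, canonical = gene %in% pcgGenes(),
             start = as.integer(start), end = as.integer(end), strand = strand,
             translTable = translTable, sequence = sequence,
             stringsAsFactors = FALSE)
}

makeRecord <- function(accession, organism = "Genus01 species01",
                       taxonomy = c("Synthozoa", "Phylum01", "Class01",
                                    "Order01", "Genus01"),
                       features = NULL, isAnnotated = !is.null(features)) {
  if (is.null(features))
    features <- mitoRates:::emptyFeatureTable()
  new("MitogenomeRecord", accession = accession, organism = organism,
      taxonomy = taxonomy, features = features, isAnnotated = isAnnotated)
}

# Concatenate codons, avoiding stop codons of table 5 (TAA/TAG).
orf <- function(...) paste(c(...), collapse = "")

smallTraitTable <- function() {
  TraitTable(data.frame(
    species = paste0("s", 1:10),
    lht = c("F", "F", "F", "MP", "Parasitoid", "EctoP", "EctoP",
            "EndoP", "EndoP", "EndoP"),
    loc = c("H", "I", "L", "H", "H", "H", "L", "L", "L", "L"),
    phylum = c(rep("PhylumA", 5), rep("PhylumB", 5)),
    class = "ClassX", order = "OrderX", stringsAsFactors = FALSE))
}

randomStateTree <- function(nTips, k, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(nTips)
    states <- as.character(seq_len(k) - 1L)
    tips <- setNames(sample(states, nTips, replace = TRUE), tr$tip.label)
    # ensure at least two states present where possible
    if (length(unique(tips)) < 2L && nTips >= 2L)
      tips[1:2] <- states[1:2]
    list(tree = tr, tipStates = tips, states = states)
  })
}
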