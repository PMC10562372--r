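# Toy mitogenome flatfile generator.  Records carry 13 clean
# protein-coding ORFs; a chosen fraction of species receive a
# duplicated gene whose surplus copy is either stop-codon-broken or
# heavily diverged, so that the resolution rules (stop_codon /
# conservation / tie_break) can be scored against known truth.
# Species come in two-species genera so a genus-level reference
# ortholog always exists.

pcgCodonLengths <- function() {
  c(atp6 = 75, atp8 = 50, cox1 = 120, cox2 = 90, cox3 = 85, cytb = 110,
    nad1 = 95, nad2 = 100, nad3 = 60, nad4 = 115, nad4l = 55,
    nad5 = 130, nad6 = 65)
}

sampleCleanOrf <- function(nCodons, code) {
  nonStop <- names(code)[code != "*"]
  body <- sample(nonStop, nCodons - 2L, replace = TRUE)
  paste(c("ATG", body, names(code)[code == "*"][1L]), collapse = "")
}

# Replace a fraction of internal codons with random non-stop codons.
mutateOrf <- function(orf, prob, code) {
  nonStop <- names(code)[code != "*"]
  cod <- substring(orf, seq(1L, nchar(orf) - 2L, by = 3L),
                   seq(3L, nchar(orf), by = 3L))
  n <- length(cod)
  hit <- which(runif(n - 2L) < prob) + 1L   # never start / terminal stop
  cod[hit] <- sample(nonStop, length(hit), replace = TRUE)
  paste(cod, collapse = "")
}

injectInternalStops <- function(orf, code, nStops = 2L) {
  stops <- names(code)[code == "*"]
  cod <- substring(orf, seq(1L, nchar(orf) - 2L, by = 3L),
                   seq(3L, nchar(orf), by = 3L))
  pos <- sample(seq(2L, length(cod) - 1L), min(nStops, length(cod) - 2L))
  cod[pos] <- sample(stops, length(pos), replace = TRUE)
  paste(cod, collapse = "")
}

formatOrigin <- function(seq) {
  n <- nchar(seq)
  starts <- seq(1L, n, by = 60L)
  vapply(starts, function(s) {
    chunk <- substr(seq, s, min(s + 59L, n))
    grps <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, by = 10L), nchar(chunk)))
    sprintf("%9d %s", s, tolower(paste(grps, collapse = " ")))
  }, character(1))
}

formatGenBankEntry <- function(accession, organism, lineage, features,
                               sequence) {
  out <- c(
    sprintf("LOCUS       %s%16d bp    DNA     circular INV 01-JAN-2026",
            accession, nchar(sequence)),
    sprintf("DEFINITION  %s mitochondrion, complete genome (synthetic).",
            organism),
    sprintf("ACCESSION   %s", accession),
    sprintf("SOURCE      %s", organism),
    sprintf("  ORGANISM  %s", organism),
    sprintf("            %s.", paste(lineage, collapse = "; ")))
  if (!is.null(features) && nrow(features)) {
    out <- c(out, "FEATURES             Location/Qualifiers",
             sprintf("     source          1..%d", nchar(sequence)))
    for (i in seq_len(nrow(features))) {
      loc <- sprintf("%d..%d", features$start[i], features$end[i])
      if (features$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      out <- c(out,
               sprintf("     CDS             %s", loc),
               sprintf("                     /gene=\"%s\"", features$gene[i]),
               sprintf("                     /transl_table=%d",
                       features$translTable[i]))
    }
  }
  c(out, "ORIGIN", formatOrigin(sequence), "//")
}

#' Simulate toy GenBank mitogenome records with known curation truth
#'
#' Every species carries clean ORFs for the 13 protein-coding genes
#' (nad6 on the minus strand).  `duplicateFraction` of the species (at
#' most one per genus) receive a second copy of one gene:
#' `stopFraction` of those surplus copies get internal stop codons
#' (resolvable by the stop-codon rule), the rest are heavily diverged
#' copies (resolvable by conservation against the sister species).
#' Optional planted records exercise the dataset filters.
#'
#' @param nSpecies number of ordinary species records.
#' @param duplicateFraction fraction of species with a duplicated gene.
#' @param stopFraction fraction of duplicates carrying internal stops.
#' @param translTable NCBI genetic-code id used for every CDS.
#' @param seed optional seed.
#' @param nUnannotated,nHybrids,nIdenticalPairs extra planted records
#'   that [applyDatasetFilters()] must remove.
#' @return list with `text` (flatfile lines) and `truth`:
#'   `duplicates` (accession, gene, case, keep, remove — feature ids as
#'   `gene@start-end`) and `filters` (accession, rule).
#' @export
#' @examples
#' gb <- simulateMitogenomeRecords(4, duplicateFraction = 0.5, seed = 1)
#' length(readGenBankRecords(gb$text))
simulateMitogenomeRecords <- function(nSpecies, duplicateFraction = 0.2,
                                      stopFraction = 0.5, translTable = 5,
                                      seed = NULL, nUnannotated = 0L,
                                      nHybrids = 0L, nIdenticalPairs = 0L) {
  stopifnot(duplicateFraction >= 0, duplicateFraction <= 1,
            stopFraction >= 0, stopFraction <= 1, nSpecies >= 1)
  code <- geneticCode(translTable)
  lens <- pcgCodonLengths()
  withSeed(seed, {
    nGenera <- ceiling(nSpecies / 2)
    genusBase <- lapply(seq_len(nGenera), function(g)
      vapply(names(lens), function(gn) sampleCleanOrf(lens[[gn]], code),
             character(1)))
    # duplicates only in complete two-species genera so a genus-level
    # reference ortholog (the sister species) always exists
    fullGenera <- which(2L * seq_len(nGenera) <= nSpecies)
    nDup <- min(round(duplicateFraction * nSpecies), length(fullGenera))
    dupGenera <- if (nDup) sample(fullGenera, nDup) else integer()
    dupSpecies <- vapply(dupGenera, function(g)
      sample(c(2L * g - 1L, 2L * g), 1L), integer(1))
    nStopCases <- round(stopFraction * nDup)
    stopCase <- rep(FALSE, nDup)
    if (nStopCases) stopCase[sample(nDup, nStopCases)] <- TRUE

    dupTruth <- data.frame(accession = character(), gene = character(),
                           case = character(), keep = character(),
                           remove = character(), stringsAsFactors = FALSE)
    filtTruth <- data.frame(accession = character(), rule = character(),
                            stringsAsFactors = FALSE)
    text <- character()
    keptEntries <- list()   # accession -> list(features, seq, organism, lineage)

    buildGenome <- function(genes, strands) {
      spacer <- function() paste(sample(c("A", "C", "G", "T"), 20L,
                                        replace = TRUE), collapse = "")
      pos <- 1L
      seqParts <- character()
      feat <- data.frame(gene = character(), start = integer(),
                         end = integer(), strand = character(),
                         translTable = integer(), stringsAsFactors = FALSE)
      for (i in seq_along(genes)) {
        sp <- spacer()
        seqParts <- c(seqParts, sp)
        pos <- pos + nchar(sp)
        coding <- genes[[i]]
        genomic <- if (strands[i] == "-") revComp(coding) else coding
        feat <- rbind(feat, data.frame(
          gene = names(genes)[i], start = pos,
          end = pos + nchar(genomic) - 1L, strand = strands[i],
          translTable = as.integer(translTable), stringsAsFactors = FALSE))
        seqParts <- c(seqParts, genomic)
        pos <- pos + nchar(genomic)
      }
      list(sequence = paste(seqParts, collapse = ""), features = feat)
    }

    for (i in seq_len(nSpecies)) {
      g <- ceiling(i / 2)
      acc <- sprintf("SYN%05d", i)
      organism <- sprintf("Genus%02d species%02d", g, i)
      lineage <- c("Synthozoa", sprintf("Phylum%02d", (g - 1L) %/% 4L + 1L),
                   sprintf("Class%02d", (g - 1L) %/% 2L + 1L),
                   sprintf("Order%02d", g), sprintf("Genus%02d", g))
      myGenes <- lapply(genusBase[[g]], mutateOrf, prob = 0.04, code = code)
      names(myGenes) <- names(lens)
      strands <- ifelse(names(myGenes) == "nad6", "-", "+")
      geneList <- myGenes
      di <- match(i, dupSpecies)
      if (!is.na(di)) {
        gn <- sample(names(lens), 1L)
        good <- myGenes[[gn]]
        bad <- if (stopCase[di]) injectInternalStops(good, code)
               else mutateOrf(genusBase[[g]][[gn]], prob = 0.5, code = code)
        badFirst <- runif(1L) < 0.5
        if (badFirst) geneList[[gn]] <- bad else geneList[[gn]] <- good
        extra <- list(if (badFirst) good else bad)
        names(extra) <- gn
        geneList <- c(geneList, extra)
        strands <- c(strands, "+")
      }
      gen <- buildGenome(geneList, strands)
      if (!is.na(di)) {
        gn <- names(geneList)[length(geneList)]
        rows <- which(gen$features$gene == gn)
        fid <- sprintf("%s@%d-%d", gn, gen$features$start[rows],
                       gen$features$end[rows])
        goodRow <- if (badFirst) 2L else 1L
        dupTruth <- rbind(dupTruth, data.frame(
          accession = acc, gene = gn,
          case = if (stopCase[di]) "stop_codon" else "conservation",
          keep = fid[goodRow], remove = fid[-goodRow],
          stringsAsFactors = FALSE))
      }
      keptEntries[[acc]] <- list(features = gen$features, seq = gen$sequence,
                                 organism = organism, lineage = lineage)
      text <- c(text, formatGenBankEntry(acc, organism, lineage,
                                         gen$features, gen$sequence))
    }

    for (u in seq_len(nUnannotated)) {
      acc <- sprintf("SYNU%04d", u)
      seq <- paste(sample(c("A", "C", "G", "T"), 600L, replace = TRUE),
                   collapse = "")
      text <- c(text, formatGenBankEntry(acc, sprintf("Unknownus ignotus%d", u),
                                         c("Synthozoa"), NULL, seq))
      filtTruth <- rbind(filtTruth, data.frame(accession = acc,
                                               rule = "unannotated"))
    }
    for (h in seq_len(nHybrids)) {
      acc <- sprintf("SYNH%04d", h)
      donor <- keptEntries[[sprintf("SYN%05d", 1L + (h - 1L) %% nSpecies)]]
      org <- sprintf("Genus%02d speciesA x Genus%02d speciesB", h, h)
      feats <- donor$features
      # perturb one gene so the hybrid is not also an identical duplicate
      text <- c(text, formatGenBankEntry(acc, org, donor$lineage, feats,
                                         mutateGenomeOnce(donor$seq)))
      filtTruth <- rbind(filtTruth, data.frame(accession = acc,
                                               rule = "hybrid"))
    }
    for (p in seq_len(nIdenticalPairs)) {
      src <- sprintf("SYN%05d", 1L + (p - 1L) %% nSpecies)
      acc <- sprintf("SYNZ%04d", p)
      donor <- keptEntries[[src]]
      text <- c(text, formatGenBankEntry(acc, paste0(donor$organism, " bis"),
                                         donor$lineage, donor$features,
                                         donor$seq))
      filtTruth <- rbind(filtTruth, data.frame(accession = acc,
                                               rule = "identical"))
    }
    list(text = text, truth = list(duplicates = dupTruth,
                                   filters = filtTruth))
  })
}

# Single-base substitution at a fixed interior position.
mutateGenomeOnce <- function(seq) {
  i <- max(2L, nchar(seq) %/% 2L)
  base <- substr(seq, i, i)
  repl <- setdiff(c("A", "C", "G", "T"), base)[1L]
  paste0(substr(seq, 1L, i - 1L), repl, substr(seq, i + 1L, nchar(seq)))
}
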