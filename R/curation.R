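# Duplicate-gene resolution and dataset filters for mitogenome records.
#
# Duplicated annotations of the same protein-coding gene are resolved
# in three ordered steps: (1) copies with internal stop codons are
# removed when at least one clean copy exists; (2) remaining ties are
# broken by conservation against orthologs from the lowest shared
# taxonomic rank that offers another species with that gene; (3) any
# residual tie falls back to the lower start coordinate.

IUPAC_NT <- c("A", "C", "G", "T", "U",
              "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

geneticCode <- function(translTable) {
  if (is.na(translTable))
    stopf("CDS lacks a /transl_table qualifier; a genetic code is required")
  id <- as.character(translTable)
  codes <- Biostrings::GENETIC_CODE_TABLE$id
  if (!id %in% codes) stopf("unknown genetic code table %s", id)
  Biostrings::getGeneticCode(id)
}

#' Count internal stop codons in a CDS
#'
#' Reads the sequence in frame from position 1 and counts stop codons
#' strictly before the final (possibly incomplete) codon.  Codons
#' containing IUPAC ambiguity codes translate as unknown and are never
#' counted as stops; characters outside the IUPAC nucleotide alphabet
#' raise an error.
#'
#' @param cds nucleotide string in coding orientation, length >= 3.
#' @param translTable NCBI genetic-code id (e.g. 2 vertebrate mito,
#'   5 invertebrate mito).
#' @return non-negative integer.
#' @export
#' @examples
#' countInternalStops("ATGTAAATT", 2)  # TAA internal -> 1
#' countInternalStops("ATGAAATAA", 2)  # only terminal stop -> 0
countInternalStops <- function(cds, translTable) {
  stopifnot(is.character(cds), length(cds) == 1L)
  s <- toupper(gsub("\\s", "", cds))
  if (nchar(s) < 3L) stopf("CDS shorter than one codon")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), IUPAC_NT)
  if (length(bad))
    stopf("non-IUPAC nucleotide character(s): %s", paste(bad, collapse = ", "))
  s <- chartr("U", "T", s)
  code <- geneticCode(translTable)
  stops <- names(code)[code == "*"]
  nCodon <- nchar(s) %/% 3L
  if (nCodon < 2L) return(0L)
  idx <- seq_len(nCodon - 1L)
  codons <- substring(s, 3L * (idx - 1L) + 1L, 3L * idx)
  sum(codons %in% stops)
}

translateCds <- function(seq, translTable) {
  s <- chartr("U", "T", toupper(gsub("\\s", "", seq)))
  n <- 3L * (nchar(s) %/% 3L)
  if (n < 3L) return("")
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(s, 1L, n)),
    genetic.code = geneticCode(translTable),
    if.fuzzy.codon = "X", no.init.codon = TRUE))
  sub("\\*$", "", aa)
}

#' Conservation score of a candidate against reference orthologs
#'
#' Mean proportion of identical aligned positions between the candidate
#' amino-acid sequence and each reference, after global alignment with
#' match = 1, mismatch = 0, linear gap penalty 1.  The denominator is
#' the alignment length (gap columns count as non-identical).
#'
#' @param candidate amino-acid string (non-empty).
#' @param references character vector of orthologous amino-acid strings.
#' @return score in [0, 1].
#' @export
#' @examples conservationScore("MKLV", c("MKLV", "MKIV"))
conservationScore <- function(candidate, references) {
  if (!length(references)) stopf("references must be non-empty")
  if (!nzchar(candidate)) stopf("candidate must be non-empty")
  alphabet <- sort(unique(c(Biostrings::AA_ALPHABET,
                            strsplit(paste(c(candidate, references), collapse = ""),
                                     "")[[1]])))
  alphabet <- setdiff(alphabet, c("-", "+", "."))
  subMat <- diag(1, length(alphabet))
  dimnames(subMat) <- list(alphabet, alphabet)
  vapply(references, function(ref) {
    aln <- Biostrings::pairwiseAlignment(candidate, ref, type = "global",
                                         substitutionMatrix = subMat,
                                         gapOpening = 0, gapExtension = 1)
    p <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
    q <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
    sum(p == q & p != "-") / length(p)
  }, numeric(1)) |> mean()
}

# Orthologs of `gene` from the most specific taxonomic rank (genus
# upward) that contains another record carrying that gene.
findReferenceOrthologs <- function(record, gene, panel) {
  others <- Filter(function(r) r@accession != record@accession &&
                     gene %in% r@features$gene[r@features$canonical], panel)
  if (!length(others)) return(NULL)
  for (rank in rev(record@taxonomy)) {
    hit <- Filter(function(r) rank %in% r@taxonomy, others)
    if (length(hit)) {
      seqs <- vapply(hit, function(r) {
        f <- r@features[r@features$gene == gene, , drop = FALSE]
        translateCds(f$sequence[1], f$translTable[1])
      }, character(1))
      seqs <- seqs[nzchar(seqs)]
      if (length(seqs)) return(list(rank = rank, aa = unname(seqs)))
    }
  }
  NULL
}

emptyResolutionLog <- function() {
  data.frame(accession = character(), gene = character(), rule = character(),
             kept = character(), removed = character(), detail = character(),
             stringsAsFactors = FALSE)
}

#' Resolve duplicated protein-coding gene annotations
#'
#' For every canonical gene annotated more than once in `record`:
#' copies carrying internal stop codons are removed first (when a clean
#' copy exists); if several copies remain, the one most conserved
#' relative to orthologs of the lowest shared taxon in
#' `referencePanel` is kept; residual ties keep the copy with the
#' lower start coordinate.  Exactly one copy per gene survives and
#' every decision is logged.
#'
#' @param record a [MitogenomeRecord-class] with standardized names.
#' @param referencePanel list of MitogenomeRecords supplying reference
#'   orthologs (typically the whole dataset; the record itself is
#'   ignored).
#' @return list with elements `record` (resolved) and `log`
#'   (data.frame: accession, gene, rule, kept, removed, detail).
#' @export
resolveDuplicates <- function(record, referencePanel = list()) {
  stopifnot(is(record, "MitogenomeRecord"))
  f <- record@features
  log <- emptyResolutionLog()
  if (!nrow(f)) return(list(record = record, log = log))
  f$..id <- paste0(f$gene, "@", f$start, "-", f$end)
  dupGenes <- names(which(table(f$gene[f$canonical]) > 1L))
  drop <- integer()
  for (g in dupGenes) {
    idx <- which(f$gene == g)
    stops <- vapply(idx, function(i)
      countInternalStops(f$sequence[i], f$translTable[i]), integer(1))
    cand <- idx
    rule <- NULL
    detail <- ""
    if (any(stops == 0L) && any(stops > 0L)) {
      cand <- idx[stops == 0L]
      if (length(cand) == 1L) {
        rule <- "stop_codon"
        detail <- sprintf("internal stops: %s",
                          paste(paste0(f$..id[idx], ":", stops), collapse = ","))
      }
    }
    if (is.null(rule) && length(cand) > 1L) {
      refs <- findReferenceOrthologs(record, g, referencePanel)
      if (is.null(refs)) {
        cand <- cand[which.min(f$start[cand])]
        rule <- "tie_break"
        detail <- "no reference ortholog at any rank"
      } else {
        sc <- vapply(cand, function(i)
          conservationScore(translateCds(f$sequence[i], f$translTable[i]),
                            refs$aa), numeric(1))
        best <- cand[sc == max(sc)]
        rule <- if (length(best) > 1L) "tie_break" else "conservation"
        cand <- best[which.min(f$start[best])]
        detail <- sprintf("rank=%s scores=%s", refs$rank,
                          paste(sprintf("%.4f", sc), collapse = ","))
      }
    }
    if (is.null(rule)) rule <- "stop_codon"
    keep <- cand[1L]
    rem <- setdiff(idx, keep)
    drop <- c(drop, rem)
    log <- rbind(log, data.frame(
      accession = record@accession, gene = g, rule = rule,
      kept = f$..id[keep], removed = paste(f$..id[rem], collapse = ";"),
      detail = detail, stringsAsFactors = FALSE))
  }
  if (length(drop)) f <- f[-drop, , drop = FALSE]
  f$..id <- NULL
  rownames(f) <- NULL
  record@features <- f
  list(record = record, log = log)
}

#' Dataset-level filters
#'
#' Drops (a) unannotated records, (b) records whose organism name
#' matches hybrid markers (`" x "` or `"hybrid"`), and (c) all but one
#' of any set of records with byte-identical concatenated
#' protein-coding sequences (suspected misidentifications; the
#' lexicographically smallest accession is kept).  The result is
#' independent of input order; kept records are returned sorted by
#' accession.
#'
#' @param records list of [MitogenomeRecord-class] objects.
#' @return list with `kept` (records) and `log` (data.frame:
#'   accession, rule, detail).
#' @export
applyDatasetFilters <- function(records) {
  acc <- vapply(records, function(r) r@accession, character(1))
  org <- vapply(records, function(r) r@organism, character(1))
  log <- data.frame(accession = character(), rule = character(),
                    detail = character(), stringsAsFactors = FALSE)
  addLog <- function(a, rule, detail) {
    log <<- rbind(log, data.frame(accession = a, rule = rule,
                                  detail = detail, stringsAsFactors = FALSE))
  }
  keep <- rep(TRUE, length(records))

  unann <- !vapply(records, function(r) r@isAnnotated, logical(1))
  for (i in which(unann)) addLog(acc[i], "unannotated", "no feature annotation")
  keep[unann] <- FALSE

  hyb <- keep & (grepl(" x ", org, fixed = TRUE) |
                   grepl("hybrid", org, ignore.case = TRUE))
  for (i in which(hyb)) addLog(acc[i], "hybrid", org[i])
  keep[hyb] <- FALSE

  key <- vapply(records, function(r) {
    f <- r@features[r@features$canonical, , drop = FALSE]
    if (!nrow(f)) return("")
    f <- f[order(f$gene), , drop = FALSE]
    paste(f$gene, f$sequence, sep = ":", collapse = "|")
  }, character(1))
  for (k in unique(key[keep & nzchar(key)])) {
    grp <- which(keep & key == k)
    if (length(grp) > 1L) {
      win <- grp[order(acc[grp])][1L]
      for (i in setdiff(grp, win))
        addLog(acc[i], "identical",
               sprintf("concatenated PCGs identical to %s", acc[win]))
      keep[setdiff(grp, win)] <- FALSE
    }
  }
  kept <- records[keep]
  kept <- kept[order(vapply(kept, function(r) r@accession, character(1)))]
  list(kept = kept, log = log)
}

#' Per-gene protein-coding sequence sets
#'
#' Collects, for each gene in `geneSet`, the species-to-sequence map
#' across resolved records.  The default gene set is the 13 PCGs minus
#' `atp8` (missing from multiple lineages).  Species lacking a gene are
#' simply absent from that gene's set.
#'
#' @param records list of resolved [MitogenomeRecord-class] objects.
#' @param geneSet canonical gene names to extract.
#' @return named list gene -> named character vector (species ->
#'   nucleotide sequence), with an `occupancy` attribute (data.frame:
#'   gene, n, frac).
#' @export
extractPcgMatrix <- function(records, geneSet = setdiff(pcgGenes(), "atp8")) {
  stopifnot(all(geneSet %in% pcgGenes()))
  for (r in records) {
    tab <- table(r@features$gene[r@features$canonical])
    if (any(tab > 1L))
      stopf("record %s has unresolved duplicates (%s); run resolveDuplicates first",
            r@accession, paste(names(tab)[tab > 1L], collapse = ", "))
  }
  out <- setNames(vector("list", length(geneSet)), geneSet)
  for (g in geneSet) out[[g]] <- character()
  for (r in records) {
    sp <- if (!is.na(r@organism)) r@organism else r@accession
    f <- r@features
    for (g in intersect(geneSet, f$gene[f$canonical])) {
      out[[g]][sp] <- f$sequence[f$gene == g][1L]
    }
  }
  counts <- unname(vapply(out, length, integer(1)))
  attr(out, "occupancy") <- data.frame(
    gene = geneSet, n = counts,
    frac = if (length(records)) counts / length(records) else NA_real_,
    row.names = NULL)
  out
}

#' Write per-gene FASTA files
#'
#' @param pcgMatrix output of [extractPcgMatrix()].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
writeGeneFasta <- function(pcgMatrix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (g in names(pcgMatrix)) {
    x <- pcgMatrix[[g]]
    path <- file.path(dir, paste0(g, ".fasta"))
    if (length(x)) {
      names(x) <- gsub("\\s+", "_", names(x))
      Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path)
    } else {
      file.create(path)
    }
    paths <- c(paths, path)
  }
  invisible(paths)
}
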