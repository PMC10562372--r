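#' The 13 mitochondrial protein-coding genes
#'
#' Canonical lower-case symbols used throughout the package.
#' @return character vector of length 13.
#' @export
#' @examples pcgGenes()
pcgGenes <- function() {
  c("atp6", "atp8", "cox1", "cox2", "cox3", "cytb",
    "nad1", "nad2", "nad3", "nad4", "nad4l", "nad5", "nad6")
}

#' Bundled gene-name synonym table
#'
#' Maps upper-cased raw CDS labels (gene symbols and common product
#' names) to the canonical 13-PCG vocabulary.  Users can extend it or
#' load their own with [readGeneSynonyms()].
#'
#' @return named character vector: names are raw labels (upper case),
#'   values canonical symbols.
#' @export
#' @examples geneSynonyms()[["COIII"]]
geneSynonyms <- function() {
  syn <- c(
    COX1 = "cox1", COI = "cox1", CO1 = "cox1", COXI = "cox1",
    "COX-1" = "cox1", "CYTOCHROME C OXIDASE SUBUNIT I" = "cox1",
    "CYTOCHROME C OXIDASE SUBUNIT 1" = "cox1",
    COX2 = "cox2", COII = "cox2", CO2 = "cox2", COXII = "cox2",
    "CYTOCHROME C OXIDASE SUBUNIT II" = "cox2",
    "CYTOCHROME C OXIDASE SUBUNIT 2" = "cox2",
    COX3 = "cox3", COIII = "cox3", CO3 = "cox3", COXIII = "cox3",
    "CYTOCHROME C OXIDASE SUBUNIT III" = "cox3",
    "CYTOCHROME C OXIDASE SUBUNIT 3" = "cox3",
    CYTB = "cytb", COB = "cytb", CYB = "cytb", "CYT B" = "cytb",
    "CYTOCHROME B" = "cytb",
    ATP6 = "atp6", ATPASE6 = "atp6", "ATPASE 6" = "atp6",
    "ATP SYNTHASE F0 SUBUNIT 6" = "atp6",
    ATP8 = "atp8", ATPASE8 = "atp8", "ATPASE 8" = "atp8",
    "ATP SYNTHASE F0 SUBUNIT 8" = "atp8",
    NAD4L = "nad4l", ND4L = "nad4l", NADH4L = "nad4l",
    "NADH DEHYDROGENASE SUBUNIT 4L" = "nad4l"
  )
  for (i in 1:6) {
    block <- setNames(rep(paste0("nad", i), 4),
                      c(paste0("NAD", i), paste0("ND", i), paste0("NADH", i),
                        paste0("NADH DEHYDROGENASE SUBUNIT ", i)))
    syn <- c(syn, block)
  }
  # identity entries so already-canonical labels pass through
  syn <- c(syn, setNames(pcgGenes(), toupper(pcgGenes())))
  syn[!duplicated(names(syn))]
}

#' Read a gene-synonym table from TSV
#'
#' @param file two-column TSV (raw label, canonical symbol), no header.
#' @return named character vector usable as the `synonyms` argument of
#'   [standardizeGeneNames()].
#' @export
readGeneSynonyms <- function(file) {
  d <- read.delim(file, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2) stopf("synonym file must have two columns")
  setNames(tolower(d[[2]]), toupper(d[[1]]))
}

# --- flatfile parsing -------------------------------------------------

parseLocation <- function(loc) {
  raw <- gsub("[<>]", "", gsub("[[:space:]]", "", loc))
  s <- raw
  comp <- FALSE
  if (grepl("^complement\\(", s)) {
    comp <- TRUE
    s <- sub("^complement\\((.*)\\)$", "\\1", s)
  }
  join <- FALSE
  if (grepl("^join\\(", s)) {
    join <- TRUE
    s <- sub("^join\\((.*)\\)$", "\\1", s)
  }
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  ok <- grepl("^[0-9]+\\.\\.[0-9]+$", parts) | grepl("^[0-9]+$", parts)
  if (!length(parts) || !all(ok)) return(NULL)
  seg <- t(vapply(parts, function(p) {
    if (grepl("\\.\\.", p)) as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    else rep(as.integer(p), 2L)
  }, integer(2)))
  list(segments = seg, complement = comp, join = join)
}

revComp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

parseOneEntry <- function(lines, entryId) {
  if (!length(lines) || !grepl("^LOCUS\\s+\\S", lines[1]))
    stopf("malformed LOCUS block in entry '%s'", entryId)
  locusName <- strsplit(lines[1], "\\s+")[[1]][2]
  accLine <- grep("^ACCESSION", lines, value = TRUE)
  accession <- if (length(accLine)) strsplit(accLine[1], "\\s+")[[1]][2] else locusName
  if (is.na(accession) || !nzchar(accession)) accession <- locusName

  orgLine <- grep("^\\s{2}ORGANISM", lines)
  organism <- NA_character_
  taxonomy <- character()
  if (length(orgLine)) {
    organism <- sub("^\\s+ORGANISM\\s+", "", lines[orgLine[1]])
    j <- orgLine[1] + 1L
    lin <- character()
    while (j <= length(lines) && grepl("^\\s{8,}\\S", lines[j]) &&
           !grepl("^\\s{0,6}\\S+\\s", lines[j])) {
      lin <- c(lin, trimws(lines[j]))
      j <- j + 1L
    }
    taxonomy <- trimws(strsplit(sub("\\.$", "", paste(lin, collapse = " ")), ";")[[1]])
    taxonomy <- taxonomy[nzchar(taxonomy)]
  }

  featStart <- grep("^FEATURES", lines)
  originAt <- grep("^ORIGIN", lines)

  sequence <- ""
  if (length(originAt)) {
    seqLines <- lines[seq(originAt[1] + 1L, length(lines))]
    seqLines <- seqLines[nzchar(trimws(seqLines))]
    bad <- !grepl("^\\s*[0-9]+[ acgtunrywskmbdhvACGTUNRYWSKMBDHV]*$", seqLines)
    if (any(bad))
      stopf("malformed ORIGIN block in entry '%s'", accession)
    sequence <- toupper(gsub("[0-9 ]", "", paste(seqLines, collapse = "")))
  }

  features <- emptyFeatureTable()
  if (length(featStart)) {
    featEnd <- if (length(originAt)) originAt[1] - 1L else length(lines)
    fl <- lines[seq(featStart[1] + 1L, featEnd)]
    starts <- grep("^\\s{1,10}\\S+\\s+\\S", fl)
    for (si in seq_along(starts)) {
      block <- fl[starts[si]:(if (si < length(starts)) starts[si + 1] - 1L else length(fl))]
      key <- strsplit(trimws(block[1]), "\\s+")[[1]][1]
      if (key != "CDS") next
      # location may continue onto lines before the first qualifier
      qualAt <- grep("^\\s+/", block)
      locEnd <- if (length(qualAt)) qualAt[1] - 1L else length(block)
      loc <- paste(trimws(sub("^\\s*CDS", "", block[1])),
                   paste(trimws(block[seq_len(locEnd)[-1]]), collapse = ""),
                   sep = "")
      pl <- parseLocation(loc)
      if (is.null(pl)) stopf("unparseable CDS location '%s' in entry '%s'", loc, accession)
      quals <- block[qualAt]
      getQual <- function(name) {
        hit <- grep(paste0("^\\s+/", name, "="), quals, value = TRUE)
        if (!length(hit)) return(NA_character_)
        gsub("\"", "", sub(paste0("^\\s+/", name, "="), "", hit[1]))
      }
      gene <- getQual("gene")
      if (is.na(gene)) gene <- getQual("product")
      tt <- suppressWarnings(as.integer(getQual("transl_table")))
      sq <- NA_character_
      if (nzchar(sequence)) {
        pieces <- apply(pl$segments, 1L, function(se) substr(sequence, se[1], se[2]))
        sq <- paste(pieces, collapse = "")
        if (pl$complement) sq <- revComp(sq)
      }
      features <- rbind(features, data.frame(
        gene = if (is.na(gene)) "unknown_cds" else gene,
        canonical = FALSE,
        start = min(pl$segments), end = max(pl$segments),
        strand = if (pl$complement) "-" else "+",
        translTable = tt, sequence = sq, stringsAsFactors = FALSE))
    }
  }
  features$canonical <- tolower(features$gene) %in% pcgGenes()
  features$gene <- ifelse(features$canonical, tolower(features$gene), features$gene)

  new("MitogenomeRecord", accession = accession, organism = organism,
      taxonomy = taxonomy, features = features,
      isAnnotated = length(featStart) > 0L && nrow(features) > 0L)
}

#' Read GenBank flatfile mitogenome records
#'
#' Parses a (multi-entry) GenBank flatfile.  Each entry must start with
#' a LOCUS line and end with `//`.  CDS features with a `/gene` or
#' `/product` qualifier become rows of the record's feature table, with
#' minus-strand sequences reverse-complemented into coding orientation.
#' Entries without a FEATURES block are kept but flagged unannotated.
#'
#' @param file path to a flatfile, or a character vector of lines.
#' @return list of [MitogenomeRecord-class] objects, in file order.
#' @export
#' @examples
#' gb <- simulateMitogenomeRecords(2, seed = 1)
#' recs <- readGenBankRecords(gb$text)
#' recs[[1]]
readGenBankRecords <- function(file) {
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file) else file
  term <- grep("^//\\s*$", lines)
  if (!length(term)) {
    if (!any(grepl("^LOCUS", lines))) return(list())
    stopf("flatfile has a LOCUS line but no '//' terminator")
  }
  begin <- c(1L, head(term, -1L) + 1L)
  out <- vector("list", length(term))
  for (i in seq_along(term)) {
    chunk <- lines[begin[i]:(term[i] - 1L)]
    chunk <- chunk[nzchar(trimws(chunk))]
    if (!length(chunk)) next
    out[[i]] <- parseOneEntry(chunk, entryId = as.character(i))
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Standardize CDS gene names against a synonym table
#'
#' Raw labels are matched case-insensitively against `synonyms`; mapped
#' features receive the canonical symbol and `canonical = TRUE`.
#' Unmapped labels are retained unchanged and flagged non-canonical
#' (never an error).
#'
#' @param record a [MitogenomeRecord-class].
#' @param synonyms named map as returned by [geneSynonyms()].
#' @return the record with standardized feature names.
#' @export
standardizeGeneNames <- function(record, synonyms = geneSynonyms()) {
  stopifnot(is(record, "MitogenomeRecord"))
  f <- record@features
  if (nrow(f)) {
    key <- toupper(trimws(f$gene))
    hit <- match(key, names(synonyms))
    f$gene <- ifelse(is.na(hit), f$gene, unname(synonyms[hit]))
    f$canonical <- f$gene %in% pcgGenes()
    record@features <- f
  }
  record
}
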