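# Life-history (LHT) and locomotory-capacity (LOC) classifications.
# Both vocabularies are closed: LHT in {F, EndoP, EctoP, Parasitoid,
# MP}, LOC in {H, I, L}.  Consumers that only feed on non-animal hosts
# are classified F upstream; the free-text `basis` column records the
# provenance of each classification and is never computed on.

LHT_LEVELS <- c("F", "MP", "Parasitoid", "EctoP", "EndoP")
LOC_LEVELS <- c("H", "I", "L")

#' Construct a TraitTable
#'
#' @param data data.frame with at least `species`, `lht`, `loc`;
#'   taxonomy columns (`phylum`, `class`, `order`) and bookkeeping
#'   columns (`excluded`, `reason`, `basis`) are added when absent.
#' @return a [TraitTable-class].
#' @export
#' @examples
#' TraitTable(data.frame(species = c("a", "b"), lht = c("F", "EndoP"),
#'                       loc = c("H", "L"), phylum = "P1"))
TraitTable <- function(data) {
  stopifnot(is.data.frame(data), all(c("species", "lht", "loc") %in% names(data)))
  for (col in c("phylum", "class", "order"))
    if (is.null(data[[col]])) data[[col]] <- NA_character_
  if (is.null(data$excluded)) data$excluded <- FALSE
  if (is.null(data$reason)) data$reason <- NA_character_
  if (is.null(data$basis)) data$basis <- NA_character_
  data$species <- as.character(data$species)
  data$lht <- as.character(data$lht)
  data$loc <- as.character(data$loc)
  new("TraitTable", data = data[c("species", "lht", "loc", "phylum", "class",
                                  "order", "excluded", "reason", "basis")])
}

#' Read / write a trait table as TSV
#'
#' @param file TSV path with the columns of [TraitTable()].
#' @return `readTraitTable()`: a [TraitTable-class].
#' @export
readTraitTable <- function(file) {
  TraitTable(read.delim(file, stringsAsFactors = FALSE))
}

#' @rdname readTraitTable
#' @param table a [TraitTable-class].
#' @export
writeTraitTable <- function(table, file) {
  write.table(traitData(table), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' Validate trait classifications
#'
#' Errors collect unknown category labels and missing fields; a
#' warning-level inconsistency is recorded for endoparasites not
#' assigned Low locomotory capacity (endoparasitism implies passive
#' dispersal inside the host, so EndoP species are expected in LOC L).
#'
#' @param table a [TraitTable-class].
#' @return list with `errors` and `warnings` (character vectors,
#'   empty when clean) and `valid` (logical).  Inconsistencies emit an
#'   R warning but never an error.
#' @export
validateTraits <- function(table) {
  d <- traitData(table)
  errors <- character()
  badLht <- d$species[!d$lht %in% LHT_LEVELS | is.na(d$lht)]
  if (length(badLht))
    errors <- c(errors, sprintf("unknown life-history label for: %s",
                                paste(badLht, collapse = ", ")))
  badLoc <- d$species[!d$loc %in% LOC_LEVELS | is.na(d$loc)]
  if (length(badLoc))
    errors <- c(errors, sprintf("unknown locomotory label for: %s",
                                paste(badLoc, collapse = ", ")))
  if (any(is.na(d$species) | !nzchar(d$species)))
    errors <- c(errors, "missing species identifiers")
  warnings <- character()
  inconsistent <- d$species[d$lht == "EndoP" & d$loc != "L" & d$loc %in% LOC_LEVELS]
  if (length(inconsistent)) {
    warnings <- c(warnings,
                  sprintf("endoparasite(s) not classified LOC=L: %s",
                          paste(inconsistent, collapse = ", ")))
    warnf("%s", warnings[length(warnings)])
  }
  if (length(errors)) stopf("%s", paste(errors, collapse = "; "))
  list(errors = errors, warnings = warnings, valid = TRUE)
}

#' Exclude species that alternate between life cycles
#'
#' Marks the listed species excluded with reason "alternating life
#' cycle"; excluded species are omitted from all downstream statistics.
#' Species absent from the table are warned about, the rest are still
#' excluded.
#'
#' @param table a [TraitTable-class].
#' @param speciesList character vector of species to exclude.
#' @return the updated [TraitTable-class].
#' @export
excludeAlternating <- function(table, speciesList) {
  d <- traitData(table)
  absent <- setdiff(speciesList, d$species)
  if (length(absent))
    warnf("species not in table: %s", paste(absent, collapse = ", "))
  hit <- d$species %in% speciesList
  d$excluded[hit] <- TRUE
  d$reason[hit] <- "alternating life cycle"
  new("TraitTable", data = d)
}

#' Recode life-history categories
#'
#' @param table a [TraitTable-class].
#' @param scheme one of `"identity"`, `"endop_vs_rest"`
#'   (EndoP vs nonEndoP), `"macroparasite_vs_rest"` (EndoP+EctoP = P vs
#'   nonP) or `"parasitic_vs_rest"` (EndoP+EctoP+Parasitoid = P vs
#'   nonP).
#' @return named character vector species -> recoded label (excluded
#'   species omitted).
#' @export
recodeLifeHistory <- function(table, scheme = "identity") {
  schemes <- c("identity", "endop_vs_rest", "macroparasite_vs_rest",
               "parasitic_vs_rest")
  if (!scheme %in% schemes)
    stopf("unknown scheme '%s'; available: %s", scheme,
          paste(schemes, collapse = ", "))
  d <- traitData(table)
  d <- d[!d$excluded, , drop = FALSE]
  lab <- switch(scheme,
    identity = d$lht,
    endop_vs_rest = ifelse(d$lht == "EndoP", "EndoP", "nonEndoP"),
    macroparasite_vs_rest = ifelse(d$lht %in% c("EndoP", "EctoP"), "P", "nonP"),
    parasitic_vs_rest = ifelse(d$lht %in% c("EndoP", "EctoP", "Parasitoid"),
                               "P", "nonP"))
  setNames(lab, d$species)
}

#' Per-phylum composition ratios
#'
#' Ratios of endoparasites, macroparasites (EndoP+EctoP) and Low-LOC
#' species per phylum, usable as continuous covariates.  Excluded
#' species are omitted.
#'
#' @param table a [TraitTable-class].
#' @return data.frame: phylum, n, endoPRatio, macroParasiteRatio,
#'   lowLocRatio.
#' @export
phylumComposition <- function(table) {
  d <- traitData(table)
  d <- d[!d$excluded & !is.na(d$phylum), , drop = FALSE]
  split_ <- split(d, d$phylum)
  out <- do.call(rbind, lapply(split_, function(s) data.frame(
    phylum = s$phylum[1], n = nrow(s),
    endoPRatio = mean(s$lht == "EndoP"),
    macroParasiteRatio = mean(s$lht %in% c("EndoP", "EctoP")),
    lowLocRatio = mean(s$loc == "L"),
    stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Subset species by classification criteria
#'
#' @param table a [TraitTable-class].
#' @param criterion a preset name (`"free_living_only"`,
#'   `"low_loc_only"`, `"ectoparasites_only"`, `"all"`) or a named list
#'   of field = value filters over lht/loc/phylum/class/order (values
#'   may be vectors).
#' @return character vector of species (excluded species never
#'   returned); empty result warns, never errors.
#' @export
subsetDataset <- function(table, criterion = "all") {
  d <- traitData(table)
  d <- d[!d$excluded, , drop = FALSE]
  if (is.character(criterion) && length(criterion) == 1L) {
    criterion <- switch(criterion,
      all = list(),
      free_living_only = list(lht = "F"),
      low_loc_only = list(loc = "L"),
      ectoparasites_only = list(lht = "EctoP"),
      stopf("unknown preset '%s'", criterion))
  }
  stopifnot(is.list(criterion))
  keep <- rep(TRUE, nrow(d))
  for (field in names(criterion)) {
    if (!field %in% c("lht", "loc", "phylum", "class", "order"))
      stopf("cannot subset on field '%s'", field)
    keep <- keep & d[[field]] %in% criterion[[field]]
  }
  out <- d$species[keep]
  if (!length(out)) warnf("subset is empty")
  out
}
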