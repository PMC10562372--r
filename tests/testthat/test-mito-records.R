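# Curation of mitogenome records: parsing, gene-name standardisation,
# stop-codon detection, duplicate resolution, dataset filters.

test_that("flatfile parsing preserves entry count, order and features", {
  gb <- simulateMitogenomeRecords(3, duplicateFraction = 0, seed = 101)
  recs <- readGenBankRecords(gb$text)
  expect_length(recs, 3L)
  expect_identical(vapply(recs, function(r) r@accession, character(1)),
                   sprintf("SYN%05d", 1:3))
  expect_true(all(vapply(recs, function(r) nrow(r@features), integer(1)) == 13L))
  expect_true(all(vapply(recs, function(r) r@isAnnotated, logical(1))))
  # minus-strand gene comes back in coding orientation (translatable ORF)
  nad6 <- recs[[1]]@features[recs[[1]]@features$gene == "nad6", ]
  expect_identical(nad6$strand, "-")
  expect_identical(countInternalStops(nad6$sequence, nad6$translTable), 0L)
})

test_that("entries without a FEATURES block are flagged unannotated", {
  gb <- simulateMitogenomeRecords(2, duplicateFraction = 0, seed = 7,
                                  nUnannotated = 1)
  recs <- readGenBankRecords(gb$text)
  expect_length(recs, 3L)
  expect_false(recs[[3]]@isAnnotated)
  expect_true(recs[[1]]@isAnnotated)
})

test_that("malformed entries raise parse errors naming the entry", {
  bad <- c("NOT_A_LOCUS line", "//")
  expect_error(readGenBankRecords(bad), "LOCUS")
  gb <- simulateMitogenomeRecords(1, duplicateFraction = 0, seed = 1)
  txt <- gb$text
  i <- grep("^ORIGIN", txt) + 1L
  txt[i] <- "     garbage !!! line"
  expect_error(readGenBankRecords(txt), "ORIGIN.*SYN00001")
})

test_that("gene names are standardized case-insensitively, unknowns kept", {
  f <- rbind(makeFeature("COIII", 1, 18, orf("ATG", "AAA", "CCC", "GGG",
                                             "TTT", "GCA")),
             makeFeature("ND2", 30, 47, orf("ATG", "AAA", "CCC", "GGG",
                                            "TTT", "GCA")),
             makeFeature("cox1", 60, 77, orf("ATG", "AAA", "CCC", "GGG",
                                             "TTT", "GCA")),
             makeFeature("orfX", 90, 107, orf("ATG", "AAA", "CCC", "GGG",
                                              "TTT", "GCA")))
  rec <- standardizeGeneNames(makeRecord("T1", features = f))
  expect_identical(rec@features$gene, c("cox3", "nad2", "cox1", "orfX"))
  expect_identical(rec@features$canonical, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("internal stop codons are counted per genetic code", {
  expect_identical(countInternalStops("ATGTAAATT", 2), 1L)   # internal TAA
  expect_identical(countInternalStops("ATGAAATAA", 2), 0L)   # terminal only
  expect_identical(countInternalStops("ATG", 2), 0L)
  # AGA is a stop in the vertebrate code but serine in invertebrate mito
  expect_identical(countInternalStops("ATGAGAATT", 2), 1L)
  expect_identical(countInternalStops("ATGAGAATT", 5), 0L)
  # ambiguity codes translate as unknown, never as stop
  expect_identical(countInternalStops("ATGTRAATT", 2), 0L)
  # trailing partial codon is dropped; the last complete codon then
  # counts as terminal
  expect_identical(countInternalStops("ATGTAAAT", 2), 0L)
  expect_identical(countInternalStops("ATGTAAATTA", 2), 1L)
  expect_error(countInternalStops("ATGXXZAAA", 2), "non-IUPAC")
  expect_error(countInternalStops("ATGAAATAA", NA), "transl_table")
})

test_that("conservation score is mean aligned identity in [0, 1]", {
  expect_equal(conservationScore("MKLV", c("MKLV", "MKLV")), 1.0)
  expect_equal(conservationScore("MKLV", c("MKIV")), 0.75)
  expect_equal(conservationScore("WWWW", c("HHHH")), 0.0)
  expect_error(conservationScore("", c("MKLV")), "candidate")
  expect_error(conservationScore("MKLV", character()), "references")
})

cleanCox1 <- orf("ATG", "AAA", "CCC", "GGG", "TTT", "GCA")
stopCox1 <- orf("ATG", "AAA", "TAA", "GGG", "TTT", "GCA")
farCox1 <- orf("ATG", "CCC", "GGG", "TTT", "AAA", "ATT")

test_that("stop-codon rule removes the broken duplicate", {
  f <- rbind(makeFeature("cox1", 1, 18, cleanCox1),
             makeFeature("cox1", 100, 117, stopCox1))
  out <- resolveDuplicates(makeRecord("T1", features = f))
  expect_identical(nrow(out$record@features), 1L)
  expect_identical(out$record@features$sequence, cleanCox1)
  expect_identical(out$log$rule, "stop_codon")
  expect_identical(out$log$kept, "cox1@1-18")
})

test_that("conservation rule keeps the copy closest to the reference", {
  ref <- makeRecord("REF1", organism = "Genus01 species02",
                    features = makeFeature("cox1", 1, 18, cleanCox1))
  # diverged copy sits first so the tie-break alone would keep the
  # wrong one; the conservation rule must override it
  f <- rbind(makeFeature("cox1", 1, 18, farCox1),
             makeFeature("cox1", 100, 117, cleanCox1))
  out <- resolveDuplicates(makeRecord("T1", features = f),
                           referencePanel = list(ref))
  expect_identical(out$log$rule, "conservation")
  expect_identical(out$record@features$sequence, cleanCox1)
})

test_that("without references ties fall back to the lower start", {
  f <- rbind(makeFeature("cox1", 100, 117, cleanCox1),
             makeFeature("cox1", 1, 18, farCox1))
  out <- resolveDuplicates(makeRecord("T1", features = f))
  expect_identical(out$log$rule, "tie_break")
  expect_identical(out$record@features$start, 1L)
})

test_that("duplicate resolution is idempotent and conserves copies", {
  f <- rbind(makeFeature("cox1", 1, 18, cleanCox1),
             makeFeature("cox1", 100, 117, stopCox1),
             makeFeature("nad2", 200, 217, cleanCox1))
  rec <- makeRecord("T1", features = f)
  once <- resolveDuplicates(rec)
  twice <- resolveDuplicates(once$record)
  expect_identical(once$record@features, twice$record@features)
  expect_identical(nrow(twice$log), 0L)
  # total logged removals equal input copies minus output copies
  nRemoved <- sum(nchar(once$log$removed) > 0)
  expect_identical(nrow(f) - nrow(once$record@features), nRemoved)
  # record without duplicates passes through untouched
  solo <- resolveDuplicates(makeRecord("T2",
    features = makeFeature("cox1", 1, 18, cleanCox1)))
  expect_identical(nrow(solo$log), 0L)
  expect_identical(solo$record@features$sequence, cleanCox1)
})

test_that("dataset filters drop unannotated, hybrid and identical records", {
  a <- makeRecord("AC001", features = makeFeature("cox1", 1, 18, cleanCox1))
  b <- makeRecord("AC002", organism = "Carassius auratus x Cyprinus carpio",
                  features = makeFeature("cox1", 1, 18, farCox1))
  c_ <- makeRecord("AC003", isAnnotated = FALSE, taxonomy = character())
  d <- makeRecord("AC004", organism = "Genus02 species9",
                  features = makeFeature("cox1", 1, 18, cleanCox1))
  out <- applyDatasetFilters(list(a, b, c_, d))
  expect_setequal(vapply(out$kept, function(r) r@accession, character(1)),
                  c("AC001"))
  expect_setequal(out$log$accession, c("AC002", "AC003", "AC004"))
  expect_identical(sort(out$log$rule), c("hybrid", "identical", "unannotated"))
  expect_identical(out$log$rule[out$log$accession == "AC004"], "identical")
})

test_that("filter outcome is invariant to input order", {
  recs <- list(
    makeRecord("AC001", features = makeFeature("cox1", 1, 18, cleanCox1)),
    makeRecord("AC002", features = makeFeature("cox1", 1, 18, cleanCox1)),
    makeRecord("AC003", features = makeFeature("cox1", 1, 18, farCox1)),
    makeRecord("AC004", isAnnotated = FALSE, taxonomy = character()))
  base <- applyDatasetFilters(recs)
  for (perm in list(c(2, 1, 4, 3), c(4, 3, 2, 1), c(3, 1, 2, 4))) {
    out <- applyDatasetFilters(recs[perm])
    expect_identical(
      vapply(out$kept, function(r) r@accession, character(1)),
      vapply(base$kept, function(r) r@accession, character(1)))
    expect_setequal(out$log$accession, base$log$accession)
  }
})

test_that("PCG matrix excludes atp8 by default and tracks occupancy", {
  gb <- simulateMitogenomeRecords(4, duplicateFraction = 0, seed = 31)
  recs <- lapply(readGenBankRecords(gb$text), standardizeGeneNames)
  pcg <- extractPcgMatrix(recs)
  expect_length(pcg, 12L)
  expect_false("atp8" %in% names(pcg))
  expect_true(all(vapply(pcg, length, integer(1)) == 4L))
  # species missing a gene is absent from only that set
  recs[[2]]@features <- recs[[2]]@features[recs[[2]]@features$gene != "nad5", ]
  pcg2 <- extractPcgMatrix(recs)
  expect_length(pcg2$nad5, 3L)
  expect_length(pcg2$cox1, 4L)
  occ <- attr(pcg2, "occupancy")
  expect_equal(occ$frac[occ$gene == "nad5"], 0.75)
  # empty input still yields the 12 empty gene sets
  empty <- extractPcgMatrix(list())
  expect_length(empty, 12L)
  expect_true(all(vapply(empty, length, integer(1)) == 0L))
  # unresolved duplicates are refused
  dup <- makeRecord("T1", features = rbind(
    makeFeature("cox1", 1, 18, cleanCox1),
    makeFeature("cox1", 100, 117, stopCox1)))
  expect_error(extractPcgMatrix(list(dup)), "resolveDuplicates")
})
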