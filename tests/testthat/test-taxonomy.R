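test_that("dereplication groups exact sequences and discards singletons", {
  ins <- list(s1 = c("AAA", "AAA", "AAA", "AAT"))
  u <- dereplicate(ins)
  expect_identical(u$uniques$sequence, "AAA")
  expect_identical(u$uniques$total, 3L)
  expect_identical(u$discarded$nSequences, 1L)
  expect_identical(u$discarded$nReads, 1L)
  # same sequence in two samples keeps per-sample counts
  u2 <- dereplicate(list(a = c("ACGT", "ACGT"), b = c("ACGT", "ACGT")))
  expect_identical(nrow(u2$uniques), 1L)
  expect_identical(u2$counts$count, c(2L, 2L))
  expect_identical(sort(u2$counts$sample_id), c("a", "b"))
  # all reads distinct: nothing survives
  u3 <- dereplicate(list(a = c("AAAA", "CCCC", "GGGG")))
  expect_identical(nrow(u3$uniques), 0L)
  expect_identical(u3$discarded$nReads, 3L)
  # count conservation
  expect_identical(sum(u$uniques$total) + u$discarded$nReads, 4L)
})

makeRefs <- function(seqs, species, genus = NULL) {
  if (is.null(genus)) genus <- paste0("G", seq_along(species))
  data.frame(accession = paste0("A", seq_along(seqs)), family = "F1",
             genus = genus, species = species, habitat = "marine",
             local = TRUE, fishery = FALSE, sequence = seqs,
             stringsAsFactors = FALSE)
}

asUniques <- function(seqs, counts = NULL, sample = "s1") {
  if (is.null(counts)) counts <- rep(2L, length(seqs))
  structure(list(
    uniques = data.frame(seq_id = sprintf("U%06d", seq_along(seqs)),
                         sequence = seqs, total = counts,
                         stringsAsFactors = FALSE),
    counts = data.frame(seq_id = sprintf("U%06d", seq_along(seqs)),
                        sample_id = sample, count = counts,
                        stringsAsFactors = FALSE),
    discarded = list(nSequences = 0L, nReads = 0L)), class = "UniqueSet")
}

test_that("identity arithmetic drives the 99% assignment threshold", {
  set.seed(4)
  refSeq <- replicate(3, rdna(170))
  ref <- makeRefs(refSeq, c("Sp one", "Sp two", "Sp three"))
  q <- c(refSeq[1],                       # exact
         mutateBases(refSeq[1], 10),      # 1 mismatch: 99.41%
         mutateBases(refSeq[1], c(10, 20)))  # 2 mismatches: 98.82%
  a <- searchReference(asUniques(q), ref)
  expect_equal(a$top_identity, c(100, 100 * 169 / 170, 100 * 168 / 170),
               tolerance = 1e-9)
  expect_identical(a$top_species, rep("Sp one", 3))
  expect_identical(a$assigned, c(TRUE, TRUE, FALSE))
  # queries shorter than the word size are unassigned with a note
  sh <- searchReference(asUniques("ACGTACGT"), ref)
  expect_false(sh$assigned)
  expect_match(sh$note, "word size")
})

test_that("reference search agrees with the all-references oracle", {
  set.seed(14)
  refSeq <- replicate(8, rdna(sample(160:180, 1)))
  species <- paste("Sp", 1:8)
  ref <- makeRefs(refSeq, species)
  queries <- c(
    vapply(1:60, function(i)
      mutateBases(refSeq[sample(8, 1)], sample(160, sample(0:4, 1))),
      character(1)),
    replicate(40, rdna(170)))
  a <- searchReference(asUniques(queries), ref)
  for (i in seq_along(queries)) {
    o <- rSearchOracle(queries[i], refSeq, species)
    expect_equal(a$top_identity[i], o$top_identity, tolerance = 1e-9)
    expect_equal(a$second_identity[i], o$second_identity, tolerance = 1e-9)
    if (o$top_identity > o$second_identity + 1e-9)
      expect_identical(a$top_species[i], o$top_species)
  }
})

test_that("confidence classes follow the runner-up identity", {
  set.seed(24)
  base <- rdna(170)
  refSeq <- c(base, mutateBases(base, 5), mutateBases(base, 1:40))
  ref <- makeRefs(refSeq, c("Sp a", "Sp b", "Sp far"),
                  genus = c("G1", "G1", "G2"))
  # top 100%, second 99.4% (congeneric pair): LOW
  a <- classifyConfidence(searchReference(asUniques(base), ref), ref)
  expect_identical(a$confidence, "LOW")
  # top 100%, second clearly separated: HIGH
  far <- rdna(170)
  ref2 <- makeRefs(c(far, refSeq[3]), c("Sp a", "Sp far"))
  a2 <- classifyConfidence(searchReference(asUniques(far), ref2), ref2)
  expect_identical(a2$confidence, "HIGH")
  # top 99.4, second 98.8: MODERATE under the 1-point margin
  q <- mutateBases(base, 100)
  a3 <- classifyConfidence(searchReference(asUniques(q), ref), ref)
  expect_identical(a3$top_identity > 99, TRUE)
  expect_identical(a3$second_identity < 99, TRUE)
  expect_identical(a3$confidence, "MODERATE")
})

test_that("OTUs cluster by species with worst-member confidence", {
  set.seed(34)
  refSeq <- c(rdna(170), rdna(170))
  ref <- makeRefs(refSeq, c("Sp a", "Sp b"))
  u <- asUniques(c(refSeq[1], mutateBases(refSeq[1], 7)), c(5L, 2L))
  a <- classifyConfidence(searchReference(u, ref), ref)
  ot <- clusterOtus(a, u, ref)
  expect_identical(nrow(ot$otus), 1L)
  expect_identical(ot$counts$reads, 7L)
  expect_identical(ot$otus$confidence, "HIGH")
  # two species: two OTUs
  u2 <- asUniques(refSeq, c(3L, 4L))
  a2 <- classifyConfidence(searchReference(u2, ref), ref)
  ot2 <- clusterOtus(a2, u2, ref)
  expect_identical(nrow(ot2$otus), 2L)
  expect_identical(sum(ot2$counts$reads), 7L)
  # nothing assigned: empty OTU list
  u3 <- asUniques(rdna(170))
  a3 <- classifyConfidence(searchReference(u3, ref), ref)
  expect_identical(nrow(clusterOtus(a3, u3, ref)$otus), 0L)
})

makeOtus <- function(taxa, conf, genus, reads = NULL, family = "F1",
                     tie = FALSE) {
  n <- length(taxa)
  if (is.null(reads)) reads <- rep(5L, n)
  structure(list(
    otus = data.frame(otu_id = sprintf("OTU%04d", seq_len(n)), taxon = taxa,
                      rank = "species", confidence = conf, genus = genus,
                      family = family, habitat = "marine", local = TRUE,
                      fishery = FALSE, tie_across_genera = tie, note = "",
                      stringsAsFactors = FALSE),
    counts = data.frame(otu_id = sprintf("OTU%04d", seq_len(n)),
                        sample_id = "s1", reads = reads,
                        stringsAsFactors = FALSE)), class = "OtuSet")
}

test_that("curation rule 1 resolves LOW OTUs through the checklist", {
  cl <- data.frame(species = c("Gx one", "Gy one", "Gy two", "Gy three"),
                   genus = c("Gx", "Gy", "Gy", "Gy"),
                   local = TRUE, substitute_for = NA_character_)
  # single local congener: species-rank assignment
  cur <- curateOtus(makeOtus("Gx other", "LOW", "Gx"), cl)
  expect_identical(cur$otus$taxon, "Gx one")
  expect_identical(cur$otus$rank, "species")
  # three local congeners: genus-rank "sp."
  cur2 <- curateOtus(makeOtus("Gy one", "LOW", "Gy"), cl)
  expect_identical(cur2$otus$taxon, "Gy sp.")
  expect_identical(cur2$otus$rank, "genus")
  # identity tie across genera: family rank
  cur3 <- curateOtus(makeOtus("Gy one", "LOW", "Gy", tie = TRUE), cl)
  expect_identical(cur3$otus$rank, "higher")
  expect_identical(cur3$otus$taxon, "F1")
})

test_that("curation rule 2 substitutes or annotates non-local species", {
  cl <- data.frame(species = c("Loc one", "Loc two"), genus = c("La", "Lb"),
                   local = TRUE,
                   substitute_for = c("Far one", NA))
  cur <- curateOtus(makeOtus("Far one", "HIGH", "Fa"), cl)
  expect_identical(cur$otus$taxon, "Loc one")
  expect_match(cur$otus$note, "rule2")
  cur2 <- curateOtus(makeOtus("Far two", "HIGH", "Fb"), cl)
  expect_identical(cur2$otus$taxon, "Far two")
  expect_match(cur2$otus$note, "non-local")
  # a substitution target outside the local set is a configuration error
  clBad <- data.frame(species = "Loc one", genus = "La", local = FALSE,
                      substitute_for = "Far one")
  expect_error(curateOtus(makeOtus("Far one", "HIGH", "Fa"), clBad),
               "substitution map")
})

test_that("curation merges converging OTUs, is order-independent and conserves reads", {
  cl <- data.frame(species = c("Gy one", "Gy two"), genus = "Gy",
                   local = TRUE, substitute_for = NA_character_)
  os <- makeOtus(c("Gy one", "Gy two", "Other sp"),
                 c("LOW", "LOW", "HIGH"), c("Gy", "Gy", "Oo"),
                 reads = c(4L, 6L, 3L))
  cur <- curateOtus(os, cl)
  gy <- cur$otus[cur$otus$taxon == "Gy sp.", ]
  expect_identical(nrow(gy), 1L)
  expect_identical(cur$counts$reads[cur$counts$otu_id == gy$otu_id], 10L)
  expect_identical(sum(cur$counts$reads), sum(os$counts$reads))
  # shuffled input produces the same curated table
  shuf <- structure(list(otus = os$otus[c(3, 1, 2), ],
                         counts = os$counts[c(2, 3, 1), ]), class = "OtuSet")
  cur2 <- curateOtus(shuf, cl)
  rownames(cur2$otus) <- rownames(cur$otus) <- NULL
  expect_equal(cur$otus$taxon, cur2$otus$taxon)
  expect_equal(cur$counts$reads, cur2$counts$reads)
})
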