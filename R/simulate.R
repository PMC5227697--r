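#' Fish-universal primer set (U and E variants)
#'
#' Two primer-pair variants targeting the hyper-variable 12S fragment. Each
#' full primer is the concatenation of a sequencing-adapter tail, a fixed
#' 6-mer pad and the variant-specific core; the variants differ by two bases
#' in the forward core and one base in the reverse core. Forward and reverse
#' primers total 127 bp, so an amplicon is insert + 127 bp.
#'
#' @return list with character vectors \code{forward} and \code{reverse},
#'   each named \code{c("U", "E")}.
#' @export
mifishPrimerSet <- function() {
  fwd_tail <- "ACACTCTTTCCCTACACGACGCTCTTCCGATCTCACGTA"    # 33 + 6 pad
  rev_tail <- "GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCTTGCAGT"   # 34 + 6 pad
  list(
    forward = c(U = paste0(fwd_tail, "GTCGGTAAAACTCGTGCCAGC"),
                E = paste0(fwd_tail, "GTTGGTAAATCTCGTGCCAGC")),
    reverse = c(U = paste0(rev_tail, "CATAGTGGGGTATCTAATCCCAGTTTG"),
                E = paste0(rev_tail, "CATAGTGGGGTATCTAATCCTAGTTTG")))
}

randomDna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

revComp <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

#' Generate a synthetic reference database
#'
#' Draws one ~170 bp 12S-like insert per species with pairwise identity at
#' most 97\% between species of different genera, except one designated
#' congeneric pair whose divergence is \code{congenericPairDivergence}
#' (default 0.005, i.e. a single base over a 170 bp insert) so that
#' LOW-confidence assignment and genus-level curation are exercised. Each
#' record carries family, genus, species, habitat class, a local-occurrence
#' flag and a fishery-target flag. Two species are reserved out of the
#' simulated communities: a terrestrial blank-contaminant species and a
#' non-local species.
#'
#' @param config a [SimulationConfig-class].
#' @param fastaPath optional path; when given the database is also written as
#'   a structured-header FASTA (see [writeReferenceFasta()]).
#' @param maxRetries attempts to draw a sequence satisfying the divergence
#'   floor before giving up.
#' @return data.frame of reference records with bookkeeping columns
#'   \code{inCommunity}, \code{isContaminant}, \code{isCongener}.
#' @export
generateReferenceDb <- function(config, fastaPath = NULL, maxRetries = 100L) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  S <- config@nSpecies
  set.seed(deriveSeed(config@seed, 1L))
  win <- config@insertWindow
  lens <- pmin(pmax(round(rnorm(S, config@insertLengthMean,
                                config@insertLengthSd)), win[1]), win[2])
  maxIdent <- 0.97
  seqs <- character(S)
  for (i in seq_len(S)) {
    if (i == 2L) next  # congener of species 1, built below
    ok <- FALSE
    for (try in seq_len(maxRetries)) {
      cand <- randomDna(1, lens[i])
      prev <- seqs[seq_len(i - 1L)]
      prev <- prev[nzchar(prev)]
      if (length(prev)) {
        d <- cpp_pairwise_hamming(rep(cand, length(prev)), prev)
        ident <- 1 - d / pmax(nchar(cand), nchar(prev))
        if (any(ident > maxIdent)) next
      }
      seqs[i] <- cand
      ok <- TRUE
      break
    }
    if (!ok) stop("could not satisfy the minimum-divergence constraint; ",
                  "reduce nSpecies or the divergence floor")
  }
  # congeneric pair: species 2 is species 1 with a fixed number of
  # substitutions implied by the configured divergence
  lens[2L] <- lens[1L]
  nSub <- max(1L, round(config@congenericPairDivergence * lens[1L]))
  s2 <- strsplit(seqs[1L], "")[[1]]
  pos <- sample(lens[1L], nSub)
  for (p in pos) s2[p] <- sample(setdiff(c("A", "C", "G", "T"), s2[p]), 1)
  seqs[2L] <- paste(s2, collapse = "")

  contIdx <- S                      # blank contaminant, terrestrial
  nonLocalIdx <- S - 1L             # in the database but not locally occurring
  communityIdx <- setdiff(seq_len(S), c(contIdx, nonLocalIdx))

  genus <- sprintf("Gen%02d", pmax(seq_len(S) - 1L, 1L))
  genus[1:2] <- "Gen01"
  spEpithet <- rep("sp1", S)
  spEpithet[2L] <- "sp2"
  species <- paste(genus, spEpithet)
  family <- sprintf("Fam%02d", ceiling(match(genus, unique(genus)) / 5))

  habitat <- rep("marine", S)
  habitat[contIdx] <- "terrestrial"
  pool <- setdiff(communityIdx, 1:2)
  nFresh <- round(config@freshwaterFraction * length(communityIdx))
  fresh <- if (nFresh > 0) sample(pool, min(nFresh, length(pool))) else integer(0)
  habitat[fresh] <- "freshwater"
  rest <- setdiff(pool, fresh)
  if (length(rest)) habitat[sample(rest, 1)] <- "diadromous"

  fishery <- rep(FALSE, S)
  marineIdx <- which(habitat == "marine" & seq_len(S) %in% communityIdx)
  if (length(marineIdx))
    fishery[sample(marineIdx, max(1L, round(0.3 * length(marineIdx))))] <- TRUE

  local <- rep(TRUE, S)
  local[c(nonLocalIdx, contIdx)] <- FALSE

  ref <- data.frame(accession = sprintf("ACC%03d", seq_len(S)),
                    family = family, genus = genus, species = species,
                    habitat = habitat, local = local, fishery = fishery,
                    sequence = seqs,
                    inCommunity = seq_len(S) %in% communityIdx,
                    isContaminant = seq_len(S) == contIdx,
                    isCongener = seq_len(S) %in% 1:2,
                    stringsAsFactors = FALSE)
  if (!is.null(fastaPath)) writeReferenceFasta(ref, fastaPath)
  ref
}

#' Simulate spatially structured fish communities
#'
#' Stations are laid out on a near-regular grid spanning the bay. Each
#' community species gets a 2D Gaussian occupancy kernel (random centre,
#' width \code{rangeScale}), a surface/bottom affinity, and a log-series
#' base abundance by rank; freshwater species are centred near a designated
#' river-mouth corner and are strongly surface-biased. Expected per-station,
#' per-layer relative abundances are the normalised product of base
#' abundance, kernel weight and layer affinity.
#'
#' @param config a [SimulationConfig-class].
#' @param reference reference data.frame from [generateReferenceDb()].
#' @return list (class \code{CommunitySimulation}) with \code{stations},
#'   \code{species} (kernel and affinity parameters), \code{composition}
#'   (station x layer x species array of expected relative abundances) and
#'   \code{trueSets} (species at or above \code{presenceThreshold} per
#'   station/layer).
#' @export
simulateCommunities <- function(config, reference) {
  stopifnot(is(config, "SimulationConfig"))
  if (config@nLayers != 2L) stop("community model assumes 2 layers")
  set.seed(deriveSeed(config@seed, 2L))
  bx <- config@bayExtent[1]; by <- config@bayExtent[2]
  nSt <- config@nStations
  nx <- ceiling(sqrt(nSt * bx / by))
  ny <- ceiling(nSt / nx)
  gx <- (rep(seq_len(nx), times = ny) - 0.5) / nx * bx
  gy <- (rep(seq_len(ny), each = nx) - 0.5) / ny * by
  stations <- data.frame(station_id = sprintf("St%02d", seq_len(nSt)),
                         x_m = gx[seq_len(nSt)], y_m = gy[seq_len(nSt)],
                         stringsAsFactors = FALSE)

  comm <- reference[reference$inCommunity, , drop = FALSE]
  S <- nrow(comm)
  rank <- seq_len(S)
  base <- config@logseriesTheta^rank / rank
  cx <- runif(S, 0, bx); cy <- runif(S, 0, by)
  aff <- rbeta(S, 2, 2)
  isFresh <- comm$habitat == "freshwater"
  # river mouth in the (0, by) corner of the bay
  cx[isFresh] <- runif(sum(isFresh), 0, 0.15 * bx)
  cy[isFresh] <- runif(sum(isFresh), 0.85 * by, by)
  aff[isFresh] <- runif(sum(isFresh), 0.85, 1)
  aff[comm$habitat == "diadromous"] <- runif(sum(comm$habitat == "diadromous"), 0.6, 0.95)

  d2 <- outer(stations$x_m, cx, "-")^2 + outer(stations$y_m, cy, "-")^2
  w <- exp(-d2 / (2 * config@rangeScale^2))      # rangeScale = Inf -> 1
  layers <- c("surface", "bottom")
  comp <- array(0, dim = c(nSt, 2L, S),
                dimnames = list(stations$station_id, layers, comm$species))
  for (l in 1:2) {
    lw <- if (l == 1L) aff else 1 - aff
    m <- sweep(w, 2, base * lw, "*")
    rs <- rowSums(m)
    comp[, l, ] <- m / ifelse(rs > 0, rs, 1)
  }
  trueSets <- list()
  for (st in seq_len(nSt)) for (l in 1:2)
    trueSets[[paste(stations$station_id[st], layers[l], sep = ".")]] <-
      comm$species[comp[st, l, ] >= config@presenceThreshold]

  structure(list(stations = stations,
                 species = cbind(comm,
                                 data.frame(rank = rank, baseAbundance = base,
                                            centreX = cx, centreY = cy,
                                            surfaceAffinity = aff)),
                 composition = comp, trueSets = trueSets),
            class = "CommunitySimulation")
}

#' Simulate paired-end amplicon reads with ground truth
#'
#' Emits two FASTQ files per PCR sample (mates R1/R2), a sample sheet and a
#' per-read provenance table. Field samples draw insert templates from the
#' station/layer community in proportion to expected abundance; a configured
#' fraction of reads are two-parent bimeras (random breakpoint at least 30 bp
#' from both amplicon ends) and a small fraction are cross-contamination from
#' the designated contaminant species. Negative controls receive only
#' contaminant reads at \code{contaminantRate * readsPerSample}. Per-base
#' substitution errors are applied independently to both mates, and Phred
#' qualities decline towards the 3' end (Normal(38 - 0.1 pos, 3), clipped to
#' [2, 40]) so that tail trimming is exercised. Everything is deterministic
#' under the configuration seed.
#'
#' @param config a [SimulationConfig-class].
#' @param communities output of [simulateCommunities()].
#' @param reference reference data.frame from [generateReferenceDb()].
#' @param outDir directory for FASTQ files and the sample sheet.
#' @return list (class \code{GroundTruth}): \code{sampleSheet},
#'   \code{reads} (per-read provenance: species, class source | chimera |
#'   contaminant, second parent, error count, clean flag), \code{reference},
#'   \code{communities}, \code{contaminantSpecies}, \code{congenericPair},
#'   \code{fastqDir}.
#' @export
simulateReads <- function(config, communities, reference, outDir) {
  stopifnot(is(config, "SimulationConfig"))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  set.seed(deriveSeed(config@seed, 3L))
  primers <- mifishPrimerSet()
  rcRev <- vapply(primers$reverse, revComp, character(1))
  comm <- communities$species
  refSeq <- setNames(reference$sequence, reference$species)
  contSp <- reference$species[reference$isContaminant]
  contAmp <- c(U = paste0(primers$forward["U"], refSeq[contSp], rcRev["U"]),
               E = paste0(primers$forward["E"], refSeq[contSp], rcRev["E"]))
  layers <- c("surface", "bottom")
  L <- config@readLength
  qualMean <- 38 - 0.1 * (seq_len(L) - 1)

  sheet <- list(); prov <- list()
  stn <- communities$stations
  for (st in seq_len(config@nStations)) for (l in 1:2)
    for (r in seq_len(config@nReplicates)) {
      sid <- sprintf("%s-%s-%d", stn$station_id[st], c("S", "B")[l], r)
      sheet[[sid]] <- data.frame(sample_id = sid,
                                 station_id = stn$station_id[st],
                                 layer = layers[l], replicate = r,
                                 is_negative = FALSE, x_m = stn$x_m[st],
                                 y_m = stn$y_m[st], stringsAsFactors = FALSE)
    }
  for (k in seq_len(config@nNegativeControls)) {
    sid <- sprintf("NC%02d", k)
    sheet[[sid]] <- data.frame(sample_id = sid, station_id = NA_character_,
                               layer = NA_character_, replicate = k,
                               is_negative = TRUE, x_m = NA_real_,
                               y_m = NA_real_, stringsAsFactors = FALSE)
  }
  sheet <- do.call(rbind, sheet)
  rownames(sheet) <- NULL

  emit <- function(sid, ampSeq, spName, cls, parent2) {
    n <- length(ampSeq)
    ids <- sprintf("%s:%05d", sid, seq_len(n))
    r1 <- substr(ampSeq, 1L, L)
    r2 <- revComp(substr(ampSeq, nchar(ampSeq) - L + 1L, nchar(ampSeq)))
    e1 <- rbinom(n, L, config@substitutionErrorRate)
    e2 <- rbinom(n, L, config@substitutionErrorRate)
    r1 <- cpp_apply_substitutions(r1, e1)
    r2 <- cpp_apply_substitutions(r2, e2)
    mkq <- function() {
      q <- matrix(round(rnorm(n * L, mean = rep(qualMean, each = n), sd = 3)), n, L)
      cpp_quals_to_strings(pmin(pmax(q, 2L), 40L))
    }
    q1 <- mkq(); q2 <- mkq()
    for (mate in 1:2) {
      x <- DNAStringSet(if (mate == 1) r1 else r2)
      names(x) <- ids
      writeXStringSet(x, file.path(outDir, sprintf("%s_R%d.fastq", sid, mate)),
                      format = "fastq",
                      qualities = BStringSet(if (mate == 1) q1 else q2))
    }
    data.frame(read_id = ids, sample_id = sid, species = spName, class = cls,
               parent2 = parent2, errors = e1 + e2,
               clean = cls == "source" & (e1 + e2) == 0L,
               stringsAsFactors = FALSE)
  }

  for (i in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[i]
    if (sheet$is_negative[i]) {
      n <- round(config@contaminantRate * config@readsPerSample)
      if (n == 0) {       # still write empty FASTQs so the sample exists
        for (mate in 1:2)
          writeXStringSet(DNAStringSet(), format = "fastq",
                          file.path(outDir, sprintf("%s_R%d.fastq", sid, mate)),
                          qualities = BStringSet())
        next
      }
      v <- ifelse(runif(n) < config@primerMixture, "U", "E")
      prov[[sid]] <- emit(sid, unname(contAmp[v]), contSp, "contaminant",
                          NA_character_)
      next
    }
    stIdx <- match(sheet$station_id[i], stn$station_id)
    lIdx <- match(sheet$layer[i], layers)
    pi <- communities$composition[stIdx, lIdx, ]
    n <- config@readsPerSample
    if (sum(pi) == 0) pi <- rep(1, length(pi))
    spIdx <- sample(nrow(comm), n, replace = TRUE, prob = pi)
    spName <- comm$species[spIdx]
    cls <- rep("source", n)
    cross <- runif(n) < config@crossContaminationRate
    spName[cross] <- contSp
    cls[cross] <- "contaminant"
    v <- ifelse(runif(n) < config@primerMixture, "U", "E")
    amp <- paste0(primers$forward[v], refSeq[spName], rcRev[v])
    parent2 <- rep(NA_character_, n)
    chim <- which(runif(n) < config@chimeraRate & !cross)
    for (j in chim) {
      pi2 <- pi
      pi2[match(spName[j], comm$species)] <- 0   # a bimera needs two parents
      if (sum(pi2) == 0) next
      p2 <- comm$species[sample(nrow(comm), 1, prob = pi2)]
      a1 <- amp[j]
      a2 <- paste0(primers$forward[v[j]], refSeq[p2], rcRev[v[j]])
      bmax <- min(nchar(a1), nchar(a2)) - 30L
      if (bmax < 30L) next
      b <- sample(30:bmax, 1)
      amp[j] <- paste0(substr(a1, 1, b), substr(a2, b + 1L, nchar(a2)))
      cls[j] <- "chimera"
      parent2[j] <- p2
    }
    prov[[sid]] <- emit(sid, amp, spName, cls, parent2)
  }

  writeSampleSheet(sheet, file.path(outDir, "sample_sheet.csv"))
  structure(list(sampleSheet = sheet,
                 reads = do.call(rbind, c(prov, list(make.row.names = FALSE))),
                 reference = reference, communities = communities,
                 contaminantSpecies = contSp,
                 congenericPair = reference$species[reference$isCongener],
                 fastqDir = outDir),
            class = "GroundTruth")
}

#' One-call synthetic dataset
#'
#' Generates the reference database, communities and reads, writing the
#' reference FASTA, per-sample FASTQs, the sample sheet and the ground-truth
#' files (summary JSON + per-read provenance TSV) under \code{outDir}.
#'
#' @param config a [SimulationConfig-class].
#' @param outDir output directory.
#' @return the \code{GroundTruth} list, with \code{referencePath} and
#'   \code{sampleSheetPath} added.
#' @export
simulateDataset <- function(config, outDir) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  refPath <- file.path(outDir, "reference.fasta")
  ref <- generateReferenceDb(config, fastaPath = refPath)
  commu <- simulateCommunities(config, ref)
  gt <- simulateReads(config, commu, ref, file.path(outDir, "fastq"))
  gt$referencePath <- refPath
  gt$sampleSheetPath <- file.path(outDir, "fastq", "sample_sheet.csv")
  writeGroundTruth(gt, outDir)
  gt
}

#' @rdname simulateDataset
#' @param gt a \code{GroundTruth} list.
#' @export
writeGroundTruth <- function(gt, outDir) {
  write.table(gt$reads, file.path(outDir, "ground_truth_reads.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  summary <- list(
    contaminant_species = gt$contaminantSpecies,
    congeneric_pair = gt$congenericPair,
    provenance_counts = as.list(table(gt$reads$class)),
    true_sets = gt$communities$trueSets)
  write_json(summary, file.path(outDir, "ground_truth.json"),
             auto_unbox = TRUE, pretty = TRUE)
  invisible(outDir)
}

#' Ground-truth recovery statistics
#'
#' Scores a pipeline detection matrix against simulation ground truth. The
#' denominator is every (PCR sample, species) cell with at least
#' \code{minCleanReads} clean reads (error-free, non-chimeric source reads);
#' a cell counts as recovered when the species -- or its genus-level curated
#' OTU (\code{"Genus sp."}) -- is detected in that sample. Also reports
#' detections of the blank contaminant species (expected 0 after
#' decontamination) and how the designated congeneric pair was reported.
#'
#' @param dm a [DetectionMatrix-class] from the pipeline.
#' @param gt \code{GroundTruth} from [simulateReads()]/[simulateDataset()].
#' @param minCleanReads clean-read threshold defining the denominator.
#' @return list with \code{recoveryRate} (\%), \code{nTruth},
#'   \code{nRecovered}, \code{contaminantDetections},
#'   \code{congenericGenusRank}, \code{congenericLowConfidence}.
#' @export
recoveryStats <- function(dm, gt, minCleanReads = 10L) {
  prov <- gt$reads
  cleanTab <- table(prov$sample_id[prov$clean], prov$species[prov$clean])
  cells <- which(cleanTab >= minCleanReads, arr.ind = TRUE)
  sampleIds <- rownames(cleanTab)[cells[, 1]]
  speciesIds <- colnames(cleanTab)[cells[, 2]]
  keep <- sampleIds %in% colnames(dm)
  sampleIds <- sampleIds[keep]; speciesIds <- speciesIds[keep]

  rd <- as.data.frame(rowData(dm))
  det <- detections(dm)
  genusOf <- setNames(gt$reference$genus, gt$reference$species)
  candidates <- function(sp) c(sp, paste(genusOf[[sp]], "sp."))
  hit <- vapply(seq_along(sampleIds), function(k) {
    rows <- which(rd$taxon %in% candidates(speciesIds[k]))
    length(rows) > 0 && any(det[rows, sampleIds[k]])
  }, logical(1))

  contRows <- which(rd$taxon %in% candidates(gt$contaminantSpecies))
  contDet <- if (length(contRows)) sum(det[contRows, , drop = FALSE]) else 0L

  pairGenus <- paste(genusOf[[gt$congenericPair[1]]], "sp.")
  pairRows <- which(rd$taxon == pairGenus)
  list(recoveryRate = 100 * mean(hit), nTruth = length(hit),
       nRecovered = sum(hit), contaminantDetections = contDet,
       congenericGenusRank = length(pairRows) > 0 &&
         all(rd$rank[pairRows] == "genus"),
       congenericLowConfidence = length(pairRows) > 0 &&
         all(rd$confidence[pairRows] == "LOW"))
}
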