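# Independent, pure-R oracles and small fixture builders. Nothing here calls
# into the package's C++ paths it is used to check.

qstr <- function(q) intToUtf8(q + 33L)

rdna <- function(len) paste(sample(c("A", "C", "G", "T"), len, TRUE),
                            collapse = "")

mutateBases <- function(seq, positions) {
  v <- strsplit(seq, "")[[1]]
  for (p in positions) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
  paste(v, collapse = "")
}

rHamming <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- min(length(av), length(bv))
  sum(av[seq_len(n)] != bv[seq_len(n)]) + abs(length(av) - length(bv))
}

# exhaustive merge-offset scan: max matching bases among admissible offsets,
# ties to the larger overlap
rMergeOracle <- function(s1, s2rc, minOverlap = 10, maxFrac = 0.25) {
  n1 <- nchar(s1); n2 <- nchar(s2rc)
  best <- NULL
  if (min(n1, n2) >= minOverlap) for (o in minOverlap:min(n1, n2)) {
    av <- strsplit(substring(s1, n1 - o + 1, n1), "")[[1]]
    bv <- strsplit(substring(s2rc, 1, o), "")[[1]]
    m <- sum(av == bv)
    if ((o - m) / o > maxFrac) next
    if (is.null(best) || m > best$m || (m == best$m && o > best$o))
      best <- list(o = o, m = m)
  }
  best
}

# all-references identity scan with per-species maxima
rSearchOracle <- function(query, refSeqs, refSpecies) {
  ident <- vapply(refSeqs, function(r) {
    n <- min(nchar(query), nchar(r))
    qv <- strsplit(query, "")[[1]][seq_len(n)]
    rv <- strsplit(r, "")[[1]][seq_len(n)]
    100 * sum(qv == rv) / nchar(query)
  }, numeric(1))
  bySp <- tapply(ident, refSpecies, max)
  ord <- order(-bySp)
  list(top_species = names(bySp)[ord[1]],
       top_identity = unname(bySp[ord[1]]),
       second_species = names(bySp)[ord[2]],
       second_identity = unname(bySp[ord[2]]))
}

# brute-force bimera scan over all parent pairs and breakpoints
rBimeraOracle <- function(seqs, counts, minFold = 2, maxMm = 1, margin = 75,
                          minParentDiv = 3, minCandDiv = 2) {
  n <- length(seqs)
  flagged <- rep(FALSE, n)
  mmLeft <- function(c, a, b) {
    if (b > nchar(a)) return(Inf)
    cv <- strsplit(substring(c, 1, b), "")[[1]]
    av <- strsplit(substring(a, 1, b), "")[[1]]
    sum(cv != av)
  }
  mmRight <- function(c, a, b) {
    sl <- nchar(c) - b
    if (sl > nchar(a)) return(Inf)
    cv <- strsplit(substring(c, b + 1, nchar(c)), "")[[1]]
    av <- strsplit(substring(a, nchar(a) - sl + 1, nchar(a)), "")[[1]]
    sum(cv != av)
  }
  for (ci in order(-counts)) {
    Lc <- nchar(seqs[ci])
    if (Lc < 2 * margin) next
    pars <- which(!flagged & counts >= minFold * counts[ci] &
                    seq_len(n) != ci)
    pars <- pars[vapply(pars, function(p)
      rHamming(seqs[ci], seqs[p]) >= minCandDiv, logical(1))]
    if (length(pars) < 2) next
    hit <- FALSE
    for (ja in pars) {
      for (jb in setdiff(pars, ja)) {
        if (rHamming(seqs[ja], seqs[jb]) < minParentDiv) next
        for (b in margin:(Lc - margin)) {
          mmL <- mmLeft(seqs[ci], seqs[ja], b)
          mmR <- mmRight(seqs[ci], seqs[jb], b)
          if (mmL > maxMm || mmR > maxMm) next
          if (mmL + mmR < rHamming(seqs[ci], seqs[ja]) &&
              mmL + mmR < rHamming(seqs[ci], seqs[jb])) { hit <- TRUE; break }
        }
        if (hit) break
      }
      if (hit) break
    }
    flagged[ci] <- hit
  }
  flagged
}

# recursive permutation enumeration (distinct from the package's internal)
rAllPerms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in rAllPerms(n - 1L)) for (pos in seq_len(n)) {
    out[[length(out) + 1L]] <- append(sub, n, after = pos - 1L)
  }
  out
}

# direct per-permutation Mantel correlogram p values via cor()
rMantelExactOracle <- function(comm, coords, nClasses) {
  n <- nrow(comm)
  D <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- sum(abs(comm[i, ] - comm[j, ])) /
      sum(comm[i, ] + comm[j, ])
  gd <- as.matrix(dist(coords))
  gv <- gd[lower.tri(gd)]
  breaks <- seq(min(gv), max(gv), length.out = nClasses + 1)
  cls <- cut(gv, breaks, include.lowest = TRUE, labels = FALSE)
  perms <- rAllPerms(n)
  keep <- which(tabulate(cls, nClasses) >= 2)
  res <- lapply(keep, function(k) {
    ind <- as.numeric(cls == k)
    rObs <- -cor(D[lower.tri(D)], ind)
    rAll <- vapply(perms, function(p) {
      Dp <- D[p, p]
      -cor(Dp[lower.tri(Dp)], ind)
    }, numeric(1))
    p <- if (rObs >= 0) mean(rAll >= rObs - 1e-12)
         else mean(rAll <= rObs + 1e-12)
    c(class = k, r = rObs, p = p)
  })
  do.call(rbind, res)
}

# DetectionMatrix from a long table (sample metadata + taxon x detection)
makeDM <- function(long, rowMeta = NULL, cutoff = 0) {
  samples <- unique(long[, c("sample_id", "station_id", "layer", "replicate")])
  samples$is_negative <- FALSE
  if (is.null(samples$x_m)) {
    samples$x_m <- as.numeric(factor(samples$station_id)) * 100
    samples$y_m <- 0
  }
  taxa <- sort(unique(long$taxon))
  cnt <- matrix(0L, length(taxa), nrow(samples),
                dimnames = list(taxa, samples$sample_id))
  det <- matrix(FALSE, length(taxa), nrow(samples),
                dimnames = dimnames(cnt))
  for (i in seq_len(nrow(long))) {
    r <- match(long$taxon[i], taxa)
    cc <- match(long$sample_id[i], samples$sample_id)
    cnt[r, cc] <- if (is.null(long$reads)) 1L else long$reads[i]
    det[r, cc] <- TRUE
  }
  if (is.null(rowMeta))
    rowMeta <- data.frame(taxon = taxa, rank = "species", confidence = "HIGH",
                          habitat = "marine", fishery = FALSE,
                          local = TRUE, stringsAsFactors = FALSE)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cnt, detected = det),
    rowData = S4Vectors::DataFrame(rowMeta, row.names = taxa),
    colData = S4Vectors::DataFrame(samples, row.names = samples$sample_id))
  new("DetectionMatrix", se, cutoff = cutoff)
}

# small simulation config for module tests
tinyConfig <- function(seed = 11, ...) {
  SimulationConfig(seed = seed, nSpecies = 10L, nStations = 6L,
                   readsPerSample = 150L, nNegativeControls = 3L, ...)
}
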