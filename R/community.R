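#' Station-level community matrix from a detection matrix
#'
#' Pools the PCR samples of each station into one community vector per
#' station. The default abundance proxy is the number of positive PCR
#' detections per species (0--6 over 2 layers x 3 replicates);
#' \code{"presence"} reduces that to 0/1 (Bray-Curtis then equals Sorensen)
#' and \code{"reads"} sums raw read counts of detected cells.
#'
#' @param dm a [DetectionMatrix-class].
#' @param value abundance proxy.
#' @return stations x taxa numeric matrix, with station coordinates in
#'   \code{attr(, "coords")}.
#' @export
stationCommunity <- function(dm, value = c("detections", "presence", "reads")) {
  value <- match.arg(value)
  cd <- as.data.frame(colData(dm))
  det <- detections(dm)
  cnt <- readCounts(dm)
  stations <- unique(cd$station_id)
  out <- matrix(0, length(stations), nrow(dm),
                dimnames = list(stations, rownames(dm)))
  for (s in seq_along(stations)) {
    cols <- which(cd$station_id == stations[s])
    out[s, ] <- switch(value,
      detections = rowSums(det[, cols, drop = FALSE]),
      presence = as.numeric(rowSums(det[, cols, drop = FALSE]) > 0),
      reads = rowSums((cnt * det)[, cols, drop = FALSE]))
  }
  coords <- cd[match(stations, cd$station_id), c("x_m", "y_m")]
  rownames(coords) <- stations
  attr(out, "coords") <- coords
  out
}

#' Species gain with PCR replication
#'
#' For each station and layer, averages the number of distinct species
#' detected over every size-k subset of the PCR replicates, then averages
#' across stations; reported for k = 1..R.
#'
#' @param dm a [DetectionMatrix-class].
#' @param layer \code{"surface"} or \code{"bottom"}.
#' @return data.frame \code{k, mean_species}.
#' @export
replicateAccumulation <- function(dm, layer = c("surface", "bottom")) {
  layer <- match.arg(layer)
  cd <- as.data.frame(colData(dm))
  det <- detections(dm)
  cols <- which(cd$layer == layer)
  stations <- unique(cd$station_id[cols])
  R <- max(cd$replicate[cols])
  perStation <- matrix(NA_real_, length(stations), R)
  skipped <- character(0)
  for (s in seq_along(stations)) {
    sc <- cols[cd$station_id[cols] == stations[s]]
    if (length(sc) < R) { skipped <- c(skipped, stations[s]); next }
    sets <- lapply(sc, function(j) which(det[, j]))
    for (k in seq_len(R)) {
      subs <- combn(length(sets), k, simplify = FALSE)
      perStation[s, k] <- mean(vapply(subs, function(ss)
        length(unique(unlist(sets[ss]))), numeric(1)))
    }
  }
  if (length(skipped))
    warning("stations with missing replicates excluded: ",
            paste(skipped, collapse = ", "))
  data.frame(k = seq_len(R),
             mean_species = colMeans(perStation, na.rm = TRUE))
}

#' Chao1 richness from replicate incidence
#'
#' Here a singleton is a species detected in exactly one PCR replicate of a
#' water sample and a doubleton one detected in exactly two. The
#' bias-corrected form \code{S_obs + f1(f1-1)/(2(f2+1))} stays defined at
#' \code{f2 = 0}; the classic form \code{S_obs + f1^2/(2 f2)} is available
#' and returns Inf when \code{f1 > 0, f2 = 0}.
#'
#' @param x species x replicates incidence matrix (logical/0-1), or an
#'   integer vector giving each species' number of positive replicates.
#' @param corrected use the bias-corrected form.
#' @return data.frame \code{S_obs, f1, f2, chao1}.
#' @export
chao1 <- function(x, corrected = TRUE) {
  counts <- if (is.matrix(x)) rowSums(x > 0) else as.integer(x)
  sObs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  est <- if (corrected) sObs + f1 * (f1 - 1) / (2 * (f2 + 1))
         else if (f2 > 0) sObs + f1^2 / (2 * f2)
         else if (f1 == 0) sObs else Inf
  data.frame(S_obs = sObs, f1 = f1, f2 = f2, chao1 = est)
}

#' Per-sample Chao1 richness across a detection matrix
#'
#' @param dm a [DetectionMatrix-class].
#' @param corrected use the bias-corrected Chao1 form.
#' @return data.frame with one row per station x layer.
#' @export
chao1Richness <- function(dm, corrected = TRUE) {
  cd <- as.data.frame(colData(dm))
  det <- detections(dm)
  combos <- unique(cd[, c("station_id", "layer")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    cols <- which(cd$station_id == combos$station_id[i] &
                    cd$layer == combos$layer[i])
    cbind(combos[i, , drop = FALSE],
          chao1(det[, cols, drop = FALSE], corrected = corrected))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Surface/bottom partition of the detected species pool
#'
#' Pools incidence over stations and replicates within each layer and splits
#' the species total into surface-only, bottom-only and shared sets; also
#' counts detection events (positive species x PCR-sample cells) per layer.
#' The three set sizes always sum to the species total.
#'
#' @param dm a [DetectionMatrix-class].
#' @return list \code{surfaceOnly, bottomOnly, both, total, events}.
#' @export
partitionByLayer <- function(dm) {
  cd <- as.data.frame(colData(dm))
  det <- detections(dm)
  surf <- rowSums(det[, cd$layer == "surface", drop = FALSE]) > 0
  bott <- rowSums(det[, cd$layer == "bottom", drop = FALSE]) > 0
  list(surfaceOnly = sum(surf & !bott), bottomOnly = sum(!surf & bott),
       both = sum(surf & bott), total = sum(surf | bott),
       events = c(surface = sum(det[, cd$layer == "surface", drop = FALSE]),
                  bottom = sum(det[, cd$layer == "bottom", drop = FALSE])))
}

#' Species counts per station by group
#'
#' Per station (layers and replicates pooled): all fish species, fishery
#' targets and freshwater species. Taxa with missing group flags count only
#' towards the all-fish total.
#'
#' @param dm a [DetectionMatrix-class].
#' @return data.frame \code{station_id, n_all, n_fishery, n_freshwater}.
#' @export
stationGroupCounts <- function(dm) {
  cd <- as.data.frame(colData(dm))
  rd <- as.data.frame(rowData(dm))
  det <- detections(dm)
  fishery <- !is.na(rd$fishery) & rd$fishery
  fresh <- !is.na(rd$habitat) & rd$habitat == "freshwater"
  stations <- unique(cd$station_id)
  rows <- lapply(stations, function(st) {
    present <- rowSums(det[, cd$station_id == st, drop = FALSE]) > 0
    data.frame(station_id = st, n_all = sum(present),
               n_fishery = sum(present & fishery),
               n_freshwater = sum(present & fresh))
  })
  do.call(rbind, rows)
}

#' Bray-Curtis dissimilarity between two communities
#'
#' \code{sum(|x - y|) / sum(x + y)}; 0 for identical vectors, 1 for disjoint
#' supports. On presence/absence data it equals Sorensen dissimilarity.
#'
#' @param x,y non-negative abundance vectors of equal length.
#' @return dissimilarity in [0, 1].
#' @export
brayCurtis <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  tot <- sum(x + y)
  if (tot == 0) stop("Bray-Curtis is undefined for two all-zero vectors")
  sum(abs(x - y)) / tot
}

# lower-triangle Bray-Curtis vector for a station x species matrix,
# aligned with the pair indexing of stats::dist
brayCurtisVec <- function(comm) {
  man <- as.vector(dist(comm, method = "manhattan"))
  rs <- rowSums(comm)
  if (any(rs == 0)) stop("station(s) with all-zero communities")
  n <- nrow(comm)
  I <- rep(seq_len(n - 1), times = (n - 1):1)
  J <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
  man / (rs[I] + rs[J])
}

#' Mantel correlogram of community dissimilarity against distance
#'
#' Bins the geographic distances between stations into equal-width classes
#' (Sturges' rule on the number of pairs unless \code{nClasses} is given) and
#' computes, per class, the Mantel statistic between the Bray-Curtis
#' dissimilarity matrix and the class-membership model matrix. The sign is
#' oriented so that a positive statistic means positive spatial
#' autocorrelation (communities within the class more similar than average).
#' Significance is assessed by permuting station labels (one-tailed in the
#' direction of the observed sign). Raw p values receive a Holm correction
#' over all tested classes by default, which controls the familywise error
#' rate across the correlogram; \code{progressive = TRUE} instead corrects
#' each class only for the classes at shorter distances (the first class is
#' then tested uncorrected). Classes with fewer than two member pairs are
#' dropped.
#'
#' @param comm stations x species abundance matrix (see
#'   [stationCommunity()]).
#' @param coords stations x 2 matrix/data.frame of planar coordinates (m).
#' @param nClasses number of distance classes; NA for Sturges' rule.
#' @param nPerm permutations (0: statistics only, p values NA).
#' @param seed RNG seed for the permutations.
#' @param exact enumerate all station permutations instead of sampling
#'   (factorial cost; only sensible for <= 8 stations).
#' @param alpha significance level applied to the corrected p values.
#' @param progressive use the class-by-class progressive correction instead
#'   of the full Holm correction.
#' @return a [CorrelogramResult-class].
#' @export
mantelCorrelogram <- function(comm, coords, nClasses = NA, nPerm = 999,
                              seed = NULL, exact = FALSE, alpha = 0.05,
                              progressive = FALSE) {
  n <- nrow(comm)
  if (n < 4) stop("need at least 4 stations")
  stopifnot(nrow(coords) == n)
  dvec <- brayCurtisVec(comm)
  gd <- as.vector(dist(as.matrix(coords)))
  m <- length(gd)
  k <- if (is.na(nClasses)) ceiling(log2(m)) + 1L else as.integer(nClasses)
  breaks <- seq(min(gd), max(gd), length.out = k + 1L)
  cls <- cut(gd, breaks, include.lowest = TRUE, labels = FALSE)
  nPairs <- tabulate(cls, nbins = k)
  keep <- which(nPairs >= 2)

  I <- rep(seq_len(n - 1), times = (n - 1):1)
  J <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
  sdD <- sd(dvec)
  rObs <- sObs <- rep(NA_real_, length(keep))
  for (ii in seq_along(keep)) {
    ind <- as.numeric(cls == keep[ii])
    sObs[ii] <- sum(dvec[cls == keep[ii]])
    rObs[ii] <- if (sdD > 0) -cor(dvec, ind) else NA_real_
  }

  pRaw <- rep(NA_real_, length(keep))
  if ((nPerm > 0 || exact) && sdD > 0) {
    Dmat <- matrix(0, n, n)
    Dmat[cbind(I, J)] <- dvec
    Dmat <- Dmat + t(Dmat)
    if (exact) {
      P <- allPermutations(n)
    } else {
      if (!is.null(seed)) set.seed(seed)
      P <- t(vapply(seq_len(nPerm), function(b) sample.int(n), integer(n)))
    }
    # class sums are a sufficient statistic for the Mantel r under
    # permutation: the multiset of dissimilarities is invariant, so r is a
    # decreasing function of the within-class sum
    B <- nrow(P)
    dperm <- matrix(0, m, B)
    for (b in seq_len(B)) {
      p <- P[b, ]
      dperm[, b] <- Dmat[cbind(p[I], p[J])]
    }
    M <- vapply(keep, function(kk) as.numeric(cls == kk),
                numeric(m))                      # m x length(keep)
    Ssum <- crossprod(M, dperm)                  # class x B
    for (ii in seq_along(keep)) {
      if (is.na(rObs[ii])) next
      eps <- 1e-12
      if (exact) {
        pRaw[ii] <- if (rObs[ii] >= 0) mean(Ssum[ii, ] <= sObs[ii] + eps)
                    else mean(Ssum[ii, ] >= sObs[ii] - eps)
      } else {
        hits <- if (rObs[ii] >= 0) sum(Ssum[ii, ] <= sObs[ii] + eps)
                else sum(Ssum[ii, ] >= sObs[ii] - eps)
        pRaw[ii] <- (hits + 1) / (B + 1)
      }
    }
  }
  pCorr <- rep(NA_real_, length(keep))
  if (any(!is.na(pRaw))) {
    if (progressive) {
      for (ii in seq_along(keep))
        pCorr[ii] <- p.adjust(pRaw[seq_len(ii)], method = "holm")[ii]
    } else pCorr <- p.adjust(pRaw, method = "holm")
  }

  tab <- data.frame(class = keep, d_lower = breaks[keep],
                    d_upper = breaks[keep + 1L],
                    midpoint = (breaks[keep] + breaks[keep + 1L]) / 2,
                    n_pairs = nPairs[keep], mantel_r = rObs, p_value = pRaw,
                    p_corrected = pCorr,
                    significant = !is.na(pCorr) & pCorr <= alpha)
  new("CorrelogramResult", table = tab,
      nPermutations = as.integer(if (exact) 0L else nPerm), exact = exact)
}

#' Sample-based rarefaction (species accumulation) curve
#'
#' Exact hypergeometric expectation: with T censuses of which \code{T_i}
#' contain species i, the expected richness after t censuses is
#' \code{S(t) = sum_i [1 - choose(T - T_i, t)/choose(T, t)]}. The confidence
#' band uses the closed-form variance including between-species joint
#' occurrence terms.
#'
#' @param census census data.frame \code{census_id, species, count}
#'   ([readCensusTable()]); a record with positive count marks presence.
#' @return data.frame (class \code{AccumulationCurve}) \code{t, richness,
#'   sd}; \code{S(T)} equals the total observed species count.
#' @export
accumulationCurve <- function(census) {
  census <- census[census$count > 0, , drop = FALSE]
  if (nrow(census) == 0) stop("census table has no positive records")
  inc <- table(census$census_id, census$species) > 0
  Tn <- nrow(inc)
  Ti <- colSums(inc)
  joint <- crossprod(inc)                       # species x species co-occurrence
  u <- outer(Ti, Ti, "+") - joint               # censuses holding i or j
  rich <- sdv <- numeric(Tn)
  for (t in seq_len(Tn)) {
    qi <- exp(lchoose(Tn - Ti, t) - lchoose(Tn, t))      # P(species i unseen)
    qij <- exp(lchoose(Tn - u, t) - lchoose(Tn, t))
    rich[t] <- sum(1 - qi)
    sdv[t] <- sqrt(max(sum(qij) - sum(qi)^2, 0))
  }
  structure(data.frame(t = seq_len(Tn), richness = rich, sd = sdv),
            class = c("AccumulationCurve", "data.frame"),
            totalSpecies = ncol(inc), nCensuses = Tn)
}

#' Detection rate of metabarcoding against a visual census
#'
#' The proportion of visually observed species also detected by
#' metabarcoding, among observed species that have reference sequences; the
#' strict variant additionally excludes species indistinguishable at the
#' marker. Rates are percentages rounded half-up to one decimal.
#'
#' @param observed species observed by the visual census.
#' @param detected species detected by metabarcoding.
#' @param noReference observed species absent from the reference database.
#' @param indistinguishable observed species that the marker cannot separate.
#' @return list \code{nShared, denominator, rate, denominatorStrict,
#'   rateStrict}.
#' @export
detectionRate <- function(observed, detected, noReference = character(),
                          indistinguishable = character()) {
  observed <- unique(observed)
  shared <- length(intersect(detected, observed))
  denom <- length(setdiff(observed, noReference))
  denomStrict <- length(setdiff(observed, union(noReference, indistinguishable)))
  if (denom == 0) stop("detection rate undefined: empty denominator")
  list(nShared = shared, denominator = denom,
       rate = roundHalfUp(100 * shared / denom, 1),
       denominatorStrict = denomStrict,
       rateStrict = if (denomStrict > 0)
         roundHalfUp(100 * shared / denomStrict, 1) else NA_real_)
}

#' Detection efficiency: censuses needed to match metabarcoding richness
#'
#' The smallest number of censuses t at which the accumulation curve reaches
#' the species count detected by metabarcoding.
#'
#' @param curve an \code{AccumulationCurve} ([accumulationCurve()]).
#' @param sMeta species count detected by metabarcoding.
#' @return list \code{reached, censuses} (NA when not reached),
#'   \code{finalRichness}.
#' @export
detectionEfficiency <- function(curve, sMeta) {
  hit <- which(curve$richness >= sMeta)
  if (length(hit) == 0)
    list(reached = FALSE, censuses = NA_integer_,
         finalRichness = curve$richness[nrow(curve)])
  else
    list(reached = TRUE, censuses = curve$t[hit[1]],
         finalRichness = curve$richness[nrow(curve)])
}
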