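dmFromSets <- function(sets, layer = "surface") {
  # sets: list(station -> list of 3 replicate species vectors)
  rows <- list()
  for (st in names(sets)) for (r in seq_along(sets[[st]])) {
    sp <- sets[[st]][[r]]
    if (length(sp))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("%s-%s-%d", st, layer, r), station_id = st,
        layer = layer, replicate = r, taxon = sp, stringsAsFactors = FALSE)
    else
      rows[[length(rows) + 1L]] <- NULL
  }
  long <- do.call(rbind, rows)
  # ensure empty replicates still appear as columns
  allSamples <- do.call(rbind, lapply(names(sets), function(st)
    data.frame(sample_id = sprintf("%s-%s-%d", st, layer,
                                   seq_along(sets[[st]])),
               station_id = st, layer = layer,
               replicate = seq_along(sets[[st]]))))
  taxa <- sort(unique(long$taxon))
  cnt <- matrix(0L, length(taxa), nrow(allSamples),
                dimnames = list(taxa, allSamples$sample_id))
  det <- cnt > 0
  for (i in seq_len(nrow(long))) {
    det[long$taxon[i], long$sample_id[i]] <- TRUE
    cnt[long$taxon[i], long$sample_id[i]] <- 1L
  }
  allSamples$is_negative <- FALSE
  allSamples$x_m <- as.numeric(factor(allSamples$station_id)) * 100
  allSamples$y_m <- 0
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cnt, detected = det),
    rowData = S4Vectors::DataFrame(
      taxon = taxa, rank = "species", confidence = "HIGH",
      habitat = "marine", fishery = FALSE, local = TRUE, row.names = taxa),
    colData = S4Vectors::DataFrame(allSamples,
                                   row.names = allSamples$sample_id))
  new("DetectionMatrix", se, cutoff = 0)
}

test_that("replicate accumulation averages species over replicate subsets", {
  dm <- dmFromSets(list(St1 = list("A", "A", "A")))
  ra <- replicateAccumulation(dm)
  expect_equal(ra$mean_species, c(1, 1, 1))
  dm2 <- dmFromSets(list(St1 = list("A", "B", "C")))
  expect_equal(replicateAccumulation(dm2)$mean_species, c(1, 2, 3))
  dm3 <- dmFromSets(list(St1 = list(c("A", "B"), "A", "A")))
  ra3 <- replicateAccumulation(dm3)
  expect_equal(ra3$mean_species[1], 4 / 3)
  expect_equal(ra3$mean_species[3], 2)
  # subset means also averaged across stations
  dm4 <- dmFromSets(list(St1 = list("A", "B", "C"), St2 = list("A", "A", "A")))
  expect_equal(replicateAccumulation(dm4)$mean_species, c(1, 1.5, 2))
})

test_that("Chao1 uses replicate singletons and doubletons", {
  # no singleton signal: estimate equals the observed count
  expect_equal(chao1(c(3, 3, 2))$chao1, 3)
  # S_obs 10, f1 4, f2 2 -> 10 + 4*3/6 = 12
  expect_equal(chao1(c(rep(1, 4), rep(2, 2), rep(3, 4)))$chao1, 12)
  # f2 = 0 stays defined in the bias-corrected form: 5 + 5*4/2 = 15
  r <- chao1(rep(1, 5))
  expect_equal(r$chao1, 15)
  expect_identical(r$f1, 5L)
  expect_identical(r$f2, 0L)
  # classic form diverges there but matches elsewhere
  expect_identical(chao1(rep(1, 5), corrected = FALSE)$chao1, Inf)
  expect_equal(chao1(c(rep(1, 4), rep(2, 2), rep(3, 4)),
                     corrected = FALSE)$chao1, 14)
  # matrix input and estimator lower bound
  set.seed(2)
  for (i in 1:20) {
    m <- matrix(rbinom(30, 1, 0.5), ncol = 3)
    r <- chao1(m)
    expect_gte(r$chao1, r$S_obs)
    expect_lte(r$f1 + r$f2, max(r$S_obs, 1))
  }
})

test_that("layer partition splits the species pool exactly", {
  long <- rbind(
    data.frame(sample_id = "s-S-1", station_id = "St1", layer = "surface",
               replicate = 1, taxon = c("A", "B", "C")),
    data.frame(sample_id = "s-B-1", station_id = "St1", layer = "bottom",
               replicate = 1, taxon = c("B", "C", "D")))
  dm <- makeDM(long)
  p <- partitionByLayer(dm)
  expect_identical(p$surfaceOnly, 1L)
  expect_identical(p$bottomOnly, 1L)
  expect_identical(p$both, 2L)
  expect_identical(p$surfaceOnly + p$bottomOnly + p$both, p$total)
  expect_identical(unname(p$events), c(3L, 3L))
  # all species in both layers
  long2 <- rbind(
    data.frame(sample_id = "s-S-1", station_id = "St1", layer = "surface",
               replicate = 1, taxon = c("A", "B")),
    data.frame(sample_id = "s-B-1", station_id = "St1", layer = "bottom",
               replicate = 1, taxon = c("A", "B")))
  p2 <- partitionByLayer(makeDM(long2))
  expect_identical(c(p2$surfaceOnly, p2$bottomOnly, p2$both), c(0L, 0L, 2L))
  # partition sums hold on random incidence patterns
  set.seed(3)
  for (i in 1:10) {
    sp <- paste0("sp", 1:8)
    long3 <- rbind(
      data.frame(sample_id = "x-S-1", station_id = "x", layer = "surface",
                 replicate = 1, taxon = sample(sp, 5)),
      data.frame(sample_id = "x-B-1", station_id = "x", layer = "bottom",
                 replicate = 1, taxon = sample(sp, 4)))
    p3 <- partitionByLayer(makeDM(long3))
    expect_identical(p3$surfaceOnly + p3$bottomOnly + p3$both, p3$total)
  }
})

test_that("station group counts honour habitat and fishery flags", {
  long <- data.frame(sample_id = "St1-S-1", station_id = "St1",
                     layer = "surface", replicate = 1,
                     taxon = c("A", "B", "C"))
  meta <- data.frame(taxon = c("A", "B", "C"), rank = "species",
                     confidence = "HIGH",
                     habitat = c("marine", "freshwater", "marine"),
                     fishery = c(TRUE, FALSE, TRUE), local = TRUE)
  g <- stationGroupCounts(makeDM(long, rowMeta = meta))
  expect_identical(g$n_all, 3L)
  expect_identical(g$n_fishery, 2L)
  expect_identical(g$n_freshwater, 1L)
  # all-marine matrix: freshwater counts zero everywhere
  meta$habitat <- "marine"
  g2 <- stationGroupCounts(makeDM(long, rowMeta = meta))
  expect_identical(g2$n_freshwater, 0L)
  expect_true(all(g2$n_fishery <= g2$n_all))
})

test_that("Bray-Curtis follows its closed form and matches vegan", {
  expect_equal(brayCurtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(brayCurtis(c(1, 2, 0), c(0, 0, 5)), 1)
  expect_equal(brayCurtis(c(2, 1, 0), c(1, 1, 1)), 2 / 6)
  expect_error(brayCurtis(c(0, 0), c(0, 0)), "undefined")
  set.seed(6)
  for (i in 1:20) {
    x <- rpois(10, 3); y <- rpois(10, 3)
    if (sum(x) == 0 || sum(y) == 0) next
    expect_equal(brayCurtis(x, y),
                 as.numeric(vegan::vegdist(rbind(x, y), "bray")),
                 tolerance = 1e-12)
    expect_equal(brayCurtis(x, y), brayCurtis(y, x))
    expect_gte(brayCurtis(x, y), 0)
    expect_lte(brayCurtis(x, y), 1)
  }
})

test_that("correlogram permutation p matches full enumeration on 5 stations", {
  set.seed(9)
  xy <- cbind(c(0, 1, 2, 10, 11), c(0, 0.5, 0, 0, 0.5))
  comm <- rbind(c(5, 4, 1, 0), c(5, 3, 2, 0), c(4, 4, 1, 1),
                c(0, 1, 4, 5), c(1, 0, 5, 4))
  res <- mantelCorrelogram(comm, xy, nClasses = 3, exact = TRUE)
  tab <- correlogramTable(res)
  oracle <- rMantelExactOracle(comm, xy, nClasses = 3)
  expect_identical(as.integer(tab$class), as.integer(oracle[, "class"]))
  expect_equal(tab$mantel_r, unname(oracle[, "r"]), tolerance = 1e-12)
  expect_equal(tab$p_value, unname(oracle[, "p"]), tolerance = 1e-12)
  expect_identical(sum(tab$n_pairs), 10L)   # all n(n-1)/2 pairs classed
})

test_that("correlogram statistics match vegan::mantel.correlog", {
  set.seed(19)
  xy <- cbind(runif(15, 0, 100), runif(15, 0, 100))
  comm <- matrix(rpois(15 * 6, 4), 15)
  comm <- comm + 1   # avoid zero rows
  D <- as.matrix(vegan::vegdist(comm, "bray"))
  gd <- dist(xy)
  k <- 4
  breaks <- seq(min(gd), max(gd), length.out = k + 1)
  bp <- breaks
  bp[1] <- bp[1] - 1e-8    # vegan bins (lo, hi]; include the minimum pair
  vc <- vegan::mantel.correlog(D, XY = xy, break.pts = bp, nperm = 0,
                               cutoff = FALSE)
  mine <- correlogramTable(mantelCorrelogram(comm, xy, nClasses = k,
                                             nPerm = 0))
  vr <- vc$mantel.res[, "Mantel.cor"]
  vr <- vr[!is.na(vr)]
  expect_equal(mine$mantel_r, unname(vr), tolerance = 1e-10)
  expect_true(all(is.na(mine$p_value)))    # nPerm = 0: no tests
})

test_that("accumulation curve matches the closed form and resampling", {
  # species present in every census contributes 1 at every t;
  # a species in exactly 1 of T censuses contributes t/T
  census <- data.frame(
    census_id = rep(paste0("c", 1:4), each = 2),
    species = c("A", "B", "A", "x1", "A", "x2", "A", "x3"),
    count = 1)
  curve <- accumulationCurve(census)
  expect_equal(curve$richness[4], 5)            # S(T) = total species
  contribB <- curve$richness - (1 + 3 * curve$t / 4)
  expect_equal(contribB, curve$t / 4, tolerance = 1e-12)  # B in 1 census
  expect_true(all(diff(curve$richness) >= 0))
  # permutation resampling agreement within 2%
  set.seed(29)
  Tn <- 10; S <- 15
  inc <- matrix(rbinom(Tn * S, 1, 0.35), Tn, S)
  inc[1, colSums(inc) == 0] <- 1
  census2 <- data.frame(
    census_id = rep(sprintf("c%02d", 1:Tn), S),
    species = rep(sprintf("sp%02d", 1:S), each = Tn),
    count = as.vector(inc))
  curve2 <- accumulationCurve(census2)
  resamp <- matrix(0, 1000, Tn)
  for (b in 1:1000) {
    ord <- sample(Tn)
    seen <- matrix(FALSE, Tn, S)
    cum <- apply(inc[ord, , drop = FALSE], 2, cumsum) > 0
    resamp[b, ] <- rowSums(cum)
  }
  expect_equal(curve2$richness, colMeans(resamp), tolerance = 0.02)
})

test_that("accumulation curve and variance match vegan::specaccum", {
  set.seed(39)
  Tn <- 12; S <- 20
  inc <- matrix(rbinom(Tn * S, 1, 0.3), Tn, S)
  inc[1, colSums(inc) == 0] <- 1
  census <- data.frame(census_id = rep(sprintf("c%02d", 1:Tn), S),
                       species = rep(sprintf("sp%02d", 1:S), each = Tn),
                       count = as.vector(inc))
  curve <- accumulationCurve(census)
  sa <- vegan::specaccum(inc, method = "exact")
  expect_equal(curve$richness, as.numeric(sa$richness), tolerance = 1e-10)
  # vegan uses a slightly different covariance estimator for the band;
  # the two agree closely but not to machine precision
  expect_equal(curve$sd[-Tn], as.numeric(sa$sd)[-Tn], tolerance = 0.06)
  expect_equal(curve$sd[Tn], 0)
})

test_that("detection rate and efficiency reproduce their definitions", {
  observed <- sprintf("ob%02d", 1:80)
  noRef <- observed[1:7]
  detected <- c(observed[8:47], "extra1", "extra2")   # 40 shared
  dr <- detectionRate(observed, detected, noRef)
  expect_identical(dr$nShared, 40L)
  expect_identical(dr$denominator, 73L)
  expect_identical(dr$rate, 54.8)
  expect_identical(detectionRate(observed, observed)$rate, 100)
  expect_identical(detectionRate(observed, character())$rate, 0)
  expect_error(detectionRate(observed, detected, noReference = observed),
               "denominator")

  curve <- structure(data.frame(t = 1:4, richness = c(5, 8, 10, 11),
                                sd = 0), class = c("AccumulationCurve",
                                                   "data.frame"))
  expect_identical(detectionEfficiency(curve, 10)$censuses, 3L)
  expect_identical(detectionEfficiency(curve, 4)$censuses, 1L)
  nr <- detectionEfficiency(curve, 12)
  expect_false(nr$reached)
  expect_equal(nr$finalRichness, 11)
})
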