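# ednaFish

An R package implementing a complete environmental DNA (eDNA) metabarcoding
pipeline for fish community surveys built on short hyper-variable 12S rRNA
amplicons, together with a full-scale synthetic-survey generator that makes
every stage testable against known ground truth.

It is written for ecologists and bioinformaticians analysing bay- or
reef-scale eDNA surveys in which water is sampled at many stations, at more
than one depth, with replicated PCR, and processed alongside negative
controls (equipment/extraction blanks).

## What it computes

**Pipeline** (raw paired FASTQ → detection matrix):

1. *Quality control*: 3' tail trimming to Phred ≥ 20; pair merging at the
   overlap (>9 bp) maximising matching bases; removal of reads with Ns or
   merged length outside 272–322 bp; de novo bimera flagging
   (abundance-aware two-parent rule); location and stripping of both
   fish-universal primer-pair variants with < 4 mismatches per terminus.
2. *Taxonomy*: exact dereplication across the run with singleton discard;
   assignment to the top reference species at ≥ 99% ungapped identity;
   HIGH/MODERATE/LOW confidence from the runner-up species; species-level
   OTU clustering; checklist curation (LOW → genus rank unless a single
   local congener exists; non-local species substituted or annotated).
3. *Decontamination*: removal of every sequence occurring in any blank, and
   a per-sample read-fraction cut-off projected from the blank read count:

   `C = floor(R_neg / N_neg × N_tot)`,  `p = round(C / R_tot, 3)`

   an OTU with less than `p` of a sample's reads is absent from that sample.

**Statistics** (from the resulting taxa × samples `DetectionMatrix`, a
`SummarizedExperiment`):

* species gain over PCR-replicate subsets (k = 1..3);
* Chao1 richness with *replicate-based* singletons/doubletons
  (`S_obs + f1(f1−1)/(2(f2+1))`);
* surface/bottom partition of the species pool and detection events;
* Bray-Curtis dissimilarity `Σ|x−y| / Σ(x+y)` and a Mantel correlogram
  (equal-width distance classes, permutation tests, Holm correction);
* exact sample-based rarefaction
  `S(t) = Σ_i [1 − C(T−T_i, t)/C(T, t)]` with closed-form variance;
* detection rate and detection efficiency against an underwater
  visual-census table.

## Worked example

Simulate a small survey (6 stations × 2 layers × 3 PCR replicates plus 3
blanks, 200 read pairs per sample, 12 reference species including a
congeneric pair and a blank contaminant), run the pipeline, and score it
against ground truth:

```r
library(ednaFish)

cfg <- SimulationConfig(seed = 7, nSpecies = 12, nStations = 6,
                        readsPerSample = 200, nNegativeControls = 3)
gt  <- simulateDataset(cfg, file.path(tempdir(), "demo"))
res <- runPipeline(gt$sampleSheetPath, gt$fastqDir, gt$referencePath,
                   config = PipelineConfig(nPermutations = 199, seed = 7))

res$cutoff
#> Negative-control cut-off derivation
#>   2 reads in 3 negative controls; 39 PCR samples in total
#>   projected contaminant reads C = 26
#>   per-sample cut-off p = 0.5% of 5,391 clustered reads

res$detectionMatrix
#> class: DetectionMatrix
#> dim: 9 36
#> assays(2): counts detected
#> ...
#> cutoff: 0.500% of sample-total reads; 192 detections

head(res$otus$otus[, c("otu_id", "taxon", "rank", "confidence")], 3)
#>    otu_id     taxon    rank confidence
#> 1 OTU0001 Gen01 sp.   genus        LOW
#> 2 OTU0002 Gen02 sp1 species       HIGH
#> 3 OTU0003 Gen03 sp1 species       HIGH

recoveryStats(res$detectionMatrix, gt)[c("recoveryRate", "nTruth",
                                         "contaminantDetections")]
#> $recoveryRate          $nTruth          $contaminantDetections
#> [1] 100                [1] 72           [1] 0
```

Reading the output: the two reads that appeared in the blanks project to a
0.5% per-sample cut-off; 9 OTUs survive decontamination, with the
indistinguishable congeneric pair correctly collapsed to a LOW-confidence
genus-rank OTU (`Gen01 sp.`); all 72 (sample, species) ground-truth cells
with ≥ 10 clean reads are recovered, and the blank-contaminant species is
detected nowhere.

Community statistics run from the detection matrix:

```r
head(res$stats$chao1, 3)
#>   station_id   layer S_obs f1 f2 chao1
#> 1       St01 surface     6  1  2     6
#> 2       St01  bottom     4  1  0     4
#> 3       St02 surface     7  1  1     7

comm <- stationCommunity(res$detectionMatrix)
mantelCorrelogram(comm, attr(comm, "coords"), nPerm = 999, seed = 1)
```

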