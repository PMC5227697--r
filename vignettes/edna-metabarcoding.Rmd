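---
title: "Methods: an eDNA metabarcoding pipeline for coastal fish communities"
author: "ednaFish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an eDNA metabarcoding pipeline for coastal fish communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ednaFish)
```

## The problem

Environmental DNA (eDNA) metabarcoding infers a fish community from water
samples alone: a short, hyper-variable fragment of the mitochondrial 12S rRNA
gene is amplified from filtered water with fish-universal (MiFish-type)
primers, sequenced on a short-read instrument, and matched against a
reference database. Between the raw reads and an ecological statement sit a
long chain of decisions — quality control, chimera screening, taxonomic
assignment, contamination control, incidence statistics — each of which can
move species in or out of the final inventory. `ednaFish` implements that
chain as a single tested pipeline for a bay-wide survey design: water
sampled at dozens of stations, at the surface and near the bottom, with
three PCR replicates per water sample and a bank of negative controls
(equipment and extraction blanks) processed alongside.

Because a real MiSeq run is neither small nor redistributable, the package
carries a first-class synthetic-data generator that emulates the survey at
full scale with known ground truth. Every downstream stage is tested
against that truth, against closed-form oracles, or against independent
reference implementations.

## Read quality control

Per PCR sample, raw paired reads pass through six stages, in a fixed order:

1. **Tail trimming.** 3' bases are removed one at a time while the terminal
   base's Phred score is below 20. The floor is the classic quality
   threshold at which base-call error probability reaches 1%.
2. **Pair merging.** The reverse read is reverse-complemented and all
   overlap offsets of at least 10 bases (i.e. "more than 9 bp") are
   scanned; the offset with the most matching bases wins, ties going to the
   larger overlap. Offsets whose mismatch fraction exceeds 25% are
   inadmissible; a pair with no admissible offset is discarded. At overlap
   disagreements the higher-quality base is kept (ties keep the forward
   base, making output deterministic); agreements keep the larger quality.
   The 25% tolerance is a package choice — the merge literature offers no
   single standard — and is exposed in `QcConfig()`.
3. **Ambiguity filter.** Any merged read containing an N is discarded.
4. **Length filter.** Merged reads outside 272--322 bp are discarded. The
   window corresponds to the expected amplicon length (insert plus 127 bp
   of primer sequence) of 297 ± 25 bp.
5. **Chimera (bimera) removal**, described below.
6. **Primer location and stripping.** Both primer-pair variants (U and E,
   differing by two bases in the forward core and one in the reverse core)
   are matched against the read termini, each tolerating at most 3
   mismatches ("fewer than 4"); reads missing a primer at either end are
   discarded, and matched primers are stripped to leave the insert.

Stage tallies are recorded per sample and must telescope exactly — input
pairs = merged + merge-rejected, and each stage consumes precisely what the
previous one produced. The test suite asserts this conservation on every
synthetic run.

### The bimera rule

The pipeline uses a deliberately simple de novo bimera detector rather than
a port of a published tool. Working on one sample's distinct sequences in
decreasing abundance order, a candidate is flagged when some breakpoint
splits it into a prefix matching one parent and a suffix matching another,
with:

* at most 1 mismatch per side;
* both parents unflagged and at least twice as abundant as the candidate;
* parents at least 3 bases apart, and each at least 2 bases from the
  candidate;
* the breakpoint at least 75 bp from both ends; and
* the two-parent model explaining the candidate **strictly better** than
  either parent alone (model mismatches < candidate-to-parent divergence,
  for both parents).

The last two conditions deserve comment, because a naive prefix/suffix rule
fails badly on real amplicons. All amplicons share nearly identical primer
termini (60 bp forward, 67 bp reverse, modulo the U/E variant bases), so
*any* sequence can serve as a "parent" for a breakpoint inside a primer
region, and a sequencing-error variant of an abundant template then
decomposes into (true parent, anything). Requiring the breakpoint to sit
beyond both primer lengths — hence the 75 bp margin — and requiring the
chimeric model to dominate the single-parent explanation removes this
failure mode while leaving genuine two-parent bimeras detectable. On
synthetic data the flagged set matches a brute-force scan over all parent
pairs and breakpoints exactly. All five parameters are exposed in
`QcConfig()`.

Chimeric reads that escape detection are rarely consequential here: most
are unique within the run and fall to the singleton filter, and a bimera of
two diverged parents almost never reaches 99% identity to any reference.

## Taxonomic assignment and OTUs

Surviving inserts are dereplicated exactly (100% identity) across the whole
run, keeping per-sample read counts; sequences with fewer than 2 reads
run-wide (singletons) are discarded. The count threshold is applied across
the run rather than per sample — the more conservative reading, noted as a
package decision.

Each unique sequence is then ranked against every reference by ungapped
identity: matching bases at offset zero over the aligned length, divided by
the query length. A query is assigned to the top species when identity
reaches 99% and the aligned length is at least 100 bp. The aligned-length
floor stands in for a BLAST E-value bound: for ~170 bp amplicons at 99%
identity an E-value threshold of 1e-5 cannot bind, so re-implementing
Karlin–Altschul statistics would add no discrimination. Ungapped comparison
is adequate because the simulator introduces substitutions only; indel
robustness is a documented limitation, not a claim.

Assignment confidence is classified from the runner-up species:

* **LOW** — the second-best species also reaches 99%: the assignment cannot
  be distinguished from the second candidate.
* **MODERATE** — the runner-up is below 99% but within 1 percentage point
  of the top hit.
* **HIGH** — otherwise.

The MODERATE/HIGH margin of one percentage point is a package choice (the
literature's reliability classes are not numerically standardised) and is
exposed in `PipelineConfig()`. Exact identity ties across genera are
flagged and later demoted to family rank.

Assigned sequences sharing a species form one OTU; counts sum per sample
and the OTU inherits its worst member confidence. Two curation rules then
run against a local checklist: (1) LOW OTUs are demoted to genus rank
("Genus sp.") unless exactly one local species of that genus exists, in
which case that species is adopted; (2) OTUs assigned to species not known
locally are renamed through an explicit substitution map when one is
supplied, otherwise kept with a "non-local" note. OTUs converging on one
taxon are merged. Curation is deterministic and order-independent, and
every change is recorded in the OTU's curation note.

## Decontamination and the detection matrix

Negative controls drive two separate defences:

1. **Sequence removal.** Any unique sequence with at least one read in any
   blank is removed from *all* samples before assignment.
2. **Read-fraction cut-off.** The blank read total is projected onto the
   whole run: with `R_neg` clustered reads across `N_neg` blanks and
   `N_tot` PCR samples in total, `C = floor(R_neg / N_neg * N_tot)`
   possible contaminant reads; expressed against the run's `R_tot`
   clustered reads this gives a per-sample fraction `p = round(C / R_tot,
   3)`. In each sample, an OTU below `p` of the sample's total OTU reads is
   considered absent; a count exactly on the boundary is present. `C` is
   truncated, not rounded — the projection is a count.

The cut-off zeroes only the incidence layer; raw counts stay in the
`counts` assay of the `DetectionMatrix` for audit. The matrix itself is a
`SummarizedExperiment`: taxa × PCR samples, with the sample sheet as
`colData` and taxon metadata (rank, confidence, habitat, fishery and local
flags, curation notes) as `rowData`. Whether sub-threshold reads should
also be excluded from downstream abundance proxies is genuinely open; the
package applies the cut-off to incidence only and documents that choice.

## Community statistics

All statistics run from a saved or freshly built `DetectionMatrix`.

* **Replicate accumulation** (`replicateAccumulation`): mean species count
  over every size-k subset of the PCR replicates, averaged across stations,
  for k = 1..3 — the empirical gain from PCR replication.
* **Chao1 richness** (`chao1`): here *singleton* means a species detected
  in exactly one of the three PCR replicates of a water sample and
  *doubleton* exactly two; the bias-corrected form
  `S_obs + f1(f1-1) / (2(f2+1))` stays defined at `f2 = 0`. The classic
  form is available and returns Inf when `f1 > 0, f2 = 0`.
* **Layer partition** (`partitionByLayer`): surface-only, bottom-only and
  shared species pools plus detection-event counts per layer; the three set
  sizes must sum to the species total, asserted on every run.
* **Bray-Curtis dissimilarity** (`brayCurtis`): `sum|x-y| / sum(x+y)`; on
  presence/absence it equals Sorensen dissimilarity.
* **Mantel correlogram** (`mantelCorrelogram`): geographic distances are
  binned into equal-width classes (Sturges' rule on the pair count by
  default); per class, the Mantel statistic between the Bray-Curtis matrix
  and the class-membership model matrix, sign-oriented so that positive
  values mean positive spatial autocorrelation. p values come from
  permuting station labels, one-tailed in the direction of the observed
  sign; under permutation the within-class dissimilarity sum is a
  sufficient statistic for the class's Mantel r, which is what makes 999
  permutations cheap. The default abundance proxy feeding the dissimilarity
  is the per-station count of positive PCR detections per species (0–6
  across 2 layers × 3 replicates); presence/absence and read counts are
  alternatives, because the choice of proxy is not standardised.
* **Sample-based rarefaction** (`accumulationCurve`): the exact
  hypergeometric expectation
  `S(t) = sum_i [1 - choose(T - T_i, t) / choose(T, t)]`, with the
  closed-form variance including between-species joint-occurrence terms for
  the confidence band.
* **Detection rate / efficiency** (`detectionRate`,
  `detectionEfficiency`): the share of visually censused species (with
  reference sequences) also found by metabarcoding, and the number of
  censuses needed before the accumulation curve reaches the metabarcoding
  species count.

### Multiple testing across correlogram classes

Mantel correlograms are often corrected *progressively* — class k corrected
only against classes 1..k. That convention tests the first (shortest)
distance class uncorrected, and across ~11 classes it lets the familywise
error rate drift to roughly 15%: spatially unstructured data then shows a
"significant" class in nearly one run in six. The package therefore applies
the full Holm correction across all tested classes by default (the same
default as `vegan::mantel.correlog`), which holds the familywise rate at
the nominal level without costing short-range power; the progressive
variant remains available via `progressive = TRUE`.

## The synthetic survey generator

`SimulationConfig()` defaults describe the emulated survey: 47 stations ×
surface and bottom × 3 PCR replicates (282 field samples) plus 30 negative
controls; 1,000 read pairs per field sample; inserts of 170 ± 8 bp flanked
by the two primer variants in equal mixture; per-base substitution rate
0.003; 3% bimeric reads with breakpoints at least 30 bp from the amplicon
ends; stations on a near-regular grid spanning a 4,000 × 3,000 m bay
(~11 km²); species occupancy kernels of width 800 m, matching the scale of
spatial autocorrelation such surveys report; log-series rank abundances
(θ = 0.95); ~15% freshwater species centred near a river-mouth corner and
strongly surface-biased. Two reference species stay out of the communities:
a terrestrial blank-contaminant species and a non-local species. One marine
congeneric pair diverges by only 0.005 (a single base over a 170 bp
insert), deliberately below the 99% assignment threshold's resolution.

Choices that need a word of justification:

* **Read geometry.** Reads are 170 bp × 2. With 127 bp of primers, the
  amplicon is insert + 127 ∈ [272, 322] bp exactly when the insert lies in
  [145, 195] bp (the generator truncates the insert distribution to that
  window; 195 bp is also the longest insert the assignment stage should
  ever see). Two 170 bp mates then overlap by 18–68 bp, comfortably above
  the >9 bp merge floor, while shorter mates could not merge the longer
  amplicons at all under that floor.
* **Blank depth.** Each negative control receives 0.5% of a field sample's
  read depth (5 reads). Blanks in published surveys carry on the order of
  0.1–1% of sample depth; the derived cut-off then lands near 0.5% of
  sample totals, so the decontamination stage is exercised without
  swallowing genuine low-abundance detections.
* **Cross-contamination** puts the contaminant species into field samples
  at 0.1% of reads, so the blank-sequence removal rule has real work to do.
* **Quality model.** Per-base Phred ~ Normal(38 − 0.1·position, 3),
  clipped to [2, 40] — enough to exercise tail trimming (about one base
  trimmed per read on average) without an instrument-specific error model.
* **Ground truth.** Every read carries exactly one provenance label
  (source species, chimera with both parents, or contaminant) and its
  injected error count. A read is *clean* when it is an error-free,
  non-chimeric source read. Recovery is scored per (PCR sample, species)
  cell with at least 10 clean reads; a cell counts as recovered when the
  species — or its genus-level curated OTU — is detected in that sample.

What the generator does **not** emulate: PCR amplification bias, indel
errors, index hopping, tag jumps, quality-dependent miscalls, or any
realistic model of eDNA transport (the spatial kernel is a stand-in for an
unknown advection process, not an estimate of one). Passing tests on
synthetic data therefore demonstrate that the pipeline's logic is faithful
to its stated rules and recovers truth under substitution-type noise — not
that any particular real survey is free of the artefacts above.

## Numerical and degenerate-input choices

* Merge ties (equal match counts) resolve to the larger overlap; equal
  base qualities at a mismatch resolve to the forward read.
* Empty reads after trimming fail the merge's minimum overlap and are
  counted as merge rejections, not errors.
* `chao1` uses the bias-corrected form by default so `f2 = 0` stays
  finite.
* Bray-Curtis on two all-zero vectors is an error, not NaN; a station with
  an all-zero community makes the correlogram error out with a clear
  message.
* With `nPerm = 0` the correlogram reports statistics with NA p values.
  `exact = TRUE` enumerates all station permutations (factorial cost,
  meant for ≤ 8 stations) and reproduces a direct per-permutation
  enumeration to machine precision.
* A sample whose OTU reads total zero triggers a warning and reports every
  taxon absent.
* Percentages in the run summary are rounded half-up to one decimal, the
  convention used in printed summary tables (base R's `round()` rounds to
  even). One published summary cell (the singleton percentage) is not
  consistent with any rounding of its own printed counts; the package
  reports the recomputed value.
* Seeds are 32-bit safe; every stochastic step derives its stream from the
  single configured seed, and fixed seeds give byte-identical FASTQ/FASTA
  output.

## Problem sizes used by the tests

The acceptance suite runs the generator at the full survey design (312 PCR
samples × 1,000 read pairs), scores recovery of ~1,900 truth cells, checks
the merge scorer on 1,000 random pairs and the reference search on 500
random queries against brute-force oracles, compares 5-station Mantel p
values against full 120-permutation enumeration, and measures correlogram
power and false-positive rate over 50 structured and 50 shuffled synthetic
surveys at 999 permutations each. Module tests use smaller designs (6–10
species, 6 stations) chosen to finish in seconds while still covering every
rule boundary.

## Known limitations

* Ungapped assignment: an indel-bearing read loses identity rapidly and
  will typically fall below 99% rather than be rescued by alignment.
* The bimera rule is intentionally minimal; it is not a UCHIME
  re-implementation and makes no attempt at multi-parent chimeras.
* The E-value criterion is represented by an aligned-length floor, valid
  for short amplicons against small references, not in general.
* Confidence classes are threshold conventions, not calibrated
  probabilities.
* The spatial community model is phenomenological; it reproduces the
  statistical signatures (distance decay, layer partitioning, log-series
  abundances) rather than any hydrodynamic mechanism.
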