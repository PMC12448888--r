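---
title: "modStream methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{modStream methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

modStream analyses modification-tagged long-read alignments (modBAM) the
way an intraoperative nanopore profiling workflow does: reads arrive in
batches, and after every batch the package recomputes a methylome
classification, a copy-number profile, MGMT promoter status, targeted SNV
calls and gene-fusion candidates, all folded into one deterministic JSON
report. This vignette documents the statistical model behind each stage,
every numerical constant the package commits to, and the conditions under
which the synthetic-data generator operates. Problem sizes used throughout
(toy genome scale, panel sizes, coverage levels) are the package's own
choices for desk-scale validation, not properties of any external dataset.

# Methylation ingest

## MM/ML tags

Basecallers store per-base modification probabilities in the standard
MM/ML auxiliary tags. `extractCpGCalls()` parses `C+m` (5mC) and `C+h`
(5hmC) sub-tags: MM delta values count skipped cytosines *in the
as-sequenced read*, so reverse-strand alignments are reverse-complemented
before indexing and their calls are remapped to the forward-strand CpG
cytosine (the G at reference position p maps to the C at p − 1). ML bytes
are decoded as `code / 255`. The SAM specification defines each byte as
the probability interval `[code/256, (code+1)/256)`; the package fixes the
point value `code / 255` (with encoding `round(p * 255)`) so that
probability round-trips through fixtures are exact on the quantisation
grid.

## 5hmC merge

Downstream methylation analysis uses a single "modified" probability per
CpG and read:

```
p_meth = min(p_5mC + p_5hmC, 1)
```

Both modifications protect the cytosine from appearing unmodified, and
the basecaller emits them as probabilities of mutually exclusive states,
so the sum (clamped to 1 against quantisation overshoot) is the
probability of *any* modification. `mergeHydroxymethyl()` implements
exactly this and rejects values outside [0, 1].

## Site summaries and binarisation

A read supports methylation at a site when `p_meth >= 0.5` (ties count as
methylated). Per-site summaries count supporting reads; a site's binary
state for classification is 1 when the supporting fraction is at least
0.5. Binarisation is restricted to the classifier panel sites; everything
else (including the MGMT promoter panel) is kept at fractional resolution.

# Methylome classification

## Reference model

The classifier reference is a `classes x panel-sites` matrix of expected
methylation rates. The synthetic generator uses two-level rates (0.1/0.9,
an independent fair coin per class and site), mirroring the bimodal
methylation landscape classifiers exploit. Three independent strategies
are trained from the same matrix (`buildModels()`); each scores only the
sites observed in the sample, which is what makes sparse intraoperative
profiles classifiable at all:

* **forest** — a random forest (ntree = 200) trained on Bernoulli draws
  from the reference rates restricted to the observed sites (40 draws per
  class). The score is 100 x the top class's vote share; confident at
  **score >= 70**.
* **perceptron** — a multiclass perceptron (25 epochs) on the same draws.
  Activations are standardised and softmaxed; the score is the margin
  between the top and second posterior; confident at **margin >= 0.2**.
* **centroid** — exact Bernoulli log-likelihood of the profile under each
  class's rate vector (rates clamped to [0.001, 0.999]), softmaxed to a
  posterior; confident at **posterior >= 0.8**.

All three are deterministic given the model seed (`withSeed()` isolates
their RNG use from the caller).

## Consensus

`consensusCall()` classifies a sample only when **at least two** strategies
are simultaneously confident *and* agree on the label. This is the
package's intraoperative decision rule: a single confident classifier is
never sufficient, and three discordant confident classifiers yield
`unclassified`.

# Copy-number profiling

Reads are assigned to fixed-width genomic bins (default **10 kb**) by
alignment midpoint, and bin counts are normalised as

```
log2((count + 0.5) / (median + 0.5))
```

with the genome-wide median as baseline and 0.5 as pseudocount.
Segmentation is exact least-squares changepoint detection per chromosome:
dynamic programming over all partitions with a per-segment penalty
(default `3 * sigma^2 * log(n)`, sigma estimated from the median absolute
successive difference). Unlike heuristic binary segmentation this is
globally optimal, and the test suite verifies it against exhaustive
enumeration of all partitions on short series.

Segment states: mean log2 ratio **<= -0.35** is a loss, **>= +0.30** a
gain (the asymmetry reflects the smaller log-scale displacement of a
single-copy gain). Region events (chromosome and arm level) are called
when **>= 70%** of a region's bins lie in segments of the same
non-neutral state. Focal deletions (e.g. CDKN2A) use a deeper
**<= -0.8** cutoff on the region's mean ratio, and joint loss of the 1p
and 19q arms is reported as a codeletion.

# MGMT promoter status

MGMT status is the unweighted mean methylated fraction over a fixed
**137-CpG** promoter panel: `methylated` when the mean strictly exceeds
**25%**, `unmethylated` otherwise, and `insufficient-data` with fewer than
**10** observed panel sites. `mgmtReadMatrix()` exposes the underlying
read x site methylation states for visual review.

# SNV calling

Tumor-only calling from base-quality-filtered pileups (quality floor 10,
primary alignments only) over the target genes. A site is eligible at
depth **>= 10**; the top non-reference base is called with **>= 3**
supporting reads at VAF **>= 0.30**. Calls are annotated against a
clinical-significance table by exact variant key (chrom, pos, ref, alt)
with a gene-level fallback for coordinate-free table rows; only annotated
calls enter the report, but all calls are retained in the full output.
`inspectSite()` returns raw allele counts at any position regardless of
thresholds — the designed path for reviewing sub-threshold variants (e.g.
a 9-of-35-read variant at VAF 0.26 that the caller deliberately withholds).

# Fusion detection

Chimeric long reads produce a primary alignment plus supplementary
alignments; each alignment block of **>= 200** aligned bases becomes a
footprint labelled with the overlapping target gene (or a binned
`elsewhere` locus). Footprints of a read are ordered by query position;
each adjacent pair of distinct loci (same-gene blocks must be > 1 Mb apart
to count) contributes a junction with strand-aware breakpoint coordinates.
Junctions of the same canonical partner pair cluster within **500 bp** on
both coordinates; a cluster is reported with **>= 3** unique supporting
reads. Reads traversing three or more loci additionally produce a
multi-partner chain record (orientation-canonicalised), matching reported
multi-gene fusion events.

# Streaming model

`watchPipeline()` replays a modBAM in cumulative batches: batch *k*
analyses the union of batches 1..k from scratch. Recomputation (rather
than incremental updating) guarantees that the final report is identical
for every batch partition and equal to one-shot processing — the property
the test suite checks byte-wise on the serialised JSON (the per-run
`batch_index` bookkeeping field aside). `firstConsensusBatch` records the
first batch whose consensus is classified, the batch-time analogue of
time-to-diagnosis. Reports serialise with stable key order and no
timestamps, so identical inputs give byte-identical output.

# Synthetic data generator

`makeToyGenome()` + `simulateReads()` build the package's validation
universe:

* five chromosomes (chr1, chr7, chr9, chr10, chr19; default 300 kb each,
  60 kb in the test suite) with CpG-free background so every CpG is
  planted and known;
* a classifier site panel (default 2,000 CpGs; 500 in the test suite), a
  **137-site** MGMT promoter panel inside an MGMT gene on chr10, and seven
  target genes at fixed chromosome fractions (including TP53, IDH1,
  CDKN2A);
* per-read CpG probability pairs (5mC + 5hmC) beta-concentrated around a
  Bernoulli state drawn from the class rate, the MGMT level (default 0.6)
  inside the promoter, or 0.5 in the background;
* planted lesions: per-arm integer copy states scale per-arm Poisson read
  counts (state/2); SNVs substitute the alt base per read with the
  configured VAF; fusions emit chimeric reads (800 bp per segment,
  soft-clip-encoded, +/- 20 bp junction jitter) as primary +
  supplementary pairs.

Generator settings are study conditions fixed in `simulationConfig()`
defaults; analysis code never sees the truth labels, which are returned
separately for validation. Read lengths are log-normal (median 11,700 bp
by default; scaled down in the test suite to fit the 60 kb chromosomes).

# Determinism and limitations

All randomness is seed-derived via `withSeed()`, which restores the
caller's RNG state; reports are reproducible byte-for-byte. Known
limitations, deliberate at this scale:

* tumor-only SNV calling has no error model — thresholds, not genotype
  likelihoods — so it is a triage tool, not a variant caller;
* CNV baselines assume the median bin is copy-neutral; genomes where most
  of the genome is aberrant shift the baseline;
* classification trusts the reference rate matrix; batch effects between
  the reference and the sample are not modelled;
* fusion detection requires split alignments and does not model read
  errors at the junction beyond the aligner's clipping.
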