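# modStream

Streaming molecular profiling from modification-tagged long-read
alignments (modBAM), modelled on intraoperative nanopore workflows for
CNS tumors: while a sample is still sequencing, each new batch of reads
refines a methylome classification, a genome-wide copy-number profile,
MGMT promoter methylation status, targeted SNV calls and split-read
gene-fusion candidates, all combined into one deterministic JSON report.

## The science in brief

Nanopore sequencing reports 5mC and 5hmC probabilities per cytosine
directly from the raw signal (standard MM/ML BAM tags), so a methylome
emerges within minutes of sequencing — long before coverage suffices for
most genomic analyses. modStream exploits this:

* **Methylome classification.** Both cytosine modifications are merged
  into one "modified" probability (`min(p5mC + p5hmC, 1)`), reads are
  summarised per CpG, and the binary profile over a classifier site panel
  is scored by three independent strategies — random-forest vote share
  (confident ≥ 70), perceptron margin (≥ 0.2) and nearest-centroid
  Bernoulli posterior (≥ 0.8). A sample is *classified* only when at
  least two strategies are simultaneously confident and agree.
* **Copy number.** Reads are binned (10 kb default), log2-normalised
  against the median bin, and segmented with exact dynamic-programming
  changepoint detection. Losses (≤ −0.35) and gains (≥ +0.30) become
  arm/chromosome events when ≥ 70 % of a region's bins agree; focal
  deletions use ≤ −0.8 and joint 1p/19q loss is reported as codeletion.
* **MGMT.** Mean methylation over a fixed 137-CpG promoter panel;
  `methylated` strictly above 25 %, `insufficient-data` under 10
  observed sites.
* **SNVs.** Pileup-based tumor-only calls gated at 10× depth, 3 alt
  reads and 0.30 VAF, filtered against a clinical-significance table;
  `inspectSite()` exposes raw counts for sub-threshold review.
* **Fusions.** Split-read (supplementary-alignment) junctions clustered
  within 500 bp, reported at ≥ 3 supporting reads, including
  multi-partner chains.

Cumulative batches are recomputed from scratch, so the final report is
byte-identical regardless of how reads were batched — the property that
makes a streaming report trustworthy.

## Worked example

The package ships a synthetic-fixture generator, so the full pipeline
runs end-to-end with no external data. Below we build a small toy genome
(5 × 60 kb chromosomes, 500-site classifier panel), plant a chr7 gain, a
10p loss, a TP53 SNV at 55 % VAF and a GENEA::GENEB fusion, then run the
one-shot pipeline.

```r
library(modStream)

cfg <- simulationConfig(
    seed = 42, chromLengths = c(chr1 = 60000L, chr7 = 60000L, chr9 = 60000L,
                                chr10 = 60000L, chr19 = 60000L),
    panelSize = 500L, nClasses = 4L, cnvBinWidth = 5000L,
    readLengthMedian = 2500, readLengthSdlog = 0.3, meanReadsPerBin = 30)
genome <- makeToyGenome(cfg)

## plant lesions: chr7 gain, 10p loss, a TP53 SNV, a GENEA::GENEB fusion
tgt   <- genome$targets[S4Vectors::mcols(genome$targets)$name == "TP53"]
pos   <- BiocGenerics::start(tgt) + 500L
chrom <- as.character(GenomicRanges::seqnames(tgt))
ref   <- substr(as.character(genome$fasta[[chrom]]), pos, pos)
alt   <- setdiff(c("A", "C", "G", "T"), ref)[1]
cfg   <- simulationConfig(
    seed = 42, chromLengths = cfg$chromLengths, panelSize = 500L,
    nClasses = 4L, cnvBinWidth = 5000L, readLengthMedian = 2500,
    readLengthSdlog = 0.3, meanReadsPerBin = 30,
    copyStates = c("7p" = 3L, "7q" = 3L, "10p" = 1L),
    snvs = data.frame(chrom = chrom, pos = pos, alt = alt, vaf = 0.55),
    fusions = list(list(partners = c("GENEA", "GENEB"), n_reads = 5L)))

sim <- simulateReads(cfg, classId = 2L, genome = genome)

## clinical-significance table: exact TP53 variant + gene-level IDH1 row
tsv <- tempfile(fileext = ".tsv")
writeLines(c("chrom\tpos\tref\talt\tgene\tprotein_change\tsignificance",
             sprintf("%s\t%d\t%s\t%s\tTP53\tp.T1X\tpathogenic",
                     chrom, pos, ref, alt),
             "\t\t\t\tIDH1\t\tpathogenic"), tsv)
clin <- readClinicalTable(tsv)

models <- buildModels(genome$classRates, seed = 7L)
report <- runPipeline(sim$bam, genome$fasta, genome$panel, genome$mgmtPanel,
                      genome$targets, genome$regions, models,
                      clinicalTable = clin,
                      params = list(binWidth = cfg$cnvBinWidth))
report
```

```
StreamReport (batch -1)
  consensus : classified [class2]
  CNV events: 4
  MGMT      : methylated
  SNVs      : 1 reported (1 total)
  fusions   : 1
```

Every planted lesion is recovered:

```r
report@cnvEvents
```
```
  region_id event fraction  mean_log2
1      chr7  gain        1  0.4151576
2        7p  gain        1  0.3396575
3       10p  loss        1 -1.3160612
4        7q  gain        1  0.4906576
```

```r
report@snvs
```
```
  chrom   pos ref alt depth alt_count   vaf gene clinical_significance
1 chr19 36500   A   C    16         6 0.375 TP53            pathogenic
  in_report
1      TRUE
```

```r
report@fusions[, 1:7]
```
```
      partners n_partners chromA  posA chromB  posB n_support
1 GENEA::GENEB          2   chr1 14195   chr7 22386         5
```

Streaming the same BAM in 400-read cumulative batches shows the
classifier trajectory stabilising immediately on this clean sample, and
the final batch report is byte-identical to the one-shot run:

```r
w <- watchPipeline(sim$bam, genome$fasta, genome$panel, genome$mgmtPanel,
                   genome$targets, genome$regions, models,
                   clinicalTable = clin,
                   params = list(binWidth = cfg$cnvBinWidth),
                   batchSize = 400L)
head(w$trajectory, 6); w$firstConsensusBatch
```
```
  batch   strategy  label       score confident n_sites_used
1     1     forest class2 100.0000000      TRUE          123
2     1 perceptron class2   0.5158811      TRUE          123
3     1   centroid class2   1.0000000      TRUE          123
4     2     forest class2 100.0000000      TRUE          196
5     2 perceptron class2   0.5808741      TRUE          196
6     2   centroid class2   1.0000000      TRUE          196
[1] 1
```

(`runPipeline`/`watchPipeline` emit a warning per untagged supplementary
alignment skipped during methylation ingest; wrap in
`suppressWarnings()` if undesired.)

## Command line

An executable front end lives at `inst/exec/modstream`
(`system.file("exec", "modstream", package = "modStream")`):

```sh
modstream simulate --dir demo --seed 1 --class 2
modstream run   --bam demo/reads.bam --genome demo --out report.json
modstream watch --bam demo/reads.bam --genome demo --out batches \
                --batch-size 500
```

## Reproducing results

* **Unit and integration tests** (testthat 3e, includes acceptance
  tests):

  ```sh
  Rscript -e 'devtools::test()'
  ```

* **Acceptance script** — runs against the *installed* package and
  writes the headline metrics (threshold locations found by sweep,
  consensus recovery rate, CNV arm concordance, SNV precision/recall,
  fusion breakpoint error) as JSON:

  ```sh
  Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
  ```

  All values are computed at runtime from seeded simulations; changing
  `--seed` changes the replicate streams but the recovered thresholds
  and near-perfect recovery rates are stable.

* **Methods details** — model descriptions, all numerical constants and
  generator conditions are documented in `vignettes/methods.Rmd`.
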