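# medtrace

Temporal gene-activity tracing from methylation-label sequencing.

## The problem

Lineage and differentiation studies need to know not just what a cell
expresses *now*, but what it expressed in the past.  One way to record
past activity is to fuse a bacterial DCM methyltransferase to an RNA
polymerase II subunit: while the fusion is induced, transcribed gene
bodies and active enhancers accumulate CCWGG (CCAGG/CCTGG) methylation, a
mark that is essentially absent from mammalian genomes and is partially
inherited through DNA replication.  Reading the mark out later with
MeD-seq — sequencing of the ~32-bp fragments that the
methylation-dependent restriction enzyme LpnPI cuts at methylated
CpG-context (CCG/CGG/GCGC) and fully methylated CCWGG sites — turns the
genome into a tape of past transcription.

`medtrace` is an R package for analysing such experiments, aimed at
epigenomics groups working with methylation-label time courses.  It
covers the full path from reads (or per-site count matrices) to:

* **read filtering and site counting** — motif scanning of the
  reference, classification of reads by the 13–17 bp restriction-site
  offset rule, exact-match placement, per-site DCM/CpG count matrices;
* **gene activity maps** — RPM normalization (absolute = by CpG total,
  relative = by DCM total), gene-body aggregation, strand-aware
  TSS/body/TES meta-profiles, Mann–Whitney calling of significantly
  labeled genes, fold changes against the day-1 calibrator, peak-day
  assignment and z-scored temporal matrices;
* **enhancer DMRs** — intergenic site filtering, rank-test + fold-change
  calling, 500-bp merging with 250-bp browser extension, closest-gene
  assignment, gene/enhancer peak-day coordination, and peak labeling
  statistics with a shuffle control;
* **propagation kinetics** — division numbers from H2B-GFP dilution
  (`log0.5` of the intensity ratio), per-division propagation rates
  (division-number-th root of the DCM/CpG ratio quotient), and in-silico
  label-dilution experiments with a `samplerate` of `p^divisions`;
* **co-methylation linkage** — 2×2 tallies of first/last-site
  methylation within reads, fully linked and fully unlinked simulated
  controls, and a linkage score anchored at the two controls.

A first-class synthetic-data generator produces toy genomes, ground-truth
time courses, pulse-chase cohorts and MeD-seq-style FASTQ reads, so every
stage is tested as a recovery problem with known truth.

## The core model

Only fully methylated duplex CCWGG sites are detectable, and each
division retains a labeled site with probability *p*.  For a pulse-chase
with GFP-high/GFP-low cohorts:

```
division nr       = log0.5( GFPlow / GFPhigh )
propagation rate  = ( DCMlow / DCMhigh ) ^ (1 / division nr)
```

where DCM denotes the DCM/CpG read-count ratio of a cohort.  In-silico
dilution thins induced samples by `p^divisions` and asks which fraction
of genes still shows a fold change above 1 over uninduced controls.

## Worked example

```r
library(medtrace)

cfg    <- simulate_config(seed = 1)     # the default synthetic study
genome <- generate_toy_genome(cfg)
genome
#> toy_genome: 2 chromosome(s) of 2200000 bp; 60 genes; 48 planted enhancers;
#>   9699 DCM sites; 137045 CpG sites

counts <- simulate_site_counts(genome, cfg)   # 21 samples: days 0..8 x 3
rpm    <- normalize_counts(counts, "relative")
gt     <- gene_body_counts(rpm, genome$genes)
act    <- call_active_genes(gt)
sum(act$significant)
#> [1] 44                                  # of 60 genes (12 are silent)

prof <- fold_change_vs_day1(gt)
head(prof$fc, 3)
#>      day_1     day_2     day_3     day_4     day_6     day_8
#> g001     1 1.0870545 0.8392820 0.6833657 0.5061151 0.4880977
#> g002     1 1.1462055 1.4440230 2.0802514 4.4634993 3.3571610
#> g003     1 0.7444416 0.6086988 0.4423530 0.3285798 0.3206138
```

Gene `g002` rises toward late days (a stem-like program, peak day 6),
`g001` and `g003` fade after an early peak — the fold changes are each
gene's mean relative RPM per day divided by its day-1 mean.

```r
sim <- simulate_pulse_chase(n_sites = 1e5, p = 0.56, division_gap = 3,
                            seed = 1)
est <- recover_propagation(sim)
sprintf("divisions: %.0f, propagation rate: %.3f (95%% CI %.3f-%.3f)",
        est$divisions, est$rate, est$ci[1], est$ci[2])
#> [1] "divisions: 3, propagation rate: 0.557 (95% CI 0.549-0.566)"
```

The chained estimators recover the simulated 56% per-division propagation
rate from the GFP intensity ratio and the DCM/CpG read ratios alone.

`run_pipeline(simulate_config(seed = 1))` chains all stages (simulate,
normalize, gene calling, temporal profiles, enhancer DMRs, peak labeling,
kinetics, linkage) into one output directory with a checksummed manifest;
rerunning with one threshold changed recomputes only the downstream
stages.

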