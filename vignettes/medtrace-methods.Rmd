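---
title: "Methods: temporal gene-activity tracing from methylation-label sequencing"
author: "medtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal gene-activity tracing from methylation-label sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medtrace)
```

## The assay and the quantities this package computes

A bacterial DCM methyltransferase fused to an RNA-polymerase-II subunit
deposits CCWGG (CCAGG/CCTGG) methylation on the gene bodies and enhancers
that are transcribed while the fusion is induced with doxycycline.  Because
CCWGG methylation is essentially absent from mammalian genomes and is
partially propagated through DNA replication, the deposited label is a
readable record of *past* transcriptional activity.  MeD-seq reads the
label out: the restriction enzyme LpnPI cuts methylated CpG-context sites
(CCG, CGG, GCGC) and fully methylated CCWGG sites, producing ~32-bp
fragments whose recognized site sits near the fragment center.

From such reads (or precomputed per-site count matrices) the package
computes:

* per-site count matrices split into DCM and CpG context classes
  (`count_sites()`), with reads-per-million normalization by either the
  CpG read total ("absolute" enrichment, tracking induction level) or the
  DCM read total ("relative" enrichment, comparing profiles across
  samples) in `normalize_counts()`;
* per-gene signal, significance of labeling, temporal fold changes
  against the day-1 calibrator, and peak days
  (`gene_body_counts()`, `call_active_genes()`, `fold_change_vs_day1()`,
  `assign_peak_day()`);
* intergenic enhancer DMRs: site filtering, Mann-Whitney + fold-change
  calling, 500-bp merging with 250-bp browser extension, closest-gene
  assignment, peak-day coordination, and peak-labeling statistics with a
  shuffle control (`filter_intergenic_sites()`, `call_dmr_sites()`,
  `merge_sites_to_regions()`, `assign_closest_gene()`,
  `coordination_matrix()`, `label_peaks()`);
* label-propagation kinetics from H2B-GFP pulse-chase cohorts and
  in-silico label dilution (`estimate_division_number()`,
  `estimate_propagation_rate()`, `recover_propagation()`,
  `simulate_dilution()`);
* within-read co-methylation linkage against fully linked and fully
  unlinked simulated controls (`comethylation_counts()`,
  `simulate_unlinked()`, `simulate_linked()`, `linkage_score()`).

A synthetic-data generator (`simulate_config()`, `generate_toy_genome()`,
`simulate_timecourse()`, `simulate_site_counts()`, `generate_reads()`)
produces every input with known ground truth, so that each stage can be
tested as a recovery problem.

## The kinetic model

Only fully methylated duplex CCWGG sites are detectable.  After one
division each such site remains fully methylated with probability $p$ (the
*propagation rate*), so after $n$ divisions a fraction $p^n$ of labeled
sites is still visible.  In a pulse-chase experiment with an H2B-GFP
division counter, the division number separating a GFP-high and a GFP-low
cohort and the propagation rate follow

$$
n \;=\; \log_{0.5}\!\left(\frac{\mathrm{GFP}_{\mathrm{low}}}{\mathrm{GFP}_{\mathrm{high}}}\right),
\qquad
p \;=\; \sqrt[\,n\,]{\frac{\mathrm{DCM}_{\mathrm{low}}}{\mathrm{DCM}_{\mathrm{high}}}},
$$

where $\mathrm{DCM}$ denotes the DCM/CpG read-count ratio of each cohort
(the CpG reads act as a depth normalizer that is unaffected by induction).
The estimators are exact for noiseless input; with $10^5$ assayed sites
the binomial sampling error of the retained fraction propagates to well
under one percentage point on $p$:

```{r pulse-chase, eval = FALSE}
sim <- simulate_pulse_chase(n_sites = 1e5, p = 0.56, division_gap = 3)
est <- recover_propagation(sim)
est$rate          # ~0.56, with a bootstrap CI from resampling sites
```

The in-silico dilution experiment (`simulate_dilution()`) thins induced
replicates' per-gene reads by a binomial *samplerate* of $p^{n}$ --
distributionally identical to subsampling the read files -- normalizes the
thinned counts by the *original* sample's CpG total, and reports the
fraction of genes whose mean diluted signal still exceeds the uninduced
mean (fold change > 1, no pseudocount; genes at zero in both groups count
as undetected).

## Statistical calling

Gene labeling and site-level DMR significance both use the two-sided
Mann-Whitney U test with the uninduced samples as set X and all induced
samples as set Y, at a raw $p < 0.05$ cutoff (no multiple-testing
correction; an optional FDR column is off by default because the
procedure is defined by the raw cut).  The implementation uses the exact
U distribution when $\min(n, m) \le 8$ and the data are tie-free, and the
normal approximation with tie and continuity corrections otherwise; the
test suite checks the exact path against full permutation enumeration for
group sizes (3,4) and (3,7) and verifies type-I control on exchangeable
nulls.  Because the test is two-sided, a direction requirement (induced
median above control median for genes; fold change $\ge 4$ for DMR sites)
makes "significant" mean *enriched*.  Fold change is the ratio of group
means; a zero control mean with a positive induced mean counts as
enriched (infinite fold change), and constant identical groups return
$p = 1$ with a flag.

DMR sites must additionally be intergenic: not overlapping a gene, more
than 1 kb from the closest gene (distance counted between base positions,
so a site 999 bp from a gene edge is removed and one 1,001 bp away is
kept), and outside repeat intervals.  Significant sites merge into
regions when consecutive sites are less than 500 bp apart (strict, by
coordinate difference); the browser-track variant extends regions by
250 bp and re-merges overlaps.  The "intestine" mode adds a floor of ten
raw reads summed over all samples.

## The synthetic study and its defaults

The generator's defaults define the conditions under which the package's
acceptance tests run.  The key choices, with reasons:

| parameter | default | meaning / rationale |
|---|---|---|
| `propagation_rate` | 0.56 | per-division duplex retention; governs pulse-chase and dilution |
| `labeling_efficiency` | 0.13 / 0.087 / 0.044 by expression tier | tier-weighted mean 0.087, the average per-site labeling of active genes; the dependence on expression level is exposed per tier rather than asserted as a functional form |
| `rise_rate` | 0.7 per day | geometric rise of a late program's measured label before its peak: lineage turnover only gradually brings dox-exposed precursor stages into the sampled population's history |
| `decay_rate` | 0.85 per day | geometric fall after the peak; slower than pure per-division dilution (0.56) because continuously induced, still-transcribed elements keep re-acquiring label.  Setting `decay_rate = 0.56` recovers the pure-dilution closed form $e\,p^{\Delta t}$, which the tests verify |
| `background_rate` | 0.001 | uninduced per-site methylated fraction; keeps the uninduced DCM read total a few percent of the induced one, matching the strong induction regime |
| `read_depth` | 150 reads per fully methylated site | deep-coverage regime in which Poisson noise does not dominate adjacent-day contrasts |
| `chrom_len`, `n_chroms` | 2 x 2.2 Mb | makes planted (labeled) sites a small minority of all CCWGG sites, as in a real genome; this matters because relative RPM fold changes are measured against the genome-average signal |
| `dcm_per_gene`, `sites_per_enhancer` | 12 / 8 | planted motif counts per 4-kb gene body and per ~500-bp enhancer |
| `days`, `n_replicates` | 0,1,2,3,4,6,8 x 3 | the sampled induction course; day 0 is the uninduced control |

Each expressed gene receives a peak day from {1,2,3,4,6,8}; a planted
intergenic enhancer 1.3 kb downstream shares that peak day.  A site's
population methylated fraction at sampling day $t$ for an element peaking
at $d^\*$ is

$$
f(t) \;=\; \mathrm{bg} + e \cdot
\begin{cases}
\mathrm{rise}^{\,d^\* - t} & t \le d^\*\\[2pt]
\mathrm{decay}^{\,t - d^\*} & t > d^\*,
\end{cases}
$$

a broad unimodal profile of the kind continuous-induction time courses
show.  Replicates share this expectation and differ only through Poisson
read sampling (`counts ~ Poisson(depth x fraction)`); no overdispersion is
modeled.  The count-matrix route (`simulate_site_counts()`) draws these
Poisson counts directly and is equal in distribution to generating reads
and counting them, which the suite verifies on a small case; the read
route (`generate_reads()`) is used for the round-trip tests of the read
filter.

All randomness flows from one master seed through named substreams
(`substream_seed()`), so the genome, the labeling, and each sample's reads
are independently reproducible and byte-identical across runs.

### What the generator does not emulate

Uniform base composition (no GC skew, no CpG islands), no repeats beyond
planted intervals, no sequencing errors, adapters, PCR duplicates, or
bisulfite chemistry, no overdispersion beyond Poisson, no real mm10
sequence.  Passing recovery tests on this synthetic study therefore
demonstrates the correctness of the algorithms under the stated model,
not performance on real tissue data.

## Numerical and convention choices

* **Coordinates** are 0-based half-open everywhere except human-readable
  logs; a read is attributed to a gene when its site coordinate falls in
  `[start, end)`.
* **Duplex sites** are enumerated on the plus strand only (the CCWGG
  motif pair is its own reverse complement); the site coordinate is the
  first C.
* **Anchor base** for the 13--17 bp read filter is the methylated
  cytosine (second C of CCWGG; the CpG C of CCG/CGG/GCGC), configurable
  to motif-start anchoring for pipelines that measured the offset to the
  restriction-site start.  Distinct CpG motifs sharing a methylated C
  (e.g. within CCGG) are collapsed to one countable site per anchor.
* **Read mapping** is exact unique matching against the reference (both
  strands); multi-mapping or unmapped reads are rejected.  A read in
  which both a DCM and a CpG anchor qualify is classified DCM with a
  conflict counter; two qualifying anchors of the same class reject the
  read.
* **Meta-profiles** use 100 upstream and 100 downstream bins of 100 bp
  and 100 body bins of 1% of the body length, strand-aware; every bin
  reports pooled reads divided by pooled site count, so flank and body
  bins share reads-per-site units and bin-size differences are absorbed
  by the site-frequency adjustment.  Bins without sites are missing, not
  zero; genes under 100 bp or with overlapping bodies are excluded.
* **Peak days** exclude day 0, break ties toward the earlier day with a
  flag, and leave all-zero profiles unassigned.  Z-scores use the
  population standard deviation (the few sampling days are the complete
  set of timepoints); constant rows become zero rows with a flag.
* **Fold change vs day 1** uses the mean of replicate relative-RPM
  values per day (not pooled reads); day-1 calibration makes the day-1
  fold change exactly 1, and a zero day-1 mean flags the gene.
* **Closest-gene ties** break to the lexicographically smaller gene id,
  flagged; distances are signed (positive when the region lies at higher
  coordinates than the gene).
* **Peak labeling** measures the distance from the peak *center* to the
  nearest significant site (strict `< 750` bp) by default, with an
  overlap-based alternative; the shuffle control re-places peaks
  uniformly over the non-genic space (genes +/- 1 kb excluded) of the
  same chromosome, preserving lengths, 100 times.  The original
  BEDTools-based shuffle is matched distributionally, not
  RNG-for-RNG.
* **Linked-control simulator**: both sites methylated with probability
  $\min(m_1, m_2)$, the higher-marginal site alone with probability
  $|m_1 - m_2|$, neither with $1 - \max(m_1, m_2)$; equal marginals give
  single-site probability exactly zero, the only internally consistent
  reading of complete linkage.  The linkage score positions the observed
  both-methylated count linearly between the realized control tables,
  clipped to [0, 1], with a multinomial bootstrap CI.
* **Peak correlation** adds a pseudocount of 1 to read counts before the
  log10 density transform so zero-count peaks are admissible, and removes
  outliers iteratively at |z| > 4 in either coordinate.

## Pipeline orchestration and problem sizes

`run_pipeline()` chains the stages on one configuration, writing FASTA,
BED, and TSV outputs plus a manifest of md5 checksums.  Every stage's
parameters (including upstream stage hashes) are hashed; a rerun reloads
unchanged stages from disk, so editing one threshold recomputes only the
stages downstream of it.

The default synthetic study (two 2.2-Mb chromosomes, 60 genes, 48
enhancers, 21 samples) runs end to end in well under a minute on one
core.  The test suite uses this scale for the recovery checks and smaller
toys (40--400 kb) for oracle comparisons; the pulse-chase bias check runs
200 replicates of $10^5$ sites.  These sizes were chosen so that binomial
and Poisson sampling errors are small relative to the tested tolerances
while the whole suite stays fast.

## Known limitations

* Hemimethylation is not modeled; the per-division retention probability
  is a single-parameter surrogate justified by the assay's
  fully-methylated-duplex detection.
* The read classifier treats minus-strand reads through the plus-strand
  anchor coordinate; the 2-bp offset between the two strands' methylated
  cytosines within a duplex site is not modeled (the simulator emits
  plus-strand fragments).
* Expression tiers are generator inputs; deriving them from real RNA-seq
  is out of scope, as are alignment of real reads (use the count-matrix
  entry point), motif analysis, and genome-browser rendering beyond
  bedGraph output.
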