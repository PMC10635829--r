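test_that("genome generation is deterministic and capacity-checked", {
  cfg <- simulate_config(n_chroms = 1L, chrom_len = 40000L, n_genes = 3L,
                         intergenic_gap = 6000L, seed = 4L)
  g1 <- generate_toy_genome(cfg)
  g2 <- generate_toy_genome(cfg)
  expect_identical(g1$chroms, g2$chroms)
  expect_identical(g1$genes, g2$genes)
  expect_identical(g1$enhancers, g2$enhancers)
  # too many genes for the chromosome
  expect_error(generate_toy_genome(
    simulate_config(n_chroms = 1L, chrom_len = 20000L, n_genes = 10L)),
    "capacity")
})

test_that("genes are non-overlapping with >= 1 kb gaps and truth is planted", {
  st <- tiny_study(seed = 21)
  g <- st$genome$genes
  for (cn in unique(g$chrom)) {
    gc <- g[g$chrom == cn, ]
    gc <- gc[order(gc$start), ]
    if (nrow(gc) > 1) {
      expect_true(all(gc$start[-1] - gc$end[-nrow(gc)] >= 1000))
    }
  }
  # planted enhancers are intergenic, > 1 kb from any gene
  e <- st$genome$enhancers
  for (i in seq_len(nrow(e))) {
    same <- g[g$chrom == e$chrom[i], ]
    gaps <- pmax(same$start - e$end[i], e$start[i] - same$end)
    expect_true(all(gaps > 1000))
  }
  # enhancer intervals contain the promised number of DCM sites
  dcm <- st$genome$dcm_sites
  for (i in seq_len(nrow(e))) {
    n <- sum(dcm$chrom == e$chrom[i] & dcm$pos >= e$start[i] &
               dcm$pos < e$end[i])
    expect_gte(n, st$cfg$sites_per_enhancer)
  }
})

test_that("observed DCM site count in random sequence matches binomial expectation", {
  L <- 100000
  seq <- rand_seq(L, seed = 99)
  n_obs <- length(scan_dcm_sites(seq))
  p <- 2 / 4^5                       # CCAGG or CCTGG per 5-mer window
  n_windows <- L - 4
  expect_lt(abs(n_obs - n_windows * p),
            3 * sqrt(n_windows * p * (1 - p)))
})

test_that("time course follows the labeling model exactly at the extremes", {
  cfg <- simulate_config(n_chroms = 1L, chrom_len = 40000L, n_genes = 3L,
                         intergenic_gap = 6000L,
                         silent_frac = 0, background_rate = 0,
                         labeling_efficiency = 1,
                         rise_rate = 1, decay_rate = 1, seed = 8L)
  g <- generate_toy_genome(cfg)
  tc <- simulate_timecourse(g)
  dcm <- g$catalog$context == "DCM"
  in_gene <- rep(FALSE, nrow(g$catalog))
  for (i in seq_len(nrow(g$genes))) {
    in_gene <- in_gene | (g$catalog$chrom == g$genes$chrom[i] &
                            g$catalog$pos >= g$genes$start[i] &
                            g$catalog$pos < g$genes$end[i])
  }
  # p = 1, efficiency = 1, background 0: every active-gene site is 1 on all
  # dox days, 0 on day 0
  for (d in c(1, 2, 4, 8)) {
    f <- tc[[paste0("day_", d)]]$fraction
    expect_true(all(f[dcm & in_gene] == 1))
  }
  expect_true(all(tc$day_0$fraction[dcm] == 0))

  # efficiency 0: all dox days equal the day-0 background
  cfg0 <- simulate_config(n_chroms = 1L, chrom_len = 40000L, n_genes = 3L,
                          intergenic_gap = 6000L,
                          labeling_efficiency = 0, seed = 8L)
  g0 <- generate_toy_genome(cfg0)
  tc0 <- simulate_timecourse(g0)
  expect_equal(tc0$day_4$fraction, tc0$day_0$fraction)

  # unknown day errors
  expect_error(simulate_timecourse(g, days = 5L), "unknown day")
})

test_that("label decays as efficiency * p^divisions after the peak", {
  # configure a pure-dilution fall (decay 0.56 per division) to check the
  # closed form; the default decay is slower because of re-labeling
  cfg <- simulate_config(n_chroms = 1L, chrom_len = 40000L, n_genes = 3L,
                         intergenic_gap = 6000L,
                         silent_frac = 0, background_rate = 0,
                         decay_rate = 0.56,
                         labeling_efficiency = 0.5, seed = 13L)
  g <- generate_toy_genome(cfg)
  tc <- simulate_timecourse(g)
  dcm_idx <- which(g$catalog$context == "DCM")
  for (i in seq_len(nrow(g$genes))) {
    gi <- g$genes[i, ]
    sites <- dcm_idx[g$catalog$chrom[dcm_idx] == gi$chrom &
                       g$catalog$pos[dcm_idx] >= gi$start &
                       g$catalog$pos[dcm_idx] < gi$end]
    # three divisions after the element's peak: f = eff * 0.56^3
    t_after <- gi$true_peak_day + 3L
    if (!t_after %in% cfg$days) next
    f <- tc[[paste0("day_", t_after)]]$fraction[sites]
    expect_equal(unique(f), 0.5 * 0.56^3, tolerance = 1e-12)
  }
})

test_that("propagation is conservative, Bernoulli-thinned, and validated", {
  m <- data.frame(chrom = "chr1", pos = seq_len(1e5) * 10L,
                  context = "DCM", anchor = seq_len(1e5) * 10L + 1L,
                  fraction = 1)
  expect_error(propagate_methylome(m, p = 1.2, divisions = 1), "\\[0, 1\\]")
  # p = 1 returns input unchanged; p = 0 clears everything
  expect_identical(propagate_methylome(m, 1, 5)$fraction, m$fraction)
  expect_true(all(propagate_methylome(m, 0, 1, seed = 2)$fraction == 0))
  # binomial CI at p = 0.56, one division, 1e5 fully methylated sites
  out <- propagate_methylome(m, 0.56, 1, seed = 3)
  expect_lt(abs(mean(out$fraction) - 0.56),
            3 * sqrt(0.56 * 0.44 / 1e5))
  # closed form p^n across division counts (3 sigma)
  for (n in c(2, 4, 7)) {
    out <- propagate_methylome(m, 0.56, n, seed = 100 + n)
    expect_lt(abs(mean(out$fraction) - 0.56^n),
              3 * sqrt(0.56^n * (1 - 0.56^n) / 1e5))
  }
  # never creates methylation (population model on fractional input)
  mf <- m; mf$fraction <- runif(nrow(m))
  out <- propagate_methylome(mf, 0.7, 2, model = "population")
  expect_true(all(out$fraction <= mf$fraction))
})

test_that("pulse-chase cohorts obey GFP halving and DCM dilution", {
  # degenerate zero-gap case: both ratios 1 in expectation
  s0 <- simulate_pulse_chase(n_sites = 2e4, efficiency = 0.3, p = 0.56,
                             division_gap = 0L, depth = 20, seed = 1)
  expect_equal(s0$obs$gfp_low / s0$obs$gfp_high, 1)
  expect_equal(s0$obs$dcm_low / s0$obs$dcm_high, 1, tolerance = 0.05)
  # gap 1: DCM ratio ~ 0.56; gap 2: ~ 0.3136 and the chained estimators
  # recover the rate
  s1 <- simulate_pulse_chase(n_sites = 1e5, division_gap = 1L, depth = 10,
                             seed = 2)
  expect_equal(s1$obs$dcm_low / s1$obs$dcm_high, 0.56, tolerance = 0.02)
  s2 <- simulate_pulse_chase(n_sites = 1e5, division_gap = 2L, depth = 10,
                             seed = 3)
  expect_equal(s2$obs$dcm_low / s2$obs$dcm_high, 0.3136, tolerance = 0.02)
  div <- estimate_division_number(s2$obs)
  expect_equal(div, 2)
  expect_equal(estimate_propagation_rate(s2$obs, div), 0.56,
               tolerance = 0.02)
})

test_that("read generation respects fractions, Poisson depth and determinism", {
  base <- strrep("AT", 200)
  seq <- paste0(substr(base, 1, 200), "CCAGG", substr(base, 206, 400))
  genome <- c(chr1 = seq)
  cat <- site_catalog(genome)
  m0 <- data.frame(chrom = cat$chrom, pos = cat$pos, context = cat$context,
                   anchor = cat$anchor, fraction = 0)
  expect_equal(length(generate_reads(genome, m0, depth = 50, seed = 1)$reads), 0L)
  m1 <- m0; m1$fraction <- 1
  rr <- generate_reads(genome, m1, depth = 100, seed = 4)
  expect_lt(abs(length(rr$reads) - 100), 3 * sqrt(100))
  cl <- classify_reads(rr$reads, genome, cat)
  expect_true(all(cl$label == "DCM"))
  # byte-identical FASTQ across runs with the same seed
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_reads_fastq(generate_reads(genome, m1, depth = 20, seed = 7)$reads, f1)
  write_reads_fastq(generate_reads(genome, m1, depth = 20, seed = 7)$reads, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("simulated count matrices are deterministic given the config", {
  st1 <- tiny_study(seed = 33, n_genes = 4, chrom_len = 40000)
  st2 <- tiny_study(seed = 33, n_genes = 4, chrom_len = 40000)
  expect_identical(st1$counts$counts, st2$counts$counts)
  expect_identical(st1$counts$totals, st2$counts$totals)
})
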