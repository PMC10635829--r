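make_counts <- function(counts, dcm_total, cpg_total, days, conditions) {
  n <- ncol(counts)
  design <- data.frame(sample_id = paste0("s", seq_len(n)),
                       condition = conditions, day = days,
                       replicate = seq_len(n), stringsAsFactors = FALSE)
  sites <- data.frame(chrom = "chr1",
                      pos = seq_len(nrow(counts)) * 100L,
                      context = "DCM", stringsAsFactors = FALSE)
  totals <- data.frame(sample_id = design$sample_id,
                       dcm_total = dcm_total, cpg_total = cpg_total)
  site_counts(sites, counts, totals, design, "raw")
}

test_that("RPM normalization follows the absolute/relative definitions", {
  m <- make_counts(matrix(c(5, 10, 0, 20), 2, byrow = TRUE),
                   dcm_total = c(1e6, 2e6),
                   cpg_total = c(1e6, 4e6), days = c(1, 1),
                   conditions = c("dox", "dox"))
  ab <- normalize_counts(m, "absolute")
  expect_equal(unname(ab$counts[1, ]), c(5, 10 / 4))
  rel <- normalize_counts(m, "relative")
  expect_equal(unname(rel$counts[1, ]), c(5, 5))
  # when totals equal column sums, relative columns sum to exactly 1e6
  m2 <- make_counts(matrix(c(3, 7, 1, 9), 2), dcm_total = c(10, 10),
                    cpg_total = c(10, 10), days = c(1, 1),
                    conditions = c("dox", "dox"))
  expect_equal(unname(colSums(normalize_counts(m2, "relative")$counts)),
               c(1e6, 1e6))
  # relative RPM is invariant to global scaling of a sample
  m3 <- make_counts(matrix(c(6, 14, 2, 18), 2), dcm_total = c(20, 20),
                    cpg_total = c(20, 20), days = c(1, 1),
                    conditions = c("dox", "dox"))
  expect_equal(normalize_counts(m3, "relative")$counts,
               normalize_counts(m2, "relative")$counts)
  # zero totals name the offending sample
  m0 <- make_counts(matrix(0, 2, 2), dcm_total = c(0, 5),
                    cpg_total = c(5, 5), days = c(1, 1),
                    conditions = c("dox", "dox"))
  expect_error(normalize_counts(m0, "relative"), "s1")
})

test_that("gene counting uses half-open intervals and matches a brute-force oracle", {
  sites <- data.frame(chrom = "chr1", pos = c(100L, 199L, 200L, 50L),
                      context = "DCM")
  counts <- matrix(c(1, 2, 4, 8), ncol = 1)
  m <- site_counts(sites, counts,
                   data.frame(sample_id = "s1", dcm_total = 15,
                              cpg_total = 15),
                   data.frame(sample_id = "s1", condition = "dox",
                              day = 1L, replicate = 1L), "raw")
  genes <- data.frame(gene_id = "gA", chrom = "chr1", start = 100L,
                      end = 200L, strand = "+")
  gt <- gene_body_counts(m, genes)
  # site at start counted, site at end coordinate not (half-open)
  expect_equal(unname(gt$table["gA", 1]), 1 + 2)
  expect_equal(gt$genes$n_dcm_sites, 2L)
  # zero-site gene flagged insufficient
  genes2 <- rbind(genes, data.frame(gene_id = "gB", chrom = "chr1",
                                    start = 300L, end = 400L, strand = "+"))
  gt2 <- gene_body_counts(m, genes2)
  expect_equal(unname(gt2$table["gB", 1]), 0)
  expect_true(gt2$genes$insufficient_sites[2])

  # randomized layout against the brute-force interval oracle
  set.seed(10)
  rs <- data.frame(chrom = sample(c("chr1", "chr2"), 300, TRUE),
                   pos = sample.int(50000, 300), context = "DCM")
  rc <- matrix(rpois(900, 5), ncol = 3)
  rg <- data.frame(gene_id = sprintf("g%02d", 1:20),
                   chrom = sample(c("chr1", "chr2"), 20, TRUE),
                   start = sample.int(45000, 20), strand = "+")
  rg$end <- rg$start + sample(500:5000, 20)
  des <- data.frame(sample_id = paste0("s", 1:3), condition = "dox",
                    day = 1L, replicate = 1:3)
  rm_ <- site_counts(rs, rc, data.frame(sample_id = des$sample_id,
                                        dcm_total = colSums(rc),
                                        cpg_total = colSums(rc)), des, "raw")
  got <- gene_body_counts(rm_, rg)
  expect_equal(unname(got$table),
               unname(brute_gene_counts(rs$chrom, rs$pos, rc, rg)))
})

test_that("meta-profiles are flat for uniform signal and strand-aware", {
  st <- tiny_study(seed = 17, n_genes = 6, chrom_len = 60000)
  m <- st$counts
  # uniform one read per site: every populated bin equals 1 read/site
  mu <- m
  mu$counts <- matrix(1, nrow(m$counts), ncol(m$counts))
  prof <- build_meta_profile(mu, st$genome$genes)
  vals <- prof$value[!is.na(prof$value)]
  expect_true(all(abs(vals - ncol(mu$counts)) < 1e-12))

  # a minus-strand gene's upstream flank lies at higher genomic coordinates
  seqs <- c(chr1 = paste0(rand_seq(3000, 1), "CCAGG", rand_seq(8000, 2)))
  cat <- site_catalog(seqs)
  dcm <- cat[cat$context == "DCM", ]
  genes <- data.frame(gene_id = "gM", chrom = "chr1", start = 500L,
                      end = 1500L, strand = "-", tier = "mid50")
  sc <- site_counts(cat[c("chrom", "pos", "context")],
                    matrix(ifelse(cat$context == "DCM" & cat$pos >= 2500,
                                  10, 0), ncol = 1),
                    data.frame(sample_id = "s1", dcm_total = 100,
                               cpg_total = 100),
                    data.frame(sample_id = "s1", condition = "dox",
                               day = 1L, replicate = 1L), "raw")
  prof2 <- build_meta_profile(sc, genes)
  up <- prof2[prof2$segment == "upstream", ]
  expect_true(any(up$reads > 0))   # genomic right of a minus gene = upstream
  dn <- prof2[prof2$segment == "downstream", ]
  expect_true(all(dn$reads == 0 | is.na(dn$value)))
})

test_that("meta-profile bins match a brute-force per-base binning oracle", {
  st <- tiny_study(seed = 29, n_genes = 8, chrom_len = 60000)
  m <- st$counts
  genes <- st$genome$genes
  prof <- build_meta_profile(m, genes)

  # oracle: per gene, assign each DCM site to a bin by explicit arithmetic
  dcm <- m$sites$context == "DCM"
  sp <- m$sites[dcm, ]; reads <- rowSums(m$counts[dcm, , drop = FALSE])
  tiers <- sort(unique(genes$tier))
  acc_r <- acc_s <- matrix(0, 300, length(tiers),
                           dimnames = list(NULL, tiers))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$end - g$start < 100) next
    for (k in which(sp$chrom == g$chrom)) {
      pos <- sp$pos[k]; bin <- NA
      if (pos >= g$start - 10000 && pos < g$start) {
        bin <- 100 - floor((g$start - 1 - pos) / 100)
      } else if (pos >= g$start && pos < g$end) {
        bin <- 100 + min(100, floor((pos - g$start) / (g$end - g$start) * 100) + 1)
      } else if (pos >= g$end && pos < g$end + 10000) {
        bin <- 200 + floor((pos - g$end) / 100) + 1
      }
      if (is.na(bin)) next
      if (g$strand == "-") bin <- 301 - bin
      acc_r[bin, g$tier] <- acc_r[bin, g$tier] + reads[k]
      acc_s[bin, g$tier] <- acc_s[bin, g$tier] + 1
    }
  }
  for (tr in tiers) {
    sub <- prof[prof$tier == tr, ]
    want <- ifelse(acc_s[, tr] > 0, acc_r[, tr] / acc_s[, tr], NA_real_)
    expect_equal(sub$value, want, tolerance = 1e-9)
  }
})

test_that("Mann-Whitney matches exhaustive permutation enumeration", {
  set.seed(4)
  for (sizes in list(c(3, 4), c(3, 7))) {
    for (rep_ in 1:5) {
      x <- round(rnorm(sizes[1]), 3)
      y <- round(rnorm(sizes[2]) + rep_ / 3, 3)
      expect_equal(mann_whitney(x, y)$p_value, brute_mw_p(x, y),
                   tolerance = 1e-12)
    }
  }
})

test_that("active-gene calling needs enrichment and handles degeneracy", {
  tab <- rbind(flat = rep(5, 24),
               up = c(rep(0, 3), seq(2, 43, 2)),
               down = c(rep(50, 3), rep(1, 21)))
  gc <- structure(list(
    table = tab,
    genes = data.frame(gene_id = rownames(tab)),
    design = data.frame(sample_id = paste0("s", 1:24),
                        condition = rep(c("nodox", "dox"), c(3, 21)),
                        day = rep(c(0L, 1L), c(3, 21)), replicate = 1:24),
    normalized = "relative"), class = "gene_counts")
  res <- call_active_genes(gc)
  expect_false(res$significant[res$gene_id == "flat"])
  expect_true(res$degenerate[res$gene_id == "flat"])
  expect_equal(res$p_value[res$gene_id == "flat"], 1)
  expect_true(res$significant[res$gene_id == "up"])
  expect_lt(res$p_value[res$gene_id == "up"], 0.05)
  # significant requires the dox median to be higher
  expect_false(res$significant[res$gene_id == "down"])
})

test_that("peak correlation is exact on proportional densities and robust to outliers", {
  set.seed(6)
  n_sites <- sample(5:20, 50, TRUE)
  len <- sample(500:2000, 50, TRUE)
  dcm <- rpois(50, 40)
  chip <- (dcm + 1) * len / n_sites - 1   # exactly proportional densities
  r <- peak_correlation(dcm, n_sites, chip, len)
  expect_equal(r$r, 1, tolerance = 1e-12)

  # planted extreme outlier is removed and leaves r unchanged
  dcm2 <- c(dcm, 1e6); chip2 <- c(chip, 1)
  n2 <- c(n_sites, 10); len2 <- c(len, 1000)
  r2 <- peak_correlation(dcm2, n2, chip2, len2)
  expect_equal(r2$n_removed, 1L)
  expect_equal(r2$r, r$r, tolerance = 1e-9)

  # independent densities decorrelate
  set.seed(7)
  rA <- peak_correlation(rpois(10000, 30), rep(10, 10000),
                         rpois(10000, 30), rep(1000, 10000))
  expect_lt(abs(rA$r), 0.05)
  expect_error(peak_correlation(1:2, c(1, 1), 1:2, c(10, 10)), "3 peaks")
})
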