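test_that("intergenic filtering applies all three criteria with exact boundaries", {
  genes <- data.frame(gene_id = "gA", chrom = "chr1", start = 10000L,
                      end = 12000L, strand = "+")
  reps <- data.frame(chrom = "chr1", start = 20000L, end = 20500L)
  sites <- data.frame(chrom = "chr1",
                      pos = c(11000L,            # inside the gene
                              12000L + 999L - 1L,  # 999 bp from the gene end
                              12000L + 1000L - 1L, # exactly 1000 bp
                              12000L + 1001L - 1L, # 1001 bp: kept
                              20100L,            # inside a repeat
                              30000L))           # clean
  got <- filter_intergenic_sites(sites, genes, reps, flank = 1000L)
  expect_equal(got$pos, c(13000L, 30000L))
  tally <- attr(got, "tally")
  expect_equal(unname(tally["genic"]), 1L)
  expect_equal(unname(tally["near_gene"]), 2L)
  expect_equal(unname(tally["repeat_overlap"]), 1L)
})

test_that("intergenic filtering matches a brute-force distance oracle", {
  set.seed(12)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:15),
                      chrom = sample(c("chr1", "chr2"), 15, TRUE),
                      start = sample.int(80000, 15), strand = "+")
  genes$end <- genes$start + sample(1000:4000, 15)
  sites <- data.frame(chrom = sample(c("chr1", "chr2"), 400, TRUE),
                      pos = sample.int(90000, 400))
  got <- filter_intergenic_sites(sites, genes, NULL, flank = 1000L)
  keep <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    d <- Inf; ingene <- FALSE
    for (j in which(genes$chrom == sites$chrom[i])) {
      if (sites$pos[i] >= genes$start[j] && sites$pos[i] < genes$end[j]) {
        ingene <- TRUE
      } else if (sites$pos[i] >= genes$end[j]) {
        d <- min(d, sites$pos[i] - (genes$end[j] - 1))
      } else {
        d <- min(d, genes$start[j] - sites$pos[i])
      }
    }
    keep[i] <- !ingene && d > 1000
  }
  expect_equal(got$pos, sites$pos[keep])
})

test_that("DMR site calling combines rank test, fold change and read floor", {
  design <- data.frame(sample_id = paste0("s", 1:21),
                       condition = rep(c("nodox", "dox"), c(3, 18)),
                       day = rep(c(0L, 1L, 2L, 3L, 4L, 6L, 8L), each = 3),
                       replicate = rep(1:3, 7))
  counts <- rbind(flat = rep(5, 21),
                  strong = c(rep(0, 3), rep(40, 18)),
                  sparse = c(rep(0, 3), rep(3, 3), rep(0, 15)))
  sites <- data.frame(chrom = "chr1", pos = c(100L, 700L, 1300L),
                      context = "DCM")
  tot <- data.frame(sample_id = design$sample_id, dcm_total = 1e6,
                    cpg_total = 1e6)
  raw <- site_counts(sites, counts, tot, design, "raw")
  rpm <- raw; rpm$normalized <- "relative"
  esc <- call_dmr_sites(rpm, raw, mode = "esc")
  intest <- call_dmr_sites(rpm, raw, mode = "intestine")
  expect_false(esc$significant[1])       # identical dox/nodox
  expect_true(esc$significant[2])        # zero controls, 40 reads, FC = Inf
  expect_true(intest$significant[2])
  # 9 total reads with astronomical FC: intestine mode rejects, ESC keeps
  expect_equal(intest$total_reads[3], 9)
  expect_false(intest$significant[3])
})

test_that("region merging chains by gap and matches transitive closure", {
  r1 <- merge_sites_to_regions(data.frame(chrom = "chr1",
                                          pos = c(100L, 550L)))
  expect_equal(nrow(r1$regions), 1L)
  r2 <- merge_sites_to_regions(data.frame(chrom = "chr1",
                                          pos = c(100L, 700L)))
  expect_equal(nrow(r2$regions), 2L)
  # pairwise-adjacent chaining joins a whole chain
  r3 <- merge_sites_to_regions(data.frame(chrom = "chr1",
                                          pos = c(0L, 400L, 800L, 1200L)))
  expect_equal(nrow(r3$regions), 1L)
  expect_equal(r3$regions$start, 0L)
  expect_equal(r3$regions$end, 1201L)
  # empty input
  expect_equal(nrow(merge_sites_to_regions(
    data.frame(chrom = character(0), pos = integer(0)))$regions), 0L)

  # randomized sites vs brute-force transitive closure
  set.seed(31)
  s <- data.frame(chrom = sample(c("chr1", "chr2"), 120, TRUE),
                  pos = sample.int(20000, 120))
  got <- merge_sites_to_regions(s)
  oracle <- brute_merge(s$chrom, s$pos, 500L)
  # same partition: the member labels must be a relabeling of the oracle's
  expect_equal(nrow(got$regions), length(unique(oracle)))
  expect_true(all(tapply(oracle, got$members, function(v)
    length(unique(v))) == 1))

  # merging is idempotent: region start points re-merge to the same set
  again <- merge_sites_to_regions(
    data.frame(chrom = got$regions$chrom, pos = got$regions$start))
  expect_lte(nrow(again$regions), nrow(got$regions))
  # raw regions are pairwise disjoint
  for (cn in unique(got$regions$chrom)) {
    rr <- got$regions[got$regions$chrom == cn, ]
    rr <- rr[order(rr$start), ]
    if (nrow(rr) > 1) expect_true(all(rr$start[-1] >= rr$end[-nrow(rr)]))
  }
})

test_that("extension by 250 bp re-merges overlapping regions", {
  # two sites exactly 500 bp apart: separate at merge (strict < 500)
  # but overlapping after +/- 250 extension
  r <- merge_sites_to_regions(data.frame(chrom = "chr1",
                                         pos = c(100L, 600L)))
  expect_equal(nrow(r$regions), 2L)
  expect_equal(nrow(r$extended), 1L)
  expect_equal(r$extended$start, 0L)   # clipped at the chromosome start
})

test_that("closest-gene assignment minimizes distance and breaks ties lexicographically", {
  genes <- data.frame(gene_id = c("gB", "gA"), chrom = "chr1",
                      start = c(5000L, 10000L), end = c(6000L, 11000L),
                      strand = "+")
  regions <- data.frame(chrom = "chr1", start = 7500L, end = 8500L)
  got <- assign_closest_gene(regions, genes)
  expect_equal(got$closest_gene, "gA")   # equidistant (1.5 kb both): tie
  expect_true(got$tie)
  # nearer gene wins over a farther one
  regions2 <- data.frame(chrom = "chr1", start = 6300L, end = 6400L)
  got2 <- assign_closest_gene(regions2, genes)
  expect_equal(got2$closest_gene, "gB")
  expect_equal(got2$distance, 300L)

  # random layouts against the exhaustive pairwise oracle
  set.seed(14)
  rg <- data.frame(gene_id = sprintf("g%02d", 1:12),
                   chrom = sample(c("chr1", "chr2"), 12, TRUE),
                   start = sample.int(50000, 12), strand = "+")
  rg$end <- rg$start + sample(500:3000, 12)
  rr <- data.frame(chrom = sample(c("chr1", "chr2"), 60, TRUE),
                   start = sample.int(52000, 60))
  rr$end <- rr$start + 200L
  got3 <- assign_closest_gene(rr, rg)
  want <- vapply(seq_len(nrow(rr)), function(i) brute_closest(rr[i, ], rg),
                 character(1))
  expect_equal(got3$closest_gene, want)
})

test_that("coordination matrix is diagonal-dominant for matched peak days", {
  set.seed(9)
  days <- c(1L, 2L, 3L, 4L, 6L, 8L)
  genes <- data.frame(chrom = "chr1",
                      start = seq(0, by = 10000, length.out = 60))
  genes$end <- genes$start + 3000L
  genes$peak_day <- rep(days, 10)
  regions <- data.frame(chrom = "chr1", start = genes$end + 1200L)
  regions$end <- regions$start + 400L
  regions$peak_day <- genes$peak_day
  cm <- coordination_matrix(regions, genes)
  expect_true(all(diag(cm$z) == apply(cm$z, 1, max)))
  # no enhancer in any window: zero counts
  far <- regions
  far$start <- genes$start + 6300L   # inside the only window-free gap
  far$end <- far$start + 400L
  cm0 <- coordination_matrix(far, genes)
  expect_true(all(cm0$counts == 0))
  # shuffled enhancer peak days: diagonal no longer systematically high
  sh <- regions; sh$peak_day <- sample(sh$peak_day)
  cmS <- coordination_matrix(sh, genes)
  expect_lt(mean(diag(cmS$z)), 3)
})

test_that("peak labeling thresholds on center distance and has a calibrated shuffle", {
  genome_len <- c(chr1 = 200000L)
  genes <- data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0))
  peaks <- data.frame(chrom = "chr1",
                      start = c(10000L, 50000L), end = c(11000L, 51000L))
  # centers at 10500 and 50500: sites 400 and 800 bp away
  sites <- data.frame(chrom = "chr1", pos = c(10900L, 51300L))
  rep_ <- label_peaks(peaks, sites, genome_len, genes, n_shuffles = 5,
                      seed = 2)
  expect_equal(rep_$n_labeled, 1L)
  expect_equal(rep_$distances, c(400, 800))
  # zero significant sites: nothing labeled, shuffle mean 0
  rep0 <- label_peaks(peaks, data.frame(chrom = character(0),
                                        pos = integer(0)),
                      genome_len, genes, n_shuffles = 5, seed = 2)
  expect_equal(rep0$fraction, 0)
  expect_equal(rep0$shuffle_mean, 0)

  # uniform site density: shuffle labeled fraction ~ 1 - (1 - 1500/L)^n
  set.seed(20)
  L <- 200000L; n_sites <- 90L
  usites <- data.frame(chrom = "chr1", pos = sort(sample.int(L, n_sites)))
  upeaks <- data.frame(chrom = "chr1",
                       start = seq(5000, 180000, length.out = 40))
  upeaks$end <- upeaks$start + 800L
  repU <- label_peaks(upeaks, usites, genome_len, genes,
                      n_shuffles = 100, seed = 5)
  expected <- 1 - (1 - 1500 / L)^n_sites
  se <- sqrt(expected * (1 - expected) / (40 * 100))
  expect_lt(abs(repU$shuffle_mean - expected), 3 * se + 0.02)
})

test_that("planted enhancer regions are recovered with high precision and recall", {
  st <- tiny_study(seed = 61, n_genes = 12, chrom_len = 100000)
  rpm <- normalize_counts(st$counts, "relative")
  dcm_idx <- rpm$sites$context == "DCM"
  cand <- filter_intergenic_sites(rpm$sites[dcm_idx, c("chrom", "pos")],
                                  st$genome$genes, st$genome$repeats)
  key <- paste(rpm$sites$chrom, rpm$sites$pos)
  sel <- match(paste(cand$chrom, cand$pos), key)
  sub <- function(x) site_counts(x$sites[sel, , drop = FALSE],
                                 x$counts[sel, , drop = FALSE],
                                 x$totals, x$design, x$normalized)
  dmr <- call_dmr_sites(sub(rpm), sub(st$counts), mode = "intestine")
  sig <- dmr[dmr$significant, ]
  regions <- merge_sites_to_regions(sig[c("chrom", "pos")])$regions
  truth <- st$genome$enhancers
  overlaps <- function(a, b) {
    any(b$chrom == a$chrom & b$start < a$end & a$start < b$end)
  }
  tp <- sum(vapply(seq_len(nrow(regions)), function(i)
    overlaps(regions[i, ], truth), logical(1)))
  recovered <- sum(vapply(seq_len(nrow(truth)), function(i)
    overlaps(truth[i, ], regions), logical(1)))
  expect_gte(tp / nrow(regions), 0.9)
  expect_gte(recovered / nrow(truth), 0.8)
})
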