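# Brute-force oracles used by DERIVED-value tests.  These deliberately share
# no code with the package implementation: plain loops and substring
# comparisons only.

# exhaustive k-mer window scan for a set of motifs; 0-based positions
brute_scan <- function(seq, motifs) {
  hits <- list()
  for (m in motifs) {
    k <- nchar(m)
    pos <- integer(0)
    if (nchar(seq) >= k) {
      for (i in seq_len(nchar(seq) - k + 1L)) {
        if (substr(seq, i, i + k - 1L) == m) pos <- c(pos, i - 1L)
      }
    }
    hits[[m]] <- pos
  }
  hits
}

# random DNA string
rand_seq <- function(n, seed, letters = c("A", "C", "G", "T")) {
  set.seed(seed)
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# brute-force per-site interval membership: counts of sites in [start, end)
brute_gene_counts <- function(site_chrom, site_pos, counts, genes) {
  out <- matrix(0, nrow(genes), ncol(counts))
  for (gi in seq_len(nrow(genes))) {
    for (si in seq_along(site_pos)) {
      if (site_chrom[si] == genes$chrom[gi] &&
          site_pos[si] >= genes$start[gi] && site_pos[si] < genes$end[gi]) {
        out[gi, ] <- out[gi, ] + counts[si, ]
      }
    }
  }
  rownames(out) <- genes$gene_id
  out
}

# transitive-closure merging of point sites: two sites link when their
# positions differ by less than gap; returns partition labels
brute_merge <- function(chrom, pos, gap) {
  n <- length(pos)
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (chrom[i] == chrom[j] && abs(pos[i] - pos[j]) < gap &&
          lab[i] != lab[j]) {
        lab[lab == max(lab[i], lab[j])] <- min(lab[i], lab[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(lab, unique(lab[order(chrom, pos)]))
}

# exhaustive pairwise closest gene (edge-to-edge, 0 on overlap, lexicographic
# tie-break)
brute_closest <- function(region, genes) {
  cand <- genes[genes$chrom == region$chrom, , drop = FALSE]
  if (nrow(cand) == 0L) return(NA_character_)
  d <- numeric(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (region$start < cand$end[i] && cand$start[i] < region$end) d[i] <- 0
    else if (cand$start[i] >= region$end) d[i] <- cand$start[i] - region$end
    else d[i] <- region$start - cand$end[i]
  }
  ids <- sort(cand$gene_id[d == min(d)])
  ids[1]
}

# exhaustive two-sided Mann-Whitney permutation p-value
brute_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x); N <- length(pooled)
  u_of <- function(xi) {
    xs <- pooled[xi]; ys <- pooled[-xi]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_len(n))
  center <- n * (N - n) / 2
  combs <- utils::combn(N, n)
  us <- apply(combs, 2, u_of)
  mean(abs(us - center) >= abs(u_obs - center) - 1e-9)
}

# brute-force 13-17 bp offset check for a read placed at a known locus:
# enumerates catalog anchors inside the span and applies the window rule
brute_classify <- function(span_start, read_len, catalog_chrom_rows, window = c(13, 17)) {
  q <- list()
  for (i in seq_len(nrow(catalog_chrom_rows))) {
    a <- catalog_chrom_rows$anchor[i]
    if (a < span_start || a >= span_start + read_len) next
    d5 <- a - span_start + 1
    d3 <- span_start + read_len - a
    if ((d5 >= window[1] && d5 <= window[2]) ||
        (d3 >= window[1] && d3 <= window[2])) {
      q[[length(q) + 1L]] <- catalog_chrom_rows[i, ]
    }
  }
  if (!length(q)) return(list(label = "REJECT"))
  q <- do.call(rbind, q)
  dcm <- q[q$context == "DCM", , drop = FALSE]
  if (nrow(dcm) == 1L) return(list(label = "DCM", pos = dcm$pos))
  if (nrow(dcm) == 0L && nrow(q) == 1L) return(list(label = "CPG", pos = q$pos))
  list(label = "REJECT")
}

# small shared simulated study used by several test files
tiny_study <- function(seed = 11, n_genes = 10, chrom_len = 60000) {
  cfg <- simulate_config(n_chroms = 2L, chrom_len = chrom_len,
                         intergenic_gap = 6000L, n_genes = n_genes,
                         seed = seed)
  genome <- generate_toy_genome(cfg)
  counts <- simulate_site_counts(genome, cfg)
  list(cfg = cfg, genome = genome, counts = counts)
}
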