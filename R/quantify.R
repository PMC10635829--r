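#' Analysis thresholds
#'
#' The constants used across gene and enhancer calling, serialized into
#' result attributes for provenance.
#'
#' @param p_cut Rank-test significance cutoff.
#' @param fc_min Minimum fold change for a differentially methylated site.
#' @param min_reads Minimum raw reads over all samples for an intestine-mode
#'   site call.
#' @param merge_gap Maximum site spacing (bp, strict) merged into one
#'   enhancer region.
#' @param extend Extension (bp) applied to regions for browser tracks.
#' @param label_dist Maximum peak-center-to-site distance (bp, strict) for a
#'   peak to count as labeled.
#' @param gene_flank Exclusion flank (bp) around genes for intergenic
#'   filtering and shuffles.
#' @param rpm_scale Reads-per-million scale factor.
#' @param min_sites_per_gene Genes with fewer DCM sites are flagged.
#' @param outlier_z Z-score above which correlation points are removed.
#' @return A named list of class `analysis_thresholds`.
#' @export
analysis_thresholds <- function(p_cut = 0.05, fc_min = 4, min_reads = 10,
                                merge_gap = 500, extend = 250,
                                label_dist = 750, gene_flank = 1000,
                                rpm_scale = 1e6, min_sites_per_gene = 10,
                                outlier_z = 4) {
  th <- list(p_cut = p_cut, fc_min = fc_min, min_reads = min_reads,
             merge_gap = merge_gap, extend = extend, label_dist = label_dist,
             gene_flank = gene_flank, rpm_scale = rpm_scale,
             min_sites_per_gene = min_sites_per_gene, outlier_z = outlier_z)
  stopifnot(all(unlist(th) > 0))
  class(th) <- "analysis_thresholds"
  th
}

#' Normalize a site count matrix to reads per million
#'
#' Absolute DCM enrichment divides each sample's counts by its total
#' CpG-context reads (tracking induction level); relative enrichment
#' divides by the sample's total DCM reads (comparing profiles across
#' samples irrespective of induction strength).  Both scale by 1e6.
#'
#' @param m A raw [site_counts()] object.
#' @param mode `"absolute"` (CpG-total normaliser) or `"relative"`
#'   (DCM-total normaliser).
#' @return A `site_counts` object with numeric RPM counts and `normalized`
#'   set to the mode.
#' @export
normalize_counts <- function(m, mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "site_counts"))
  if (m$normalized != "raw") stop("matrix is already normalized (", m$normalized, ")")
  tot <- if (mode == "absolute") m$totals$cpg_total else m$totals$dcm_total
  bad <- which(tot <= 0)
  if (length(bad)) {
    stop("zero ", if (mode == "absolute") "CpG" else "DCM",
         " total for sample(s): ",
         paste(m$design$sample_id[bad], collapse = ", "))
  }
  out <- m
  out$counts <- sweep(m$counts, 2, tot, "/") * 1e6
  out$normalized <- mode
  out
}

#' Aggregate site counts to gene bodies
#'
#' A read is attributed to a gene when its site coordinate falls within the
#' half-open interval `[start, end)` (optionally extended by `flank` on
#' both sides, or restricted to TSS/TES windows).
#'
#' @param m A `site_counts` object (raw or normalized); only DCM-context
#'   rows are aggregated.
#' @param genes Gene annotation data frame (`gene_id`, `chrom`, `start`,
#'   `end`, `strand`).
#' @param flank Symmetric extension in bp (default 0).
#' @param region `"body"` (default), `"tss"` or `"tes"`: the latter two
#'   count sites within `flank` bp around the strand-aware TSS/TES.
#' @param thresholds [analysis_thresholds()] supplying
#'   `min_sites_per_gene`.
#' @return A `gene_counts` data-frame-like list: `table` (gene x sample
#'   matrix), `genes` (annotation plus `n_dcm_sites`, `length`,
#'   `overlapping`, `insufficient_sites` flags).
#' @export
gene_body_counts <- function(m, genes, flank = 0L,
                             region = c("body", "tss", "tes"),
                             thresholds = analysis_thresholds()) {
  region <- match.arg(region)
  stopifnot(inherits(m, "site_counts"))
  keep <- m$sites$context == "DCM"
  sites <- m$sites[keep, , drop = FALSE]
  counts <- m$counts[keep, , drop = FALSE]

  if (region == "body") {
    ws <- genes$start - flank
    we <- genes$end + flank
  } else {
    tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
    tes <- ifelse(genes$strand == "+", genes$end - 1L, genes$start)
    ref <- if (region == "tss") tss else tes
    ws <- ref - flank
    we <- ref + flank + 1L
  }
  gr_sites <- GenomicRanges::GRanges(sites$chrom,
                                     IRanges::IRanges(sites$pos + 1L,
                                                      width = 1L))
  gr_genes <- GenomicRanges::GRanges(genes$chrom,
                                     IRanges::IRanges(ws + 1L, we))
  # half-open: site pos in [ws, we) <=> 1-based site in [ws+1, we]
  hits <- GenomicRanges::findOverlaps(gr_sites, gr_genes)
  tab <- matrix(0, nrow = nrow(genes), ncol = ncol(counts),
                dimnames = list(genes$gene_id, colnames(counts)))
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    for (j in seq_len(ncol(counts))) {
      s <- tapply(counts[qh, j], sh, sum)
      tab[as.integer(names(s)), j] <- s
    }
  }
  n_sites <- integer(nrow(genes))
  if (length(hits)) {
    ns <- table(S4Vectors::subjectHits(hits))
    n_sites[as.integer(names(ns))] <- as.integer(ns)
  }
  body <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start + 1L, genes$end))
  overlapping <- GenomicRanges::countOverlaps(body, body) > 1L
  ga <- genes
  ga$n_dcm_sites <- n_sites
  ga$length <- genes$end - genes$start
  ga$overlapping <- overlapping
  ga$insufficient_sites <- n_sites < thresholds$min_sites_per_gene
  structure(list(table = tab, genes = ga, design = m$design,
                 normalized = m$normalized, totals = m$totals),
            class = "gene_counts")
}

#' @export
print.gene_counts <- function(x, ...) {
  cat("gene_counts:", nrow(x$table), "genes x", ncol(x$table),
      "samples (", x$normalized, ")\n")
  invisible(x)
}

#' Mann-Whitney U test used throughout the package
#'
#' Exact U distribution when `min(n, m) <= 8` and the data are tie-free;
#' normal approximation with tie correction (and continuity correction)
#' otherwise.  Two groups of constant, identical values return `p = 1` by
#' convention with a flag.
#'
#' @param x,y Numeric vectors (group X, group Y).
#' @return A list with `p_value`, `method`, `degenerate`.
#' @export
mann_whitney <- function(x, y) {
  if (length(unique(c(x, y))) == 1L) {
    return(list(p_value = 1, method = "degenerate", degenerate = TRUE))
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  if (!ties && min(length(x), length(y)) <= 8L) {
    p <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    return(list(p_value = p, method = "exact", degenerate = FALSE))
  }
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  list(p_value = p, method = "normal_tie_corrected", degenerate = FALSE)
}

#' Call significantly labeled (active) genes
#'
#' Two-sided Mann-Whitney U test per gene on normalized per-gene values,
#' with the uninduced (`nodox`) samples as set X and all induced (`dox`)
#' samples as set Y; a gene is significant when `p < p_cut` and the dox
#' median exceeds the nodox median, so that "significantly labeled" means
#' enriched.
#'
#' @param t A `gene_counts` object, normalized in relative mode.
#' @param design Optional design override (defaults to `t$design`).
#' @param thresholds [analysis_thresholds()].
#' @return Data frame `gene_id`, `p_value`, `significant`, `degenerate`,
#'   with the thresholds attached as an attribute.
#' @export
call_active_genes <- function(t, design = t$design,
                              thresholds = analysis_thresholds()) {
  stopifnot(inherits(t, "gene_counts"))
  xi <- design$condition == "nodox"
  yi <- design$condition == "dox"
  if (sum(xi) < 2L || sum(yi) < 2L) {
    stop("need >= 2 samples in each of the dox and nodox groups")
  }
  res <- lapply(seq_len(nrow(t$table)), function(i) {
    v <- t$table[i, ]
    mw <- mann_whitney(v[xi], v[yi])
    data.frame(gene_id = rownames(t$table)[i],
               p_value = mw$p_value,
               significant = !mw$degenerate &&
                 mw$p_value < thresholds$p_cut &&
                 stats::median(v[yi]) > stats::median(v[xi]),
               degenerate = mw$degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "thresholds") <- thresholds
  out
}

#' Build strand-aware gene meta-profiles
#'
#' Pools eligible genes of each expression tier into a 300-bin profile:
#' 100 upstream bins of 100 bp (10 kb before the TSS), 100 gene-body bins
#' of 1% of the body length, and 100 downstream bins of 100 bp (10 kb after
#' the TES), oriented along the coding strand.  Each bin's value is the
#' pooled read count divided by the pooled DCM site count of the bin, so
#' flank and body bins share reads-per-site units and bin-size differences
#' are absorbed by the site-frequency adjustment.  Genes shorter than
#' 100 bp or with overlapping bodies are excluded; bins containing no site
#' are reported as missing (`NA`), not zero.
#'
#' @param m A `site_counts` object (DCM rows are used).
#' @param genes Gene annotation (with `tier` column when `tiers` is NULL).
#' @param tiers Optional named vector gene_id -> tier; defaults to
#'   `genes$tier`.
#' @param flank_bins,body_bins Bin counts (defaults 100 each).
#' @param flank_bp Flank bin width in bp (default 100).
#' @return Long data frame: `tier`, `bin` (1..300), `segment`
#'   (`upstream`/`body`/`downstream`), `reads`, `sites`, `value`.
#' @export
build_meta_profile <- function(m, genes, tiers = NULL,
                               flank_bins = 100L, body_bins = 100L,
                               flank_bp = 100L) {
  stopifnot(inherits(m, "site_counts"))
  if (is.null(tiers)) tiers <- stats::setNames(genes$tier, genes$gene_id)
  keep <- m$sites$context == "DCM"
  sites <- m$sites[keep, , drop = FALSE]
  reads <- rowSums(m$counts[keep, , drop = FALSE])

  body <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start + 1L, genes$end))
  overlapping <- GenomicRanges::countOverlaps(body, body) > 1L
  eligible <- !overlapping & (genes$end - genes$start) >= 100L
  n_bins <- 2L * flank_bins + body_bins

  acc_reads <- acc_sites <- matrix(0, nrow = n_bins,
                                   ncol = length(unique(tiers)),
                                   dimnames = list(NULL, sort(unique(tiers))))
  site_split <- split(seq_len(nrow(sites)), sites$chrom)
  for (i in which(eligible)) {
    g <- genes[i, ]
    idx <- site_split[[g$chrom]]
    if (is.null(idx)) next
    pos <- sites$pos[idx]
    L <- g$end - g$start
    up_lo <- g$start - flank_bins * flank_bp
    dn_hi <- g$end + flank_bins * flank_bp
    sel <- idx[pos >= up_lo & pos < dn_hi]
    pos <- sites$pos[sel]
    bin <- integer(length(pos))
    before <- pos < g$start
    after <- pos >= g$end
    inside <- !before & !after
    bin[before] <- flank_bins - ((g$start - 1L - pos[before]) %/% flank_bp)
    bin[inside] <- flank_bins +
      pmin(body_bins, floor((pos[inside] - g$start) / L * body_bins) + 1L)
    bin[after] <- flank_bins + body_bins +
      ((pos[after] - g$end) %/% flank_bp) + 1L
    if (g$strand == "-") bin <- n_bins + 1L - bin
    tier <- tiers[[g$gene_id]]
    for (k in seq_along(sel)) {
      acc_reads[bin[k], tier] <- acc_reads[bin[k], tier] + reads[sel[k]]
      acc_sites[bin[k], tier] <- acc_sites[bin[k], tier] + 1L
    }
  }
  segs <- rep(c("upstream", "body", "downstream"),
              c(flank_bins, body_bins, flank_bins))
  out <- do.call(rbind, lapply(colnames(acc_reads), function(tr) {
    if (all(acc_sites[, tr] == 0)) {
      warning("tier ", tr, " has no eligible genes or sites; empty profile")
    }
    data.frame(tier = tr, bin = seq_len(n_bins), segment = segs,
               reads = acc_reads[, tr], sites = acc_sites[, tr],
               value = ifelse(acc_sites[, tr] > 0,
                              acc_reads[, tr] / acc_sites[, tr], NA_real_),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Correlate site signal with an external peak track
#'
#' Computes Pearson correlation between `log10((DCM reads + 1) / DCM sites
#' in peak)` and `log10((ChIP reads + 1) / peak length)` over peaks,
#' iteratively removing points whose z-score exceeds `outlier_z` in either
#' coordinate.  The pseudocount admits zero-count peaks and is recorded in
#' the result.
#'
#' @param dcm_reads,n_sites Numeric vectors per peak: DCM read counts and
#'   DCM site counts (peaks with zero sites are dropped).
#' @param chip_reads,peak_length Numeric vectors per peak.
#' @param thresholds [analysis_thresholds()] (supplies `outlier_z`).
#' @return A list: `r`, `n_used`, `n_removed`, `pseudocount`.
#' @export
peak_correlation <- function(dcm_reads, n_sites, chip_reads, peak_length,
                             thresholds = analysis_thresholds()) {
  keep <- n_sites > 0 & peak_length > 0
  x <- log10((dcm_reads[keep] + 1) / n_sites[keep])
  y <- log10((chip_reads[keep] + 1) / peak_length[keep])
  removed <- 0L
  repeat {
    if (length(x) < 3L) stop("fewer than 3 peaks remain after filtering")
    zx <- abs(x - mean(x)) / stats::sd(x)
    zy <- abs(y - mean(y)) / stats::sd(y)
    drop <- zx > thresholds$outlier_z | zy > thresholds$outlier_z
    drop[is.na(drop)] <- FALSE
    if (!any(drop)) break
    removed <- removed + sum(drop)
    x <- x[!drop]; y <- y[!drop]
  }
  list(r = stats::cor(x, y), n_used = length(x), n_removed = removed,
       pseudocount = 1)
}
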