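#' Filter sites to intergenic, repeat-free candidates
#'
#' Keeps sites that (1) do not overlap any gene body, (2) lie more than
#' `flank` bp from the closest gene, and (3) do not overlap any repeat
#' interval.  Distances are counted between base positions: a site on the
#' base immediately after a gene is 1 bp away, so a site 999 bp from a gene
#' edge is removed at the default 1-kb flank while a site 1,001 bp away is
#' kept.  Per-criterion removal tallies are attached.
#'
#' @param sites Data frame with `chrom`, `pos` (0-based site coordinates).
#' @param genes Gene annotation (`chrom`, `start`, `end`, 0-based
#'   half-open).
#' @param repeats Repeat intervals, same conventions (may be empty).
#' @param flank Minimum distance to the closest gene in bp (default 1000).
#' @return The surviving rows of `sites`, with a `tally` attribute
#'   recording removals per criterion.
#' @export
filter_intergenic_sites <- function(sites, genes, repeats = NULL,
                                    flank = 1000L) {
  if (is.null(repeats)) {
    repeats <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0))
  }
  gr_sites <- GenomicRanges::GRanges(sites$chrom,
                                     IRanges::IRanges(sites$pos + 1L,
                                                      width = 1L))
  gr_genes <- GenomicRanges::GRanges(genes$chrom,
                                     IRanges::IRanges(genes$start + 1L,
                                                      genes$end))
  in_gene <- GenomicRanges::countOverlaps(gr_sites, gr_genes) > 0L
  # distance between base positions: GenomicRanges gap + 1
  d <- rep(Inf, nrow(sites))
  dtn <- GenomicRanges::distanceToNearest(gr_sites, gr_genes)
  d[S4Vectors::queryHits(dtn)] <- S4Vectors::mcols(dtn)$distance + 1L
  too_close <- !in_gene & d <= flank
  in_repeat <- rep(FALSE, nrow(sites))
  if (nrow(repeats)) {
    gr_rep <- GenomicRanges::GRanges(repeats$chrom,
                                     IRanges::IRanges(repeats$start + 1L,
                                                      repeats$end))
    in_repeat <- GenomicRanges::countOverlaps(gr_sites, gr_rep) > 0L
  }
  keep <- !in_gene & !too_close & !in_repeat
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tally") <- c(genic = sum(in_gene),
                          near_gene = sum(too_close & !in_gene),
                          repeat_overlap = sum(in_repeat & !in_gene &
                                                 !too_close))
  out
}

#' Call differentially methylated sites between induced and control samples
#'
#' Per site, a two-sided Mann-Whitney U test of all induced (`dox`) samples
#' against the uninduced controls on normalized values, combined with a
#' fold-change filter (ratio of group means, induced over control) and -- in
#' intestine mode -- a minimum raw read total.  In intestine mode all dox
#' days are pooled against the controls; ESC mode expects a single-timepoint
#' design and applies the same pooled comparison without the read floor.
#'
#' @param m Normalized `site_counts` (relative mode recommended).
#' @param raw The matching raw `site_counts` (for the read floor); only
#'   needed in intestine mode.
#' @param thresholds [analysis_thresholds()].
#' @param mode `"intestine"` (default; adds the `min_reads` floor) or
#'   `"esc"`.
#' @param design Optional design override.
#' @return Data frame per site: `chrom`, `pos`, `p_value`, `fold_change`,
#'   `total_reads`, `significant`, plus per-day mean normalized signal in
#'   `day_*` columns.
#' @export
call_dmr_sites <- function(m, raw = NULL,
                           thresholds = analysis_thresholds(),
                           mode = c("intestine", "esc"),
                           design = m$design) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "site_counts"))
  xi <- which(design$condition == "nodox")
  yi <- which(design$condition == "dox")
  if (length(xi) < 3L || length(yi) < 3L) {
    stop("need >= 3 samples per compared group")
  }
  counts <- m$counts
  totals_raw <- if (!is.null(raw)) rowSums(raw$counts) else rep(NA_real_, nrow(counts))
  days <- sort(unique(design$day[design$day > 0L]))
  day_means <- sapply(days, function(d) {
    rowMeans(counts[, design$day == d, drop = FALSE])
  })
  colnames(day_means) <- paste0("day_", days)

  p <- fc <- numeric(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    v <- counts[i, ]
    p[i] <- mann_whitney(v[xi], v[yi])$p_value
    mx <- mean(v[xi])
    fc[i] <- if (mx == 0) {
      if (mean(v[yi]) > 0) Inf else NaN
    } else mean(v[yi]) / mx
  }
  sig <- !is.na(p) & p < thresholds$p_cut & !is.nan(fc) &
    fc >= thresholds$fc_min
  if (mode == "intestine") {
    if (is.null(raw)) stop("intestine mode needs the raw count matrix")
    sig <- sig & totals_raw >= thresholds$min_reads
  }
  out <- data.frame(chrom = m$sites$chrom, pos = m$sites$pos,
                    p_value = p, fold_change = fc,
                    total_reads = totals_raw, significant = sig,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(day_means))
}

#' Merge differentially methylated sites into enhancer regions
#'
#' Single-linkage chaining: consecutive sites on a chromosome belong to one
#' region when they are less than `merge_gap` bp apart (distance between
#' site coordinates, strict inequality).  Raw regions span their member
#' sites; the browser-track variant extends each region by `extend` bp on
#' both sides and re-merges regions that overlap after extension.
#'
#' @param sites Data frame with `chrom`, `pos` (one row per significant
#'   site); extra columns are carried into the member list.
#' @param merge_gap Chaining threshold in bp (default 500, strict).
#' @param extend Extension in bp for the browser variant (default 250).
#' @return A list with `regions` (raw: `chrom`, `start`, `end`, `n_sites`,
#'   `region_id`) and `extended` (after extension and re-merge), plus
#'   `members` mapping sites to raw regions.
#' @export
merge_sites_to_regions <- function(sites, merge_gap = 500L, extend = 250L) {
  if (nrow(sites) == 0L) {
    empty <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), n_sites = integer(0),
                        region_id = character(0))
    return(list(regions = empty, extended = empty[-4],
                members = integer(0)))
  }
  ord <- order(sites$chrom, sites$pos)
  s <- sites[ord, , drop = FALSE]
  new_chrom <- c(TRUE, s$chrom[-1] != s$chrom[-nrow(s)])
  gap <- c(Inf, diff(s$pos))
  gap[new_chrom] <- Inf
  region <- cumsum(new_chrom | gap >= merge_gap)
  regions <- do.call(rbind, lapply(split(seq_len(nrow(s)), region), function(ix) {
    data.frame(chrom = s$chrom[ix[1]], start = min(s$pos[ix]),
               end = max(s$pos[ix]) + 1L, n_sites = length(ix),
               stringsAsFactors = FALSE)
  }))
  regions$region_id <- sprintf("dmr%04d", seq_len(nrow(regions)))
  rownames(regions) <- NULL
  members <- integer(nrow(sites))
  members[ord] <- region

  gr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(pmax(regions$start - extend, 0L) + 1L,
                                                regions$end + extend))
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  extended <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                         start = BiocGenerics::start(red) - 1L,
                         end = BiocGenerics::end(red),
                         stringsAsFactors = FALSE)
  list(regions = regions, extended = extended, members = members)
}

#' Assign the closest gene to each region
#'
#' Minimal edge-to-edge distance between region and gene (0 when they
#' overlap); ties break to the lexicographically smaller gene id and are
#' flagged.  The distance is signed: positive when the region lies
#' downstream (higher coordinates) of the gene, negative when upstream.
#'
#' @param regions Data frame `chrom`, `start`, `end` (0-based half-open).
#' @param genes Gene annotation; when `significant_only` is TRUE it must
#'   carry a logical `significant` column and only those genes are
#'   eligible.
#' @param significant_only Restrict to significantly labeled genes.
#' @return `regions` with added `closest_gene`, `distance` (signed),
#'   `tie` columns; regions on chromosomes without eligible genes stay
#'   unassigned (`NA`).
#' @export
assign_closest_gene <- function(regions, genes, significant_only = FALSE) {
  g <- genes
  if (significant_only) {
    stopifnot("significant" %in% names(g))
    g <- g[g$significant, , drop = FALSE]
  }
  if (nrow(g) == 0L) stop("no eligible genes")
  out <- regions
  out$closest_gene <- NA_character_
  out$distance <- NA_integer_
  out$tie <- FALSE
  for (i in seq_len(nrow(regions))) {
    cand <- which(g$chrom == regions$chrom[i])
    if (!length(cand)) next
    # edge-to-edge gap between half-open intervals; 0 on overlap
    gap_left <- g$start[cand] - regions$end[i]   # gene right of region
    gap_right <- regions$start[i] - g$end[cand]  # gene left of region
    d <- pmax(0L, pmax(gap_left, gap_right))
    best <- which(d == min(d))
    ids <- g$gene_id[cand[best]]
    pick <- best[order(ids)[1]]
    out$closest_gene[i] <- g$gene_id[cand[pick]]
    sign <- if (d[pick] == 0L) 1L else if (gap_right[pick] > 0L) 1L else -1L
    out$distance[i] <- sign * d[pick]
    out$tie[i] <- length(best) > 1L
  }
  out
}

#' Gene/enhancer peak-day coordination matrix
#'
#' Counts, for every combination of gene peak day and enhancer peak day,
#' how many enhancers fall within `window` bp around a gene with that peak
#' day, then converts each gene-day row to proportions over enhancer days
#' and z-scores it (population standard deviation).  A diagonal-dominant
#' z-matrix indicates that enhancers and their neighbouring genes peak on
#' the same day.
#'
#' @param regions Enhancer regions with `chrom`, `start`, `end`,
#'   `peak_day`.
#' @param genes Genes with `chrom`, `start`, `end`, `peak_day`.
#' @param window Flank in bp around the gene body (default 3000).
#' @param days Day levels (default the union of observed peak days).
#' @return A list with `counts`, `proportions`, `z` matrices
#'   (rows = gene peak day, columns = enhancer peak day).
#' @export
coordination_matrix <- function(regions, genes, window = 3000L,
                                days = NULL) {
  if (is.null(days)) {
    days <- sort(unique(c(genes$peak_day, regions$peak_day)))
  }
  days <- days[!is.na(days)]
  lab <- paste0("day_", days)
  counts <- matrix(0, length(days), length(days), dimnames = list(lab, lab))
  gr_g <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(pmax(genes$start - window, 0L) + 1L,
                                                  genes$end + window))
  gr_e <- GenomicRanges::GRanges(regions$chrom,
                                 IRanges::IRanges(regions$start + 1L,
                                                  regions$end))
  hits <- GenomicRanges::findOverlaps(gr_e, gr_g)
  for (k in seq_along(hits)) {
    e <- S4Vectors::queryHits(hits)[k]
    g <- S4Vectors::subjectHits(hits)[k]
    gd <- genes$peak_day[g]; ed <- regions$peak_day[e]
    if (is.na(gd) || is.na(ed)) next
    counts[paste0("day_", gd), paste0("day_", ed)] <-
      counts[paste0("day_", gd), paste0("day_", ed)] + 1
  }
  rs <- rowSums(counts)
  props <- counts / ifelse(rs == 0, 1, rs)
  props[rs == 0, ] <- NA_real_
  z <- props
  for (i in seq_len(nrow(props))) {
    v <- props[i, ]
    if (all(is.na(v))) next
    sdp <- sqrt(mean((v - mean(v))^2))
    z[i, ] <- if (sdp == 0) 0 else (v - mean(v)) / sdp
  }
  list(counts = counts, proportions = props, z = z)
}

#' Classify peaks as labeled by significant DCM sites, with shuffle control
#'
#' A peak is labeled when the nearest significant site lies strictly within
#' `label_dist` bp of the peak center (default semantics), or when any
#' significant site overlaps the peak interval (`mode = "overlap"`).  The
#' null distribution of the labeled fraction is obtained by re-placing the
#' peaks uniformly at random `n_shuffles` times on the same chromosome,
#' preserving peak lengths and excluding genic regions plus/minus the
#' exclusion flank (rejection sampling).
#'
#' @param peaks Data frame `chrom`, `start`, `end`.
#' @param sig_sites Data frame `chrom`, `pos` of significant sites.
#' @param genome A `toy_genome` or named vector of chromosome lengths.
#' @param genes Gene annotation for the exclusion zone.
#' @param label_dist Center-to-site distance threshold in bp (strict).
#' @param n_shuffles Number of random permutations (default 100).
#' @param exclusion_flank Genic exclusion flank in bp (default 1000).
#' @param mode `"center"` (default) or `"overlap"`.
#' @param seed Seed for the shuffles.
#' @return A list of class `peak_label_report`: `n_peaks`, `n_labeled`,
#'   `fraction`, `distances` (distance to nearest significant site per
#'   peak), `shuffle_fractions`, `shuffle_mean`, `shuffle_sd`.
#' @export
label_peaks <- function(peaks, sig_sites, genome, genes,
                        label_dist = 750L, n_shuffles = 100L,
                        exclusion_flank = 1000L,
                        mode = c("center", "overlap"), seed = 1L) {
  mode <- match.arg(mode)
  chrom_len <- if (inherits(genome, "toy_genome")) {
    vapply(genome$chroms, nchar, integer(1))
  } else genome
  sites_by_chrom <- split(sig_sites$pos, sig_sites$chrom)

  label_one <- function(p) {
    sp <- sites_by_chrom[[p$chrom]]
    if (is.null(sp) || !length(sp)) return(list(lab = FALSE, d = Inf))
    if (mode == "center") {
      ctr <- (p$start + p$end) %/% 2L
      d <- min(abs(sp - ctr))
      list(lab = d < label_dist, d = d)
    } else {
      lab <- any(sp >= p$start & sp < p$end)
      ctr <- (p$start + p$end) %/% 2L
      list(lab = lab, d = min(abs(sp - ctr)))
    }
  }
  res <- lapply(seq_len(nrow(peaks)), function(i) label_one(peaks[i, ]))
  labeled <- vapply(res, `[[`, logical(1), "lab")
  dists <- vapply(res, `[[`, numeric(1), "d")

  # allowed space per chromosome (complement of genes +/- flank)
  allowed <- lapply(names(chrom_len), function(cn) {
    gr <- GenomicRanges::GRanges(cn, IRanges::IRanges(1, chrom_len[[cn]]))
    gg <- genes[genes$chrom == cn, , drop = FALSE]
    if (nrow(gg)) {
      excl <- GenomicRanges::GRanges(cn,
                IRanges::IRanges(pmax(gg$start - exclusion_flank, 0L) + 1L,
                                 gg$end + exclusion_flank))
      gr <- GenomicRanges::setdiff(gr, GenomicRanges::reduce(excl))
    }
    gr
  })
  names(allowed) <- names(chrom_len)

  shuffle_fractions <- with_seed(substream_seed(seed, "peak_shuffle"), {
    vapply(seq_len(n_shuffles), function(s) {
      labs <- vapply(seq_len(nrow(peaks)), function(i) {
        p <- peaks[i, ]
        w <- p$end - p$start
        space <- allowed[[p$chrom]]
        if (is.null(space) || length(space) == 0L) return(NA)
        widths <- BiocGenerics::width(space)
        ok <- widths >= w
        if (!any(ok)) return(NA)
        # uniform over all allowed start positions: pick a segment weighted
        # by how many starts it admits, then a start within it
        segs <- which(ok)
        seg <- segs[sample.int(length(segs), 1L,
                               prob = widths[segs] - w + 1)]
        st <- BiocGenerics::start(space)[seg] - 1L +
          sample.int(widths[seg] - w + 1L, 1L) - 1L
        np <- data.frame(chrom = p$chrom, start = st, end = st + w)
        label_one(np)$lab
      }, logical(1))
      mean(labs, na.rm = TRUE)
    }, numeric(1))
  })
  structure(list(n_peaks = nrow(peaks), n_labeled = sum(labeled),
                 fraction = mean(labeled), distances = dists,
                 shuffle_fractions = shuffle_fractions,
                 shuffle_mean = mean(shuffle_fractions),
                 shuffle_sd = stats::sd(shuffle_fractions)),
            class = "peak_label_report")
}

#' @export
print.peak_label_report <- function(x, ...) {
  cat(sprintf("peak_label_report: %d/%d labeled (%.1f%%); shuffle %.1f%% +/- %.1f%%\n",
              x$n_labeled, x$n_peaks, 100 * x$fraction,
              100 * x$shuffle_mean, 100 * x$shuffle_sd))
  invisible(x)
}
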