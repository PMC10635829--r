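#' @importFrom Biostrings DNAString DNAStringSet matchPattern readDNAStringSet
#'   reverseComplement width PDict matchPDict
#' @importFrom S4Vectors elementNROWS
NULL

# Motif table shared by the scanners, the read classifier and the simulator.
# `anchor` is the 0-based offset of the methylated cytosine within the motif:
# C(meC)WGG, C(meC)G, (meC)GG, G(meC)GC.
MOTIFS <- data.frame(
  motif   = c("CCAGG", "CCTGG", "CCG", "CGG", "GCGC"),
  context = c("DCM",   "DCM",   "CCG", "CGG", "GCGC"),
  anchor  = c(1L,      1L,      1L,    0L,    1L),
  stringsAsFactors = FALSE
)

.as_dna <- function(seq) {
  if (is(seq, "DNAString")) return(seq)
  if (is.character(seq) && length(seq) == 1L) {
    return(tryCatch(DNAString(seq),
                    error = function(e) stop("sequence contains non-IUPAC characters: ",
                                             conditionMessage(e), call. = FALSE)))
  }
  stop("`seq` must be a single character string or a DNAString")
}

.scan_motif <- function(dna, motif) {
  # matchPattern reports overlapping occurrences; fixed = TRUE so that
  # ambiguity codes (including N) never match.
  BiocGenerics::start(matchPattern(motif, dna, fixed = TRUE)) - 1L
}

#' Scan a sequence for DCM (CCWGG) sites
#'
#' Enumerates the 0-based start positions of all `CCAGG` and `CCTGG`
#' occurrences on the plus strand.  Because the motif pair is its own
#' reverse complement, scanning the plus strand alone enumerates each duplex
#' CCWGG site exactly once; a site's coordinate is the first C of the
#' plus-strand occurrence.
#'
#' @param seq A character string or [Biostrings::DNAString] over
#'   `A,C,G,T,N`.  `N` never matches; non-IUPAC characters are an error.
#' @return Sorted integer vector of 0-based positions.
#' @export
#' @examples
#' scan_dcm_sites("TTCCAGGTT")
scan_dcm_sites <- function(seq) {
  dna <- .as_dna(seq)
  pos <- sort(unique(c(.scan_motif(dna, "CCAGG"), .scan_motif(dna, "CCTGG"))))
  as.integer(pos)
}

#' Scan a sequence for LpnPI CpG-context sites
#'
#' Finds all `CCG`, `CGG` and `GCGC` occurrences on the plus strand.  These
#' are the CpG-context targets recognised by LpnPI when the central CpG is
#' methylated; both strands' methylated cytosines are represented by the
#' three plus-strand motifs.
#'
#' @inheritParams scan_dcm_sites
#' @return A data frame with columns `pos` (0-based motif start) and
#'   `context` (one of `CCG`, `CGG`, `GCGC`), sorted by position.
#' @export
#' @examples
#' scan_cpg_sites("AGCGCA")
scan_cpg_sites <- function(seq) {
  dna <- .as_dna(seq)
  hits <- lapply(c("CCG", "CGG", "GCGC"), function(m) {
    p <- .scan_motif(dna, m)
    if (length(p)) data.frame(pos = p, context = m, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    return(data.frame(pos = integer(0), context = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- out[order(out$pos, out$context), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the reference site catalog used for read classification
#'
#' Collects every DCM and CpG-context motif occurrence in a genome and
#' derives the anchor base (the methylated cytosine) of each.  Distinct CpG
#' motifs can share an anchor (e.g. `CCGG` carries both a `CCG` and a `CGG`
#' occurrence whose methylated C is the same base); the catalog keeps one
#' countable site per (chromosome, anchor), preferring the earliest motif
#' start and then alphabetical context, so that read counts are attributed
#' to a unique site per methylated cytosine.
#'
#' @param genome A `toy_genome` (see [generate_toy_genome()]) or a named
#'   [Biostrings::DNAStringSet] / named character vector of chromosome
#'   sequences.
#' @return A data frame with columns `chrom`, `pos` (0-based motif start),
#'   `context` (`DCM`, `CCG`, `CGG`, `GCGC`) and `anchor` (0-based position
#'   of the methylated C), sorted by chromosome and anchor.
#' @export
site_catalog <- function(genome) {
  seqs <- genome_sequences(genome)
  per_chrom <- lapply(names(seqs), function(cn) {
    dna <- DNAString(as.character(seqs[[cn]]))
    dcm <- scan_dcm_sites(dna)
    cpg <- scan_cpg_sites(dna)
    df <- rbind(
      if (length(dcm)) data.frame(pos = dcm, context = "DCM",
                                  stringsAsFactors = FALSE),
      cpg
    )
    if (is.null(df) || nrow(df) == 0L) return(NULL)
    df$chrom <- cn
    df$anchor <- df$pos + MOTIFS$anchor[match(df$context, MOTIFS$context)]
    df
  })
  cat <- do.call(rbind, per_chrom)
  if (is.null(cat)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      context = character(0), anchor = integer(0),
                      stringsAsFactors = FALSE))
  }
  cat <- cat[order(cat$chrom, cat$anchor, cat$pos, cat$context), , drop = FALSE]
  cat <- cat[!duplicated(cat[c("chrom", "anchor")]), , drop = FALSE]
  rownames(cat) <- NULL
  cat[c("chrom", "pos", "context", "anchor")]
}

#' Extract chromosome sequences from a genome-like object
#' @param genome A `toy_genome`, DNAStringSet, or named character vector.
#' @return A named character vector of sequences.
#' @keywords internal
genome_sequences <- function(genome) {
  if (inherits(genome, "toy_genome")) {
    return(genome$chroms)
  }
  if (is(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- names(genome)
    return(out)
  }
  if (is.character(genome) && !is.null(names(genome))) return(genome)
  stop("`genome` must be a toy_genome, DNAStringSet or named character vector")
}

# Qualifying anchor windows within a mapped read span.
# A candidate anchor qualifies when its 1-based distance to the 5' or the 3'
# read end lies in [window[1], window[2]].
.qualifying <- function(anchor, span_start, read_width, window) {
  d5 <- anchor - span_start + 1L
  d3 <- span_start + read_width - anchor
  (d5 >= window[1] & d5 <= window[2]) | (d3 >= window[1] & d3 <= window[2])
}

#' Classify MeD-seq reads by restriction-site offset
#'
#' Maps each read to the reference by exact unique match (both strands) and
#' keeps it when exactly one catalog site's anchor base lies 13--17 bp
#' (1-based, inclusive; configurable) from either read end.  When both a
#' DCM and a CpG-context anchor qualify, the DCM site wins and a conflict
#' counter is incremented; two or more qualifying anchors of the same class
#' reject the read, as do reads that fail to map or map to more than one
#' locus.
#'
#' @param reads A [Biostrings::DNAStringSet] or character vector of read
#'   sequences (32--50 bp).
#' @param genome Reference genome (see [site_catalog()]).
#' @param catalog Optional precomputed [site_catalog()]; computed from
#'   `genome` when `NULL`.
#' @param window Integer length-2: allowed 1-based distances of the anchor
#'   base from a read end.  Default `c(13, 17)`.
#' @param anchor `"methyl-c"` (default) anchors the offset window on the
#'   methylated cytosine; `"motif-start"` anchors it on the first motif
#'   base, for pipelines that measured the offset to the restriction-site
#'   start.
#' @return A data frame with one row per read: `label` (`DCM`, `CPG`,
#'   `REJECT`), `chrom`, `pos` (0-based catalog motif start or `NA`),
#'   `context`, `offset` (distance to the nearer read end), `reason` for
#'   rejections.  Attribute `tally` holds QC counts, including the
#'   DCM-over-CpG conflict counter.
#' @export
classify_reads <- function(reads, genome, catalog = NULL,
                           window = c(13L, 17L),
                           anchor = c("methyl-c", "motif-start")) {
  anchor <- match.arg(anchor)
  if (is.character(reads)) reads <- DNAStringSet(reads)
  if (is.null(catalog)) catalog <- site_catalog(genome)
  seqs <- genome_sequences(genome)
  n <- length(reads)
  out <- data.frame(
    label = rep("REJECT", n), chrom = NA_character_, pos = NA_integer_,
    context = NA_character_, offset = NA_integer_,
    reason = NA_character_, stringsAsFactors = FALSE
  )
  if (n == 0L) {
    attr(out, "tally") <- c(mapped = 0L, multimapped = 0L, unmapped = 0L,
                            no_site = 0L, ambiguous = 0L, conflict_dcm = 0L)
    return(out)
  }
  anchor_col <- if (anchor == "methyl-c") catalog$anchor else catalog$pos

  hit_chrom <- rep(NA_character_, n)
  hit_start <- rep(NA_integer_, n)   # 0-based span start on plus strand
  hit_n <- integer(n)

  widths <- width(reads)
  rc <- reverseComplement(reads)
  for (cn in names(seqs)) {
    subject <- DNAString(seqs[[cn]])
    for (strand_reads in list(reads, rc)) {
      for (w in unique(widths)) {
        idx <- which(widths == w)
        pats <- strand_reads[idx]
        names(pats) <- NULL
        pd <- PDict(pats)
        m <- matchPDict(pd, subject)
        starts <- BiocGenerics::start(m)
        nh <- elementNROWS(starts)
        for (j in which(nh > 0L)) {
          i <- idx[j]
          hit_n[i] <- hit_n[i] + nh[j]
          hit_chrom[i] <- cn
          hit_start[i] <- starts[[j]][1] - 1L
        }
      }
    }
  }

  tally <- c(mapped = 0L, multimapped = 0L, unmapped = 0L,
             no_site = 0L, ambiguous = 0L, conflict_dcm = 0L)
  cat_by_chrom <- split(seq_len(nrow(catalog)), catalog$chrom)

  for (i in seq_len(n)) {
    if (hit_n[i] == 0L) {
      out$reason[i] <- "unmapped"; tally["unmapped"] <- tally["unmapped"] + 1L
      next
    }
    if (hit_n[i] > 1L) {
      out$reason[i] <- "multimapped"
      tally["multimapped"] <- tally["multimapped"] + 1L
      next
    }
    tally["mapped"] <- tally["mapped"] + 1L
    ci <- cat_by_chrom[[hit_chrom[i]]]
    if (is.null(ci)) ci <- integer(0)
    s <- hit_start[i]; w <- widths[i]
    cand <- ci[anchor_col[ci] >= s & anchor_col[ci] < s + w]
    q <- cand[.qualifying(anchor_col[cand], s, w, window)]
    if (length(q) == 0L) {
      out$reason[i] <- "no_site_in_window"
      tally["no_site"] <- tally["no_site"] + 1L
      next
    }
    is_dcm <- catalog$context[q] == "DCM"
    pick <- NA_integer_
    if (sum(is_dcm) == 1L) {
      pick <- q[is_dcm]
      if (any(!is_dcm)) tally["conflict_dcm"] <- tally["conflict_dcm"] + 1L
    } else if (sum(is_dcm) == 0L && length(q) == 1L) {
      pick <- q
    }
    if (is.na(pick)) {
      out$reason[i] <- "ambiguous"
      tally["ambiguous"] <- tally["ambiguous"] + 1L
      next
    }
    a <- anchor_col[pick]
    d5 <- a - s + 1L
    d3 <- s + w - a
    out$label[i] <- if (catalog$context[pick] == "DCM") "DCM" else "CPG"
    out$chrom[i] <- catalog$chrom[pick]
    out$pos[i] <- catalog$pos[pick]
    out$context[i] <- catalog$context[pick]
    out$offset[i] <- min(d5, d3)
    out$reason[i] <- NA_character_
  }
  attr(out, "tally") <- tally
  out
}

#' Classify a single read
#'
#' Single-read convenience wrapper around [classify_reads()].
#'
#' @inheritParams classify_reads
#' @param read A single read sequence (character or DNAString).
#' @return A one-row data frame as in [classify_reads()].
#' @export
classify_read <- function(read, genome, catalog = NULL,
                          window = c(13L, 17L),
                          anchor = c("methyl-c", "motif-start")) {
  classify_reads(as.character(read), genome, catalog, window, anchor)
}

#' Construct a per-site count matrix object
#'
#' @param sites Data frame with `chrom`, `pos`, `context` (and optionally
#'   `anchor`).
#' @param counts Integer matrix, `nrow(sites)` x `nrow(design)`.
#' @param totals Data frame with `sample_id`, `dcm_total`, `cpg_total`.
#' @param design Data frame with `sample_id`, `condition` (`dox`/`nodox`),
#'   `day`, `replicate`.
#' @param normalized `"raw"`, `"absolute"` or `"relative"`.
#' @return A `site_counts` object.
#' @export
site_counts <- function(sites, counts, totals, design, normalized = "raw") {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == nrow(sites),
            ncol(counts) == nrow(design),
            all(design$sample_id %in% totals$sample_id),
            all(counts >= 0))
  colnames(counts) <- design$sample_id
  structure(list(sites = sites, counts = counts,
                 totals = totals[match(design$sample_id, totals$sample_id), ,
                                 drop = FALSE],
                 design = design, normalized = normalized),
            class = "site_counts")
}

#' @export
print.site_counts <- function(x, ...) {
  cat("site_counts: ", nrow(x$sites), " sites x ", ncol(x$counts),
      " samples (", x$normalized, ")\n", sep = "")
  cat("contexts:", paste(names(table(x$sites$context)),
                         table(x$sites$context), sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

#' Count classified reads per reference site
#'
#' Runs [classify_reads()] on each sample's reads and tabulates passing
#' reads over the reference site catalog, yielding one count matrix row per
#' catalog site (all contexts together; subset with [dcm_counts()]).
#' Per-sample totals record the number of DCM- and CpG-classified reads;
#' rejected reads are tallied in the `rejects` attribute.
#'
#' @param reads A named list (names = sample ids) whose elements are FASTQ
#'   file paths, character vectors of read sequences, or
#'   [Biostrings::DNAStringSet]s.
#' @param genome Reference genome.
#' @param design Sample design data frame (`sample_id`, `condition`, `day`,
#'   `replicate`); every sample in `reads` must appear.
#' @inheritParams classify_reads
#' @return A [site_counts()] object with `normalized = "raw"`.
#' @export
count_sites <- function(reads, genome, design, catalog = NULL,
                        window = c(13L, 17L),
                        anchor = c("methyl-c", "motif-start")) {
  anchor <- match.arg(anchor)
  if (is.null(catalog)) catalog <- site_catalog(genome)
  stopifnot(all(names(reads) %in% design$sample_id))
  key <- paste(catalog$chrom, catalog$pos)
  counts <- matrix(0L, nrow = nrow(catalog), ncol = nrow(design))
  totals <- data.frame(sample_id = design$sample_id,
                       dcm_total = 0L, cpg_total = 0L,
                       stringsAsFactors = FALSE)
  rejects <- list()
  for (sid in design$sample_id) {
    rs <- reads[[sid]]
    j <- match(sid, design$sample_id)
    if (is.null(rs)) next
    if (is.character(rs) && length(rs) == 1L && file.exists(rs)) {
      rs <- readDNAStringSet(rs, format = "fastq")
    }
    if (length(rs) == 0L) {
      warning("sample ", sid, " has zero reads; column retained as zeros")
      next
    }
    cl <- classify_reads(rs, genome, catalog, window, anchor)
    rejects[[sid]] <- attr(cl, "tally")
    pass <- cl$label != "REJECT"
    if (!any(pass)) {
      warning("sample ", sid, " has zero passing reads; column retained as zeros")
      next
    }
    tab <- table(factor(paste(cl$chrom[pass], cl$pos[pass]), levels = key))
    counts[, j] <- counts[, j] + as.integer(tab)
    totals$dcm_total[j] <- sum(cl$label == "DCM")
    totals$cpg_total[j] <- sum(cl$label == "CPG")
  }
  out <- site_counts(catalog, counts, totals, design, "raw")
  attr(out, "rejects") <- rejects
  out
}

#' Subset a site_counts object to DCM-context sites
#'
#' @param x A `site_counts` object.
#' @return A `site_counts` object containing only CCWGG rows.
#' @export
dcm_counts <- function(x) {
  stopifnot(inherits(x, "site_counts"))
  keep <- x$sites$context == "DCM"
  site_counts(x$sites[keep, , drop = FALSE],
              x$counts[keep, , drop = FALSE],
              x$totals, x$design, x$normalized)
}
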