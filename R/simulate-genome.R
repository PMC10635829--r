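#' Simulation configuration for the synthetic MeD-seq study
#'
#' Bundles and validates every parameter of the synthetic-data generator.
#' The defaults describe the study conditions the package is tested
#' against: an inducible DCM--RNA-polymerase fusion labeling transcribed
#' gene bodies and active enhancers over an 8-day differentiation course
#' sampled in triplicate, with per-division label retention of 56% and a
#' mean per-site labeling efficiency of 8.7% in active genes.
#'
#' @param n_chroms Number of toy chromosomes.
#' @param chrom_len Chromosome length in bp.
#' @param n_genes Total genes across all chromosomes.
#' @param gene_length Gene body length in bp.
#' @param intergenic_gap Gap between consecutive gene slots in bp.
#' @param silent_frac Fraction of genes that are never transcribed.
#' @param rise_rate Per-day geometric factor governing how an element's
#'   measured label rises before its peak day: sampled cells acquired a
#'   late program's label only once lineage turnover brought dox-exposed
#'   precursor stages into their history, so days before the peak see
#'   `rise_rate^(peak - day)` of the full signal.
#' @param decay_rate Per-day geometric factor after the peak.  Under
#'   continuous induction, elements that are still partially transcribed
#'   keep re-acquiring label, so the population-level fall (default 0.85)
#'   is slower than the pure per-division molecular retention rate (0.56)
#'   that governs pulse-chase dilution once transcription has ceased.
#' @param labeling_efficiency Named numeric: per-site probability that a
#'   transcribed site is fully methylated at the peak of the gene's
#'   activity, per expression tier (`top25`, `mid50`, `bottom25`).  A
#'   scalar is recycled to all tiers.  The tier-weighted mean of the
#'   default is 0.087.
#' @param propagation_rate Per-division probability that a fully methylated
#'   duplex site remains fully methylated (default 0.56).
#' @param background_rate Per-site methylated fraction in uninduced
#'   (`-dox`) samples.
#' @param read_depth Expected MeD-seq reads per fully methylated DCM site
#'   per sample.
#' @param cpg_depth Expected reads per fully methylated CpG-context site
#'   per sample (kept low; CpG reads are used as a depth normaliser).
#' @param cpg_meth Constant endogenous CpG methylated fraction.
#' @param divisions_per_day Cell divisions per day in the renewing tissue.
#' @param dcm_per_gene Number of CCWGG motifs planted in each gene body.
#' @param sites_per_enhancer Number of CCWGG motifs planted per enhancer.
#' @param enhancer_spacing Spacing in bp between planted enhancer motifs.
#' @param enhancer_frac Fraction of expressed genes that receive a planted
#'   intergenic enhancer sharing the gene's peak day.
#' @param n_repeats Number of planted repeat intervals (for the intergenic
#'   site filter).
#' @param days Sampling days; day 0 is the uninduced control.
#' @param n_replicates Replicates per day.
#' @param read_len Read length in bp.
#' @param seed Master seed; all randomness flows from it via named
#'   substreams.
#' @return A validated `sim_config` list.
#' @export
simulate_config <- function(n_chroms = 2L,
                            chrom_len = 2200000L,
                            n_genes = 60L,
                            gene_length = 4000L,
                            intergenic_gap = 16000L,
                            silent_frac = 0.2,
                            labeling_efficiency = c(top25 = 0.13,
                                                    mid50 = 0.087,
                                                    bottom25 = 0.044),
                            propagation_rate = 0.56,
                            rise_rate = 0.7,
                            decay_rate = 0.85,
                            background_rate = 0.001,
                            read_depth = 150,
                            cpg_depth = 3,
                            cpg_meth = 0.75,
                            divisions_per_day = 1,
                            dcm_per_gene = 12L,
                            sites_per_enhancer = 8L,
                            enhancer_spacing = 60L,
                            enhancer_frac = 1,
                            n_repeats = 20L,
                            days = c(0L, 1L, 2L, 3L, 4L, 6L, 8L),
                            n_replicates = 3L,
                            read_len = 32L,
                            seed = 1L) {
  if (length(labeling_efficiency) == 1L && is.null(names(labeling_efficiency))) {
    labeling_efficiency <- c(top25 = labeling_efficiency,
                             mid50 = labeling_efficiency,
                             bottom25 = labeling_efficiency)
  }
  stopifnot(
    chrom_len >= 10000, n_genes >= 1,
    all(labeling_efficiency >= 0 & labeling_efficiency <= 1),
    propagation_rate >= 0, propagation_rate <= 1,
    rise_rate > 0, rise_rate <= 1, decay_rate > 0, decay_rate <= 1,
    background_rate >= 0, background_rate <= 1,
    cpg_meth >= 0, cpg_meth <= 1,
    silent_frac >= 0, silent_frac < 1,
    read_depth > 0, read_len >= 20,
    all(days %in% c(0L, 1L, 2L, 3L, 4L, 6L, 8L)),
    n_replicates >= 1
  )
  cfg <- list(n_chroms = as.integer(n_chroms),
              chrom_len = as.integer(chrom_len),
              n_genes = as.integer(n_genes),
              gene_length = as.integer(gene_length),
              intergenic_gap = as.integer(intergenic_gap),
              silent_frac = silent_frac,
              labeling_efficiency = labeling_efficiency,
              propagation_rate = propagation_rate,
              rise_rate = rise_rate,
              decay_rate = decay_rate,
              background_rate = background_rate,
              read_depth = read_depth,
              cpg_depth = cpg_depth,
              cpg_meth = cpg_meth,
              divisions_per_day = divisions_per_day,
              dcm_per_gene = as.integer(dcm_per_gene),
              sites_per_enhancer = as.integer(sites_per_enhancer),
              enhancer_spacing = as.integer(enhancer_spacing),
              enhancer_frac = enhancer_frac,
              n_repeats = as.integer(n_repeats),
              days = as.integer(sort(unique(days))),
              n_replicates = as.integer(n_replicates),
              read_len = as.integer(read_len),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

PEAK_DAYS <- c(1L, 2L, 3L, 4L, 6L, 8L)

#' Generate a toy genome with planted genes, enhancers and repeats
#'
#' Draws uniform-composition chromosome sequences, lays out non-overlapping
#' gene bodies on a regular grid (>= 1 kb apart by construction), plants
#' CCWGG motifs inside gene bodies and inside intergenic enhancer intervals
#' (each enhancer is paired with an expressed gene and shares its peak
#' day), and records repeat intervals for the intergenic site filter.
#' Ground truth (gene tiers, peak days, enhancer intervals) is returned
#' alongside the sequences for recovery tests.
#'
#' @param config A [simulate_config()] object.
#' @return A `toy_genome` list with elements `chroms` (named character
#'   vector of sequences), `genes`, `enhancers`, `repeats`, `peaks`
#'   (enhancer-derived peak track), `dcm_sites`, `cpg_sites` (site
#'   catalogs) and `config`.  All coordinates are 0-based half-open.
#' @export
generate_toy_genome <- function(config = simulate_config()) {
  stopifnot(inherits(config, "sim_config"))
  slot <- config$gene_length + config$intergenic_gap
  margin <- 3000L
  per_chrom <- ceiling(config$n_genes / config$n_chroms)
  need <- margin + per_chrom * slot
  if (need > config$chrom_len) {
    stop("capacity error: ", config$n_genes, " non-overlapping genes of ",
         config$gene_length, " bp with ", config$intergenic_gap,
         " bp gaps do not fit ", config$n_chroms, " x ", config$chrom_len,
         " bp (need >= ", need, " bp per chromosome)")
  }

  with_seed(substream_seed(config$seed, "genome"), {
    chroms <- vapply(seq_len(config$n_chroms), function(i) {
      paste(sample(c("A", "C", "G", "T"), config$chrom_len, replace = TRUE),
            collapse = "")
    }, character(1))
    names(chroms) <- sprintf("chr%d", seq_len(config$n_chroms))

    # gene layout: round-robin over chromosomes, regular slots
    gid <- sprintf("g%03d", seq_len(config$n_genes))
    gchrom <- names(chroms)[((seq_len(config$n_genes) - 1L) %% config$n_chroms) + 1L]
    gslot <- (seq_len(config$n_genes) - 1L) %/% config$n_chroms
    gstart <- margin + gslot * slot
    gend <- gstart + config$gene_length
    gstrand <- sample(c("+", "-"), config$n_genes, replace = TRUE)

    n_silent <- round(config$silent_frac * config$n_genes)
    status <- sample(rep(c("silent", "expressed"),
                         c(n_silent, config$n_genes - n_silent)))
    n_expr <- sum(status == "expressed")
    # expression tiers among expressed genes: top 25% / middle 50% / bottom 25%
    tier_pool <- rep(c("top25", "mid50", "bottom25"),
                     diff(round(n_expr * c(0, 0.25, 0.75, 1))))
    tier <- rep("silent", config$n_genes)
    tier[status == "expressed"] <- sample(tier_pool)
    peak <- rep(NA_integer_, config$n_genes)
    peak[status == "expressed"] <- sample(PEAK_DAYS, n_expr, replace = TRUE)

    genes <- data.frame(gene_id = gid, chrom = gchrom, start = gstart,
                        end = gend, strand = gstrand, tier = tier,
                        true_peak_day = peak, stringsAsFactors = FALSE)

    # plant CCWGG motifs in gene bodies (evenly spaced with jitter)
    chrom_chars <- lapply(chroms, function(s) strsplit(s, "")[[1]])
    plant <- function(cn, positions) {
      for (p in positions) {
        w <- sample(c("A", "T"), 1L)
        chrom_chars[[cn]][(p + 1L):(p + 5L)] <<- c("C", "C", w, "G", "G")
      }
    }
    gene_site_pos <- vector("list", config$n_genes)
    for (i in seq_len(config$n_genes)) {
      step <- config$gene_length / config$dcm_per_gene
      base <- gstart[i] + round((seq_len(config$dcm_per_gene) - 0.5) * step)
      jit <- sample(-floor(step / 4):floor(step / 4), config$dcm_per_gene,
                    replace = TRUE)
      pos <- pmin(pmax(base + jit, gstart[i]), gend[i] - 6L)
      pos <- sort(unique(pos))
      gene_site_pos[[i]] <- pos
      plant(gchrom[i], pos)
    }

    # enhancers: one per selected expressed gene, in the gap downstream of
    # the gene slot, > 1 kb from both flanking genes, sharing its peak day
    expr_idx <- which(status == "expressed")
    n_enh <- round(config$enhancer_frac * length(expr_idx))
    enh_idx <- sort(sample(expr_idx, n_enh))
    enh <- NULL
    for (k in seq_along(enh_idx)) {
      i <- enh_idx[k]
      first <- gend[i] + 1300L
      pos <- first + (seq_len(config$sites_per_enhancer) - 1L) *
        config$enhancer_spacing
      if (max(pos) + 6L > config$chrom_len) next
      plant(gchrom[i], pos)
      enh <- rbind(enh, data.frame(
        enhancer_id = sprintf("e%03d", k), chrom = gchrom[i],
        start = min(pos), end = max(pos) + 5L,
        target_gene = gid[i], true_peak_day = peak[i],
        stringsAsFactors = FALSE))
    }

    # repeats: intervals in gaps, clear of genes (>= 1 kb) and enhancers
    rep_df <- NULL
    if (config$n_repeats > 0L) {
      cand <- which(!(seq_len(config$n_genes) %in% enh_idx))
      cand <- cand[gend[cand] + 4500L <= config$chrom_len]
      take <- cand[seq_len(min(length(cand), config$n_repeats))]
      if (length(take)) {
        rep_df <- data.frame(chrom = gchrom[take],
                             start = gend[take] + 4000L,
                             end = gend[take] + 4500L,
                             stringsAsFactors = FALSE)
      }
    }
    if (is.null(rep_df)) {
      rep_df <- data.frame(chrom = character(0), start = integer(0),
                           end = integer(0), stringsAsFactors = FALSE)
    }

    chroms <- vapply(chrom_chars, paste, character(1), collapse = "")

    genome <- structure(list(chroms = chroms, genes = genes,
                             enhancers = if (is.null(enh)) {
                               data.frame(enhancer_id = character(0),
                                          chrom = character(0),
                                          start = integer(0), end = integer(0),
                                          target_gene = character(0),
                                          true_peak_day = integer(0))
                             } else enh,
                             repeats = rep_df,
                             config = config),
                       class = "toy_genome")
    cat <- site_catalog(genome)
    genome$dcm_sites <- cat[cat$context == "DCM", c("chrom", "pos", "anchor")]
    rownames(genome$dcm_sites) <- NULL
    genome$cpg_sites <- cat[cat$context != "DCM",
                            c("chrom", "pos", "context", "anchor")]
    rownames(genome$cpg_sites) <- NULL
    genome$catalog <- cat
    # peak track mirrors the enhancer truth, padded like called peaks
    genome$peaks <- if (nrow(genome$enhancers)) {
      data.frame(chrom = genome$enhancers$chrom,
                 start = pmax(genome$enhancers$start - 100L, 0L),
                 end = genome$enhancers$end + 100L,
                 name = genome$enhancers$enhancer_id,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 name = character(0), stringsAsFactors = FALSE)
    }
    genome
  })
}

#' @export
print.toy_genome <- function(x, ...) {
  cat("toy_genome:", length(x$chroms), "chromosome(s) of",
      x$config$chrom_len, "bp;", nrow(x$genes), "genes;",
      nrow(x$enhancers), "planted enhancers;",
      nrow(x$dcm_sites), "DCM sites;", nrow(x$cpg_sites), "CpG sites\n")
  invisible(x)
}

#' Build the sample design table for a simulated time course
#'
#' @param config A [simulate_config()].
#' @return Data frame with `sample_id`, `condition` (`dox` for days > 0,
#'   `nodox` for day 0), `day`, `replicate`.
#' @export
sim_design <- function(config) {
  grid <- expand.grid(replicate = seq_len(config$n_replicates),
                      day = config$days)
  data.frame(sample_id = sprintf("d%d_r%d", grid$day, grid$replicate),
             condition = ifelse(grid$day == 0L, "nodox", "dox"),
             day = as.integer(grid$day),
             replicate = as.integer(grid$replicate),
             stringsAsFactors = FALSE)
}
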