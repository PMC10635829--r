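#' Temporal activity fraction of a labeled element
#'
#' The measured methylated fraction of a site in an element peaking at day
#' `peak`, sampled at day `t`, rises geometrically before the peak (lineage
#' turnover gradually brings dox-exposed precursor stages into the sampled
#' cells' history) and falls geometrically after it (division dilution,
#' slowed by residual transcription under continuous induction).
#'
#' @param peak Peak day of the element.
#' @param t Sampling day.
#' @param rise,decay Per-day geometric factors for the two flanks.
#' @return Multiplier in `(0, 1]` applied to the labeling efficiency.
#' @keywords internal
.activity_fraction <- function(peak, t, rise, decay) {
  ifelse(t <= peak, rise^(peak - t), decay^(t - peak))
}

.empty_methylome <- function(genome, sample_id = "m") {
  cat <- genome$catalog
  m <- data.frame(chrom = cat$chrom, pos = cat$pos, context = cat$context,
                  anchor = cat$anchor, fraction = 0,
                  stringsAsFactors = FALSE)
  attr(m, "sample_id") <- sample_id
  class(m) <- c("methylome", "data.frame")
  m
}

# fraction of every catalog site at sampling day t (population expectation)
.day_fractions <- function(genome, t) {
  cfg <- genome$config
  cat <- genome$catalog
  frac <- ifelse(cat$context == "DCM", cfg$background_rate, cfg$cpg_meth)
  if (t > 0) {
    dcm <- which(cat$context == "DCM")
    key <- paste(cat$chrom[dcm], cat$pos[dcm])
    bump <- function(df, eff_of_row) {
      for (i in seq_len(nrow(df))) {
        if (is.na(df$true_peak_day[i])) next
        hit <- dcm[cat$chrom[dcm] == df$chrom[i] &
                     cat$pos[dcm] >= df$start[i] & cat$pos[dcm] < df$end[i]]
        if (!length(hit)) next
        a <- .activity_fraction(df$true_peak_day[i], t,
                                cfg$rise_rate, cfg$decay_rate)
        frac[hit] <<- pmin(1, frac[hit] + eff_of_row(df[i, ]) * a)
      }
    }
    bump(genome$genes,
         function(g) {
           e <- cfg$labeling_efficiency[g$tier]
           if (is.na(e)) 0 else unname(e)
         })
    if (nrow(genome$enhancers)) {
      eff_mean <- sum(cfg$labeling_efficiency * c(top25 = 0.25, mid50 = 0.5,
                                                  bottom25 = 0.25)[
                        names(cfg$labeling_efficiency)])
      bump(genome$enhancers, function(e) eff_mean)
    }
  }
  frac
}

#' Simulate the methylome time course of a continuous induction experiment
#'
#' For each requested day, computes the population methylated fraction of
#' every catalog site.  Day 0 is the uninduced control at the background
#' rate.  On induced days, DCM sites inside expressed gene bodies and
#' planted enhancer intervals carry the element's labeling efficiency
#' scaled by [.activity_fraction()]; all other DCM sites stay at
#' background.  CpG-context sites sit at the constant endogenous level.
#' Fractions are population expectations; replicate-to-replicate noise
#' enters downstream through Poisson read sampling only.
#'
#' @param genome A `toy_genome`.
#' @param config Its [simulate_config()]; defaults to `genome$config`.
#' @param days Days to simulate (subset of the config's days).
#' @return Named list `day_<d>` of `methylome` data frames (`chrom`, `pos`,
#'   `context`, `anchor`, `fraction`).
#' @export
simulate_timecourse <- function(genome, config = genome$config,
                                days = config$days) {
  stopifnot(inherits(genome, "toy_genome"))
  if (!all(days %in% c(0L, 1L, 2L, 3L, 4L, 6L, 8L))) {
    stop("unknown day(s): ", paste(setdiff(days, c(0:4, 6, 8)), collapse = ", "))
  }
  out <- lapply(days, function(t) {
    m <- .empty_methylome(genome, sprintf("day_%d", t))
    m$fraction <- .day_fractions(genome, t)
    m
  })
  names(out) <- sprintf("day_%d", days)
  out
}

#' Propagate a methylome through cell divisions
#'
#' Each fully methylated duplex site is retained with probability
#' `p^divisions` and otherwise lost (only fully methylated sites are
#' detectable, so a site that fails to re-methylate after replication drops
#' out).  Propagation never creates methylation.
#'
#' @param m A `methylome` data frame (column `fraction`).
#' @param p Per-division retention probability in `[0, 1]`.
#' @param divisions Non-negative integer number of divisions.
#' @param seed Seed for the retention draws (molecule model).
#' @param model `"molecule"` (default) treats each site as a single duplex
#'   molecule: fractions must be 0/1 and retention is Bernoulli.
#'   `"population"` multiplies population fractions by `p^divisions`
#'   deterministically.
#' @return A methylome of the same shape.
#' @export
propagate_methylome <- function(m, p, divisions, seed = 1L,
                                model = c("molecule", "population")) {
  model <- match.arg(model)
  if (!is.numeric(p) || p < 0 || p > 1) stop("`p` must lie in [0, 1]")
  stopifnot(divisions >= 0)
  keep_prob <- p^divisions
  out <- m
  if (model == "population") {
    out$fraction <- m$fraction * keep_prob
    return(out)
  }
  if (!all(m$fraction %in% c(0, 1))) {
    stop("molecule model requires 0/1 fractions; use model = \"population\"")
  }
  if (divisions == 0 || p == 1) return(out)
  with_seed(seed, {
    meth <- which(m$fraction == 1)
    out$fraction[meth] <- as.numeric(stats::rbinom(length(meth), 1L, keep_prob))
  })
  out
}

#' Simulate an H2B-GFP / DCM pulse-chase experiment
#'
#' Labels `n_sites` duplex DCM sites at the pulse with per-site probability
#' `efficiency` (the GFP-high cohort), then lets the GFP-low cohort divide
#' `division_gap` more times: its GFP intensity halves per division and its
#' methylome is propagated with retention `p` per division.  MeD-seq read
#' counts for both cohorts are Poisson-sampled and expressed as DCM/CpG
#' read-count ratios, the form consumed by the kinetics estimators.
#'
#' @param n_sites Number of DCM sites assayed.
#' @param efficiency Per-site labeling probability at the pulse.
#' @param p Per-division retention probability.
#' @param division_gap Divisions separating the cohorts (>= 0; 0 is a
#'   degenerate case allowed for testing).
#' @param depth Expected reads per fully methylated site.
#' @param n_cpg_sites CpG-context sites backing the depth normaliser.
#' @param cpg_meth Endogenous CpG methylated fraction.
#' @param gfp_high GFP intensity of the high cohort (arbitrary units).
#' @param seed Master seed.
#' @return A list of class `pulse_chase` with `obs` (gfp_high, gfp_low,
#'   dcm_high, dcm_low), the two binary methylomes (`high`, `low`), the raw
#'   read counts, and the true parameters.
#' @export
simulate_pulse_chase <- function(n_sites = 1e5, efficiency = 0.087,
                                 p = 0.56, division_gap = 3L,
                                 depth = 10, n_cpg_sites = 3 * n_sites,
                                 cpg_meth = 0.75, gfp_high = 1000,
                                 seed = 1L) {
  stopifnot(division_gap >= 0, p >= 0, p <= 1,
            efficiency >= 0, efficiency <= 1)
  with_seed(substream_seed(seed, "pulse_chase"), {
    high <- as.numeric(stats::rbinom(n_sites, 1L, efficiency))
    keep <- stats::rbinom(n_sites, 1L, p^division_gap)
    low <- high * keep
    dcm_reads_high <- stats::rpois(n_sites, depth * high)
    dcm_reads_low <- stats::rpois(n_sites, depth * low)
    cpg_high <- stats::rpois(1L, n_cpg_sites * cpg_meth * depth)
    cpg_low <- stats::rpois(1L, n_cpg_sites * cpg_meth * depth)
    obs <- list(gfp_high = gfp_high,
                gfp_low = gfp_high * 0.5^division_gap,
                dcm_high = sum(dcm_reads_high) / cpg_high,
                dcm_low = sum(dcm_reads_low) / cpg_low)
    structure(list(obs = obs, high = high, low = low,
                   dcm_reads_high = dcm_reads_high,
                   dcm_reads_low = dcm_reads_low,
                   cpg_high = cpg_high, cpg_low = cpg_low,
                   truth = list(p = p, division_gap = division_gap,
                                efficiency = efficiency)),
              class = "pulse_chase")
  })
}

#' Simulate per-site MeD-seq count matrices for a time course
#'
#' The count-matrix route of the generator: per-site read counts are drawn
#' as `Poisson(depth x methylated fraction)` independently per replicate,
#' which is equal in distribution to generating reads with
#' [generate_reads()] and counting them with [count_sites()] (the package
#' tests this equivalence).  Totals per sample cover the whole catalog.
#'
#' @param genome A `toy_genome`.
#' @param config Its configuration.
#' @param days Days to simulate.
#' @return A [site_counts()] object (`normalized = "raw"`) over the full
#'   site catalog, with the design table from [sim_design()].
#' @export
simulate_site_counts <- function(genome, config = genome$config,
                                 days = config$days) {
  tc <- simulate_timecourse(genome, config, days)
  design <- sim_design(config)
  design <- design[design$day %in% days, , drop = FALSE]
  cat <- genome$catalog
  is_dcm <- cat$context == "DCM"
  depth <- ifelse(is_dcm, config$read_depth, config$cpg_depth)
  counts <- matrix(0L, nrow = nrow(cat), ncol = nrow(design))
  with_seed(substream_seed(config$seed, "site_counts"), {
    for (j in seq_len(nrow(design))) {
      frac <- tc[[sprintf("day_%d", design$day[j])]]$fraction
      counts[, j] <- stats::rpois(nrow(cat), depth * frac)
    }
  })
  totals <- data.frame(sample_id = design$sample_id,
                       dcm_total = colSums(counts[is_dcm, , drop = FALSE]),
                       cpg_total = colSums(counts[!is_dcm, , drop = FALSE]),
                       stringsAsFactors = FALSE)
  site_counts(cat, counts, totals, design, "raw")
}

#' Generate MeD-seq-style reads from a methylome
#'
#' Emits 32-bp plus-strand fragments around methylated sites.  The number
#' of reads per site is `Poisson(depth x fraction)`; for each read the
#' anchor base (the methylated cytosine) is placed 13--17 bp (1-based,
#' inclusive) from one read end, with the end and the offset drawn
#' uniformly among placements in which the emitting site is the unique
#' classifiable site of the read (so that simulator truth and
#' [classify_reads()] assignments agree; placements in which a second site
#' of the same class would qualify are re-drawn, and the read is dropped
#' with a QC tally if no placement works).  Sites too close to a
#' chromosome edge for a full fragment are skipped with a warning.
#'
#' @param genome A `toy_genome` (or anything [site_catalog()] accepts).
#' @param m A `methylome` data frame.
#' @param depth Expected reads per fully methylated site.
#' @param seed Seed for Poisson draws and placements.
#' @param sample_id Sample name used in read ids.
#' @param window Offset window, as in [classify_reads()].
#' @return A list with `reads` (named [Biostrings::DNAStringSet]) and
#'   `truth` (data frame `read`, `chrom`, `pos`, `context` recording the
#'   emitting site of every read) plus a `skipped` tally attribute.
#' @export
generate_reads <- function(genome, m, depth, seed = 1L, sample_id = "s1",
                           window = c(13L, 17L)) {
  stopifnot(depth > 0)
  seqs <- genome_sequences(genome)
  cat <- if (inherits(genome, "toy_genome")) genome$catalog else site_catalog(genome)
  rl <- if (inherits(genome, "toy_genome")) genome$config$read_len else 32L
  key_cat <- paste(cat$chrom, cat$pos)
  key_m <- paste(m$chrom, m$pos)
  frac <- m$fraction[match(key_cat, key_m)]
  frac[is.na(frac)] <- 0

  anchors_by_chrom <- split(cat$anchor, cat$chrom)
  ctx_by_chrom <- split(cat$context, cat$chrom)

  with_seed(seed, {
    n_per_site <- stats::rpois(nrow(cat), depth * frac)
    reads <- character(sum(n_per_site))
    truth <- data.frame(read = character(sum(n_per_site)),
                        chrom = character(sum(n_per_site)),
                        pos = integer(sum(n_per_site)),
                        context = character(sum(n_per_site)),
                        stringsAsFactors = FALSE)
    skipped_edge <- 0L; skipped_ambiguous <- 0L
    k <- 0L
    combos <- expand.grid(offset = window[1]:window[2], end = c(5L, 3L))
    for (i in which(n_per_site > 0L)) {
      cn <- cat$chrom[i]; a <- cat$anchor[i]
      chrom_len <- nchar(seqs[[cn]])
      anchors <- anchors_by_chrom[[cn]]
      ctx <- ctx_by_chrom[[cn]]
      emitted <- 0L
      for (r in seq_len(n_per_site[i])) {
        ord <- sample.int(nrow(combos))
        placed <- FALSE
        for (ci in ord) {
          off <- combos$offset[ci]
          s <- if (combos$end[ci] == 5L) a - (off - 1L) else a - (rl - off)
          if (s < 0L || s + rl > chrom_len) next
          q <- anchors[.qualifying(anchors, s, rl, window) &
                         anchors >= s & anchors < s + rl]
          qc <- ctx[match(q, anchors)]
          ok <- if (cat$context[i] == "DCM") {
            sum(qc == "DCM") == 1L && a %in% q
          } else {
            length(q) == 1L && q == a
          }
          if (!ok) next
          k <- k + 1L
          reads[k] <- substr(seqs[[cn]], s + 1L, s + rl)
          truth$read[k] <- sprintf("%s:%s:%d:%d", sample_id, cn, cat$pos[i], k)
          truth$chrom[k] <- cn
          truth$pos[k] <- cat$pos[i]
          truth$context[k] <- cat$context[i]
          emitted <- emitted + 1L
          placed <- TRUE
          break
        }
        if (!placed) {
          # distinguish pure edge failures from ambiguity failures
          any_fit <- any(vapply(seq_len(nrow(combos)), function(ci) {
            off <- combos$offset[ci]
            s <- if (combos$end[ci] == 5L) a - (off - 1L) else a - (rl - off)
            s >= 0L && s + rl <= chrom_len
          }, logical(1)))
          if (any_fit) skipped_ambiguous <- skipped_ambiguous + 1L
          else skipped_edge <- skipped_edge + 1L
        }
      }
      if (emitted == 0L && n_per_site[i] > 0L && skipped_edge > 0L) {
        warning("site ", cn, ":", cat$pos[i],
                " too close to a chromosome edge; reads skipped",
                call. = FALSE)
      }
    }
    reads <- reads[seq_len(k)]
    truth <- truth[seq_len(k), , drop = FALSE]
    rs <- DNAStringSet(reads)
    names(rs) <- truth$read
    out <- list(reads = rs, truth = truth)
    attr(out, "skipped") <- c(edge = skipped_edge,
                              ambiguous = skipped_ambiguous)
    out
  })
}
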