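#' Tally co-methylation of the first and last site within reads
#'
#' For each gene, restricts to sites whose marginal methylation across the
#' gene's reads is above zero, takes the first and last such site in
#' genomic coordinate order, keeps reads covering both, and tallies the
#' 2x2 methylation pattern (both / first only / last only / neither).
#' Per-gene tables are summed into an overall table; reads covering fewer
#' than two qualifying sites are skipped with a tally.
#'
#' @param calls Data frame of per-read methylation calls: `read_id`,
#'   `gene_id`, `site_pos`, `status` (0/1).
#' @return A list of class `linkage_table`: `n_both`, `n_first_only`,
#'   `n_last_only`, `n_none`, `n` (total reads tallied), `m1`, `m2`
#'   (marginals of the summed table), `per_gene` (data frame), and
#'   `n_skipped`.
#' @export
comethylation_counts <- function(calls) {
  stopifnot(all(c("read_id", "gene_id", "site_pos", "status") %in%
                  names(calls)),
            all(calls$status %in% c(0L, 1L)))
  skipped <- 0L
  per_gene <- list()
  for (g in unique(calls$gene_id)) {
    cg <- calls[calls$gene_id == g, , drop = FALSE]
    marg <- tapply(cg$status, cg$site_pos, mean)
    ok_sites <- as.numeric(names(marg)[marg > 0])
    if (length(ok_sites) < 2L) {
      skipped <- skipped + length(unique(cg$read_id))
      next
    }
    first <- min(ok_sites); last <- max(ok_sites)
    f <- cg[cg$site_pos == first, c("read_id", "status")]
    l <- cg[cg$site_pos == last, c("read_id", "status")]
    both_reads <- intersect(f$read_id, l$read_id)
    skipped <- skipped + length(setdiff(unique(cg$read_id), both_reads))
    if (!length(both_reads)) next
    fs <- f$status[match(both_reads, f$read_id)]
    ls <- l$status[match(both_reads, l$read_id)]
    per_gene[[g]] <- data.frame(
      gene_id = g, first_site = first, last_site = last,
      n_both = sum(fs == 1 & ls == 1),
      n_first_only = sum(fs == 1 & ls == 0),
      n_last_only = sum(fs == 0 & ls == 1),
      n_none = sum(fs == 0 & ls == 0),
      stringsAsFactors = FALSE)
  }
  pg <- if (length(per_gene)) do.call(rbind, per_gene) else
    data.frame(gene_id = character(0), first_site = numeric(0),
               last_site = numeric(0), n_both = integer(0),
               n_first_only = integer(0), n_last_only = integer(0),
               n_none = integer(0))
  rownames(pg) <- NULL
  tot <- colSums(pg[c("n_both", "n_first_only", "n_last_only", "n_none")])
  n <- sum(tot)
  structure(list(n_both = unname(tot["n_both"]),
                 n_first_only = unname(tot["n_first_only"]),
                 n_last_only = unname(tot["n_last_only"]),
                 n_none = unname(tot["n_none"]),
                 n = n,
                 m1 = if (n > 0) unname(tot["n_both"] + tot["n_first_only"]) / n else NA_real_,
                 m2 = if (n > 0) unname(tot["n_both"] + tot["n_last_only"]) / n else NA_real_,
                 per_gene = pg, n_skipped = skipped),
            class = "linkage_table")
}

.linkage_table <- function(fs, ls) {
  structure(list(n_both = sum(fs & ls), n_first_only = sum(fs & !ls),
                 n_last_only = sum(!fs & ls), n_none = sum(!fs & !ls),
                 n = length(fs), m1 = mean(fs), m2 = mean(ls),
                 per_gene = NULL, n_skipped = 0L),
            class = "linkage_table")
}

#' @export
print.linkage_table <- function(x, ...) {
  cat(sprintf("linkage_table (N=%d): both=%d first=%d last=%d none=%d (m1=%.3f, m2=%.3f)\n",
              x$n, x$n_both, x$n_first_only, x$n_last_only, x$n_none,
              x$m1, x$m2))
  invisible(x)
}

#' Simulate a fully unlinked co-methylation control
#'
#' Each read's two site statuses are drawn independently as Bernoulli with
#' the observed marginal methylation fractions, destroying any within-read
#' linkage while preserving the marginals in expectation.
#'
#' @param m1,m2 Marginal methylation fractions of the first and last site.
#' @param N Number of reads.
#' @param seed Seed.
#' @return A `linkage_table`.
#' @export
simulate_unlinked <- function(m1, m2, N, seed = 1L) {
  stopifnot(m1 >= 0, m1 <= 1, m2 >= 0, m2 <= 1)
  with_seed(substream_seed(seed, "unlinked"), {
    fs <- stats::rbinom(N, 1L, m1) == 1L
    ls <- stats::rbinom(N, 1L, m2) == 1L
    .linkage_table(fs, ls)
  })
}

#' Simulate a fully linked co-methylation control
#'
#' Per read, both sites are methylated with probability `min(m1, m2)` (the
#' lower marginal caps joint methylation), exactly the higher-marginal site
#' alone with probability `|m1 - m2|`, and neither with probability
#' `1 - max(m1, m2)`.  When the marginals are equal the single-site
#' probability is zero, the only internally consistent reading of complete
#' linkage.
#'
#' @inheritParams simulate_unlinked
#' @return A `linkage_table`.
#' @export
simulate_linked <- function(m1, m2, N, seed = 1L) {
  stopifnot(m1 >= 0, m1 <= 1, m2 >= 0, m2 <= 1)
  with_seed(substream_seed(seed, "linked"), {
    u <- stats::runif(N)
    both <- u < min(m1, m2)
    single <- !both & u < max(m1, m2)
    fs <- both | (single & m1 > m2)
    ls <- both | (single & m2 > m1)
    .linkage_table(fs, ls)
  })
}

#' Position the observed co-methylation between the two controls
#'
#' Scales the observed both-methylated count linearly between the unlinked
#' and the fully linked control: 0 at the unlinked expectation, 1 at the
#' linked expectation, clipped to `[0, 1]`.  A bootstrap confidence
#' interval resamples reads from the observed table.  When the two
#' controls coincide (a marginal of 0 or 1, or `m1 * m2 = min(m1, m2)`) the
#' score is undefined and flagged.
#'
#' @param observed,unlinked,linked `linkage_table` objects sharing `N` and
#'   marginals (within tolerance).
#' @param n_boot Bootstrap replicates.
#' @param seed Seed.
#' @param tol Tolerance for the shared-marginal check.
#' @return A list: `score`, `ci`, `undefined`, `n_both` triple.
#' @export
linkage_score <- function(observed, unlinked, linked, n_boot = 200L,
                          seed = 1L, tol = 0.05) {
  stopifnot(inherits(observed, "linkage_table"),
            inherits(unlinked, "linkage_table"),
            inherits(linked, "linkage_table"))
  if (abs(observed$m1 - unlinked$m1) > tol ||
      abs(observed$m2 - unlinked$m2) > tol ||
      abs(observed$m1 - linked$m1) > tol ||
      abs(observed$m2 - linked$m2) > tol) {
    warning("control marginals deviate from the observed table by more than ",
            tol)
  }
  lo <- unlinked$n_both * (observed$n / unlinked$n)
  hi <- linked$n_both * (observed$n / linked$n)
  if (hi <= lo) {
    return(list(score = NA_real_, ci = c(NA_real_, NA_real_),
                undefined = TRUE,
                n_both = c(observed = observed$n_both, unlinked = lo,
                           linked = hi)))
  }
  clip01 <- function(v) pmin(1, pmax(0, v))
  score <- clip01((observed$n_both - lo) / (hi - lo))
  probs <- c(observed$n_both, observed$n_first_only,
             observed$n_last_only, observed$n_none) / observed$n
  boot <- with_seed(substream_seed(seed, "linkage_boot"), {
    draws <- stats::rmultinom(n_boot, observed$n, probs)
    clip01((draws[1, ] - lo) / (hi - lo))
  })
  list(score = score,
       ci = stats::quantile(boot, c(0.025, 0.975), names = FALSE),
       undefined = FALSE,
       n_both = c(observed = observed$n_both, unlinked = lo, linked = hi))
}

#' Simulate per-read methylation calls with molecule-level linkage
#'
#' Generates a WGBS-style per-read call table for genes with two sites
#' each: with probability `linkage`, a read's molecule was labeled as a
#' unit (both sites methylated together with probability `efficiency`);
#' otherwise the two sites are labeled independently at the same
#' efficiency.  `linkage = 1` emulates processive labeling of whole
#' molecules, `linkage = 0` independent site-wise labeling.
#'
#' @param n_genes Number of genes.
#' @param reads_per_gene Reads per gene.
#' @param efficiency Per-molecule (or per-site) labeling probability.
#' @param linkage Fraction of reads whose sites are labeled jointly.
#' @param seed Seed.
#' @return A calls data frame as accepted by [comethylation_counts()].
#' @export
simulate_read_calls <- function(n_genes = 20L, reads_per_gene = 200L,
                                efficiency = 0.5, linkage = 1,
                                seed = 1L) {
  with_seed(substream_seed(seed, "read_calls"), {
    rows <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      joint <- stats::runif(reads_per_gene) < linkage
      lab <- stats::rbinom(reads_per_gene, 1L, efficiency)
      s1 <- ifelse(joint, lab, stats::rbinom(reads_per_gene, 1L, efficiency))
      s2 <- ifelse(joint, lab, stats::rbinom(reads_per_gene, 1L, efficiency))
      rid <- sprintf("g%02d_r%04d", g, seq_len(reads_per_gene))
      rows[[g]] <- data.frame(
        read_id = rep(rid, 2L),
        gene_id = sprintf("g%02d", g),
        site_pos = rep(c(100L, 400L), each = reads_per_gene),
        status = c(s1, s2), stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}
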