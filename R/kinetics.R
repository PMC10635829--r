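#' Estimate the number of cell divisions from GFP dilution
#'
#' H2B-GFP fluorescence halves each division, so the division number
#' separating two sorted fractions is the log base 0.5 of their intensity
#' ratio.
#'
#' @param obs A list or `pulse_chase$obs` with `gfp_high`, `gfp_low`, or
#'   two numerics via `gfp_high`/`gfp_low` arguments.
#' @param gfp_high,gfp_low Optional explicit intensities (override `obs`).
#' @return Real-valued division number (>= 0 for ratios <= 1).  A ratio
#'   above 1 warns and returns a negative value; a non-positive ratio is an
#'   error.
#' @export
#' @examples
#' estimate_division_number(gfp_high = 1000, gfp_low = 250)  # 2 divisions
estimate_division_number <- function(obs = NULL, gfp_high = obs$gfp_high,
                                     gfp_low = obs$gfp_low) {
  ratio <- gfp_low / gfp_high
  if (!is.finite(ratio) || ratio <= 0) stop("GFP ratio must be positive")
  if (ratio > 1) {
    warning("GFP ratio > 1: low fraction brighter than high; ",
            "negative division number returned")
  }
  log(ratio) / log(0.5)
}

#' Estimate the per-division label propagation rate
#'
#' The propagation rate is the division-number-th root of the DCM/CpG
#' read-ratio quotient between the chased and the pulsed fraction.
#'
#' @param obs A list with `dcm_high`, `dcm_low` (DCM/CpG read-count ratios).
#' @param divisions Division number separating the fractions (> 0).
#' @param dcm_high,dcm_low Optional explicit ratios (override `obs`).
#' @return Rate in `(0, 1]` (values above 1 are possible for noisy input
#'   and returned as-is).
#' @export
#' @examples
#' estimate_propagation_rate(divisions = 2, dcm_high = 1, dcm_low = 0.3136)
estimate_propagation_rate <- function(obs = NULL, divisions,
                                      dcm_high = obs$dcm_high,
                                      dcm_low = obs$dcm_low) {
  if (divisions == 0) stop("divisions must be > 0 (0th root undefined)")
  ratio <- dcm_low / dcm_high
  if (!is.finite(ratio) || ratio <= 0) stop("DCM ratio must be positive")
  ratio^(1 / divisions)
}

#' Recover the propagation rate from a simulated pulse-chase
#'
#' Chains [estimate_division_number()] and [estimate_propagation_rate()] on
#' a [simulate_pulse_chase()] result and attaches a bootstrap confidence
#' interval obtained by resampling sites.
#'
#' @param sim A `pulse_chase` object.
#' @param n_boot Bootstrap replicates (default 200).
#' @param conf Confidence level (default 0.95).
#' @param seed Seed for the bootstrap.
#' @return A list: `divisions`, `rate`, `ci` (length-2), `boot` (vector of
#'   bootstrap rates).
#' @export
recover_propagation <- function(sim, n_boot = 200L, conf = 0.95, seed = 1L) {
  stopifnot(inherits(sim, "pulse_chase"))
  div <- estimate_division_number(sim$obs)
  rate <- estimate_propagation_rate(sim$obs, div)
  n <- length(sim$dcm_reads_high)
  boot <- with_seed(substream_seed(seed, "prop_boot"), {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      dh <- sum(sim$dcm_reads_high[idx]) / sim$cpg_high
      dl <- sum(sim$dcm_reads_low[idx]) / sim$cpg_low
      if (dh <= 0 || dl <= 0) return(NA_real_)
      (dl / dh)^(1 / div)
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  list(divisions = div, rate = rate,
       ci = stats::quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE,
                            names = FALSE),
       boot = boot)
}

#' In-silico label-dilution experiment
#'
#' Thins the induced replicates' per-gene read counts by a binomial
#' 'samplerate' of `p^divisions` (each read independently retained, equal
#' in distribution to subsampling the read files), normalizes the thinned
#' counts by the ORIGINAL sample's CpG read total, and reports the fraction
#' of genes whose mean diluted signal still exceeds the mean uninduced
#' signal (fold change > 1, no pseudocount: genes at 0 in both groups count
#' as undetected).
#'
#' @param dox_counts Gene x replicate matrix of raw induced counts
#'   (typically genes significantly labeled and peaking on day 2).
#' @param bg_counts Gene x replicate matrix of raw uninduced counts.
#' @param dox_cpg_totals,bg_cpg_totals CpG read totals per replicate of the
#'   original samples (depth normalisers).
#' @param p Propagation rate per division (default 0.56).
#' @param divisions Number of divisions simulated (>= 0).
#' @param seed Seed for the binomial thinning.
#' @return A list of class `dilution_result`: `divisions`, `samplerate`,
#'   `fold_change` (per gene), `detectable_fraction`, `diluted_rpm`,
#'   `bg_rpm`.
#' @export
simulate_dilution <- function(dox_counts, bg_counts,
                              dox_cpg_totals, bg_cpg_totals,
                              p = 0.56, divisions = 0L, seed = 1L) {
  dox_counts <- as.matrix(dox_counts)
  bg_counts <- as.matrix(bg_counts)
  if (nrow(dox_counts) == 0L) stop("empty gene universe")
  stopifnot(nrow(dox_counts) == nrow(bg_counts),
            length(dox_cpg_totals) == ncol(dox_counts),
            length(bg_cpg_totals) == ncol(bg_counts),
            divisions >= 0, p >= 0, p <= 1)
  samplerate <- p^divisions
  thinned <- with_seed(substream_seed(seed, "dilution"), {
    matrix(stats::rbinom(length(dox_counts), as.vector(dox_counts),
                         samplerate),
           nrow = nrow(dox_counts))
  })
  diluted_rpm <- sweep(thinned, 2, dox_cpg_totals, "/") * 1e6
  bg_rpm <- sweep(bg_counts, 2, bg_cpg_totals, "/") * 1e6
  num <- rowMeans(diluted_rpm)
  den <- rowMeans(bg_rpm)
  fc <- ifelse(den == 0, ifelse(num > 0, Inf, NaN), num / den)
  detectable <- !is.nan(fc) & fc > 1
  structure(list(divisions = divisions, samplerate = samplerate,
                 fold_change = fc,
                 detectable_fraction = mean(detectable),
                 diluted_rpm = diluted_rpm, bg_rpm = bg_rpm),
            class = "dilution_result")
}

#' @export
print.dilution_result <- function(x, ...) {
  cat(sprintf("dilution_result: %s divisions, samplerate %.4g, %.1f%% of %d genes detectable\n",
              format(x$divisions), x$samplerate,
              100 * x$detectable_fraction, length(x$fold_change)))
  invisible(x)
}
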