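#' Per-gene temporal profiles and fold changes versus day 1
#'
#' Averages the relative-RPM values of each gene per sampling day (mean of
#' replicate values, with the standard error of the mean as the
#' variability measure) and expresses each induced day as a fold change
#' over day 1, the calibrator.  Genes whose day-1 mean is zero get an
#' undefined fold change and are flagged.
#'
#' @param t A `gene_counts` object normalized in relative mode.
#' @param design Optional design override.
#' @return A list of class `temporal_profiles`: `means`, `sem` (gene x day
#'   matrices over induced days), `fc` (fold change vs day 1), `peak`
#'   (data frame from [assign_peak_day()]), `undefined_fc` flag vector.
#' @export
fold_change_vs_day1 <- function(t, design = t$design) {
  stopifnot(inherits(t, "gene_counts"))
  days <- sort(unique(design$day[design$day > 0L]))
  if (!1L %in% days) stop("day 1 must be present to calibrate fold changes")
  mean_mat <- sapply(days, function(d) {
    rowMeans(t$table[, design$day == d, drop = FALSE])
  })
  sem_mat <- sapply(days, function(d) {
    cols <- t$table[, design$day == d, drop = FALSE]
    apply(cols, 1, stats::sd) / sqrt(ncol(cols))
  })
  colnames(mean_mat) <- colnames(sem_mat) <- paste0("day_", days)
  d1 <- mean_mat[, "day_1"]
  fc <- sweep(mean_mat, 1, d1, "/")
  undefined <- d1 == 0
  fc[undefined, ] <- NA_real_
  peak <- assign_peak_day(mean_mat, days)
  structure(list(means = mean_mat, sem = sem_mat, fc = fc,
                 days = days, peak = peak, undefined_fc = undefined),
            class = "temporal_profiles")
}

#' Assign the peak day of each temporal profile
#'
#' The peak day is the induced day with the maximum mean signal; day 0 (the
#' uninduced control) is never eligible.  Ties break toward the earlier day
#' and are flagged; all-zero profiles are unassigned (`NA`).
#'
#' @param means Gene x day matrix of mean signals (columns ordered as
#'   `days`), or a single numeric vector.
#' @param days Integer vector of days corresponding to the columns.
#' @return Data frame `peak_day`, `tie`, `unassigned`, one row per profile.
#' @export
assign_peak_day <- function(means, days) {
  if (is.null(dim(means))) means <- matrix(means, nrow = 1)
  stopifnot(ncol(means) == length(days), length(days) >= 2L)
  keep <- days > 0L
  means <- means[, keep, drop = FALSE]
  days <- days[keep]
  res <- t(apply(means, 1, function(v) {
    if (all(v == 0) || all(is.na(v))) return(c(NA_integer_, FALSE, TRUE))
    i <- which(v == max(v, na.rm = TRUE))
    c(days[i[1]], length(i) > 1L, FALSE)
  }))
  data.frame(peak_day = as.integer(res[, 1]), tie = as.logical(res[, 2]),
             unassigned = as.logical(res[, 3]),
             row.names = rownames(means), stringsAsFactors = FALSE)
}

#' Z-score temporal profiles per gene
#'
#' Standardizes each row (gene) across days to mean 0 and standard
#' deviation 1, using the population standard deviation (divisor `n`) since
#' the handful of sampling days is the complete set of timepoints, not a
#' sample from a larger one.  Constant rows become all-zero and are
#' flagged.
#'
#' @param means Gene x day matrix.
#' @return Matrix of the same shape; attribute `constant` flags rows that
#'   were constant.
#' @export
zscore_matrix <- function(means) {
  stopifnot(ncol(means) >= 2L)
  mu <- rowMeans(means)
  sdp <- sqrt(rowMeans((means - mu)^2))
  constant <- sdp == 0
  z <- (means - mu) / ifelse(sdp == 0, 1, sdp)
  z[constant, ] <- 0
  attr(z, "constant") <- constant
  z
}
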