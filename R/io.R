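#' @importFrom utils read.delim write.table
NULL

#' Write a toy genome to FASTA
#'
#' @param genome A `toy_genome` (or named character vector of sequences).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- genome_sequences(genome)
  x <- Biostrings::DNAStringSet(unlist(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write reads to FASTQ with dummy Phred-33 qualities
#'
#' @param reads A named [Biostrings::DNAStringSet].
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  quals <- Biostrings::BStringSet(vapply(Biostrings::width(reads), function(w)
    strrep("I", w), character(1)))
  Biostrings::writeXStringSet(reads, path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

#' Write intervals as BED6
#'
#' @param df Data frame with `chrom`, `start`, `end` (0-based half-open)
#'   and optionally `name`, `score`, `strand`.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  bed <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                    name = if ("name" %in% names(df)) df$name else ".",
                    score = if ("score" %in% names(df)) df$score else 0,
                    strand = if ("strand" %in% names(df)) df$strand else ".")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write per-site values as bedGraph
#'
#' @param sites Data frame with `chrom`, `pos`.
#' @param values Numeric vector, one per site.
#' @param path Output bedGraph path.
#' @param track_name Track line name.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(sites, values, path, track_name = "medtrace") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", track_name), con)
  write.table(data.frame(sites$chrom, sites$pos, sites$pos + 1L,
                         signif(values, 6)),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write / read a site_counts object as TSV files
#'
#' Serializes the count matrix together with its site coordinates, totals
#' and design into a single directory prefix (`<prefix>_counts.tsv`,
#' `<prefix>_totals.tsv`, `<prefix>_design.tsv`).
#'
#' @param m A `site_counts` object.
#' @param prefix File prefix (path without suffix).
#' @return The prefix, invisibly.
#' @export
write_site_counts <- function(m, prefix) {
  stopifnot(inherits(m, "site_counts"))
  df <- cbind(m$sites[c("chrom", "pos", "context")], as.data.frame(m$counts))
  write.table(df, paste0(prefix, "_counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  tot <- m$totals
  tot$normalized <- m$normalized
  write.table(tot, paste0(prefix, "_totals.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(m$design, paste0(prefix, "_design.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_site_counts
#' @export
read_site_counts <- function(prefix) {
  df <- read.delim(paste0(prefix, "_counts.tsv"), check.names = FALSE)
  tot <- read.delim(paste0(prefix, "_totals.tsv"))
  design <- read.delim(paste0(prefix, "_design.tsv"))
  design$sample_id <- as.character(design$sample_id)
  normalized <- as.character(tot$normalized[1])
  tot$normalized <- NULL
  sites <- df[c("chrom", "pos", "context")]
  counts <- as.matrix(df[, design$sample_id, drop = FALSE])
  site_counts(sites, counts, tot, design, normalized)
}
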