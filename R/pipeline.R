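#' Orchestrate the full synthetic-study pipeline
#'
#' Runs the stages of the analysis in dependency order on a simulated
#' study: generate the toy genome and per-site counts, normalize, aggregate
#' to genes, call significantly labeled genes, build temporal profiles,
#' call and merge enhancer DMRs with closest-gene assignment and peak-day
#' coordination, classify the peak track, estimate the propagation rate
#' from a matched pulse-chase, run the in-silico dilution, and score
#' co-methylation linkage.  Each stage's parameters (including the hashes
#' of its upstream stages) are hashed into `<stage>.hash` under `out_dir`;
#' on rerun, a stage whose hash matches and whose outputs exist is reloaded
#' from disk rather than recomputed, so changing one parameter only
#' recomputes the stages downstream of it.
#'
#' @param config A [simulate_config()].
#' @param out_dir Output directory (created if needed).
#' @param thresholds [analysis_thresholds()].
#' @param stages Character vector of stages to run (default all, in
#'   order).
#' @return A list of class `pipeline_result`: `manifest` (data frame
#'   `stage`, `file`, `md5`, `recomputed`) and the principal in-memory
#'   results per stage.
#' @export
run_pipeline <- function(config = simulate_config(),
                         out_dir = tempfile("medtrace_"),
                         thresholds = analysis_thresholds(),
                         stages = c("simulate", "normalize", "genes",
                                    "active", "temporal", "enhancer",
                                    "labelpeaks", "kinetics", "linkage")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(stage = character(0), file = character(0),
                         md5 = character(0), recomputed = logical(0),
                         stringsAsFactors = FALSE)
  results <- list()
  hashes <- list()

  param_hash <- function(params) {
    f <- tempfile()
    on.exit(unlink(f))
    saveRDS(params, f, version = 2, compress = FALSE)
    unname(tools::md5sum(f))
  }
  log_line <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), "", ..., "\n",
        file = file.path(out_dir, "pipeline.log"), append = TRUE, sep = "")
  }
  run_stage <- function(name, params, outputs, compute, load = NULL) {
    h <- param_hash(params)
    hashes[[name]] <<- h
    hf <- file.path(out_dir, paste0(name, ".hash"))
    paths <- file.path(out_dir, outputs)
    cached <- !is.null(load) && file.exists(hf) &&
      identical(readLines(hf, warn = FALSE)[1], h) && all(file.exists(paths))
    if (cached) {
      log_line("stage ", name, ": cached")
      obj <- load(paths)
    } else {
      log_line("stage ", name, ": computing")
      obj <- compute(paths)
      writeLines(h, hf)
    }
    manifest <<- rbind(manifest, data.frame(
      stage = name, file = outputs, md5 = unname(tools::md5sum(paths)),
      recomputed = !cached, stringsAsFactors = FALSE))
    results[[name]] <<- obj
    obj
  }

  if ("simulate" %in% stages) {
    sim <- run_stage("simulate", list(config = config),
      c("genome.fasta", "genes.bed", "enhancers_truth.bed", "repeats.bed",
        "raw_counts.tsv", "raw_totals.tsv", "raw_design.tsv"),
      compute = function(paths) {
        genome <- generate_toy_genome(config)
        counts <- simulate_site_counts(genome, config)
        write_genome_fasta(genome, paths[1])
        write_bed(cbind(genome$genes,
                        data.frame(name = genome$genes$gene_id)), paths[2])
        write_bed(cbind(genome$enhancers,
                        data.frame(name = genome$enhancers$enhancer_id)),
                  paths[3])
        write_bed(genome$repeats, paths[4])
        write_site_counts(counts, file.path(out_dir, "raw"))
        list(genome = genome, counts = counts)
      },
      load = function(paths) {
        # the genome is cheap to regenerate deterministically from config
        genome <- generate_toy_genome(config)
        list(genome = genome,
             counts = read_site_counts(file.path(out_dir, "raw")))
      })
  }
  genome <- results$simulate$genome

  if ("normalize" %in% stages) {
    run_stage("normalize",
      list(up = hashes$simulate, mode = "relative"),
      c("rpm_counts.tsv", "rpm_totals.tsv", "rpm_design.tsv"),
      compute = function(paths) {
        rpm <- normalize_counts(results$simulate$counts, "relative")
        write_site_counts(rpm, file.path(out_dir, "rpm"))
        rpm
      },
      load = function(paths) read_site_counts(file.path(out_dir, "rpm")))
  }

  if ("genes" %in% stages) {
    run_stage("genes",
      list(up = hashes$normalize,
           min_sites = thresholds$min_sites_per_gene),
      "gene_rpm.tsv",
      compute = function(paths) {
        gt <- gene_body_counts(results$normalize, genome$genes,
                               thresholds = thresholds)
        write.table(cbind(gt$genes, as.data.frame(gt$table)), paths[1],
                    sep = "\t", quote = FALSE, row.names = FALSE)
        gt
      },
      load = function(paths) {
        df <- read.delim(paths[1], check.names = FALSE)
        ids <- results$normalize$design$sample_id
        tab <- as.matrix(df[, ids, drop = FALSE])
        rownames(tab) <- df$gene_id
        structure(list(table = tab,
                       genes = df[, setdiff(names(df), ids), drop = FALSE],
                       design = results$normalize$design,
                       normalized = results$normalize$normalized,
                       totals = results$normalize$totals),
                  class = "gene_counts")
      })
  }

  if ("active" %in% stages) {
    run_stage("active", list(up = hashes$genes, p_cut = thresholds$p_cut),
      "active_genes.tsv",
      compute = function(paths) {
        act <- call_active_genes(results$genes, thresholds = thresholds)
        write.table(act, paths[1], sep = "\t", quote = FALSE,
                    row.names = FALSE)
        act
      },
      load = function(paths) read.delim(paths[1]))
  }

  if ("temporal" %in% stages) {
    run_stage("temporal", list(up = hashes$active),
      c("temporal_means.tsv", "temporal_fc.tsv", "temporal_peaks.tsv"),
      compute = function(paths) {
        prof <- fold_change_vs_day1(results$genes)
        write.table(prof$means, paths[1], sep = "\t", quote = FALSE)
        write.table(prof$fc, paths[2], sep = "\t", quote = FALSE)
        peaks <- cbind(gene_id = rownames(prof$peak), prof$peak,
                       significant = results$active$significant[
                         match(rownames(prof$peak),
                               results$active$gene_id)])
        write.table(peaks, paths[3], sep = "\t", quote = FALSE,
                    row.names = FALSE)
        prof
      },
      load = function(paths) {
        means <- as.matrix(read.delim(paths[1], check.names = FALSE))
        fc <- as.matrix(read.delim(paths[2], check.names = FALSE))
        pk <- read.delim(paths[3])
        rownames(pk) <- pk$gene_id
        structure(list(means = means, fc = fc,
                       days = as.integer(sub("day_", "", colnames(means))),
                       peak = pk, undefined_fc = means[, "day_1"] == 0),
                  class = "temporal_profiles")
      })
  }

  if ("enhancer" %in% stages) {
    run_stage("enhancer",
      list(up = hashes$normalize, act = hashes$active,
           th = thresholds[c("p_cut", "fc_min", "min_reads", "merge_gap",
                             "extend", "gene_flank")]),
      c("dmr_sites.tsv", "enhancer_regions.bed",
        "enhancer_regions_extended.bed", "coordination_z.tsv"),
      compute = function(paths) {
        rpm <- results$normalize
        raw <- results$simulate$counts
        dcm_idx <- rpm$sites$context == "DCM"
        cand <- filter_intergenic_sites(
          rpm$sites[dcm_idx, c("chrom", "pos")], genome$genes,
          genome$repeats, flank = thresholds$gene_flank)
        key <- paste(rpm$sites$chrom, rpm$sites$pos)
        sel <- match(paste(cand$chrom, cand$pos), key)
        take <- function(x) site_counts(x$sites[sel, , drop = FALSE],
                                        x$counts[sel, , drop = FALSE],
                                        x$totals, x$design, x$normalized)
        dmr <- call_dmr_sites(take(rpm), take(raw), thresholds, "intestine")
        write.table(dmr, paths[1], sep = "\t", quote = FALSE,
                    row.names = FALSE)
        sig <- dmr[dmr$significant, , drop = FALSE]
        merged <- merge_sites_to_regions(sig[c("chrom", "pos")],
                                         thresholds$merge_gap,
                                         thresholds$extend)
        # per-region peak day from summed member-site day means
        day_cols <- grep("^day_", names(sig), value = TRUE)
        reg_days <- t(vapply(seq_len(nrow(merged$regions)), function(r) {
          colSums(sig[merged$members == r, day_cols, drop = FALSE])
        }, numeric(length(day_cols))))
        days <- as.integer(sub("day_", "", day_cols))
        pk <- assign_peak_day(reg_days, days)
        regions <- merged$regions
        regions$peak_day <- pk$peak_day
        sig_genes <- genome$genes
        sig_genes$significant <- results$active$significant[
          match(sig_genes$gene_id, results$active$gene_id)]
        regions <- assign_closest_gene(regions, sig_genes,
                                       significant_only = TRUE)
        write_bed(cbind(regions, data.frame(name = regions$region_id)),
                  paths[2])
        write_bed(merged$extended, paths[3])
        gene_peaks <- results$temporal$peak
        gp <- genome$genes
        gp$peak_day <- gene_peaks$peak_day[match(gp$gene_id,
                                                 rownames(gene_peaks))]
        gp <- gp[sig_genes$significant %in% TRUE, , drop = FALSE]
        coord <- coordination_matrix(regions, gp)
        write.table(coord$z, paths[4], sep = "\t", quote = FALSE)
        list(dmr = dmr, regions = regions, extended = merged$extended,
             coordination = coord)
      })
  }

  if ("labelpeaks" %in% stages) {
    run_stage("labelpeaks",
      list(up = hashes$enhancer, dist = thresholds$label_dist,
           seed = config$seed),
      "peak_label_report.tsv",
      compute = function(paths) {
        dmr <- results$enhancer$dmr
        rep_ <- label_peaks(genome$peaks,
                            dmr[dmr$significant, c("chrom", "pos")],
                            genome, genome$genes,
                            label_dist = thresholds$label_dist,
                            exclusion_flank = thresholds$gene_flank,
                            seed = config$seed)
        write.table(data.frame(n_peaks = rep_$n_peaks,
                               n_labeled = rep_$n_labeled,
                               fraction = rep_$fraction,
                               shuffle_mean = rep_$shuffle_mean,
                               shuffle_sd = rep_$shuffle_sd),
                    paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
        rep_
      })
  }

  if ("kinetics" %in% stages) {
    run_stage("kinetics",
      list(up = hashes$active, p = config$propagation_rate,
           seed = config$seed),
      c("propagation.tsv", "dilution.tsv"),
      compute = function(paths) {
        sim <- simulate_pulse_chase(
          n_sites = 1e5,
          efficiency = mean(config$labeling_efficiency),
          p = config$propagation_rate, division_gap = 3L,
          seed = substream_seed(config$seed, "kinetics"))
        prop <- recover_propagation(sim, seed = config$seed)
        write.table(data.frame(divisions = prop$divisions,
                               rate = prop$rate,
                               ci_lo = prop$ci[1], ci_hi = prop$ci[2]),
                    paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
        # dilution over significant genes peaking on day 2
        act <- results$active
        pk <- results$temporal$peak
        keep <- act$gene_id[act$significant &
                              pk$peak_day[match(act$gene_id,
                                                rownames(pk))] %in% 2L]
        raw_gt <- gene_body_counts(results$simulate$counts, genome$genes,
                                   thresholds = thresholds)
        des <- raw_gt$design
        dox2 <- des$sample_id[des$day == 2L]
        bg <- des$sample_id[des$condition == "nodox"]
        tot <- raw_gt$totals
        dil <- lapply(0:7, function(dv) {
          simulate_dilution(
            raw_gt$table[keep, dox2, drop = FALSE],
            raw_gt$table[keep, bg, drop = FALSE],
            tot$cpg_total[match(dox2, tot$sample_id)],
            tot$cpg_total[match(bg, tot$sample_id)],
            p = config$propagation_rate, divisions = dv,
            seed = substream_seed(config$seed, paste0("dil", dv)))
        })
        df <- data.frame(divisions = 0:7,
                         samplerate = vapply(dil, `[[`, numeric(1),
                                             "samplerate"),
                         detectable = vapply(dil, `[[`, numeric(1),
                                             "detectable_fraction"))
        write.table(df, paths[2], sep = "\t", quote = FALSE,
                    row.names = FALSE)
        list(propagation = prop, dilution = df, n_genes = length(keep))
      })
  }

  if ("linkage" %in% stages) {
    run_stage("linkage", list(seed = config$seed,
                              eff = mean(config$labeling_efficiency)),
      "linkage.tsv",
      compute = function(paths) {
        calls <- simulate_read_calls(
          n_genes = 20L, reads_per_gene = 200L,
          efficiency = mean(config$labeling_efficiency) * 5,
          linkage = 1, seed = substream_seed(config$seed, "linkage"))
        obs <- comethylation_counts(calls)
        unl <- simulate_unlinked(obs$m1, obs$m2, obs$n,
                                 seed = substream_seed(config$seed, "u"))
        lnk <- simulate_linked(obs$m1, obs$m2, obs$n,
                               seed = substream_seed(config$seed, "l"))
        sc <- linkage_score(obs, unl, lnk)
        write.table(data.frame(n = obs$n, n_both = obs$n_both,
                               m1 = obs$m1, m2 = obs$m2,
                               score = sc$score,
                               ci_lo = sc$ci[1], ci_hi = sc$ci[2]),
                    paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
        list(observed = obs, score = sc)
      },
      load = function(paths) {
        df <- read.delim(paths[1])
        list(observed = NULL, score = list(score = df$score,
                                           ci = c(df$ci_lo, df$ci_hi)),
             summary = df)
      })
  }

  structure(list(manifest = manifest, results = results,
                 out_dir = out_dir, config = config,
                 thresholds = thresholds),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", length(unique(x$manifest$stage)), "stages,",
      nrow(x$manifest), "files in", x$out_dir, "\n")
  print(x$manifest[c("stage", "file", "recomputed")], row.names = FALSE)
  invisible(x)
}
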