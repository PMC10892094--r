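#' Run the full m6A dynamics pipeline on a simulated dataset
#'
#' Executes simulate -> per-replicate peak calling (each IP replicate
#' against the condition's pooled input) -> replicate consensus ->
#' stress/control/shared classification -> transcript and ncRNA
#' categorisation -> metagene and start/stop frequency profiles -> feature
#' breakdown -> abundance fold changes with category comparisons ->
#' polysome occupancy with category comparisons -> k-mer motif enrichment,
#' and writes every result table as TSV (plus NarrowPeak files for the
#' consensus sets) into `out_dir`. All stages derive their randomness from
#' `cfg$seed`, so two runs with the same config produce byte-identical
#' report tables.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Report directory (created if needed).
#' @param alpha,min_windows,merge_gap,lambda_smooth Peak-caller settings
#'   (see [call_peaks()]).
#' @param keep_data Also write the simulated input dataset under
#'   `out_dir/data` (via [write_dataset()]).
#' @return Invisibly, a list with all in-memory results.
#' @export
run_all <- function(cfg, out_dir, alpha = 0.05, min_windows = 2L,
                    merge_gap = 1L, lambda_smooth = 3L, keep_data = FALSE) {
  t0 <- Sys.time()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(stage, msg)
    message(sprintf("[INFO] [%s] %s", stage, msg))
  wt <- function(df, f) utils::write.table(df, file.path(out_dir, f),
                                           sep = "\t", quote = FALSE,
                                           row.names = FALSE)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  log_stage("simulate", sprintf("generating dataset (n=%d, seed=%d)",
                                cfg$n_transcripts, cfg$seed))
  sim <- run_stage("simulate", simulate_dataset(cfg))
  if (keep_data) write_dataset(sim, file.path(out_dir, "data"))
  anno <- sim$annotation

  log_stage("callpeaks", "per-replicate Poisson calling vs pooled input")
  cons <- list()
  for (cond in c("control", "copper")) {
    pooled_input <- pool_tracks(
      sim$tracks[sprintf("input_%s_%d", cond, seq_len(cfg$n_ip_reps))])
    calls <- lapply(seq_len(cfg$n_ip_reps), function(r)
      call_peaks(sim$tracks[[sprintf("ip_%s_%d", cond, r)]], pooled_input,
                 alpha = alpha, min_windows = min_windows,
                 merge_gap = merge_gap, lambda_smooth = lambda_smooth,
                 name_prefix = sprintf("%s_rep%d", cond, r)))
    cons[[cond]] <- run_stage("dynamics",
                              consensus_peaks(calls, condition = cond))
    write_narrowpeak(cons[[cond]],
                     file.path(out_dir, sprintf("consensus_%s.narrowPeak",
                                                cond)))
    log_stage("dynamics", sprintf("%s: %d consensus peaks", cond,
                                  nrow(cons[[cond]])))
  }

  cat_peaks <- run_stage("dynamics",
                         classify_peaks(cons$control, cons$copper))
  tx_cat <- run_stage("dynamics", assign_to_transcripts(cat_peaks, anno))
  nc_tab <- ncrna_breakdown(tx_cat)
  wt(cat_peaks, "peak_categories.tsv")
  wt(tx_cat, "transcript_categories.tsv")
  wt(nc_tab, "ncrna_breakdown.tsv")

  log_stage("metagene", "binned density and positional frequency profiles")
  mg <- run_stage("metagene", {
    do.call(rbind, lapply(c("ip_control", "ip_copper", "input_control",
                            "input_copper"), function(lib) {
      parts <- strsplit(lib, "_")[[1]]
      pooled <- pool_tracks(
        sim$tracks[sprintf("%s_%s_%d", parts[1], parts[2],
                           seq_len(cfg$n_ip_reps))])
      cbind(library = lib,
            suppressMessages(metagene_density(pooled, anno)))
    }))
  })
  wt(mg, "metagene.tsv")
  freq <- run_stage("metagene", rbind(
    positional_frequency(cat_peaks, tx_cat, anno, "start"),
    positional_frequency(cat_peaks, tx_cat, anno, "stop")))
  wt(freq, "frequency.tsv")
  fb <- run_stage("metagene", feature_breakdown(cat_peaks, anno))
  wt(fb, "feature_breakdown.tsv")

  log_stage("quant", "fold changes and category comparisons")
  fc <- run_stage("quant", log2_fold_change(sim$rna))
  fc$category <- tx_cat$category[match(fc$transcript_id,
                                       tx_cat$transcript_id)]
  fc$biotype <- anno$transcripts$biotype[
    match(fc$transcript_id, anno$transcripts$transcript_id)]
  wt(fc, "fold_changes.tsv")
  mrna <- fc[!is.na(fc$category) & fc$biotype == "mRNA", ]
  cmp_lfc <- run_stage("quant",
                       category_comparison(mrna$log2fc, mrna$category))
  thr <- threshold_counts(fc, tx_cat$transcript_id[
    tx_cat$category == "stress-enriched" & tx_cat$biotype == "mRNA"])

  log_stage("occupancy", "polysome occupancy change by category")
  occ <- run_stage("occupancy",
                   suppressMessages(polysome_occupancy(sim$polysome, sim$rna)))
  occ$category <- tx_cat$category[match(occ$transcript_id,
                                        tx_cat$transcript_id)]
  occ$biotype <- anno$transcripts$biotype[
    match(occ$transcript_id, anno$transcripts$transcript_id)]
  wt(occ, "occupancy.tsv")
  occ_m <- occ[!is.na(occ$category) & occ$biotype == "mRNA", ]
  cmp_occ <- run_stage("occupancy",
                       category_comparison(occ_m$occupancy_change,
                                           occ_m$category))

  # non-coding contrast: abundance change of stress-enriched lncRNA hosts
  lnc <- fc[!is.na(fc$category) & fc$biotype == "lncRNA", ]
  lnc_stress_median <- stats::median(
    lnc$log2fc[lnc$category == "stress-enriched"])
  lnc_p <- if (sum(lnc$category == "stress-enriched") >= 2 &&
               sum(lnc$category == "shared") >= 2)
    stats::t.test(lnc$log2fc[lnc$category == "stress-enriched"],
                  lnc$log2fc[lnc$category == "shared"])$p.value
  else NA_real_

  log_stage("motif", "k-mer enrichment over peak sequences")
  peak_seqs <- run_stage("motif", suppressWarnings(
    extract_peak_sequences(cat_peaks, anno, sim$sequences)))
  motifs <- run_stage("motif",
                      kmer_enrichment(peak_seqs, seed = cfg$seed + 4L))
  wt(utils::head(motifs, 25), "motifs.tsv")

  pair_p <- function(cmp, g1, g2) {
    i <- which((cmp$pairs$group1 == g1 & cmp$pairs$group2 == g2) |
                 (cmp$pairs$group1 == g2 & cmp$pairs$group2 == g1))
    if (length(i)) cmp$pairs$pvalue[i] else NA_real_
  }
  med <- function(cmp, g) {
    i <- match(g, cmp$summary$category)
    if (!is.na(i)) cmp$summary$median[i] else NA_real_
  }
  summary_df <- data.frame(key = c(
    "n_consensus_control", "n_consensus_copper",
    "n_stress_enriched_peaks", "n_control_enriched_peaks", "n_shared_peaks",
    "n_stress_enriched_transcripts", "n_control_enriched_transcripts",
    "n_shared_transcripts",
    "median_lfc_stress", "median_lfc_control", "median_lfc_shared",
    "p_lfc_stress_vs_shared", "p_occ_stress_vs_shared",
    "median_occ_change_stress", "median_lfc_lncRNA_stress",
    "p_lfc_lncRNA_stress_vs_shared",
    "n_increase_gt50pct_stress", "n_decrease_gt50pct_stress",
    "top_motif", "top_motif_padj"),
    value = c(nrow(cons$control), nrow(cons$copper),
              sum(cat_peaks$category == "stress-enriched"),
              sum(cat_peaks$category == "control-enriched"),
              sum(cat_peaks$category == "shared"),
              sum(tx_cat$category == "stress-enriched"),
              sum(tx_cat$category == "control-enriched"),
              sum(tx_cat$category == "shared"),
              med(cmp_lfc, "stress-enriched"),
              med(cmp_lfc, "control-enriched"), med(cmp_lfc, "shared"),
              pair_p(cmp_lfc, "stress-enriched", "shared"),
              pair_p(cmp_occ, "stress-enriched", "shared"),
              med(cmp_occ, "stress-enriched"), lnc_stress_median, lnc_p,
              thr[["increase"]], thr[["decrease"]],
              motifs$kmer[1], motifs$padj[1]),
    stringsAsFactors = FALSE)
  wt(summary_df, "summary.tsv")
  log_stage("report", sprintf("done in %.1f s; report in %s",
                              as.numeric(difftime(Sys.time(), t0, "secs")),
                              out_dir))
  invisible(list(sim = sim, consensus = cons, cat_peaks = cat_peaks,
                 tx_categories = tx_cat, ncrna = nc_tab, metagene = mg,
                 frequency = freq, feature_breakdown = fb,
                 fold_changes = fc, cmp_lfc = cmp_lfc, occupancy = occ,
                 cmp_occ = cmp_occ, motifs = motifs, summary = summary_df))
}
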