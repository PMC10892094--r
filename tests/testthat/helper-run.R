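# one shared full-scale pipeline run (study-default conditions), computed
# lazily and cached for the session so several test files can score it
.run_cache <- new.env(parent = emptyenv())

get_default_run <- function() {
  if (!is.null(.run_cache$run)) return(.run_cache$run)
  cfg <- sim_config(seed = 1)   # defaults: 2000 transcripts, 8x, depth 30
  sim <- simulate_dataset(cfg)
  cons <- list()
  for (cond in c("control", "copper")) {
    pooled <- pool_tracks(
      sim$tracks[sprintf("input_%s_%d", cond, seq_len(cfg$n_ip_reps))])
    calls <- lapply(seq_len(cfg$n_ip_reps), function(r)
      call_peaks(sim$tracks[[sprintf("ip_%s_%d", cond, r)]], pooled,
                 name_prefix = sprintf("%s_rep%d", cond, r)))
    cons[[cond]] <- consensus_peaks(calls, condition = cond)
  }
  cat_peaks <- classify_peaks(cons$control, cons$copper)
  tx_cat <- suppressMessages(assign_to_transcripts(cat_peaks,
                                                   sim$annotation))
  .run_cache$run <- list(cfg = cfg, sim = sim, cons = cons,
                         cat_peaks = cat_peaks, tx_cat = tx_cat)
  .run_cache$run
}

# same-strand >=1 nt overlap counts between a peak table and a truth table
overlap_counts <- function(a_chrom, a_start, a_end, a_strand,
                           b_chrom, b_start, b_end, b_strand) {
  ga <- GenomicRanges::GRanges(a_chrom,
                               IRanges::IRanges(a_start + 1L, a_end),
                               strand = a_strand)
  gb <- GenomicRanges::GRanges(b_chrom,
                               IRanges::IRanges(b_start + 1L, b_end),
                               strand = b_strand)
  GenomicRanges::countOverlaps(ga, gb, ignore.strand = FALSE)
}
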