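#' Generate a synthetic transcriptome
#'
#' Draws transcript structures on five chromosomes: segment lengths are
#' truncated-normal around the configured means (CDS lengths rounded to
#' codons), 1-3 exons per transcript with 60-200 nt introns, alternating
#' random strands, and non-overlapping genomic footprints separated by
#' 300 nt gaps. About `frac_noncoding` of transcripts are non-coding with
#' biotype counts allocated deterministically so that lncRNA is always the
#' largest non-coding class. Transcript sequences are i.i.d. random DNA;
#' motif signal is planted later by [plant_peaks()].
#'
#' All randomness derives from `cfg$seed`, so repeated runs are
#' byte-identical.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_transcriptome` with elements `annotation`
#'   (a [tx_annotation]), `sequences` (named `DNAStringSet` of spliced
#'   transcript sequences) and `chrom_lengths`.
#' @export
generate_transcriptome <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_transcripts
  if (n < 1) stop("n_transcripts must be >= 1")

  # deterministic non-coding biotype allocation (lncRNA largest by design)
  n_nc <- round(cfg$frac_noncoding * n)
  shares <- c(lncRNA = 0.5, ncRNA = 0.25, miRNA_precursor = 0.125,
              snoRNA = 0.125)
  nc_counts <- floor(shares * n_nc)
  nc_counts["lncRNA"] <- nc_counts["lncRNA"] + (n_nc - sum(nc_counts))
  biotype <- rep("mRNA", n)
  if (n_nc > 0)
    biotype[sample.int(n, n_nc)] <- sample(rep(names(nc_counts), nc_counts))

  trunc_norm <- function(n, mean, min) pmax(min, round(stats::rnorm(n, mean, 0.25 * mean)))
  u5 <- trunc_norm(n, cfg$utr5_len, 60)
  cd <- trunc_norm(n, cfg$cds_len, 300); cd <- 3L * round(cd / 3)
  u3 <- trunc_norm(n, cfg$utr3_len, 80)
  nc_L <- trunc_norm(n, cfg$nc_len, 250)
  coding <- biotype == "mRNA"
  L <- ifelse(coding, u5 + cd + u3, nc_L)
  min_len <- max(cfg$peak_len_range)
  if (any(L < min_len))
    stop("transcript lengths too short to host a peak (< ", min_len, " nt)")

  chroms <- as.character(1:5)
  cursor <- stats::setNames(rep(0L, 5), chroms)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  n_ex <- sample(1:3, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))

  ids <- sprintf("TX%05d", seq_len(n))
  tx_start <- tx_end <- integer(n)
  tx_chrom <- character(n)
  e_tid <- e_chrom <- e_strand <- vector("list", n)
  e_start <- e_end <- e_rank <- vector("list", n)
  for (i in seq_len(n)) {
    k <- n_ex[i]
    w <- L[i]
    widths <- if (k == 1) w else {
      ws <- NULL
      for (try in 1:50) {
        cuts <- sort(sample.int(w - 1L, k - 1L))
        d <- diff(c(0L, cuts, w))
        if (all(d >= 60L)) { ws <- d; break }
      }
      if (is.null(ws)) { k <- 1L; w } else ws
    }
    introns <- if (k > 1) sample(60:200, k - 1L, replace = TRUE) else integer(0)
    chrom <- chroms[((i - 1L) %% 5L) + 1L]
    g0 <- cursor[chrom]
    gw <- if (strand[i] == "+") widths else rev(widths)
    gi <- if (strand[i] == "+") introns else rev(introns)
    gstarts <- g0 + cumsum(c(0L, gw[-k] + gi))
    gends <- gstarts + gw
    cursor[chrom] <- gends[k] + 300L
    tx_chrom[i] <- chrom; tx_start[i] <- g0; tx_end[i] <- gends[k]
    e_tid[[i]] <- rep(ids[i], k); e_chrom[[i]] <- rep(chrom, k)
    e_strand[[i]] <- rep(strand[i], k)
    e_start[[i]] <- gstarts; e_end[[i]] <- gends
    e_rank[[i]] <- if (strand[i] == "+") seq_len(k) else rev(seq_len(k))
  }
  tx_df <- data.frame(
    transcript_id = ids, gene_id = sprintf("G%05d", seq_len(n)),
    chrom = tx_chrom, strand = strand, start = tx_start, end = tx_end,
    biotype = biotype,
    utr5_len = ifelse(coding, u5, 0L), cds_len = ifelse(coding, cd, 0L),
    utr3_len = ifelse(coding, u3, 0L), stringsAsFactors = FALSE)
  ex_df <- data.frame(
    transcript_id = unlist(e_tid), chrom = unlist(e_chrom),
    strand = unlist(e_strand), start = as.integer(unlist(e_start)),
    end = as.integer(unlist(e_end)), exon_rank = unlist(e_rank),
    stringsAsFactors = FALSE)
  anno <- tx_annotation(tx_df, ex_df)

  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), L[i], replace = TRUE), collapse = ""),
    "")
  names(seqs) <- anno$transcripts$transcript_id
  chrom_lengths <- cursor
  structure(list(annotation = anno,
                 sequences = Biostrings::DNAStringSet(seqs),
                 chrom_lengths = chrom_lengths),
            class = "sim_transcriptome")
}

# sample a peak interval [s, e) (transcript coordinates) of length `len`
# for one coding transcript, given a positional bias vector over
# (utr5, start, cds, stop, utr3). Peaks of the pure-region classes lie
# fully inside their region when it is long enough; the codon-proximal
# classes straddle the boundary (centre within +/- codon_flank nt).
.sample_peak_interval <- function(tx_row, bias, len, codon_flank = 50L) {
  u5 <- tx_row$utr5_len; cd <- tx_row$cds_len; L <- tx_row$tx_len
  region <- sample(names(bias), 1L, prob = bias)
  clip <- function(s) max(0L, min(s, L - len))
  if (region %in% c("start", "stop")) {
    a <- if (region == "start") u5 else u5 + cd
    center <- a - codon_flank + sample.int(2L * codon_flank, 1L) - 1L
    s <- clip(center - len %/% 2L)
  } else {
    rng <- switch(region, utr5 = c(0L, u5), cds = c(u5, u5 + cd),
                  utr3 = c(u5 + cd, L))
    if (rng[2] - rng[1] >= len)        # fits: place fully inside the region
      s <- rng[1] + sample.int(rng[2] - rng[1] - len + 1L, 1L) - 1L
    else {                             # short region: centre on it and clip
      center <- rng[1] + sample.int(max(1L, rng[2] - rng[1]), 1L) - 1L
      s <- clip(center - len %/% 2L)
    }
  }
  c(s, s + len)
}

#' Plant m6A peaks, classes and motif copies
#'
#' Selects `frac_methylated` of transcripts as methylated hosts, assigns
#' each host's single peak to the stress-only / control-only / shared class,
#' draws a 150-200 nt peak interval in transcript coordinates with the
#' class's positional bias (non-coding hosts: uniform), and inserts motif
#' copies into peak sequences at `motif_rate_in_peaks` (plus sparse
#' background copies at `motif_rate_background`). Host-transcript effect
#' sizes are recorded: mRNA hosts of stress-only peaks get
#' `lfc_shift_stress_enriched` (lncRNA hosts the negative
#' `lfc_shift_lncRNA_stress`) and `occupancy_shift_stress_enriched`;
#' control-only mRNA hosts get `lfc_shift_control_enriched`.
#'
#' A planted peak's nucleotides always lie in exons; its genomic span may
#' bridge an intron when the host is multi-exonic.
#'
#' @param txome A `sim_transcriptome` from [generate_transcriptome()].
#' @param cfg The same [sim_config()].
#' @return A list with `truth` (list of data.frames `peaks`, `motifs`,
#'   `tx_effects`) and `sequences` (motif-planted `DNAStringSet`).
#' @export
plant_peaks <- function(txome, cfg) {
  set.seed(cfg$seed + 1L)
  anno <- txome$annotation
  tx <- anno$transcripts
  n <- nrow(tx)
  seqs <- as.character(txome$sequences)

  hosts_ok <- which(tx$tx_len >= max(cfg$peak_len_range))
  if (!length(hosts_ok)) stop("no transcript long enough to host a peak")
  n_meth <- round(cfg$frac_methylated * n)
  if (n_meth > length(hosts_ok))
    stop("too few transcripts can host a peak after bounded retries")
  meth <- sort(sample(hosts_ok, n_meth))
  cls <- sample(c("stress", "control", "shared"), n_meth, replace = TRUE,
                prob = c(cfg$frac_stress_only, cfg$frac_control_only,
                         1 - cfg$frac_stress_only - cfg$frac_control_only))

  peak_rows <- vector("list", n_meth)
  motif_rows <- list()
  mot <- cfg$motif; mk <- nchar(mot)
  for (j in seq_len(n_meth)) {
    i <- meth[j]
    row <- tx[i, ]
    len <- sample(seq(cfg$peak_len_range[1], cfg$peak_len_range[2]), 1L)
    se <- if (row$cds_len > 0)
      .sample_peak_interval(row, cfg$positional_bias[[cls[j]]], len)
    else {
      s0 <- sample.int(row$tx_len - len + 1L, 1L) - 1L
      c(s0, s0 + len)
    }
    s <- se[1]; e <- se[2]
    center <- s + len %/% 2L
    blocks <- transcript_blocks_to_genome(anno, row$transcript_id, s, e)
    gsum <- transcript_to_genome(anno, row$transcript_id, center)
    name <- sprintf("planted_%05d", j)
    peak_rows[[j]] <- data.frame(
      name = name, transcript_id = row$transcript_id, class = cls[j],
      chrom = row$chrom, strand = row$strand,
      start = min(blocks$start), end = max(blocks$end),
      tx_start = s, tx_end = e, summit_gpos = gsum,
      stringsAsFactors = FALSE)
    if (stats::runif(1) < cfg$motif_rate_in_peaks) {
      off <- sample.int(len - mk + 1L, 1L) - 1L
      tp <- s + off
      substr(seqs[row$transcript_id], tp + 1L, tp + mk) <- mot
      motif_rows[[length(motif_rows) + 1L]] <-
        data.frame(peak = name, transcript_id = row$transcript_id,
                   tx_offset = tp, peak_offset = off, stringsAsFactors = FALSE)
    }
  }
  peaks <- if (n_meth > 0) do.call(rbind, peak_rows) else
    data.frame(name = character(0), transcript_id = character(0),
               class = character(0), chrom = character(0),
               strand = character(0), start = integer(0), end = integer(0),
               tx_start = integer(0), tx_end = integer(0),
               summit_gpos = integer(0), stringsAsFactors = FALSE)

  # sparse background motif copies outside planted peaks
  for (i in seq_len(n)) {
    if (stats::runif(1) >= cfg$motif_rate_background) next
    id <- tx$transcript_id[i]
    Li <- tx$tx_len[i]
    if (Li < mk) next
    pk <- peaks[peaks$transcript_id == id, , drop = FALSE]
    for (try in 1:10) {
      tp <- sample.int(Li - mk + 1L, 1L) - 1L
      inside <- nrow(pk) && any(tp < pk$tx_end & tp + mk > pk$tx_start)
      if (!inside) {
        substr(seqs[id], tp + 1L, tp + mk) <- mot
        break
      }
    }
  }

  shift_ab <- numeric(n); shift_oc <- numeric(n)
  cat_tx <- rep("none", n)
  cat_tx[meth] <- c(stress = "stress-enriched", control = "control-enriched",
                    shared = "shared")[cls]
  is_stress <- cat_tx == "stress-enriched"
  is_control <- cat_tx == "control-enriched"
  shift_ab[is_stress] <- ifelse(tx$biotype[is_stress] == "lncRNA",
                                cfg$lfc_shift_lncRNA_stress,
                                ifelse(tx$biotype[is_stress] == "mRNA",
                                       cfg$lfc_shift_stress_enriched, 0))
  shift_ab[is_control & tx$biotype == "mRNA"] <- cfg$lfc_shift_control_enriched
  shift_oc[is_stress] <- cfg$occupancy_shift_stress_enriched

  truth <- list(
    peaks = peaks,
    motifs = if (length(motif_rows)) do.call(rbind, motif_rows) else
      data.frame(peak = character(0), transcript_id = character(0),
                 tx_offset = integer(0), peak_offset = integer(0)),
    tx_effects = data.frame(transcript_id = tx$transcript_id,
                            biotype = tx$biotype, category = cat_tx,
                            abundance_shift = shift_ab,
                            occupancy_shift = shift_oc,
                            stringsAsFactors = FALSE))
  list(truth = truth, sequences = Biostrings::DNAStringSet(seqs))
}

# negative-binomial (or Poisson when dispersion == 0) draw
.rcounts <- function(n, mu, dispersion) {
  if (dispersion == 0) stats::rpois(n, mu)
  else stats::rnbinom(n, size = 1 / dispersion, mu = mu)
}

# accumulate `weight * overlap_nt` of genomic block [gs, ge) into per-window
# vector `acc` (windows of width w starting at 0)
.add_block <- function(acc, gs, ge, w, weight) {
  if (ge <= gs) return(acc)
  i0 <- gs %/% w; i1 <- (ge - 1L) %/% w
  idx <- i0:i1
  ov <- pmin(ge, (idx + 1L) * w) - pmax(gs, idx * w)
  acc[idx + 1L] <- acc[idx + 1L] + weight * ov
  acc
}

# per chrom:strand baseline weighted-exonic-nt vectors for the input library
.baseline_profile <- function(anno, chrom_lengths, cfg) {
  w <- cfg$window_size
  keys <- as.vector(outer(names(chrom_lengths), c("+", "-"), .track_key))
  nwin <- ceiling(chrom_lengths / w)
  acc <- stats::setNames(lapply(keys, function(k)
    numeric(nwin[.key_chrom(k)])), keys)
  tx <- anno$transcripts
  rw <- cfg$region_weights
  for (i in seq_len(nrow(tx))) {
    row <- tx[i, ]
    key <- .track_key(row$chrom, row$strand)
    segs <- if (row$cds_len > 0) {
      b <- .tx_segments(row)
      list(c(b$utr5, rw[["utr5"]]), c(b$cds, rw[["cds"]]),
           c(b$utr3, rw[["utr3"]]))
    } else list(c(0, row$tx_len, 1))
    for (sg in segs) {
      if (sg[2] <= sg[1]) next
      blocks <- transcript_blocks_to_genome(anno, row$transcript_id,
                                            sg[1], sg[2])
      for (b in seq_len(nrow(blocks)))
        acc[[key]] <- .add_block(acc[[key]], blocks$start[b], blocks$end[b],
                                 w, sg[3])
    }
  }
  acc
}

# per chrom:strand per-window fraction covered by peaks active in `classes`
.peak_cover_fraction <- function(anno, truth, chrom_lengths, cfg, classes) {
  w <- cfg$window_size
  keys <- as.vector(outer(names(chrom_lengths), c("+", "-"), .track_key))
  nwin <- ceiling(chrom_lengths / w)
  acc <- stats::setNames(lapply(keys, function(k)
    numeric(nwin[.key_chrom(k)])), keys)
  pk <- truth$peaks[truth$peaks$class %in% classes, , drop = FALSE]
  for (j in seq_len(nrow(pk))) {
    blocks <- transcript_blocks_to_genome(anno, pk$transcript_id[j],
                                          pk$tx_start[j], pk$tx_end[j])
    key <- .track_key(pk$chrom[j], pk$strand[j])
    for (b in seq_len(nrow(blocks)))
      acc[[key]] <- .add_block(acc[[key]], blocks$start[b], blocks$end[b],
                               w, 1)
  }
  lapply(acc, function(v) pmin(v / w, 1))
}

#' Simulate windowed IP and input count tracks
#'
#' Input windows draw NB counts with mean `depth x weighted exonic
#' content`; IP windows inside a peak active in the sample's condition have
#' their mean multiplied by `1 + (ip_enrichment - 1) x covered fraction`
#' (shared peaks are active in both conditions, stress-only under copper
#' only, control-only under control only). Three IP and three input
#' replicates are produced per condition.
#'
#' @param txome A `sim_transcriptome`.
#' @param truth Truth object from [plant_peaks()].
#' @param cfg The [sim_config()].
#' @return Named list of [window_tracks] (`ip_control_1`, ...,
#'   `input_copper_3`).
#' @export
simulate_ip_counts <- function(txome, truth, cfg) {
  set.seed(cfg$seed + 2L)
  anno <- txome$annotation
  base <- .baseline_profile(anno, txome$chrom_lengths, cfg)
  w <- cfg$window_size
  mu0 <- lapply(base, function(v) cfg$depth * v / w)
  active <- list(control = c("shared", "control"),
                 copper = c("shared", "stress"))
  out <- list()
  for (cond in c("control", "copper")) {
    frac <- .peak_cover_fraction(anno, truth, txome$chrom_lengths, cfg,
                                 active[[cond]])
    mu_ip <- Map(function(m, f) m * (1 + (cfg$ip_enrichment - 1) * f),
                 mu0, frac)
    for (r in seq_len(cfg$n_ip_reps)) {
      for (ty in c("ip", "input")) {
        mu <- if (ty == "ip") mu_ip else mu0
        cnt <- lapply(mu, function(m) .rcounts(length(m), m, cfg$dispersion))
        out[[paste(ty, cond, r, sep = "_")]] <- window_tracks(cnt, w)
      }
    }
  }
  out
}

#' Simulate RNA-seq and polysome-seq count matrices
#'
#' Per-transcript base means are log-normal; copper RNA means are shifted by
#' the planted `abundance_shift` (log2), and copper polysome means
#' additionally by the planted `occupancy_shift`, so that the polysome/RNA
#' RPM ratio recovers the occupancy effect. Replicate layout is 3 + 3
#' (RNA) and 2 + 2 (polysome).
#'
#' @inheritParams simulate_ip_counts
#' @return List with `rna` and `polysome` `SummarizedExperiment`s (see
#'   [count_se()]).
#' @export
simulate_expression <- function(txome, truth, cfg) {
  set.seed(cfg$seed + 3L)
  eff <- truth$tx_effects
  n <- nrow(eff)
  base <- stats::rlnorm(n, log(cfg$base_mean), cfg$base_sdlog)
  mu_rna <- list(control = base, copper = base * 2^eff$abundance_shift)
  mu_poly <- list(control = base,
                  copper = base * 2^(eff$abundance_shift + eff$occupancy_shift))
  draw <- function(mus, reps) {
    cols <- list(); cond <- character(0); rep_i <- integer(0)
    for (cd in c("control", "copper")) for (r in seq_len(reps)) {
      cols[[length(cols) + 1L]] <- .rcounts(n, mus[[cd]], cfg$dispersion)
      cond <- c(cond, cd); rep_i <- c(rep_i, r)
    }
    m <- do.call(cbind, cols)
    rownames(m) <- eff$transcript_id
    list(m = m, cond = cond, rep = rep_i)
  }
  rna <- draw(mu_rna, cfg$n_rna_reps)
  poly <- draw(mu_poly, cfg$n_poly_reps)
  list(rna = count_se(rna$m, rna$cond, "rna", rna$rep),
       polysome = count_se(poly$m, poly$cond, "polysome", poly$rep))
}

#' Run the full generator
#'
#' Convenience wrapper: transcriptome, planted truth, IP/input tracks and
#' expression matrices in one deterministic call.
#'
#' @param cfg A [sim_config()].
#' @param tracks Set `FALSE` to skip the (comparatively expensive) windowed
#'   coverage simulation when only expression matrices are needed.
#' @return List with `annotation`, `sequences`, `chrom_lengths`, `truth`,
#'   `tracks`, `rna`, `polysome`, `cfg`.
#' @export
simulate_dataset <- function(cfg, tracks = TRUE) {
  txome <- generate_transcriptome(cfg)
  planted <- plant_peaks(txome, cfg)
  txome$sequences <- planted$sequences
  expr <- simulate_expression(txome, planted$truth, cfg)
  list(annotation = txome$annotation, sequences = txome$sequences,
       chrom_lengths = txome$chrom_lengths, truth = planted$truth,
       tracks = if (tracks) simulate_ip_counts(txome, planted$truth, cfg)
                else NULL,
       rna = expr$rna, polysome = expr$polysome, cfg = cfg)
}

#' Write a simulated dataset to disk
#'
#' Emits GTF annotation, transcript FASTA, per-sample strand-split BedGraph
#' window tracks, RNA and polysome count TSVs, and the truth tables
#' (planted peaks, motif positions, per-transcript effects).
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gtf(sim$annotation, file.path(dir, "annotation.gtf"))
  Biostrings::writeXStringSet(sim$sequences, file.path(dir, "transcripts.fa"))
  if (!is.null(sim$tracks)) {
    tdir <- file.path(dir, "tracks")
    dir.create(tdir, showWarnings = FALSE)
    for (nm in names(sim$tracks)) {
      write_bedgraph(sim$tracks[[nm]], "+",
                     file.path(tdir, paste0(nm, ".plus.bedGraph")))
      write_bedgraph(sim$tracks[[nm]], "-",
                     file.path(tdir, paste0(nm, ".minus.bedGraph")))
    }
  }
  write_counts_tsv(sim$rna, file.path(dir, "counts_rna.tsv"))
  write_counts_tsv(sim$polysome, file.path(dir, "counts_polysome.tsv"))
  wt <- function(df, f) utils::write.table(df, file.path(dir, f),
                                           sep = "\t", quote = FALSE,
                                           row.names = FALSE)
  wt(sim$truth$peaks, "truth_peaks.tsv")
  wt(sim$truth$motifs, "truth_motifs.tsv")
  wt(sim$truth$tx_effects, "truth_effects.tsv")
  cfg <- sim$cfg; class(cfg) <- NULL
  cfg$positional_bias <- lapply(cfg$positional_bias, as.list)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
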