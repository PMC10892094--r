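# Brute-force oracles and hand-built fixtures. Everything here is written
# independently of the package's implementation paths (naive per-base /
# per-position loops, direct summation), so agreement is meaningful.

# per-base membership overlap of two 0-based half-open intervals
oracle_overlap <- function(s1, e1, s2, e2) {
  a <- if (e1 > s1) s1:(e1 - 1) else integer(0)
  b <- if (e2 > s2) s2:(e2 - 1) else integer(0)
  length(intersect(a, b))
}

# upper Poisson tail P(X >= k) by direct summation of the pmf
oracle_poisson_tail <- function(k, lambda) {
  if (k <= 0) return(1)
  sum(stats::dpois(k:(k + 2000L), lambda))
}

# rank-sum statistic by all-pairs enumeration (ties count 1/2)
oracle_ranksum <- function(x, y) {
  s <- 0
  for (xi in x) for (yj in y)
    s <- s + (xi > yj) + 0.5 * (xi == yj)
  s
}

# sliding-window k-mer occurrence count
oracle_kmer_count <- function(seqs, kmer) {
  k <- nchar(kmer)
  tot <- 0L
  for (s in as.character(seqs)) {
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1))
      if (substr(s, i, i + k - 1) == kmer) tot <- tot + 1L
  }
  tot
}

# naive per-base consensus: peaks_list is a list of data.frames
# (start, end, strand on one chromosome); returns data.frame of consensus
# intervals (union of members of each left-to-right core run, members
# consumed at most once)
oracle_consensus <- function(peaks_list, strand = "+") {
  peaks_list <- lapply(peaks_list, function(d)
    d[d$strand == strand, , drop = FALSE])
  if (any(vapply(peaks_list, nrow, 0L) == 0))
    return(data.frame(start = integer(0), end = integer(0)))
  maxpos <- max(vapply(peaks_list, function(d) max(d$end), 0))
  covered <- matrix(FALSE, nrow = maxpos, ncol = length(peaks_list))
  for (r in seq_along(peaks_list)) {
    d <- peaks_list[[r]]
    for (i in seq_len(nrow(d)))
      covered[(d$start[i] + 1):d$end[i], r] <- TRUE
  }
  core <- which(rowSums(covered) == length(peaks_list))  # 1-based positions
  if (!length(core)) return(data.frame(start = integer(0), end = integer(0)))
  runs <- split(core, cumsum(c(1, diff(core) > 1)))
  used <- lapply(peaks_list, function(d) rep(FALSE, nrow(d)))
  out <- list()
  for (run in runs) {
    lo <- min(run) - 1L; hi <- max(run)      # back to 0-based half-open
    members <- list(); ok <- TRUE
    for (r in seq_along(peaks_list)) {
      d <- peaks_list[[r]]
      hit <- which(!used[[r]] & d$start < hi & d$end > lo)
      if (!length(hit)) { ok <- FALSE; break }
      members[[r]] <- hit
    }
    if (!ok) next
    for (r in seq_along(members)) used[[r]][members[[r]]] <- TRUE
    allm <- do.call(rbind, Map(function(d, idx) d[idx, c("start", "end")],
                               peaks_list, members))
    out[[length(out) + 1L]] <- data.frame(start = min(allm$start),
                                          end = max(allm$end))
  }
  do.call(rbind, out)
}

# naive classification: for each stress interval, shared iff any control
# interval shares a base on the same strand
oracle_classify <- function(stress, control) {
  lab <- character(nrow(stress))
  for (i in seq_len(nrow(stress))) {
    hit <- FALSE
    for (j in seq_len(nrow(control))) {
      if (stress$strand[i] == control$strand[j] &&
          stress$chrom[i] == control$chrom[j] &&
          oracle_overlap(stress$start[i], stress$end[i],
                         control$start[j], control$end[j]) > 0) {
        hit <- TRUE; break
      }
    }
    lab[i] <- if (hit) "shared" else "stress-enriched"
  }
  lab
}

# independent genomic-position map of a transcript: vector g such that
# g[t + 1] is the genomic position of transcript offset t (built by walking
# the exon table directly)
oracle_tx_map <- function(anno, transcript_id) {
  e <- anno$exons[anno$exons$transcript_id == transcript_id, , drop = FALSE]
  e <- e[order(e$exon_rank), , drop = FALSE]
  unlist(lapply(seq_len(nrow(e)), function(i) {
    if (e$strand[i] == "+") e$start[i]:(e$end[i] - 1)
    else (e$end[i] - 1):e$start[i]
  }))
}

# per-position frequency recount: for each relative position, count unique
# peaks of the category covering it on any category transcript
oracle_frequency <- function(cat_peaks, tx_cat, anno, anchor, flank = 100L) {
  tx <- anno$transcripts
  positions <- seq(-flank, flank)
  cats <- c("stress-enriched", "control-enriched", "shared")
  out <- list()
  for (cat in cats) {
    ids <- tx_cat$transcript_id[tx_cat$category == cat]
    ids <- ids[tx$cds_len[match(ids, tx$transcript_id)] > 0]
    counts <- setNames(numeric(length(positions)), positions)
    for (pos in positions) {
      seen <- character(0)
      for (id in ids) {
        row <- tx[match(id, tx$transcript_id), ]
        a <- if (anchor == "start") row$utr5_len else
          row$utr5_len + row$cds_len - 3L
        t_off <- a + pos
        if (t_off < 0 || t_off >= row$tx_len) next
        g <- oracle_tx_map(anno, id)[t_off + 1]
        pk <- cat_peaks[cat_peaks$category == cat, , drop = FALSE]
        for (j in seq_len(nrow(pk)))
          if (pk$chrom[j] == row$chrom && pk$strand[j] == row$strand &&
              g >= pk$start[j] && g < pk$end[j])
            seen <- union(seen, pk$name[j])
      }
      counts[as.character(pos)] <- length(seen)
    }
    out[[cat]] <- counts / max(1, length(ids)) * ifelse(length(ids) > 0, 1, 0)
  }
  out
}

# hand-built three-transcript annotation: multi-exon plus / minus coding
# transcripts and a single-exon lncRNA, all on chr1
make_tiny_anno <- function() {
  txs <- data.frame(
    transcript_id = c("tplus", "tminus", "tnc"),
    gene_id = c("g1", "g2", "g3"),
    chrom = "chr1", strand = c("+", "-", "+"),
    start = c(100L, 500L, 900L), end = c(400L, 800L, 1200L),
    biotype = c("mRNA", "mRNA", "lncRNA"),
    utr5_len = c(50L, 40L, 0L), cds_len = c(100L, 120L, 0L),
    utr3_len = c(50L, 40L, 0L), stringsAsFactors = FALSE)
  exs <- data.frame(
    transcript_id = c("tplus", "tplus", "tminus", "tminus", "tnc"),
    chrom = "chr1",
    strand = c("+", "+", "-", "-", "+"),
    start = c(100L, 300L, 500L, 700L, 900L),
    end = c(200L, 400L, 600L, 800L, 1200L),
    exon_rank = c(1L, 2L, 2L, 1L, 1L), stringsAsFactors = FALSE)
  tx_annotation(txs, exs)
}

# random peak tables on one chromosome for oracle-equivalence tests
random_peak_df <- function(n, max_pos = 4000L, strand_opts = c("+", "-")) {
  start <- sample.int(max_pos, n) - 1L
  len <- sample(50:250, n, replace = TRUE)
  data.frame(chrom = "chr1", start = start, end = start + len,
             strand = sample(strand_opts, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

as_peaks <- function(df, prefix = "p") {
  peak_table(df$chrom, df$start, df$end,
             sprintf("%s_%04d", prefix, seq_len(nrow(df))), df$strand,
             enrichment = rep(2, nrow(df)), pvalue = rep(0.01, nrow(df)),
             summit = (df$end - df$start) %/% 2L)
}
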