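#' Extract spliced peak sequences
#'
#' Returns the transcript-orientation sequence of each peak region by
#' mapping the peak's genomic interval onto its host transcript and taking
#' the corresponding substring of the (already 5'->3') transcript sequence:
#' minus-strand peaks therefore come out reverse-complemented relative to
#' the genome, and peaks spanning an exon junction come out
#' junction-spliced with length equal to their exonic overlap. When a peak
#' overlaps several transcripts the host with the largest exonic overlap
#' (ties: smallest id) is used; peaks overlapping no exon are skipped with
#' a warning.
#'
#' @param peaks A peak table.
#' @param anno A [tx_annotation].
#' @param sequences Named `DNAStringSet` of transcript sequences.
#' @return Named `DNAStringSet` (names = peak names).
#' @export
extract_peak_sequences <- function(peaks, anno, sequences) {
  if (!nrow(peaks)) return(Biostrings::DNAStringSet())
  pairs <- peak_transcript_overlaps(peaks, anno)
  out <- character(0)
  skipped <- 0L
  for (i in seq_len(nrow(peaks))) {
    pk <- peaks[i, ]
    cand <- sort(pairs$transcript_id[pairs$name == pk$name])
    if (!length(cand)) { skipped <- skipped + 1L; next }
    best <- NULL; best_ov <- -1L
    for (id in cand) {
      tp <- .peak_tx_positions(anno, id, pk$start, pk$end)
      if (length(tp) > best_ov) { best <- list(id = id, tp = tp); best_ov <- length(tp) }
    }
    s <- as.character(sequences[[best$id]])
    out[pk$name] <- substr(s, min(best$tp) + 1L, max(best$tp) + 1L)
  }
  if (skipped) warning(skipped, " peak(s) outside exons skipped")
  Biostrings::DNAStringSet(out)
}

# Altschul-Erickson dinucleotide-preserving shuffle of one sequence
# (random Eulerian path on the dinucleotide multigraph; preserves mono- and
# di-nucleotide composition and the first/last residue exactly)
.dinuc_shuffle_one <- function(ch) {
  n <- length(ch)
  if (n <= 3) return(ch)
  verts <- unique(ch)
  last <- ch[n]
  edges <- split(ch[-1], factor(ch[-n], levels = verts))
  sources <- verts[vapply(edges, length, 0L) > 0]
  # terminal edge per non-last vertex, resampled until they form a tree
  # converging on `last`
  repeat {
    term <- stats::setNames(rep(NA_character_, length(verts)), verts)
    for (v in sources)
      if (v != last) term[v] <- edges[[v]][sample.int(length(edges[[v]]), 1L)]
    ok <- TRUE
    for (v in setdiff(sources, last)) {
      cur <- v; hops <- 0L
      while (cur != last) {
        cur <- term[[cur]]
        hops <- hops + 1L
        if (is.na(cur) || hops > length(verts)) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) break
  }
  elists <- stats::setNames(vector("list", length(verts)), verts)
  for (v in verts) {
    e <- edges[[v]]
    if (!length(e)) next
    elists[[v]] <- if (v == last) e[sample.int(length(e))] else {
      i <- match(term[[v]], e)
      rest <- e[-i]
      c(if (length(rest)) rest[sample.int(length(rest))], term[[v]])
    }
  }
  out <- character(n)
  out[1] <- cur <- ch[1]
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  for (i in 2:n) {
    nxt <- elists[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- cur <- nxt
  }
  out
}

#' Dinucleotide-preserving sequence shuffles
#'
#' @param seqs Character vector or `DNAStringSet`.
#' @param n_shuffles Shuffles per sequence.
#' @param seed Integer seed (deterministic output).
#' @return Character vector of length `length(seqs) * n_shuffles`.
#' @export
dinuc_shuffle <- function(seqs, n_shuffles = 100L, seed = 1L) {
  set.seed(seed)
  seqs <- as.character(seqs)
  split_seqs <- strsplit(seqs, "")
  out <- character(length(seqs) * n_shuffles)
  k <- 1L
  for (ch in split_seqs) for (j in seq_len(n_shuffles)) {
    out[k] <- paste(.dinuc_shuffle_one(ch), collapse = "")
    k <- k + 1L
  }
  out
}

#' k-mer enrichment of peak sequences against a shuffled background
#'
#' Counts every k-mer (sliding window) in the foreground sequences and in
#' `n_shuffles` dinucleotide-preserving shuffles of them, estimates the
#' background per-position rate (with a 0.5 pseudocount), and scores each
#' k-mer with an upper-tail binomial test of the foreground occurrence
#' count over foreground positions. P-values are Benjamini-Hochberg
#' adjusted across all tested k-mers and results ranked by p-value, ties
#' broken by enrichment fold then lexicographically, so output order is
#' deterministic.
#'
#' @param fg Foreground sequences (character or `DNAStringSet`), e.g. from
#'   [extract_peak_sequences()].
#' @param k Vector of k-mer lengths (default 4:6). Sequences shorter than
#'   k contribute no positions for that k.
#' @param n_shuffles Background shuffles per sequence.
#' @param seed Integer seed for the shuffles.
#' @return data.frame `kmer`, `k`, `fg_count`, `bg_count`, `fg_rate`,
#'   `bg_rate`, `enrichment`, `pvalue`, `padj`, `rank` (sorted by rank).
#' @export
kmer_enrichment <- function(fg, k = 4:6, n_shuffles = 100L, seed = 1L) {
  fg <- Biostrings::DNAStringSet(as.character(fg))
  if (!length(fg)) stop("empty foreground")
  bg <- Biostrings::DNAStringSet(dinuc_shuffle(fg, n_shuffles, seed))
  res <- list()
  for (kk in sort(unique(as.integer(k)))) {
    fg_tab <- colSums(Biostrings::oligonucleotideFrequency(fg, width = kk))
    bg_tab <- colSums(Biostrings::oligonucleotideFrequency(bg, width = kk))
    fg_n <- sum(pmax(0L, Biostrings::width(fg) - kk + 1L))
    bg_n <- sum(pmax(0L, Biostrings::width(bg) - kk + 1L))
    if (fg_n == 0) next
    rate <- (bg_tab + 0.5) / (bg_n + 1)
    pv <- stats::pbinom(fg_tab - 1, fg_n, rate, lower.tail = FALSE)
    res[[as.character(kk)]] <- data.frame(
      kmer = names(fg_tab), k = kk,
      fg_count = as.integer(fg_tab), bg_count = as.integer(bg_tab),
      fg_rate = as.numeric(fg_tab) / fg_n, bg_rate = rate,
      enrichment = (as.numeric(fg_tab) / fg_n) / rate,
      pvalue = pv, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$padj <- stats::p.adjust(out$pvalue, method = "BH")
  ord <- order(out$pvalue, -out$enrichment, out$kmer)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
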