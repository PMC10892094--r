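# mean density per nt of each of B equal bins over a per-nt density vector,
# with fractional-nt weighting at bin edges (exact for any L, B)
.bin_fractional <- function(d, B) {
  L <- length(d)
  cs <- c(0, cumsum(d))
  S <- function(x) {  # integral of the step function from 0 to x
    i <- pmin(floor(x), L - 1)
    cs[i + 1] + d[i + 1] * (x - i)
  }
  edges <- seq(0, L, length.out = B + 1)
  vals <- S(edges)
  diff(vals) / (L / B)
}

# per-nt coverage of one transcript in transcript orientation, from a
# window_tracks object (density level = count of the covering window)
.tx_density <- function(anno, transcript_id, tracks) {
  e <- .tx_exons(anno, transcript_id)
  w <- tracks$window_size
  out <- numeric(sum(e$end - e$start))
  pos <- 1L
  for (i in seq_len(nrow(e))) {
    g <- if (e$strand[i] == "+") seq(e$start[i], e$end[i] - 1L)
         else seq(e$end[i] - 1L, e$start[i])
    key <- .track_key(e$chrom[i], e$strand[i])
    v <- tracks$counts[[key]]
    idx <- g %/% w + 1L
    cov <- numeric(length(idx))
    ok <- idx <= length(v)
    cov[ok] <- v[idx[ok]]
    out[pos:(pos + length(g) - 1L)] <- cov
    pos <- pos + length(g)
  }
  out
}

#' Binned metagene density profile over 5'UTR / CDS / 3'UTR
#'
#' For every coding transcript with all three regions of nonzero length,
#' per-nucleotide read density (the covering window's count) is normalised
#' by the transcript's total density, each region is divided into a fixed
#' number of equal bins with fractional-nt weighting at the edges, and the
#' profile is averaged over transcripts. Computed per library (call once
#' for IP and once for input to compare their shapes). Transcripts missing
#' a region, or with zero coverage, are excluded and counted in the
#' `excluded` attribute.
#'
#' The profile is invariant to transcript order and to scaling all counts
#' by a constant.
#'
#' @param tracks A [window_tracks] library.
#' @param anno A [tx_annotation].
#' @param bins_per_region Bins per region in `count` mode (default 20).
#' @param bin_mode `"count"`: fixed bin count per region (variable-length
#'   UTRs share one axis); `"width"`: bin count derived from the mean
#'   region length divided by `bin_width`.
#' @param bin_width Bin width (nt) for `width` mode.
#' @return data.frame `region`, `bin` (global index), `density`, with
#'   attributes `n_transcripts` and `excluded`.
#' @export
metagene_density <- function(tracks, anno, bins_per_region = 20L,
                             bin_mode = c("count", "width"),
                             bin_width = 100L) {
  bin_mode <- match.arg(bin_mode)
  tx <- anno$transcripts
  use <- tx$utr5_len > 0 & tx$cds_len > 0 & tx$utr3_len > 0
  excluded <- sum(!use)
  if (excluded)
    message(excluded, " transcript(s) without all three regions excluded")
  tx <- tx[use, , drop = FALSE]
  if (!nrow(tx)) stop("no coding transcripts with all three regions")
  B <- if (bin_mode == "count") rep(as.integer(bins_per_region), 3)
       else pmax(1L, as.integer(round(c(mean(tx$utr5_len), mean(tx$cds_len),
                                        mean(tx$utr3_len)) / bin_width)))
  acc <- list(numeric(B[1]), numeric(B[2]), numeric(B[3]))
  n_used <- 0L
  for (i in seq_len(nrow(tx))) {
    row <- tx[i, ]
    d <- .tx_density(anno, row$transcript_id, tracks)
    tot <- sum(d)
    if (tot == 0) { excluded <- excluded + 1L; next }
    d <- d / tot
    seg <- .tx_segments(row)
    for (r in 1:3) {
      rg <- seg[[r]]
      acc[[r]] <- acc[[r]] + .bin_fractional(d[(rg[1] + 1L):rg[2]], B[r])
    }
    n_used <- n_used + 1L
  }
  if (n_used == 0) stop("no transcript with nonzero coverage")
  regions <- c("utr5", "cds", "utr3")
  out <- do.call(rbind, lapply(1:3, function(r)
    data.frame(region = regions[r],
               bin = if (r == 1) seq_len(B[1]) else sum(B[seq_len(r - 1)]) +
                 seq_len(B[r]),
               density = acc[[r]] / n_used, stringsAsFactors = FALSE)))
  attr(out, "n_transcripts") <- n_used
  attr(out, "excluded") <- excluded
  out
}

# transcript-coordinate positions of a peak on one transcript (exonic only)
.peak_tx_positions <- function(anno, transcript_id, pstart, pend) {
  tp <- genome_to_transcript(anno, transcript_id, seq(pstart, pend - 1L))
  sort(tp[!is.na(tp)])
}

#' Per-nucleotide methylation frequency around start/stop codons
#'
#' For each m6A category and each transcript-coordinate position p in
#' `[anchor - flank, anchor + flank]`, the raw frequency is the number of
#' unique peaks of the category overlapping p on any of the category's
#' (coding) transcripts, divided by the number of methylated transcripts in
#' the category; each category's profile is then normalised to its maximum
#' over the window. Position 0 is the first nucleotide of the start or
#' stop codon.
#'
#' @param cat_peaks Categorised peak table ([classify_peaks()]).
#' @param tx_categories Transcript labels ([assign_to_transcripts()]).
#' @param anno A [tx_annotation].
#' @param anchor `"start"` or `"stop"` codon.
#' @param flank Window half-width, nt (default 100).
#' @param denominator `"category"`: the category's methylated coding
#'   transcripts (declared default); `"all"`: all methylated coding
#'   transcripts.
#' @return data.frame `category`, `anchor`, `position`, `raw`,
#'   `normalized`. Empty categories yield all-zero profiles flagged via the
#'   `empty_categories` attribute.
#' @export
positional_frequency <- function(cat_peaks, tx_categories, anno,
                                 anchor = c("start", "stop"), flank = 100L,
                                 denominator = c("category", "all")) {
  anchor <- match.arg(anchor)
  denominator <- match.arg(denominator)
  tx <- anno$transcripts
  coding_ids <- tx$transcript_id[tx$cds_len > 0]
  cats <- c("stress-enriched", "control-enriched", "shared")
  pairs <- peak_transcript_overlaps(cat_peaks, anno)
  pairs$category <- cat_peaks$category[match(pairs$name, cat_peaks$name)]
  pairs <- pairs[pairs$transcript_id %in% coding_ids, , drop = FALSE]
  # keep peak-transcript pairs whose transcript carries the same category
  tx_cat <- tx_categories$category[match(pairs$transcript_id,
                                         tx_categories$transcript_id)]
  pairs <- pairs[!is.na(tx_cat) & tx_cat == pairs$category, , drop = FALSE]
  n_all <- length(intersect(tx_categories$transcript_id, coding_ids))
  positions <- seq(-flank, flank)
  res <- list(); empty <- character(0)
  for (cat in cats) {
    denom <- if (denominator == "all") n_all else
      sum(tx_categories$category == cat &
            tx_categories$transcript_id %in% coding_ids)
    sub <- pairs[pairs$category == cat, , drop = FALSE]
    hits <- character(0)
    for (j in seq_len(nrow(sub))) {
      id <- sub$transcript_id[j]
      row <- tx[match(id, tx$transcript_id), ]
      a <- if (anchor == "start") row$utr5_len else
        row$utr5_len + row$cds_len - 3L
      pk <- cat_peaks[match(sub$name[j], cat_peaks$name), ]
      rel <- .peak_tx_positions(anno, id, pk$start, pk$end) - a
      rel <- rel[rel >= -flank & rel <= flank]
      if (length(rel)) hits <- c(hits, paste(sub$name[j], rel))
    }
    cnt <- table(factor(as.integer(sub(".* ", "", unique(hits))),
                        levels = positions))
    raw <- if (denom > 0) as.numeric(cnt) / denom else numeric(length(positions))
    if (denom == 0 || all(raw == 0)) empty <- c(empty, cat)
    normalized <- if (max(raw) > 0) raw / max(raw) else raw
    res[[cat]] <- data.frame(category = cat, anchor = anchor,
                             position = positions, raw = raw,
                             normalized = normalized,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "empty_categories") <- empty
  out
}

# feature of a transcript-coordinate position on a transcript row
.tx_feature <- function(tx_row, tpos) {
  if (tx_row$cds_len == 0) return("noncoding")
  u5 <- tx_row$utr5_len; ce <- u5 + tx_row$cds_len
  if (tpos < u5) "utr5"
  else if (tpos < u5 + 3L) "start_codon"
  else if (tpos < ce - 3L) "cds"
  else if (tpos < ce) "stop_codon"
  else "utr3"
}

#' Percent breakdown of peaks by transcript feature
#'
#' Each peak votes once per category according to the feature at its summit
#' (`summit` rule): 5'UTR, the 3-nt start codon, CDS, the 3-nt stop codon
#' or 3'UTR of its host transcript (the transcript whose exons contain the
#' summit; ties broken by transcript id). With `rule = "overlap"` a peak
#' casts one vote for every feature its transcript-coordinate span touches.
#' Summits on non-coding hosts vote `noncoding`; summits in no transcript
#' vote `other`. Percentages sum to 100 within each category.
#'
#' @inheritParams positional_frequency
#' @param rule Feature assignment rule (see above).
#' @return data.frame `category`, `feature`, `count`, `percent`.
#' @export
feature_breakdown <- function(cat_peaks, anno,
                              rule = c("summit", "overlap")) {
  rule <- match.arg(rule)
  tx <- anno$transcripts
  feats <- c("utr5", "start_codon", "cds", "stop_codon", "utr3",
             "noncoding", "other")
  if (!nrow(cat_peaks))
    return(data.frame(category = character(0), feature = character(0),
                      count = integer(0), percent = numeric(0)))
  pairs <- peak_transcript_overlaps(cat_peaks, anno)
  votes <- list()
  for (i in seq_len(nrow(cat_peaks))) {
    pk <- cat_peaks[i, ]
    cand <- pairs$transcript_id[pairs$name == pk$name]
    gsum <- pk$start + pk$summit
    host <- NA_character_; tsum <- NA_integer_
    for (id in sort(cand)) {
      tp <- genome_to_transcript(anno, id, gsum)
      if (!is.na(tp)) { host <- id; tsum <- tp; break }
    }
    f <- if (is.na(host)) "other" else {
      row <- tx[match(host, tx$transcript_id), ]
      if (rule == "summit") .tx_feature(row, tsum)
      else unique(vapply(.peak_tx_positions(anno, host, pk$start, pk$end),
                         function(p) .tx_feature(row, p), ""))
    }
    votes[[i]] <- data.frame(category = pk$category, feature = f,
                             stringsAsFactors = FALSE)
  }
  v <- do.call(rbind, votes)
  out <- do.call(rbind, lapply(unique(v$category), function(cat) {
    tb <- table(factor(v$feature[v$category == cat], levels = feats))
    data.frame(category = cat, feature = feats, count = as.integer(tb),
               percent = 100 * as.integer(tb) / sum(tb),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
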