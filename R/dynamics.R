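#' High-confidence consensus peaks across replicates
#'
#' A consensus peak is emitted wherever all replicates of a condition carry
#' mutually overlapping peaks on the same strand. Pairwise-overlapping 1D
#' intervals always share a common base (Helly property), so consensus
#' seeds are exactly the runs of bases covered by every replicate; each
#' seed's consensus interval is the union of its member peaks (one or more
#' per replicate), and a member peak joins at most one consensus (seeds are
#' processed left to right). Peaks present in fewer than all replicates
#' never form a consensus.
#'
#' @param rep_peaks List of peak tables, one per replicate of a single
#'   condition (typically 3).
#' @param condition Condition label stored with the result.
#' @param min_overlap_frac Optional stricter membership rule: a member must
#'   overlap the consensus seed by at least this fraction of its own length
#'   (default 0 = any overlap of >= 1 nt).
#' @return A peak table with extra columns `condition`, `n_members` and
#'   `members` (member peak names, `;`-separated). The reported summit and
#'   p-value are those of the most significant member; the enrichment is
#'   the member mean.
#' @export
consensus_peaks <- function(rep_peaks, condition = "condition",
                            min_overlap_frac = 0) {
  stopifnot(length(rep_peaks) >= 1)
  n_rep <- length(rep_peaks)
  all_pk <- do.call(rbind, Map(function(pk, r) {
    if (!nrow(pk)) return(NULL)
    pk2 <- as.data.frame(pk)[, c("chrom", "start", "end", "name", "strand",
                                 "enrichment", "pvalue", "summit")]
    pk2$rep <- r
    pk2
  }, rep_peaks, seq_len(n_rep)))
  out <- list()
  if (!is.null(all_pk)) {
    for (key in sort(unique(.track_key(all_pk$chrom, all_pk$strand)))) {
      sub <- all_pk[.track_key(all_pk$chrom, all_pk$strand) == key, ,
                    drop = FALSE]
      if (length(unique(sub$rep)) < n_rep) next
      ir <- function(d) IRanges::IRanges(d$start + 1L, d$end)
      core <- Reduce(IRanges::intersect,
                     lapply(split(sub, sub$rep),
                            function(d) IRanges::reduce(ir(d))))
      if (!length(core)) next
      core <- core[order(IRanges::start(core))]
      used <- rep(FALSE, nrow(sub))
      for (ci in seq_along(core)) {
        ov <- IRanges::overlapsAny(ir(sub), core[ci])
        if (min_overlap_frac > 0) {
          w_ov <- IRanges::width(IRanges::pintersect(
            ir(sub), rep(core[ci], nrow(sub)), resolve.empty = "max.start"))
          ov <- ov & (w_ov >= min_overlap_frac * (sub$end - sub$start))
        }
        mem <- which(ov & !used)
        if (length(unique(sub$rep[mem])) < n_rep) next
        used[mem] <- TRUE
        m <- sub[mem, , drop = FALSE]
        best <- which.min(m$pvalue)[1]
        cs <- min(m$start); ce <- max(m$end)
        out[[length(out) + 1L]] <- data.frame(
          chrom = .key_chrom(key), start = cs, end = ce,
          strand = .key_strand(key),
          enrichment = mean(m$enrichment), pvalue = min(m$pvalue),
          summit = m$start[best] + m$summit[best] - cs,
          n_members = nrow(m),
          members = paste(m$name, collapse = ";"), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    res <- empty_peaks()
    res$condition <- character(0); res$n_members <- integer(0)
    res$members <- character(0)
    return(res)
  }
  df <- do.call(rbind, out)
  res <- peak_table(df$chrom, df$start, df$end,
                    sprintf("cons_%s_%05d", condition, seq_len(nrow(df))),
                    df$strand, df$enrichment, df$pvalue, df$summit)
  res$condition <- condition
  res$n_members <- df$n_members
  res$members <- df$members
  res
}

#' Classify consensus peaks as stress-enriched, control-enriched or shared
#'
#' A stress-side consensus peak overlapping (>= 1 nt, same strand) any
#' control-side consensus peak is `shared`, and vice versa; peaks without a
#' cross-condition counterpart are condition-specific. Shared peaks are
#' reported once, using the stress-side coordinates, so the categories
#' partition the distinct consensus peaks.
#'
#' @param control_cons,stress_cons Consensus peak tables from
#'   [consensus_peaks()] for the control and stress conditions.
#' @return A peak table with a `category` column over
#'   `{stress-enriched, control-enriched, shared}`.
#' @export
classify_peaks <- function(control_cons, stress_cons) {
  hit_s <- .overlaps_any(stress_cons, control_cons)
  hit_c <- .overlaps_any(control_cons, stress_cons)
  s <- as.data.frame(stress_cons)
  s$category <- ifelse(hit_s, "shared", "stress-enriched")
  cdf <- as.data.frame(control_cons)[!hit_c, , drop = FALSE]
  if (nrow(cdf)) cdf$category <- "control-enriched"
  keep <- c("chrom", "start", "end", "name", "strand", "enrichment",
            "pvalue", "summit", "category")
  out <- rbind(s[, keep, drop = FALSE],
               if (nrow(cdf)) cdf[, keep, drop = FALSE])
  rownames(out) <- NULL
  class(out) <- c("m6a_peaks", "data.frame")
  out
}

# same-strand >=1 nt overlap indicator of a against b
.overlaps_any <- function(a, b) {
  if (!nrow(a)) return(logical(0))
  if (!nrow(b)) return(rep(FALSE, nrow(a)))
  ga <- .peaks_granges(a); gb <- .peaks_granges(b)
  GenomicRanges::countOverlaps(ga, gb, ignore.strand = FALSE) > 0
}

#' Exonic peak-to-transcript overlaps
#'
#' Pairs every peak with every transcript whose exons it overlaps on the
#' same strand (>= 1 nt).
#'
#' @param peaks A peak table.
#' @param anno A [tx_annotation].
#' @return data.frame with columns `name` (peak) and `transcript_id`.
#' @export
peak_transcript_overlaps <- function(peaks, anno) {
  if (!nrow(peaks))
    return(data.frame(name = character(0), transcript_id = character(0)))
  gp <- .peaks_granges(peaks)
  ge <- .exons_granges(anno)
  h <- GenomicRanges::findOverlaps(gp, ge, ignore.strand = FALSE)
  df <- unique(data.frame(
    name = peaks$name[S4Vectors::queryHits(h)],
    transcript_id = ge$transcript_id[S4Vectors::subjectHits(h)],
    stringsAsFactors = FALSE))
  rownames(df) <- NULL
  df
}

#' Label transcripts by the m6A category of their peaks
#'
#' Each peak is assigned to every transcript whose exons it overlaps on the
#' same strand. A transcript is `stress-enriched` if it hosts at least one
#' stress-enriched peak, otherwise `control-enriched` if it hosts a
#' control-enriched peak, otherwise `shared` (precedence
#' stress > control > shared). Transcripts without peaks are absent from
#' the result. Peaks overlapping no transcript are counted in the
#' `intergenic` attribute and reported with a message.
#'
#' @param cat_peaks Categorised peak table from [classify_peaks()].
#' @param anno A [tx_annotation].
#' @return data.frame `transcript_id`, `biotype`, `category`, `n_peaks`,
#'   with attribute `intergenic` (peak names overlapping no transcript).
#' @export
assign_to_transcripts <- function(cat_peaks, anno) {
  pairs <- peak_transcript_overlaps(cat_peaks, anno)
  orphan <- setdiff(cat_peaks$name, pairs$name)
  if (length(orphan))
    message(length(orphan), " peak(s) overlap no transcript (intergenic)")
  pairs$category <- cat_peaks$category[match(pairs$name, cat_peaks$name)]
  prec <- c("stress-enriched" = 1L, "control-enriched" = 2L, "shared" = 3L)
  agg <- split(pairs, pairs$transcript_id)
  out <- data.frame(
    transcript_id = names(agg),
    category = vapply(agg, function(d)
      names(prec)[min(prec[d$category])], ""),
    n_peaks = vapply(agg, nrow, 0L),
    stringsAsFactors = FALSE)
  out$biotype <- anno$transcripts$biotype[
    match(out$transcript_id, anno$transcripts$transcript_id)]
  out <- out[order(out$transcript_id), c("transcript_id", "biotype",
                                         "category", "n_peaks")]
  rownames(out) <- NULL
  attr(out, "intergenic") <- orphan
  out
}

#' Non-coding RNA biotype breakdown by m6A category
#'
#' Counts unique methylated non-coding transcripts per biotype, split by
#' m6A category.
#'
#' @param tx_categories Output of [assign_to_transcripts()].
#' @return data.frame with one row per non-coding biotype, columns per
#'   category plus `total`, sorted by decreasing total.
#' @export
ncrna_breakdown <- function(tx_categories) {
  nc <- tx_categories[tx_categories$biotype != "mRNA", , drop = FALSE]
  cats <- c("stress-enriched", "control-enriched", "shared")
  if (!nrow(nc)) {
    out <- data.frame(biotype = character(0))
    for (cat in cats) out[[cat]] <- integer(0)
    out$total <- integer(0)
    return(out)
  }
  tab <- table(factor(nc$biotype), factor(nc$category, levels = cats))
  out <- data.frame(biotype = rownames(tab), stringsAsFactors = FALSE)
  for (cat in cats) out[[cat]] <- as.integer(tab[, cat])
  out$total <- as.integer(rowSums(tab))
  out <- out[order(-out$total, out$biotype), , drop = FALSE]
  rownames(out) <- NULL
  out
}
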