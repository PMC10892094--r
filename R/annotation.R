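#' Transcript annotation container
#'
#' Bundles a transcript table and an exon table into the annotation object
#' used throughout the package. All coordinates are 0-based half-open (BED
#' convention); GTF/GFF3 1-based inclusive coordinates are converted at the
#' file boundary by [read_annotation()].
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `start`, `end`, `biotype`, `utr5_len`, `cds_len`,
#'   `utr3_len`. For non-coding transcripts `utr5_len` and `utr3_len` are 0
#'   and `cds_len` is 0; `tx_len` (spliced length) is recomputed from exons.
#' @param exons data.frame with columns `transcript_id`, `chrom`, `strand`,
#'   `start`, `end`, `exon_rank` where rank 1 is the 5'-most exon in
#'   transcript orientation.
#'
#' @return An object of class `tx_annotation`: a list with elements
#'   `transcripts` and `exons`.
#' @export
tx_annotation <- function(transcripts, exons) {
  need_tx <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end",
               "biotype", "utr5_len", "cds_len", "utr3_len")
  need_ex <- c("transcript_id", "chrom", "strand", "start", "end", "exon_rank")
  stopifnot(all(need_tx %in% names(transcripts)), all(need_ex %in% names(exons)))
  if (anyDuplicated(transcripts$transcript_id))
    stop("duplicated transcript_id in annotation")
  if (!all(transcripts$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(exons$end <= exons$start))
    stop("exon with start >= end")
  exons <- exons[order(exons$transcript_id, exons$exon_rank), , drop = FALSE]
  # spliced length and basic structural invariants
  widths <- exons$end - exons$start
  tx_len <- tapply(widths, exons$transcript_id, sum)
  transcripts$tx_len <- as.integer(tx_len[transcripts$transcript_id])
  if (any(is.na(transcripts$tx_len)))
    stop("transcript without exons: ",
         paste(transcripts$transcript_id[is.na(transcripts$tx_len)], collapse = ", "))
  coding <- transcripts$cds_len > 0
  bad <- coding & (transcripts$utr5_len + transcripts$cds_len +
                     transcripts$utr3_len != transcripts$tx_len)
  if (any(bad))
    stop("UTR + CDS lengths do not sum to transcript length for: ",
         paste(transcripts$transcript_id[bad], collapse = ", "))
  og <- order(exons$transcript_id, exons$start)
  same <- exons$transcript_id[og][-1] == exons$transcript_id[og][-length(og)]
  if (any(same & exons$start[og][-1] < exons$end[og][-length(og)]))
    stop("overlapping exons in transcript ",
         exons$transcript_id[og][-1][same &
           exons$start[og][-1] < exons$end[og][-length(og)]][1])
  # precomputed spliced offsets (exons are sorted by rank within transcript)
  exons$cum_before <- stats::ave(exons$end - exons$start,
                                 exons$transcript_id,
                                 FUN = function(w) cumsum(c(0L, w[-length(w)])))
  rownames(transcripts) <- transcripts$transcript_id
  structure(list(transcripts = transcripts, exons = exons,
                 exon_index = split(seq_len(nrow(exons)),
                                    exons$transcript_id)),
            class = "tx_annotation")
}

#' @export
print.tx_annotation <- function(x, ...) {
  cat(sprintf("tx_annotation: %d transcripts, %d exons, %d chromosome(s)\n",
              nrow(x$transcripts), nrow(x$exons),
              length(unique(x$transcripts$chrom))))
  bt <- table(x$transcripts$biotype)
  cat("biotypes:", paste(sprintf("%s=%d", names(bt), bt), collapse = ", "), "\n")
  invisible(x)
}

#' Read a transcript annotation from GTF/GFF3
#'
#' Parses the file with `rtracklayer::import()` and assembles one transcript
#' model per `transcript_id` from its exon records. When CDS records are
#' present, 5' UTR / CDS / 3' UTR segment lengths are derived in transcript
#' orientation. The biotype is taken from a `transcript_biotype` (or
#' `gene_biotype`/`biotype`) attribute; when absent it defaults to `mRNA` if
#' the transcript has a CDS and `ncRNA` otherwise.
#'
#' Records whose coordinates are malformed (start > end in the 1-based file
#' convention) are rejected individually with a warning rather than failing
#' the whole import. A transcript with no exon records is an error.
#'
#' @param path GTF or GFF3 file.
#' @return A [tx_annotation] object.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  dat <- !startsWith(lines, "#") & nzchar(lines)
  fields <- strsplit(lines[dat], "\t", fixed = TRUE)
  ok9 <- vapply(fields, length, 0L) == 9L
  st <- suppressWarnings(as.numeric(vapply(fields, function(f) f[4][1], "")))
  en <- suppressWarnings(as.numeric(vapply(fields, function(f) f[5][1], "")))
  bad <- ok9 & (is.na(st) | is.na(en) | st > en)
  if (any(bad)) {
    warning(sum(bad), " record(s) with malformed coordinates (start > end) rejected")
    keep <- rep(TRUE, length(lines)); keep[which(dat)[bad]] <- FALSE
    path2 <- tempfile(fileext = paste0(".", tools::file_ext(path)))
    writeLines(lines[keep], path2)
    on.exit(unlink(path2))
    path <- path2
  }
  gr <- rtracklayer::import(path)
  m <- S4Vectors::mcols(gr)
  type <- as.character(m$type)
  first_or_na <- function(x) if (length(x)) as.character(x[[1]]) else NA_character_
  tid <- if ("transcript_id" %in% names(m)) as.character(m$transcript_id)
         else vapply(m$Parent, first_or_na, "")  # GFF3 exon/CDS carry Parent
  tid <- sub("^transcript:", "", tid)
  gid <- if ("gene_id" %in% names(m)) as.character(m$gene_id) else tid
  bt_col <- intersect(c("transcript_biotype", "gene_biotype", "biotype"), names(m))
  bt <- if (length(bt_col)) as.character(m[[bt_col[1]]]) else rep(NA_character_, length(gr))

  is_exon <- type == "exon"
  is_cds <- type == "CDS"
  if (!any(is_exon)) stop("no exon records in ", path)
  ex <- data.frame(
    transcript_id = tid[is_exon],
    gene_id = gid[is_exon],
    chrom = as.character(GenomicRanges::seqnames(gr))[is_exon],
    strand = as.character(GenomicRanges::strand(gr))[is_exon],
    start = GenomicRanges::start(gr)[is_exon] - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr)[is_exon],
    stringsAsFactors = FALSE)
  ex <- ex[order(ex$transcript_id, ex$start), , drop = FALSE]
  # rank exons 5'->3' in transcript orientation
  ex$exon_rank <- stats::ave(seq_len(nrow(ex)), ex$transcript_id,
                             FUN = function(i) {
                               if (ex$strand[i[1]] == "+") seq_along(i) else rev(seq_along(i))
                             })
  ids <- unique(ex$transcript_id)

  tx <- data.frame(
    transcript_id = ids,
    gene_id = ex$gene_id[match(ids, ex$transcript_id)],
    chrom = ex$chrom[match(ids, ex$transcript_id)],
    strand = ex$strand[match(ids, ex$transcript_id)],
    start = as.integer(tapply(ex$start, ex$transcript_id, min)[ids]),
    end = as.integer(tapply(ex$end, ex$transcript_id, max)[ids]),
    biotype = NA_character_, utr5_len = 0L, cds_len = 0L, utr3_len = 0L,
    stringsAsFactors = FALSE)

  # biotype: taken from any record of the transcript that carries one
  has <- !is.na(bt) & !is.na(tid)
  if (any(has))
    tx$biotype <- bt[has][match(tx$transcript_id, tid[has])]

  # provisional annotation (no CDS segments yet) for coordinate mapping
  anno0 <- tx_annotation(tx, ex[, c("transcript_id", "chrom", "strand",
                                    "start", "end", "exon_rank")])

  if (any(is_cds)) {
    cds_tid <- tid[is_cds]
    cds_min <- tapply(GenomicRanges::start(gr)[is_cds] - 1L, cds_tid, min)
    cds_max <- tapply(GenomicRanges::end(gr)[is_cds], cds_tid, max)
    for (id in names(cds_min)) {
      i <- match(id, tx$transcript_id)
      if (is.na(i)) next
      # genomic CDS span -> transcript coordinates via the exon map
      gmin <- as.integer(cds_min[[id]]); gmax <- as.integer(cds_max[[id]])
      t1 <- genome_to_transcript(anno0, id, gmin)
      t2 <- genome_to_transcript(anno0, id, gmax - 1L)
      if (is.na(t1) || is.na(t2))
        stop("CDS boundary outside exons for transcript ", id)
      lo <- min(t1, t2); hi <- max(t1, t2)
      L <- anno0$transcripts$tx_len[match(id, anno0$transcripts$transcript_id)]
      tx$utr5_len[i] <- lo
      tx$cds_len[i] <- hi - lo + 1L
      tx$utr3_len[i] <- L - hi - 1L
    }
  }
  tx$biotype <- ifelse(!is.na(tx$biotype), tx$biotype,
                       ifelse(tx$cds_len > 0, "mRNA", "ncRNA"))
  tx_annotation(tx, anno0$exons)
}

#' Write an annotation as GTF
#'
#' Emits transcript, exon and (for coding transcripts) CDS records with
#' `gene_id`, `transcript_id` and `transcript_biotype` attributes, converting
#' internal 0-based half-open coordinates to the GTF 1-based inclusive
#' convention.
#'
#' @param anno A [tx_annotation].
#' @param path Output file.
#' @export
write_gtf <- function(anno, path) {
  tx <- anno$transcripts; ex <- anno$exons
  attrs <- function(tid) {
    i <- match(tid, tx$transcript_id)
    sprintf('gene_id "%s"; transcript_id "%s"; transcript_biotype "%s";',
            tx$gene_id[i], tid, tx$biotype[i])
  }
  row9 <- function(chrom, feat, s0, e0, strand, tid)
    sprintf("%s\tm6Adyn\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, feat, s0 + 1L, e0, strand, attrs(tid))
  out <- character(0)
  for (i in seq_len(nrow(tx))) {
    id <- tx$transcript_id[i]
    out <- c(out, row9(tx$chrom[i], "transcript", tx$start[i], tx$end[i],
                       tx$strand[i], id))
    e <- ex[ex$transcript_id == id, , drop = FALSE]
    out <- c(out, row9(e$chrom, "exon", e$start, e$end, e$strand, id))
    if (tx$cds_len[i] > 0) {
      # CDS span in transcript coordinates -> genomic blocks
      lo <- tx$utr5_len[i]; hi <- lo + tx$cds_len[i] - 1L
      blocks <- transcript_blocks_to_genome(anno, id, lo, hi + 1L)
      out <- c(out, row9(blocks$chrom, "CDS", blocks$start, blocks$end,
                         blocks$strand, id))
    }
  }
  writeLines(out, path)
  invisible(path)
}

# exon table of one transcript in transcript (5'->3') order, with cumulative
# spliced offsets. Internal workhorse for the coordinate maps.
.tx_exons <- function(anno, transcript_id) {
  idx <- anno$exon_index[[transcript_id]]
  if (is.null(idx)) stop("unknown transcript: ", transcript_id)
  anno$exons[idx, , drop = FALSE]
}

#' Map genomic positions to spliced transcript coordinates
#'
#' Returns the 0-based transcript-orientation offset of each genomic position
#' that falls in an exon of the transcript, and `NA` for intronic or outside
#' positions (the none-return is the contract, not an error). The inverse is
#' [transcript_to_genome()].
#'
#' @param anno A [tx_annotation].
#' @param transcript_id Single transcript id.
#' @param pos Vector of 0-based genomic positions.
#' @return Integer vector, `NA` where `pos` is not exonic.
#' @export
genome_to_transcript <- function(anno, transcript_id, pos) {
  e <- .tx_exons(anno, transcript_id)
  out <- rep(NA_integer_, length(pos))
  for (i in seq_len(nrow(e))) {
    hit <- !is.na(pos) & pos >= e$start[i] & pos < e$end[i]
    if (!any(hit)) next
    out[hit] <- if (e$strand[i] == "+")
      e$cum_before[i] + (pos[hit] - e$start[i])
    else
      e$cum_before[i] + (e$end[i] - 1L - pos[hit])
  }
  as.integer(out)
}

#' Map spliced transcript coordinates to genomic positions
#'
#' @param anno A [tx_annotation].
#' @param transcript_id Single transcript id.
#' @param tpos Vector of 0-based transcript-orientation offsets.
#' @return Integer vector of genomic positions (`NA` outside `[0, tx_len)`).
#' @export
transcript_to_genome <- function(anno, transcript_id, tpos) {
  e <- .tx_exons(anno, transcript_id)
  w <- e$end - e$start
  out <- rep(NA_integer_, length(tpos))
  for (i in seq_len(nrow(e))) {
    off <- tpos - e$cum_before[i]
    hit <- !is.na(tpos) & off >= 0L & off < w[i]
    if (!any(hit)) next
    out[hit] <- if (e$strand[i] == "+") e$start[i] + off[hit]
                else e$end[i] - 1L - off[hit]
  }
  as.integer(out)
}

# A half-open transcript-coordinate interval [tstart, tend) mapped to its
# genomic exon blocks (data.frame chrom/start/end/strand, genome order).
transcript_blocks_to_genome <- function(anno, transcript_id, tstart, tend) {
  stopifnot(tend > tstart)
  e <- .tx_exons(anno, transcript_id)
  w <- e$end - e$start
  res <- list()
  for (i in seq_len(nrow(e))) {
    lo <- max(tstart, e$cum_before[i])
    hi <- min(tend, e$cum_before[i] + w[i])
    if (hi <= lo) next
    if (e$strand[i] == "+") {
      gs <- e$start[i] + (lo - e$cum_before[i]); ge <- gs + (hi - lo)
    } else {
      ge <- e$end[i] - (lo - e$cum_before[i]); gs <- ge - (hi - lo)
    }
    res[[length(res) + 1L]] <- data.frame(chrom = e$chrom[i], start = gs,
                                          end = ge, strand = e$strand[i],
                                          stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out[order(out$start), , drop = FALSE]
}

#' Overlap length of two stranded genomic intervals
#'
#' Half-open interval intersection length in nucleotides; 0 when the
#' intervals are disjoint (abutting half-open intervals share no base), on
#' different chromosomes, or on different strands when `same_strand` is set.
#' All arguments are vectorised.
#'
#' @param chrom1,start1,end1,strand1 First interval set.
#' @param chrom2,start2,end2,strand2 Second interval set.
#' @param same_strand Require matching strand (default TRUE; peaks are
#'   strand-specific throughout the pipeline).
#' @return Integer vector of overlap lengths.
#' @export
interval_overlap <- function(chrom1, start1, end1, strand1,
                             chrom2, start2, end2, strand2,
                             same_strand = TRUE) {
  ov <- pmax(0L, pmin(end1, end2) - pmax(start1, start2))
  ov[chrom1 != chrom2] <- 0L
  if (same_strand) ov[strand1 != strand2] <- 0L
  as.integer(ov)
}

#' Keep the longest transcript per gene
#'
#' Transcript-level analyses represent each gene by its longest spliced
#' isoform (ties broken by transcript id for determinism).
#'
#' @param anno A [tx_annotation].
#' @return A filtered [tx_annotation].
#' @export
collapse_to_longest <- function(anno) {
  tx <- anno$transcripts
  tx <- tx[order(tx$gene_id, -tx$tx_len, tx$transcript_id), , drop = FALSE]
  keep <- tx$transcript_id[!duplicated(tx$gene_id)]
  tx_annotation(anno$transcripts[anno$transcripts$transcript_id %in% keep, ],
                anno$exons[anno$exons$transcript_id %in% keep, ])
}

# GRanges of all exons with transcript_id metadata (internal)
.exons_granges <- function(anno) {
  e <- anno$exons
  GenomicRanges::GRanges(e$chrom,
                         IRanges::IRanges(e$start + 1L, e$end),
                         strand = e$strand, transcript_id = e$transcript_id)
}

# transcript-coordinate segment boundaries: list(utr5=c(lo,hi), ...)
# half-open in transcript coordinates; NULL segments have zero length
.tx_segments <- function(tx_row) {
  u5 <- tx_row$utr5_len; cd <- tx_row$cds_len; L <- tx_row$tx_len
  list(utr5 = c(0L, u5), cds = c(u5, u5 + cd), utr3 = c(u5 + cd, L))
}
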