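#' Construct a peak table
#'
#' Peaks are plain data.frames with one row per peak and the columns
#' `chrom`, `start`, `end` (0-based half-open), `name`, `strand`,
#' `enrichment` (IP/expected-input fold), `pvalue` and `summit` (offset of
#' the summit from `start`, in nt). This mirrors the ENCODE NarrowPeak
#' fields; [write_narrowpeak()] and [read_narrowpeak()] convert to and from
#' the file encoding.
#'
#' @param chrom,start,end,strand Interval fields.
#' @param name Peak identifiers (unique).
#' @param enrichment Fold enrichment (>= 0).
#' @param pvalue Peak p-value in `[0, 1]`.
#' @param summit Summit offset from `start` (0 <= summit < end - start).
#' @return data.frame of class `c("m6a_peaks", "data.frame")`.
#' @export
peak_table <- function(chrom, start, end, name, strand, enrichment, pvalue,
                       summit) {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), name = as.character(name),
                   strand = as.character(strand),
                   enrichment = as.numeric(enrichment),
                   pvalue = as.numeric(pvalue), summit = as.integer(summit),
                   stringsAsFactors = FALSE)
  validate_peaks(df)
  class(df) <- c("m6a_peaks", "data.frame")
  df
}

validate_peaks <- function(df) {
  if (!nrow(df)) return(invisible(df))
  stopifnot(all(df$start < df$end),
            all(df$strand %in% c("+", "-")),
            all(df$pvalue >= 0 & df$pvalue <= 1),
            all(df$enrichment >= 0),
            all(df$summit >= 0 & df$summit < df$end - df$start))
  invisible(df)
}

#' @rdname peak_table
#' @export
empty_peaks <- function() {
  peak_table(character(0), integer(0), integer(0), character(0), character(0),
             numeric(0), numeric(0), integer(0))
}

# internal: peaks -> GRanges (1-based) with metadata
.peaks_granges <- function(pk) {
  GenomicRanges::GRanges(pk$chrom, IRanges::IRanges(pk$start + 1L, pk$end),
                         strand = pk$strand, name = pk$name)
}

#' Write / read ENCODE NarrowPeak
#'
#' Columns follow the ENCODE BED6+4 convention: chrom, chromStart, chromEnd,
#' name, score (`min(1000, round(100 * enrichment))`), strand, signalValue
#' (enrichment fold), pValue (as -log10, 4 decimal places, capped at 400),
#' qValue (-1, not computed at this stage) and peak (summit offset). Reading
#' back recovers p-values to the 4-dp precision of the -log10 encoding; all
#' other fields round-trip exactly.
#'
#' @param peaks A peak table (see [peak_table()]).
#' @param path File path.
#' @return `read_narrowpeak` returns a peak table; `write_narrowpeak`
#'   invisibly returns `path`.
#' @export
write_narrowpeak <- function(peaks, path) {
  validate_peaks(peaks)
  lines <- if (nrow(peaks)) {
    mlog10 <- ifelse(peaks$pvalue > 0, pmin(-log10(peaks$pvalue), 400), 400)
    sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%.4f\t%.4f\t-1\t%d",
            peaks$chrom, peaks$start, peaks$end, peaks$name,
            pmin(1000L, as.integer(round(100 * peaks$enrichment))),
            peaks$strand, peaks$enrichment, mlog10, peaks$summit)
  } else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_narrowpeak
#' @export
read_narrowpeak <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_peaks())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 0L)
  if (any(nf != 10L))
    stop("narrowPeak column-count mismatch (expected 10) at line ",
         which(nf != 10L)[1], " of ", path)
  m <- do.call(rbind, fields)
  peak_table(chrom = m[, 1], start = as.integer(m[, 2]),
             end = as.integer(m[, 3]), name = m[, 4], strand = m[, 6],
             enrichment = as.numeric(m[, 7]),
             pvalue = 10^(-as.numeric(m[, 8])), summit = as.integer(m[, 10]))
}

#' Windowed coverage tracks for one library
#'
#' A `window_tracks` object stores the fixed-grid window counts of one
#' sequencing library: a named list of integer vectors keyed `"chrom:strand"`
#' (window i covers `[i-1, i) * window_size` on that chromosome), the window
#' size in nt and the library size in reads (by default the total count).
#'
#' @param counts Named list of non-negative integer vectors, names like
#'   `"1:+"`.
#' @param window_size Window width, nt.
#' @param library_size Total reads; defaults to `sum(unlist(counts))`.
#' @return A `window_tracks` object.
#' @export
window_tracks <- function(counts, window_size, library_size = NULL) {
  stopifnot(window_size > 0, length(counts) > 0, !is.null(names(counts)))
  if (any(unlist(counts, use.names = FALSE) < 0)) stop("negative window count")
  if (is.null(library_size))
    library_size <- sum(as.numeric(unlist(counts, use.names = FALSE)))
  structure(list(counts = counts, window_size = as.integer(window_size),
                 library_size = library_size),
            class = "window_tracks")
}

#' @export
print.window_tracks <- function(x, ...) {
  cat(sprintf("window_tracks: %d track(s), window %d nt, library size %.0f\n",
              length(x$counts), x$window_size, x$library_size))
  invisible(x)
}

# "chrom:strand" key helpers
.track_key <- function(chrom, strand) paste(chrom, strand, sep = ":")
.key_chrom <- function(key) sub(":[+-]$", "", key)
.key_strand <- function(key) substr(key, nchar(key), nchar(key))

#' Write / read window tracks as BedGraph
#'
#' BedGraph carries no strand, so one file holds one strand of a library
#' (the strand-split convention of the peak-calling stage). All windows are
#' written, including zero-count windows, so that the grid round-trips
#' losslessly.
#'
#' @param tracks A [window_tracks] object.
#' @param strand `"+"` or `"-"`; which strand's chromosomes to write.
#' @param path File path.
#' @export
write_bedgraph <- function(tracks, strand, path) {
  keys <- names(tracks$counts)[.key_strand(names(tracks$counts)) == strand]
  con <- file(path, "w")
  on.exit(close(con))
  w <- tracks$window_size
  for (k in sort(keys)) {
    v <- tracks$counts[[k]]
    n <- length(v)
    writeLines(sprintf("%s\t%d\t%d\t%d", .key_chrom(k),
                       (seq_len(n) - 1L) * w, seq_len(n) * w, v), con)
  }
  invisible(path)
}

#' @rdname write_bedgraph
#' @param window_size Expected window width; checked against the file grid.
#' @param library_size Optional; when reading one strand of a library the
#'   full library size cannot be recovered from the file and should be
#'   supplied (defaults to the strand total).
#' @export
read_bedgraph <- function(path, strand, window_size, library_size = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "count"),
                          colClasses = c("character", "integer", "integer",
                                         "numeric"))
  if (nrow(df) && any(df$end - df$start != window_size))
    stop("BedGraph intervals do not match window size ", window_size)
  counts <- lapply(split(df, df$chrom), function(d) {
    v <- integer(max(d$end) / window_size)
    v[d$start / window_size + 1L] <- as.integer(d$count)
    v
  })
  names(counts) <- .track_key(names(counts), strand)
  window_tracks(counts, window_size, library_size)
}

#' Assemble a count matrix with sample metadata
#'
#' The pipeline's count container is a
#' [SummarizedExperiment::SummarizedExperiment] with one `counts` assay and
#' per-sample `condition` (`control`/`copper`), `assay_type`
#' (`rna`/`polysome`/`ip`/`input`), `replicate` and `library_size` columns.
#' Sample names encode the metadata as `assay_condition_replicate` so that
#' TSV round-trips preserve it.
#'
#' @param counts Integer matrix, features x samples.
#' @param condition,assay_type,replicate Per-sample metadata vectors.
#' @param library_size Per-sample totals; defaults to column sums.
#' @return A `SummarizedExperiment`.
#' @export
count_se <- function(counts, condition, assay_type, replicate,
                     library_size = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  if (anyDuplicated(rownames(counts))) stop("feature ids not unique")
  if (is.null(library_size)) library_size <- colSums(counts)
  colnames(counts) <- paste(assay_type, condition, replicate, sep = "_")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(condition = condition,
                                   assay_type = assay_type,
                                   replicate = as.integer(replicate),
                                   library_size = as.numeric(library_size),
                                   row.names = colnames(counts)))
}

#' Write / read a count matrix TSV
#'
#' Tab-separated, header row = sample ids (encoding
#' `assay_condition_replicate`), first column `feature_id`. A leading
#' `#library_size:` comment preserves library sizes that differ from column
#' sums.
#'
#' @param se A `SummarizedExperiment` from [count_se()].
#' @param path File path.
#' @export
write_counts_tsv <- function(se, path) {
  m <- SummarizedExperiment::assay(se, "counts")
  cd <- SummarizedExperiment::colData(se)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#library_size:\t",
                    paste(sprintf("%.10g", cd$library_size), collapse = "\t")),
             con)
  writeLines(paste(c("feature_id", colnames(m)), collapse = "\t"), con)
  writeLines(paste(rownames(m),
                   apply(m, 1, paste, collapse = "\t"), sep = "\t"), con)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  lines <- readLines(path)
  lib <- NULL
  if (length(lines) && startsWith(lines[1], "#library_size:")) {
    lib <- as.numeric(strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1])
    lines <- lines[-1]
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 0L)
  if (length(unique(nf)) != 1L)
    stop("counts TSV column-count mismatch at line ", which(nf != nf[1])[1],
         " of ", path)
  header <- fields[[1]][-1]
  m <- do.call(rbind, lapply(fields[-1], function(f) as.numeric(f[-1])))
  rownames(m) <- vapply(fields[-1], `[[`, "", 1L)
  colnames(m) <- header
  meta <- strsplit(header, "_", fixed = TRUE)
  count_se(m, condition = vapply(meta, `[[`, "", 2L),
           assay_type = vapply(meta, `[[`, "", 1L),
           replicate = as.integer(vapply(meta, `[[`, "", 3L)),
           library_size = lib)
}
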