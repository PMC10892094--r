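#' Genome-wide expected-input rate (lambda floor)
#'
#' Mean input count per window across all tracks, scaled to the IP
#' sequencing depth. Used by [call_peaks()] where the local input estimate
#' is zero, so that isolated IP counts over empty input never produce
#' p = 0 artifacts.
#'
#' @param input A [window_tracks] object (the input/background library).
#' @param ip_library_size IP library size for depth scaling (default: equal
#'   depths).
#' @return Scalar expected IP-scale input count per window.
#' @export
lambda_floor <- function(input, ip_library_size = NULL) {
  v <- unlist(input$counts, use.names = FALSE)
  if (!length(v) || sum(v) == 0) stop("empty input track")
  ratio <- if (is.null(ip_library_size)) 1
           else ip_library_size / input$library_size
  mean(v) * ratio
}

#' Pool several libraries into one track
#'
#' Sums window counts and library sizes; used to pool a condition's input
#' replicates into a single background library before peak calling.
#'
#' @param track_list List of [window_tracks] on the same grid.
#' @return A [window_tracks].
#' @export
pool_tracks <- function(track_list) {
  stopifnot(length(track_list) >= 1)
  ref <- track_list[[1]]
  for (t in track_list[-1]) .check_grid(ref, t)
  counts <- stats::setNames(lapply(names(ref$counts), function(k)
    Reduce(`+`, lapply(track_list, function(t) t$counts[[k]]))),
    names(ref$counts))
  window_tracks(counts, ref$window_size,
                sum(vapply(track_list, function(t) t$library_size, 0)))
}

.check_grid <- function(a, b) {
  if (a$window_size != b$window_size ||
      !setequal(names(a$counts), names(b$counts)) ||
      !all(lengths(a$counts) == lengths(b$counts)[names(a$counts)]))
    stop("IP and input tracks do not share a window grid")
  invisible(TRUE)
}

# centred running mean with shrinking edge windows
.running_mean <- function(x, k) {
  x <- as.numeric(x)
  if (k <= 1L || length(x) <= 1L) return(x)
  h <- k %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(0L, seq_len(n) - 1L - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' Per-window Poisson enrichment p-values
#'
#' For every window, the expected IP count lambda is the input count rate
#' (smoothed by a centred running mean over `lambda_smooth` windows and
#' pooled across whatever replicates were merged into `input`) scaled by the
#' library-size ratio; where the local estimate is zero it is replaced by
#' the genome-wide [lambda_floor()]. The p-value is the upper Poisson tail
#' `P(X >= k_ip | lambda)`. Strands and chromosomes are processed
#' independently.
#'
#' @param ip,input [window_tracks] on a shared grid.
#' @param lambda_smooth Running-mean width, windows (odd; 1 = raw
#'   per-window input).
#' @return List with per-track-key numeric vectors `pvalue` and `lambda`.
#' @export
window_pvalues <- function(ip, input, lambda_smooth = 3L) {
  .check_grid(ip, input)
  if (ip$library_size <= 0 || input$library_size <= 0)
    stop("zero library size")
  ratio <- ip$library_size / input$library_size
  floor_val <- lambda_floor(input, ip$library_size)
  keys <- names(ip$counts)
  lam <- p <- stats::setNames(vector("list", length(keys)), keys)
  for (k in keys) {
    l <- .running_mean(input$counts[[k]], lambda_smooth) * ratio
    l[l == 0] <- floor_val
    lam[[k]] <- l
    p[[k]] <- stats::ppois(ip$counts[[k]] - 1, l, lower.tail = FALSE)
  }
  list(pvalue = p, lambda = lam)
}

#' Call enrichment peaks from windowed IP vs input counts
#'
#' The strand-split windowed Poisson caller: per-window upper-tail p-values
#' from [window_pvalues()], windows with `p < alpha` merged into runs when
#' separated by at most `merge_gap` non-significant windows, runs with fewer
#' than `min_windows` significant windows dropped. Each peak reports its
#' summit (midpoint of the max-IP-count window), an enrichment score (sum of
#' IP counts over the run divided by the summed lambda) and the minimum
#' window p-value. No multiple-testing correction is applied at this stage;
#' downstream replicate consensus provides the confidence filter.
#'
#' @inheritParams window_pvalues
#' @param alpha Per-window significance threshold (default 0.05).
#' @param min_windows Minimum significant windows per peak.
#' @param merge_gap Maximum non-significant gap (windows) bridged when
#'   merging.
#' @param name_prefix Prefix for peak names.
#' @return A peak table ([peak_table()]).
#' @export
call_peaks <- function(ip, input, alpha = 0.05, min_windows = 2L,
                       merge_gap = 1L, lambda_smooth = 3L,
                       name_prefix = "peak") {
  wp <- window_pvalues(ip, input, lambda_smooth)
  w <- ip$window_size
  rows <- list()
  for (k in sort(names(ip$counts))) {
    pv <- wp$pvalue[[k]]; lam <- wp$lambda[[k]]; cnt <- ip$counts[[k]]
    sig <- which(pv < alpha)
    if (!length(sig)) next
    grp <- cumsum(c(1L, diff(sig) > merge_gap + 1L))
    for (g in split(sig, grp)) {
      if (length(g) < min_windows) next
      i0 <- g[1]; i1 <- g[length(g)]
      span <- i0:i1
      peak_start <- (i0 - 1L) * w
      imax <- span[which.max(cnt[span])]
      summit <- (imax - 1L) * w + w %/% 2L - peak_start
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = .key_chrom(k), start = peak_start, end = i1 * w,
        strand = .key_strand(k),
        enrichment = sum(cnt[span]) / sum(lam[span]),
        pvalue = min(pv[g]), summit = summit, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_peaks())
  df <- do.call(rbind, rows)
  peak_table(df$chrom, df$start, df$end,
             sprintf("%s_%05d", name_prefix, seq_len(nrow(df))),
             df$strand, df$enrichment, df$pvalue, df$summit)
}
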