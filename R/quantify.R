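#' Median-of-ratios size factors
#'
#' For each sample, the factor is the median across features of the ratio
#' of its count to the feature's geometric mean over samples, computed on
#' features with all-positive counts, then rescaled so the factors have
#' geometric mean 1. When no feature is positive in every sample the
#' factors fall back to library-size ratios with a warning.
#'
#' @param counts Features x samples count matrix (or a `SummarizedExperiment`
#'   from [count_se()]).
#' @return Named numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  if (methods::is(counts, "SummarizedExperiment"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  if (ncol(counts) < 2) stop("need >= 2 samples")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    warning("no feature with all-positive counts; using library-size ratios")
    sf <- colSums(counts)
    return(sf / exp(mean(log(sf))))
  }
  m <- counts[pos, , drop = FALSE]
  logg <- rowMeans(log(m))
  sf <- apply(m, 2, function(col) exp(stats::median(log(col) - logg)))
  sf / exp(mean(log(sf)))
}

#' Abundance log2 fold change (copper vs control) with a simplified DE test
#'
#' Counts are normalised by [size_factors()]; the fold change is
#' `log2((mean normalised copper + pc) / (mean normalised control + pc))`.
#' Per-transcript p-values come from a Welch t-test on
#' `log2(normalised + pc)` values (a deliberately simplified stand-in for a
#' negative-binomial Wald test: the category-level conclusions downstream
#' rest on rank-sum comparisons, not on this per-transcript test), adjusted
#' by Benjamini-Hochberg (`adjust = "bonferroni"` available); `padj < 0.05`
#' is the declared significance rule.
#'
#' @param se RNA `SummarizedExperiment` with `condition` in
#'   `{control, copper}`.
#' @param pseudocount Added to normalised means (and logged values) to keep
#'   fold changes finite.
#' @param adjust Multiple-testing method (`"BH"` default).
#' @return data.frame `transcript_id`, `baseMean`, `log2fc`, `pvalue`,
#'   `padj`, `significant`.
#' @export
log2_fold_change <- function(se, pseudocount = 1, adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  cond <- SummarizedExperiment::colData(se)$condition
  if (!all(c("control", "copper") %in% cond))
    stop("need replicates of both conditions")
  m <- SummarizedExperiment::assay(se, "counts")
  norm <- sweep(m, 2, size_factors(m), "/")
  a <- norm[, cond == "copper", drop = FALSE]
  b <- norm[, cond == "control", drop = FALSE]
  lfc <- log2((rowMeans(a) + pseudocount) / (rowMeans(b) + pseudocount))
  la <- log2(a + pseudocount); lb <- log2(b + pseudocount)
  pv <- vapply(seq_len(nrow(m)), function(i) {
    x <- la[i, ]; y <- lb[i, ]
    if (stats::sd(x) == 0 && stats::sd(y) == 0)
      return(if (mean(x) == mean(y)) 1 else 0)
    stats::t.test(x, y)$p.value
  }, 0)
  padj <- stats::p.adjust(pv, method = adjust)
  data.frame(transcript_id = rownames(m),
             baseMean = rowMeans(norm), log2fc = lfc, pvalue = pv,
             padj = padj, significant = padj < 0.05,
             stringsAsFactors = FALSE, row.names = NULL)
}

# reads per million for one SummarizedExperiment, averaged over replicates
# within each condition
.rpm_by_condition <- function(se) {
  m <- SummarizedExperiment::assay(se, "counts")
  cd <- SummarizedExperiment::colData(se)
  rpm <- sweep(m, 2, cd$library_size / 1e6, "/")
  vapply(c("control", "copper"), function(cond) {
    cols <- which(cd$condition == cond)
    if (!length(cols)) stop("missing condition '", cond, "' in count matrix")
    rowMeans(rpm[, cols, drop = FALSE])
  }, numeric(nrow(m)))
}

#' Polysome occupancy and its change under stress
#'
#' Occupancy per condition is `log2(RPM_polysome / RPM_RNA)` with RPM
#' averaged over replicates within assay x condition, and
#' `occupancy_change = occupancy_copper - occupancy_control` (exactly).
#' Transcripts with RPM below `rpm_floor` in any of the four cells are
#' excluded; their ids are kept in the `excluded` attribute.
#'
#' @param poly_se,rna_se Polysome and RNA `SummarizedExperiment`s with
#'   matched transcript ids.
#' @param rpm_floor Minimum RPM in every cell for inclusion (default 1).
#' @return data.frame `transcript_id`, `occupancy_control`,
#'   `occupancy_copper`, `occupancy_change`.
#' @export
polysome_occupancy <- function(poly_se, rna_se, rpm_floor = 1) {
  ids <- rownames(SummarizedExperiment::assay(rna_se, "counts"))
  if (!identical(ids, rownames(SummarizedExperiment::assay(poly_se, "counts"))))
    stop("polysome and RNA matrices must share transcript ids")
  rp <- .rpm_by_condition(poly_se)
  rr <- .rpm_by_condition(rna_se)
  keep <- rowSums(cbind(rp, rr) < rpm_floor) == 0
  if (any(!keep))
    message(sum(!keep), " transcript(s) below the RPM floor excluded")
  occ_ct <- log2(rp[keep, "control"] / rr[keep, "control"])
  occ_cu <- log2(rp[keep, "copper"] / rr[keep, "copper"])
  out <- data.frame(transcript_id = ids[keep], occupancy_control = occ_ct,
                    occupancy_copper = occ_cu,
                    occupancy_change = occ_cu - occ_ct,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "excluded") <- ids[!keep]
  out
}

#' Compare a per-transcript statistic between m6A categories
#'
#' Pairwise two-sided Wilcoxon rank-sum (default) or Welch t-tests over the
#' stress-enriched / control-enriched / shared groups, with per-category
#' medians and sizes. Categories with fewer than 2 values are skipped with
#' a warning.
#'
#' @param values Named numeric vector (names = transcript ids) or plain
#'   vector aligned with `labels`.
#' @param labels Category label per value.
#' @param test `"wilcoxon"` or `"ttest"`.
#' @return List with `summary` (category, n, median) and `pairs`
#'   (group1, group2, pvalue).
#' @export
category_comparison <- function(values, labels,
                                test = c("wilcoxon", "ttest")) {
  test <- match.arg(test)
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- as.character(labels)[keep]
  cats <- intersect(c("stress-enriched", "control-enriched", "shared"),
                    unique(labels))
  if (length(cats) < 2) stop("need >= 2 non-empty categories")
  summary <- data.frame(
    category = cats,
    n = vapply(cats, function(cat) sum(labels == cat), 0L),
    median = vapply(cats, function(cat)
      stats::median(values[labels == cat]), 0),
    stringsAsFactors = FALSE, row.names = NULL)
  cmb <- utils::combn(cats, 2)
  rows <- list()
  for (j in seq_len(ncol(cmb))) {
    g1 <- cmb[1, j]; g2 <- cmb[2, j]
    x <- values[labels == g1]; y <- values[labels == g2]
    if (length(x) < 2 || length(y) < 2) {
      warning("category with n < 2; comparison ", g1, " vs ", g2, " skipped")
      next
    }
    pv <- if (test == "wilcoxon")
      suppressWarnings(stats::wilcox.test(x, y)$p.value)
    else stats::t.test(x, y)$p.value
    rows[[length(rows) + 1L]] <- data.frame(group1 = g1, group2 = g2,
                                            pvalue = pv,
                                            stringsAsFactors = FALSE)
  }
  list(summary = summary,
       pairs = if (length(rows)) do.call(rbind, rows) else
         data.frame(group1 = character(0), group2 = character(0),
                    pvalue = numeric(0)))
}

#' Count transcripts beyond fold-change thresholds
#'
#' Counts transcripts of one category whose abundance ratio
#' (`2^log2fc`) exceeds `up` (a ">50% increase" is ratio > 1.5) or falls
#' below `down` (a ">50% decrease" is ratio < 0.5).
#'
#' @param fc FoldChange table from [log2_fold_change()].
#' @param transcript_ids Ids of the category's transcripts (default: all
#'   rows).
#' @param up,down Ratio cutoffs.
#' @return Named integer vector `c(increase, decrease)`.
#' @export
threshold_counts <- function(fc, transcript_ids = NULL, up = 1.5,
                             down = 0.5) {
  sub <- if (is.null(transcript_ids)) fc else
    fc[fc$transcript_id %in% transcript_ids, , drop = FALSE]
  ratio <- 2^sub$log2fc
  c(increase = sum(ratio > up), decrease = sum(ratio < down))
}
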