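test_that("median-of-ratios size factors match the closed forms", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2,
              dimnames = list(c("a", "b", "c"), NULL))
  expect_equal(unname(size_factors(m)), c(1, 1))
  # sample B = 2 x sample A -> (1/sqrt(2), sqrt(2)) after geometric scaling
  m2 <- cbind(A = c(10, 20, 30), B = c(20, 40, 60))
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  # permuting feature order leaves factors unchanged
  set.seed(701)
  m3 <- matrix(rpois(300, 50) + 1, ncol = 3)
  expect_equal(size_factors(m3), size_factors(m3[sample(100), ]))
  # fallback when no feature is positive everywhere
  m4 <- cbind(c(10, 0), c(0, 10))
  expect_warning(sf <- size_factors(m4), "library-size")
  expect_equal(unname(sf), c(1, 1))
})

test_that("size factors agree with the DESeq2 median-of-ratios estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(702)
  m <- matrix(rnbinom(2000, mu = 80, size = 10) + 1, ncol = 4,
              dimnames = list(sprintf("f%d", 1:500), sprintf("s%d", 1:4)))
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  ref <- ref / exp(mean(log(ref)))  # same geometric-mean-1 convention
  expect_equal(unname(size_factors(m)), unname(ref), tolerance = 1e-10)
})

# count matrix with stable background features so the size factors are
# exactly 1 and the fold-change arithmetic can be checked in closed form
fc_fixture <- function(copper_mean, control_mean) {
  m <- rbind(target = rep(c(control_mean, copper_mean), each = 3),
             matrix(100, nrow = 99, ncol = 6,
                    dimnames = list(sprintf("bg%d", 1:99), NULL)))
  count_se(m, condition = rep(c("control", "copper"), each = 3),
           assay_type = "rna", replicate = rep(1:3, 2))
}

test_that("log2 fold change follows the pseudocount formula", {
  fc <- log2_fold_change(fc_fixture(10, 10))
  expect_equal(fc$log2fc[fc$transcript_id == "target"], 0)
  fc2 <- log2_fold_change(fc_fixture(40, 10))
  expect_equal(fc2$log2fc[fc2$transcript_id == "target"], log2(41 / 11),
               tolerance = 1e-12)
  expect_true(all(fc2$padj >= fc2$pvalue))
  # a condition with no replicates is an error
  se <- fc_fixture(10, 10)[, 1:3]
  expect_error(log2_fold_change(se), "condition")
})

test_that("the simplified DE stage controls the null false-discovery rate", {
  cfg <- sim_config(n_transcripts = 2000, seed = 41,
                    lfc_shift_stress_enriched = 0,
                    lfc_shift_control_enriched = 0,
                    lfc_shift_lncRNA_stress = 0,
                    occupancy_shift_stress_enriched = 0)
  sim <- simulate_dataset(cfg, tracks = FALSE)
  fc <- log2_fold_change(sim$rna)
  expect_lte(mean(fc$padj < 0.05), 0.05)
})

test_that("polysome occupancy matches the RPM formulas exactly", {
  ids <- sprintf("t%d", 1:4)
  rna <- count_se(matrix(c(100, 200, 300, 400,
                           110, 190, 310, 390,
                           100, 200, 300, 400,
                           100, 210, 290, 410), ncol = 4,
                         dimnames = list(ids, NULL)),
                  condition = c("control", "control", "copper", "copper"),
                  assay_type = "rna", replicate = c(1, 2, 1, 2))
  poly <- count_se(matrix(c(200, 400, 600, 800,
                            220, 380, 620, 780,
                            100, 200, 300, 400,
                            100, 210, 290, 410), ncol = 4,
                          dimnames = list(ids, NULL)),
                   condition = c("control", "control", "copper", "copper"),
                   assay_type = "polysome", replicate = c(1, 2, 1, 2))
  occ <- polysome_occupancy(poly, rna, rpm_floor = 0)
  # brute-force recomputation from raw counts and library sizes
  rpm <- function(se) {
    m <- SummarizedExperiment::assay(se, "counts")
    sweep(m, 2, colSums(m) / 1e6, "/")
  }
  rr <- rpm(rna); rp <- rpm(poly)
  want_ct <- log2(rowMeans(rp[, 1:2]) / rowMeans(rr[, 1:2]))
  want_cu <- log2(rowMeans(rp[, 3:4]) / rowMeans(rr[, 3:4]))
  expect_equal(occ$occupancy_control, unname(want_ct), tolerance = 1e-12)
  expect_equal(occ$occupancy_copper, unname(want_cu), tolerance = 1e-12)
  expect_equal(occ$occupancy_change,
               occ$occupancy_copper - occ$occupancy_control)
})

test_that("occupancy formula examples: doubling and the null", {
  ids <- c("t1", "t2")
  mk <- function(m, assay) count_se(m, condition = c("control", "copper"),
                                    assay_type = assay, replicate = c(1, 1))
  rna <- mk(matrix(c(100, 300, 100, 300), ncol = 2,
                   dimnames = list(ids, NULL)), "rna")
  # polysome RPM = 2 x RNA RPM for t1 given equal library sizes
  poly <- mk(matrix(c(200, 200, 200, 200), ncol = 2,
                    dimnames = list(ids, NULL)), "polysome")
  occ <- polysome_occupancy(poly, rna, rpm_floor = 0)
  # t1: RPM share doubles (0.5 vs 0.25): occupancy = 1 log2 unit
  expect_equal(occ$occupancy_control[occ$transcript_id == "t1"], 1)
  # equal occupancies across conditions -> zero change
  expect_equal(occ$occupancy_change, c(0, 0))
  # condition swap (in both assays) negates the change (antisymmetry)
  swap <- function(se, assay) count_se(
    SummarizedExperiment::assay(se, "counts")[, 2:1],
    condition = c("control", "copper"), assay_type = assay,
    replicate = c(1, 1))
  rna_sw <- mk(matrix(c(100, 300, 50, 300), ncol = 2,
                      dimnames = list(ids, NULL)), "rna")
  occ1 <- polysome_occupancy(poly, rna_sw, rpm_floor = 0)
  occ2 <- polysome_occupancy(swap(poly, "polysome"), swap(rna_sw, "rna"),
                             rpm_floor = 0)
  expect_equal(occ1$occupancy_change, -occ2$occupancy_change,
               tolerance = 1e-12)
})

test_that("occupancy excludes sub-floor transcripts and checks inputs", {
  ids <- c("hi", "lo")
  rna <- count_se(matrix(c(1e6, 1, 1e6, 1), ncol = 2,
                         dimnames = list(ids, NULL)),
                  condition = c("control", "copper"), assay_type = "rna",
                  replicate = c(1, 1))
  poly <- count_se(matrix(c(1e6, 1, 1e6, 1), ncol = 2,
                          dimnames = list(ids, NULL)),
                   condition = c("control", "copper"),
                   assay_type = "polysome", replicate = c(1, 1))
  expect_message(occ <- polysome_occupancy(poly, rna, rpm_floor = 10),
                 "excluded")
  expect_equal(occ$transcript_id, "hi")
  expect_equal(attr(occ, "excluded"), "lo")
  # mismatched ids / missing condition
  rna_bad <- count_se(matrix(c(5, 5), ncol = 2,
                             dimnames = list("other", NULL)),
                      condition = c("control", "copper"), assay_type = "rna",
                      replicate = c(1, 1))
  expect_error(polysome_occupancy(poly, rna_bad), "ids")
  poly_ct <- poly[, 1]
  expect_error(polysome_occupancy(poly_ct, rna[, 1]), "condition")
})

test_that("category comparisons: exact ties, skips, and the rank-sum oracle", {
  v <- c(1, 2, 3, 1, 2, 3)
  lab <- rep(c("stress-enriched", "shared"), each = 3)
  cmp <- category_comparison(v, lab)
  expect_equal(cmp$pairs$pvalue, 1)  # identical lists, two-sided
  expect_equal(cmp$summary$median, c(2, 2))
  expect_error(category_comparison(v, rep("shared", 6)), "categories")
  w <- capture_warnings(
    cmp1 <- category_comparison(c(v, 9), c(lab, "control-enriched")))
  expect_true(all(grepl("skipped", w)))   # one warning per skipped pair
  expect_equal(nrow(cmp1$pairs), 1)       # only stress vs shared compared
  # Wilcoxon statistic equals the all-pairs enumeration on short lists
  set.seed(703)
  for (i in 1:25) {
    x <- sample(1:10, sample(3:8, 1), replace = TRUE)
    y <- sample(1:10, sample(3:8, 1), replace = TRUE)
    W <- suppressWarnings(wilcox.test(x, y)$statistic)
    expect_equal(unname(W), oracle_ranksum(x, y))
  }
})

test_that("threshold counts implement the >50% increase/decrease rule", {
  fc <- data.frame(transcript_id = c("a", "b", "c"),
                   log2fc = log2(c(0.4, 0.6, 1.6)))
  expect_equal(threshold_counts(fc), c(increase = 1L, decrease = 1L))
  fc0 <- data.frame(transcript_id = "a", log2fc = 0)
  expect_equal(threshold_counts(fc0), c(increase = 0L, decrease = 0L))
  expect_equal(threshold_counts(fc, transcript_ids = c("b", "c")),
               c(increase = 1L, decrease = 0L))
})
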