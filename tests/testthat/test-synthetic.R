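test_that("the generator is deterministic: same seed, byte-identical files", {
  cfg <- sim_config(n_transcripts = 60, seed = 3)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(simulate_dataset(cfg), d1)
  write_dataset(simulate_dataset(cfg), d2)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 10)
  expect_setequal(files, list.files(d2, recursive = TRUE))
  for (f in files)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
})

test_that("lncRNA is the largest non-coding biotype and lengths track the config", {
  cfg <- sim_config(n_transcripts = 2000, seed = 21)
  txome <- generate_transcriptome(cfg)
  tx <- txome$annotation$transcripts
  bt <- table(tx$biotype[tx$biotype != "mRNA"])
  expect_true(all(bt["lncRNA"] > bt[setdiff(names(bt), "lncRNA")]))
  # law of large numbers: mean 3'UTR length within 10% of the configured mean
  coding <- tx$biotype == "mRNA"
  expect_lt(abs(mean(tx$utr3_len[coding]) / cfg$utr3_len - 1), 0.10)
  expect_lt(abs(mean(tx$utr5_len[coding]) / cfg$utr5_len - 1), 0.10)
  # non-overlapping footprints per chromosome
  for (ch in unique(tx$chrom)) {
    s <- tx[tx$chrom == ch, ]
    s <- s[order(s$start), ]
    expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
  }
})

test_that("planted peaks are 150-200 nt, exonic, and class-positioned", {
  cfg <- sim_config(n_transcripts = 800, seed = 13)
  txome <- generate_transcriptome(cfg)
  pl <- plant_peaks(txome, cfg)
  pk <- pl$truth$peaks
  tx <- txome$annotation$transcripts

  lens <- pk$tx_end - pk$tx_start
  expect_true(all(lens >= 150 & lens <= 200))
  # classes partition the planted peaks
  expect_setequal(unique(pk$class), c("stress", "control", "shared"))
  # every peak's nucleotides lie in exons of its host
  for (j in sample(nrow(pk), 50)) {
    L <- tx$tx_len[match(pk$transcript_id[j], tx$transcript_id)]
    expect_true(pk$tx_start[j] >= 0 && pk$tx_end[j] <= L)
    g <- transcript_to_genome(txome$annotation, pk$transcript_id[j],
                              pk$tx_start[j]:(pk$tx_end[j] - 1L))
    expect_false(anyNA(g))
  }

  # stress-only peaks hit the 5'UTR/start region more often than shared
  u5_start_frac <- function(cls) {
    sub <- pk[pk$class == cls, ]
    sub <- sub[tx$cds_len[match(sub$transcript_id, tx$transcript_id)] > 0, ]
    hit <- mapply(function(id, s, e) {
      u5 <- tx$utr5_len[match(id, tx$transcript_id)]
      s < u5 + 3L   # overlaps 5'UTR or start codon
    }, sub$transcript_id, sub$tx_start, sub$tx_end)
    mean(hit)
  }
  expect_gt(u5_start_frac("stress"), u5_start_frac("shared"))
})

test_that("a degenerate 3'UTR bias vector places every shared peak in the 3'UTR", {
  bias1 <- c(utr5 = 0, start = 0, cds = 0, stop = 0, utr3 = 1)
  cfg <- sim_config(n_transcripts = 300, seed = 5, frac_noncoding = 0,
                    positional_bias = list(shared = bias1, stress = bias1,
                                           control = bias1))
  txome <- generate_transcriptome(cfg)
  pl <- plant_peaks(txome, cfg)
  pk <- pl$truth$peaks
  tx <- txome$annotation$transcripts
  u3_start <- tx$utr5_len + tx$cds_len
  m <- match(pk$transcript_id, tx$transcript_id)
  # 3'UTR is >= 80 nt but can be shorter than the peak; the peak then
  # overlaps the 3'UTR even if it spills upstream
  expect_true(all(pk$tx_end > u3_start[m]))
  fully <- (tx$utr3_len[m] >= (pk$tx_end - pk$tx_start))
  expect_true(all(pk$tx_start[fully] >= u3_start[m][fully]))
})

test_that("IP windows recover the configured enrichment and the null is flat", {
  cfg <- sim_config(n_transcripts = 250, seed = 17, dispersion = 0)
  txome <- generate_transcriptome(cfg)
  pl <- plant_peaks(txome, cfg)
  tracks <- simulate_ip_counts(txome, pl$truth, cfg)
  frac <- m6Adyn:::.peak_cover_fraction(txome$annotation, pl$truth,
                                        txome$chrom_lengths, cfg,
                                        c("shared", "stress"))
  base <- m6Adyn:::.baseline_profile(txome$annotation, txome$chrom_lengths,
                                     cfg)
  fr <- unlist(frac); bs <- unlist(base)
  inside <- fr == 1; outside <- fr == 0 & bs > 0
  ip <- unlist(tracks$ip_copper_1$counts)
  inp <- unlist(tracks$input_copper_1$counts)
  # empirical IP/input fold inside planted peaks ~ ip_enrichment (+/- 10%)
  fold <- (mean(ip[inside]) / mean(inp[inside]))
  expect_lt(abs(fold / cfg$ip_enrichment - 1), 0.10)
  expect_lt(abs(mean(ip[outside]) / mean(inp[outside]) - 1), 0.05)

  # ip_enrichment = 1: equal expected means everywhere
  cfg1 <- sim_config(n_transcripts = 250, seed = 17, dispersion = 0,
                     ip_enrichment = 1)
  tr1 <- simulate_ip_counts(txome, pl$truth, cfg1)
  ip1 <- unlist(tr1$ip_copper_1$counts)
  in1 <- unlist(tr1$input_copper_1$counts)
  expect_lt(abs(mean(ip1[inside]) / mean(in1[inside]) - 1), 0.10)

  # dispersion -> 0 gives the Poisson variance/mean limit on uniform windows
  hom <- bs == cfg$window_size * cfg$region_weights[["cds"]]
  vm <- var(inp[hom]) / mean(inp[hom])
  expect_lt(abs(vm - 1), 0.10)
})

test_that("window counts match the configured NB law (goodness of fit)", {
  cfg <- sim_config(n_transcripts = 500, seed = 29)
  txome <- generate_transcriptome(cfg)
  pl <- plant_peaks(txome, cfg)
  tracks <- simulate_ip_counts(txome, pl$truth, cfg)
  base <- m6Adyn:::.baseline_profile(txome$annotation, txome$chrom_lengths,
                                     cfg)
  bs <- unlist(base)
  mu <- cfg$depth * cfg$region_weights[["cds"]]
  hom <- bs == cfg$window_size * cfg$region_weights[["cds"]]
  x <- unlist(tracks$input_control_1$counts)[hom]
  expect_gt(length(x), 10000)
  # chi-square GoF against NB(mu, size = 1/dispersion), tails pooled
  brk <- stats::qnbinom(seq(0, 1, length.out = 21), size = 1 / cfg$dispersion,
                        mu = mu)
  brk <- unique(c(-1, brk[-c(1, 21)], Inf))
  obs <- table(cut(x, brk))
  pr <- diff(stats::pnbinom(brk, size = 1 / cfg$dispersion, mu = mu))
  gof <- suppressWarnings(stats::chisq.test(as.integer(obs), p = pr,
                                            rescale.p = TRUE))
  expect_gt(gof$p.value, 0.01)
})

test_that("expression matrices carry the replicate layout and planted shifts", {
  cfg <- sim_config(n_transcripts = 2000, seed = 31, frac_methylated = 0.75,
                    frac_stress_only = 1 / 3, frac_control_only = 1 / 3)
  sim <- simulate_dataset(cfg, tracks = FALSE)
  cd_rna <- SummarizedExperiment::colData(sim$rna)
  cd_poly <- SummarizedExperiment::colData(sim$polysome)
  expect_equal(unname(table(cd_rna$condition)["control"]), 3L)
  expect_equal(unname(table(cd_rna$condition)["copper"]), 3L)
  expect_equal(unname(table(cd_poly$condition)["control"]), 2L)
  expect_equal(unname(table(cd_poly$condition)["copper"]), 2L)

  # mean empirical log2 fold change of stress-enriched mRNA hosts ~ +0.5
  m <- SummarizedExperiment::assay(sim$rna, "counts")
  cond <- cd_rna$condition
  lfc <- log2((rowMeans(m[, cond == "copper"]) + 1) /
                (rowMeans(m[, cond == "control"]) + 1))
  eff <- sim$truth$tx_effects
  sel <- eff$category == "stress-enriched" & eff$biotype == "mRNA"
  expect_lt(abs(mean(lfc[sel]) - cfg$lfc_shift_stress_enriched), 0.1)
  sel0 <- eff$category == "shared" & eff$biotype == "mRNA"
  expect_lt(abs(mean(lfc[sel0])), 0.1)
})

test_that("zero planted shifts leave category means statistically null", {
  cfg <- sim_config(n_transcripts = 2000, seed = 37,
                    lfc_shift_stress_enriched = 0,
                    lfc_shift_control_enriched = 0,
                    lfc_shift_lncRNA_stress = 0,
                    occupancy_shift_stress_enriched = 0)
  sim <- simulate_dataset(cfg, tracks = FALSE)
  m <- SummarizedExperiment::assay(sim$rna, "counts")
  cond <- SummarizedExperiment::colData(sim$rna)$condition
  lfc <- log2((rowMeans(m[, cond == "copper"]) + 1) /
                (rowMeans(m[, cond == "control"]) + 1))
  eff <- sim$truth$tx_effects
  tt <- t.test(lfc[eff$category == "stress-enriched"],
               lfc[eff$category == "shared"])
  expect_lt(abs(tt$statistic), 3)
})

test_that("config validation rejects out-of-domain parameters", {
  expect_error(sim_config(frac_methylated = 1.2), "frac_methylated")
  expect_error(sim_config(ip_enrichment = 0.5), "ip_enrichment")
  expect_error(sim_config(depth = 0), "depth")
  expect_error(sim_config(motif = "UGUA"), "motif")
  bad <- list(shared = c(utr5 = 0.5, start = 0.5, cds = 0.5, stop = 0,
                         utr3 = 0),
              stress = c(utr5 = 0.2, start = 0.2, cds = 0.25, stop = 0.1,
                         utr3 = 0.25),
              control = c(utr5 = 0.2, start = 0.2, cds = 0.25, stop = 0.1,
                          utr3 = 0.25))
  expect_error(sim_config(positional_bias = bad), "positional_bias")
})

test_that("YAML configs load with overrides and warn on unknown fields", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_transcripts: 42", "seed: 9", "bogus_field: 1"), f)
  expect_warning(cfg <- read_config(f), "bogus_field")
  expect_equal(cfg$n_transcripts, 42)
  expect_equal(cfg$seed, 9)
  expect_equal(cfg$depth, 30)  # untouched default
})
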