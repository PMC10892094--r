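#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generator with defaults that
#' emulate the copper-stress MeRIP-seq study design: 3 IP + 3 input
#' replicates per condition for peak calling, 3 x 2 RNA-seq and 2 x 2
#' polysome-seq replicates, peaks of 150-200 nt planted with a 3'UTR bias
#' (shared class) or elevated 5'UTR/start-codon probability (condition-only
#' classes), a UGUA motif (DNA "TGTA" on the sense strand) enriched inside
#' peak regions, and condition-dependent abundance / polysome-occupancy
#' effects keyed to the m6A category of the host transcript.
#'
#' @param n_transcripts Number of transcripts.
#' @param utr5_len,cds_len,utr3_len Mean segment lengths, nt (coding
#'   transcripts).
#' @param nc_len Mean length of non-coding transcripts, nt.
#' @param frac_noncoding Fraction of non-coding transcripts (biotypes drawn
#'   deterministically as lncRNA 50%, ncRNA 25%, miRNA_precursor 12.5%,
#'   snoRNA 12.5%, so lncRNA is always the largest class).
#' @param frac_methylated Fraction of transcripts hosting a planted peak.
#' @param frac_stress_only,frac_control_only Class shares among methylated
#'   transcripts (the remainder is shared; defaults mirror the roughly
#'   13/15/72 split of condition-specific and shared peaks in copper-stress
#'   Arabidopsis data).
#' @param positional_bias Named list of probability vectors over the regions
#'   `(utr5, start, cds, stop, utr3)` for the `shared`, `stress` and
#'   `control` peak classes ("start"/"stop" place the peak centre within
#'   +/-50 nt of the codon).
#' @param peak_len_range Planted peak length range, nt.
#' @param ip_enrichment Mean multiplier for IP windows inside an active
#'   peak (>= 1).
#' @param depth Mean input reads per window at weight 1.
#' @param window_size Simulation/caller window width, nt.
#' @param region_weights Relative input coverage of `(utr5, cds, utr3)`;
#'   the CDS weight > 1 emulates the CDS enrichment of background polyA+
#'   RNA-seq reads.
#' @param motif Planted motif, DNA alphabet, sense strand.
#' @param motif_rate_in_peaks Probability that a planted peak carries an
#'   inserted motif copy.
#' @param motif_rate_background Probability that a transcript carries an
#'   additional motif copy outside any peak.
#' @param lfc_shift_stress_enriched,lfc_shift_control_enriched Abundance
#'   shifts (log2, copper vs control) for mRNA hosts of stress-only /
#'   control-only peaks.
#' @param lfc_shift_lncRNA_stress Abundance shift for lncRNA hosts of
#'   stress-only peaks (negative: stressed non-coding hosts lose abundance,
#'   opposite to mRNA).
#' @param occupancy_shift_stress_enriched Polysome-occupancy shift (log2)
#'   for hosts of stress-only peaks under copper.
#' @param dispersion Negative-binomial inverse-size parameter (0 = Poisson).
#' @param base_mean,base_sdlog Log-normal parameters of per-transcript mean
#'   expression counts.
#' @param n_ip_reps,n_rna_reps,n_poly_reps Replicate counts.
#' @param seed Integer seed; every generator stage derives its stream from
#'   it, so outputs are byte-identical across runs.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 2000,
                       utr5_len = 150, cds_len = 1200, utr3_len = 300,
                       nc_len = 800,
                       frac_noncoding = 0.10,
                       frac_methylated = 0.60,
                       frac_stress_only = 0.13, frac_control_only = 0.15,
                       positional_bias = list(
                         shared  = c(utr5 = 0.02, start = 0.03, cds = 0.15,
                                     stop = 0.10, utr3 = 0.70),
                         stress  = c(utr5 = 0.20, start = 0.20, cds = 0.25,
                                     stop = 0.10, utr3 = 0.25),
                         control = c(utr5 = 0.20, start = 0.20, cds = 0.25,
                                     stop = 0.10, utr3 = 0.25)),
                       peak_len_range = c(150L, 200L),
                       ip_enrichment = 8, depth = 30, window_size = 25,
                       region_weights = c(utr5 = 0.8, cds = 1.3,
                                          utr3 = 0.8),
                       motif = "TGTA",
                       motif_rate_in_peaks = 0.8,
                       motif_rate_background = 0.05,
                       lfc_shift_stress_enriched = 0.5,
                       lfc_shift_control_enriched = -0.5,
                       lfc_shift_lncRNA_stress = -0.5,
                       occupancy_shift_stress_enriched = 0.5,
                       dispersion = 0.02,
                       base_mean = 150, base_sdlog = 0.8,
                       n_ip_reps = 3, n_rna_reps = 3, n_poly_reps = 2,
                       seed = 1) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Validate a simulation configuration
#'
#' Checks fraction domains, probability-vector sums, depth/enrichment
#' bounds and the motif alphabet; errors on the first violation.
#'
#' @param cfg A `sim_config` (or plain list with the same fields).
#' @return Invisibly, `cfg`.
#' @export
validate_sim_config <- function(cfg) {
  frac01 <- c("frac_noncoding", "frac_methylated", "frac_stress_only",
              "frac_control_only", "motif_rate_in_peaks",
              "motif_rate_background")
  for (f in frac01)
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
  if (cfg$frac_stress_only + cfg$frac_control_only > 1)
    stop("class fractions exceed 1")
  for (cls in c("shared", "stress", "control")) {
    v <- cfg$positional_bias[[cls]]
    if (is.null(v) || length(v) != 5 || any(v < 0) ||
        abs(sum(v) - 1) > 1e-8)
      stop("positional_bias$", cls,
           " must be a length-5 probability vector summing to 1")
  }
  if (cfg$depth <= 0) stop("depth must be > 0")
  if (cfg$ip_enrichment < 1) stop("ip_enrichment must be >= 1")
  if (cfg$dispersion < 0) stop("dispersion must be >= 0")
  if (cfg$window_size <= 0) stop("window_size must be > 0")
  if (diff(cfg$peak_len_range) < 0 || cfg$peak_len_range[1] <= 0)
    stop("invalid peak_len_range")
  if (nchar(cfg$motif) < 1 ||
      !all(strsplit(cfg$motif, "")[[1]] %in% c("A", "C", "G", "T")))
    stop("motif must be a non-empty DNA string")
  if (cfg$seed != as.integer(cfg$seed)) stop("seed must be an integer")
  invisible(cfg)
}

#' Load a simulation / pipeline configuration from YAML
#'
#' Scalar fields override [sim_config()] defaults; `positional_bias` may be
#' given as a mapping of class name to a 5-element list.
#'
#' @param path YAML file.
#' @return A `sim_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  defaults <- formals(sim_config)
  known <- intersect(names(y), names(defaults))
  unknown <- setdiff(names(y), names(defaults))
  if (length(unknown))
    warning("ignoring unknown config field(s): ", paste(unknown, collapse = ", "))
  args <- y[known]
  if (!is.null(args$positional_bias))
    args$positional_bias <- lapply(args$positional_bias, function(v) {
      v <- unlist(v)
      names(v) <- c("utr5", "start", "cds", "stop", "utr3")
      v
    })
  if (!is.null(args$region_weights)) {
    args$region_weights <- unlist(args$region_weights)
    names(args$region_weights) <- c("utr5", "cds", "utr3")
  }
  if (!is.null(args$peak_len_range))
    args$peak_len_range <- as.integer(unlist(args$peak_len_range))
  do.call(sim_config, args)
}
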