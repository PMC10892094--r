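Package: m6Adyn
Title: Condition-Specific m6A Epitranscriptome Dynamics from MeRIP-Seq Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for analysing N6-methyladenosine (m6A)
    epitranscriptome dynamics between two conditions from windowed
    m6A-IP-seq (MeRIP-seq) coverage tracks. Provides a strand-split
    Poisson enrichment peak caller (IP versus scaled input), replicate
    consensus peak building, stress-enriched / control-enriched / shared
    peak and transcript classification, binned metagene density and
    per-nucleotide methylation-frequency profiles around start and stop
    codons, median-of-ratios normalisation with abundance fold changes,
    polysome-occupancy statistics by m6A category, k-mer motif enrichment
    against dinucleotide-preserving shuffled backgrounds, and non-coding
    RNA biotype breakdowns. A fully parameterised synthetic-data
    generator with known ground truth (planted peaks, motifs and effect
    sizes) makes every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
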