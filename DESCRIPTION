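Package: epiqc
Title: Quality Control Metrics for ChIP-seq and DNase-seq Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the three layers of quality metrics used to triage
    ChIP-seq and DNase-seq experiments: read-layer metrics (median base
    quality, uniquely mapped ratio, contamination screen, library
    complexity as NRF and PBC at a fixed subsample depth), ChIP-layer
    metrics (peak census at fold-enrichment cutoffs, fraction of reads in
    peaks, replicate signal correlation and peak-overlap consistency) and
    annotation-layer metrics (meta-region distribution of peak summits,
    conservation profiles, union-DHS and blacklist overlap of top peaks,
    and distance-weighted regulatory potential of genes). Includes a
    historical QC atlas with percentile lookup and good/bad threshold
    flagging, a deterministic synthetic-data generator with bookkept
    ground truth for every metric, and a one-command QC runner that emits
    a metrics JSON and a markdown report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
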