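# ChIP-layer metrics: peak census at fold-enrichment cutoffs, fraction of
# reads in peaks (FRiP) at the fixed subsample depth, and replicate
# consistency (RPM-normalised binned Pearson correlation + peak overlap).

#' Peak census at fold-enrichment cutoffs
#'
#' High-quality datasets show many peaks and a high fraction passing the
#' 10x / 20x fold-enrichment cutoffs ("10- and 20-fold confident peaks").
#' Thresholds are applied inclusively (>= 10, >= 20) and are configurable.
#'
#' @param peaks Peak tibble with a `fold_enrichment` column.
#' @param fc_thresholds Two ascending cutoffs (default `c(10, 20)`).
#' @return One-row tibble `n_peaks`, `n_fc10`, `n_fc20`.
#' @export
peak_census <- function(peaks, fc_thresholds = c(10, 20)) {
  stopifnot(length(fc_thresholds) == 2, fc_thresholds[1] <= fc_thresholds[2])
  tibble(
    n_peaks = nrow(peaks),
    n_fc10 = sum(peaks$fold_enrichment >= fc_thresholds[1]),
    n_fc20 = sum(peaks$fold_enrichment >= fc_thresholds[2])
  )
}

#' Fraction of reads in peaks (FRiP)
#'
#' The signal-to-noise measure of ChIP enrichment: the fraction of
#' non-mitochondrial uniquely mapped reads whose 5' position falls inside
#' a peak. Reads are subsampled to a fixed depth (default 4 million)
#' first, because FRiP grows with sequencing depth; when fewer reads are
#' available all of them are used and `below_subsample_depth` is set.
#' Peaks are expected to be called from all reads — with that convention
#' the subsampled FRiP is approximately depth-stable. Membership uses the
#' read's 5' base only, under half-open coordinates (`pos5 == end` is
#' outside the peak).
#'
#' @param reads Uniquely mapped read tibble.
#' @param peaks Peak tibble (all-reads peak calls).
#' @param subsample Fixed depth (default 4e6).
#' @param mito_names Chromosome names treated as mitochondrial and dropped.
#' @param seed Integer seed for the subsample.
#' @return One-row tibble with `frip`, `subsample_depth_used`,
#'   `below_subsample_depth`.
#' @export
compute_frip <- function(reads, peaks, subsample = 4e6,
                         mito_names = c("chrM", "MT", "chrMT"), seed = 1) {
  sub <- subsample_reads(reads, n = subsample, seed = seed)
  depth <- attr(sub, "subsample_depth_used")
  below <- attr(sub, "below_subsample_depth")
  sub <- sub[!(sub$chrom %in% mito_names), , drop = FALSE]
  if (!nrow(sub)) abort("no non-mitochondrial reads: cannot compute FRiP")
  if (!nrow(peaks)) {
    warn("empty peak set: FRiP reported as 0")
    return(tibble(frip = 0, subsample_depth_used = depth,
                  below_subsample_depth = below))
  }
  pts <- tibble(chrom = sub$chrom, start = sub$pos5, end = sub$pos5 + 1L)
  hit <- overlaps_any(pts, peaks)
  tibble(frip = mean(hit), subsample_depth_used = depth,
         below_subsample_depth = below)
}

#' Pearson correlation of two RPM-normalised signal tracks
#'
#' Each track is scaled to reads per million (1e6 / total signal) and the
#' Pearson correlation is computed over the concatenated bins of all
#' shared chromosomes. The metric is invariant to positive rescaling of
#' either track. A zero-variance (flat or empty) track yields NaN with a
#' warning rather than a silent drop.
#'
#' @param track_a,track_b `epiqc_track` tibbles with identical bin size.
#' @return Pearson r in [-1, 1], or NaN for a flat track.
#' @export
wiggle_correlation <- function(track_a, track_b) {
  ba <- attr(track_a, "bin_size"); bb <- attr(track_b, "bin_size")
  if (!identical(ba, bb)) abort("tracks have different bin sizes")
  shared <- intersect(unique(track_a$chrom), unique(track_b$chrom))
  if (!length(shared)) abort("tracks share no chromosomes")
  a <- track_a[track_a$chrom %in% shared, ]
  b <- track_b[track_b$chrom %in% shared, ]
  m <- dplyr::inner_join(a, b, by = c("chrom", "bin"),
                         suffix = c("_a", "_b"))
  ta <- attr(track_a, "total_signal"); tb <- attr(track_b, "total_signal")
  va <- m$value_a * (1e6 / ta)
  vb <- m$value_b * (1e6 / tb)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0 || !is.finite(stats::sd(va)) ||
      !is.finite(stats::sd(vb))) {
    warn("flat signal track: correlation undefined (NaN)")
    return(NaN)
  }
  cor(va, vb)
}

#' Peak-overlap consistency between two replicates
#'
#' The number of peaks of the LARGER set that overlap at least one peak of
#' the smaller set, divided by the larger peak number — numerator and
#' denominator refer to the same set, so the ratio lies in [0, 1] and the
#' unordered pair is well defined (ties broken by the first argument).
#'
#' @param peaks_a,peaks_b Non-empty peak tibbles.
#' @return Overlap ratio in [0, 1].
#' @export
peak_overlap_consistency <- function(peaks_a, peaks_b) {
  if (!nrow(peaks_a) || !nrow(peaks_b))
    abort("both replicates need at least one peak")
  if (nrow(peaks_b) > nrow(peaks_a)) {
    larger <- peaks_b; smaller <- peaks_a
  } else {
    larger <- peaks_a; smaller <- peaks_b
  }
  mean(overlaps_any(larger, smaller))
}

#' Consistency metrics for every replicate pair
#'
#' Computes the wiggle correlation and peak-overlap ratio for each of the
#' C(k, 2) unordered pairs of replicates.
#'
#' @param replicates List of replicates, each a list with elements `reads`
#'   (tibble) and `peaks` (tibble); optionally `id`.
#' @param chrom_sizes Genome sizes for signal binning.
#' @param bin_size Correlation bin width in bp (default 1000).
#' @return Tibble with one row per pair: `id_a`, `id_b`,
#'   `wiggle_correlation`, `peak_overlap_ratio`. Empty (with a message)
#'   when fewer than two replicates are supplied.
#' @export
pairwise_consistency <- function(replicates, chrom_sizes, bin_size = 1000) {
  k <- length(replicates)
  ids <- purrr::imap_chr(replicates, function(r, i) r$id %||% paste0("rep", i))
  empty <- tibble(id_a = character(), id_b = character(),
                  wiggle_correlation = numeric(), peak_overlap_ratio = numeric())
  if (k < 2) {
    message("fewer than 2 replicates: no consistency metrics")
    return(empty)
  }
  tracks <- lapply(replicates, function(r)
    bin_reads(r$reads, chrom_sizes, bin_size = bin_size))
  pairs <- utils::combn(k, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    tibble(
      id_a = ids[i1], id_b = ids[i2],
      wiggle_correlation = wiggle_correlation(tracks[[i1]], tracks[[i2]]),
      peak_overlap_ratio = peak_overlap_consistency(replicates[[i1]]$peaks,
                                                    replicates[[i2]]$peaks)
    )
  })
}
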