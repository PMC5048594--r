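# Annotation-layer metrics: genomic context of the peaks. Summit-centred
# meta-region distribution, conservation profile, overlap of the top peaks
# with union-DHS / blacklist region sets, and distance-weighted regulatory
# potential of genes.

#' Summit positions of a peak set
#'
#' narrowPeak summits are `start + summit_offset`; peaks without a summit
#' (broadPeak, plain BED, `summit_offset = -1`) use the interval midpoint
#' `floor((start + end) / 2)`.
#'
#' @param peaks Peak tibble.
#' @return Tibble with columns `chrom`, `position` (0-based).
#' @export
summit_positions <- function(peaks) {
  off <- peaks$summit_offset %||% rep(-1L, nrow(peaks))
  pos <- ifelse(off >= 0, peaks$start + off,
                (peaks$start + peaks$end) %/% 2L)
  tibble(chrom = peaks$chrom, position = as.integer(pos))
}

#' Meta-region distribution of peak summits
#'
#' Assigns each summit exactly one label with precedence
#' promoter > exon > intron > intergenic: promoter is TSS +/-
#' `promoter_window` bp (any transcript), exon is inside an annotated
#' exon, intron is inside a transcript body but not exon/promoter, and
#' everything else is intergenic. Fractions sum to 1.
#'
#' @param summits Tibble from [summit_positions()] (`chrom`, `position`).
#' @param genes Gene tibble from [read_gene_table()].
#' @param promoter_window Half-width of the promoter window (default 2000).
#' @return One-row tibble with fractions `promoter`, `exon`, `intron`,
#'   `intergenic` and the count `n_summits`; attribute `labels` carries
#'   the per-summit assignment.
#' @export
classify_summits <- function(summits, genes, promoter_window = 2000) {
  if (!nrow(summits)) abort("no summits to classify")
  pts <- tibble(chrom = summits$chrom, start = summits$position,
                end = summits$position + 1L)
  promoters <- tibble(chrom = genes$chrom,
                      start = pmax(0L, genes$tss - as.integer(promoter_window)),
                      end = genes$tss + as.integer(promoter_window) + 1L)
  exons <- tibble(
    chrom = rep(genes$chrom, lengths(genes$exon_starts)),
    start = unlist(genes$exon_starts, use.names = FALSE) %||% integer(),
    end = unlist(genes$exon_ends, use.names = FALSE) %||% integer()
  )
  bodies <- tibble(chrom = genes$chrom, start = genes$tx_start,
                   end = genes$tx_end)
  in_prom <- if (nrow(promoters)) overlaps_any(pts, promoters) else rep(FALSE, nrow(pts))
  in_exon <- if (nrow(exons)) overlaps_any(pts, exons) else rep(FALSE, nrow(pts))
  in_body <- if (nrow(bodies)) overlaps_any(pts, bodies) else rep(FALSE, nrow(pts))
  labels <- ifelse(in_prom, "promoter",
            ifelse(in_exon, "exon",
            ifelse(in_body, "intron", "intergenic")))
  n <- length(labels)
  out <- tibble(
    promoter = sum(labels == "promoter") / n,
    exon = sum(labels == "exon") / n,
    intron = sum(labels == "intron") / n,
    intergenic = sum(labels == "intergenic") / n,
    n_summits = n
  )
  attr(out, "labels") <- labels
  out
}

#' Top peaks by score
#'
#' Sorted by MACS score descending; ties broken by (chrom, start)
#' ascending so the selection is deterministic.
#'
#' @param peaks Peak tibble.
#' @param n Number of peaks to keep (default 5000).
#' @return The first `min(n, nrow(peaks))` peaks in that order.
#' @export
top_peaks <- function(peaks, n = 5000) {
  stopifnot(n >= 1)
  peaks %>%
    arrange(dplyr::desc(.data$score), .data$chrom, .data$start) %>%
    head(n)
}

#' Fraction of peaks overlapping a region set
#'
#' Used for the union-DHS and blacklist overlap ratios of the top peaks.
#' Overlap means >= 1 shared bp; regions should be pre-merged with
#' [merge_intervals()].
#'
#' @param peaks Non-empty peak tibble.
#' @param regions Merged region tibble.
#' @return Fraction in [0, 1].
#' @export
region_overlap_ratio <- function(peaks, regions) {
  if (!nrow(peaks)) abort("empty peak list")
  mean(overlaps_any(peaks, regions))
}

#' Average conservation profile around peak summits
#'
#' Averages a per-base conservation track (e.g. PhastCons, supplied as a
#' bedGraph tibble) over windows of +/- `flank` bp centred on the summits,
#' binned into `bin`-bp offset bins. Bases not covered by the track read
#' as 0 (counted in `n_uncovered_bases` with a warning); summits within
#' `flank` of a chromosome edge are zero-padded and tallied in
#' `n_truncated`.
#'
#' @param summits Tibble (`chrom`, `position`).
#' @param track bedGraph tibble (`chrom`, `start`, `end`, `value`).
#' @param flank Half-window in bp (default 2000).
#' @param bin Offset-bin width in bp (default 50); must divide `2 * flank`.
#' @param chrom_sizes Optional chrom sizes to detect right-edge truncation.
#' @return Tibble of class `epiqc_profile` with columns `offset` (bin
#'   centre relative to the summit, bp) and `value` (mean conservation);
#'   attributes `flank`, `bin`, `n_summits`, `n_truncated`.
#' @export
conservation_profile <- function(summits, track, flank = 2000, bin = 50,
                                 chrom_sizes = NULL) {
  if (!nrow(summits)) abort("no summits")
  if ((2 * flank) %% bin != 0) abort("bin must divide 2 * flank")
  width <- as.integer(2 * flank)
  acc <- numeric(width)
  n_trunc <- 0L
  uncovered <- 0L
  cs <- if (!is.null(chrom_sizes)) as_chrom_sizes(chrom_sizes) else NULL

  for (ch in unique(summits$chrom)) {
    s <- summits$position[summits$chrom == ch]
    tr <- track[track$chrom == ch, , drop = FALSE]
    chrom_len <- if (!is.null(cs) && ch %in% cs$chrom)
      cs$size[cs$chrom == ch] else Inf
    needed <- min(max(s) + flank, chrom_len)
    tr <- tr[tr$start < needed, , drop = FALSE]
    rle <- if (nrow(tr)) {
      IRanges::coverage(
        IRanges::IRanges(start = tr$start + 1L, end = pmin(tr$end, needed)),
        weight = tr$value, width = as.integer(needed))
    } else S4Vectors::Rle(0, as.integer(max(needed, 1)))
    covered_len <- length(rle)
    for (pos in s) {
      # window covers 0-based positions [pos - flank, pos + flank)
      lo <- pos - flank + 1L  # 1-based
      hi <- pos + flank
      clip_lo <- max(lo, 1L)
      clip_hi <- min(hi, covered_len, chrom_len)
      vals <- numeric(width)
      covered_here <- 0L
      if (clip_hi >= clip_lo) {
        seg <- as.numeric(S4Vectors::window(rle, clip_lo, clip_hi))
        vals[(clip_lo - lo + 1L):(clip_lo - lo + length(seg))] <- seg
        covered_here <- length(seg)
      }
      if (lo < 1L || hi > chrom_len) n_trunc <- n_trunc + 1L
      uncovered <- uncovered + (width - covered_here)
      acc <- acc + vals
    }
  }
  n <- nrow(summits)
  per_base <- acc / n
  n_bins <- width %/% bin
  binned <- vapply(seq_len(n_bins), function(b)
    mean(per_base[((b - 1L) * bin + 1L):(b * bin)]), numeric(1))
  offsets <- -flank + (seq_len(n_bins) - 0.5) * bin
  if (uncovered > 0)
    warn(sprintf("%d window bases not covered by the track (read as 0)",
                 uncovered))
  structure(
    tibble(offset = offsets, value = binned),
    flank = flank, bin = bin, n_summits = n, n_truncated = n_trunc,
    class = c("epiqc_profile", class(tibble()))
  )
}

rp_weight_fun <- function(weight, max_dist, d0 = 10000) {
  if (is.function(weight)) return(weight)
  switch(weight,
    cistrome = function(d) exp(-(0.5 + 4 * d / max_dist)),
    exp2 = function(d) 2^(-d / d0),
    uniform = function(d) rep(1, length(d)),
    abort(sprintf("unknown regulatory-potential weight '%s'", weight))
  )
}

#' Regulatory potential of genes near a peak set
#'
#' For each gene, the distance-weighted sum of peak summits within
#' `max_dist` bp of its TSS: `score(g) = sum_d w(d)` over qualifying
#' peaks. Genes ranked by descending score are the putative target genes
#' of the assayed factor. The default weight is the exponential decay
#' `w(d) = exp(-(0.5 + 4 d / max_dist))`, so a peak directly at the TSS
#' contributes `exp(-0.5)`; `"exp2"` (`2^(-d/d0)`) and `"uniform"` are
#' available, or pass any non-increasing function of distance. Genes with
#' several transcripts score each transcript TSS and keep the maximum.
#'
#' @param peaks Peak tibble (summit-to-TSS distances are used).
#' @param genes Gene tibble from [read_gene_table()].
#' @param max_dist Hard distance cutoff in bp (default 100000).
#' @param weight `"cistrome"`, `"exp2"`, `"uniform"`, or a function of
#'   distance in bp.
#' @return Tibble (`gene_id`, `score`) sorted by descending score; genes
#'   with no nearby peak score 0.
#' @export
regulatory_potential <- function(peaks, genes, max_dist = 1e5,
                                 weight = "cistrome") {
  wf <- rp_weight_fun(weight, max_dist)
  summits <- summit_positions(peaks)
  tx_score <- vapply(seq_len(nrow(genes)), function(i) {
    d <- abs(summits$position[summits$chrom == genes$chrom[i]] - genes$tss[i])
    d <- d[d <= max_dist]
    if (!length(d)) 0 else sum(wf(d))
  }, numeric(1))
  tibble(gene_id = genes$gene_id, score = tx_score) %>%
    group_by(.data$gene_id) %>%
    summarise(score = max(.data$score), .groups = "drop") %>%
    arrange(dplyr::desc(.data$score), .data$gene_id)
}

#' All annotation-layer metrics for one sample
#'
#' @param peaks Peak tibble.
#' @param genes Gene tibble (or NULL to skip gene-based metrics).
#' @param dhs,blacklist Region tibbles (or NULL to skip).
#' @param conservation bedGraph tibble (or NULL to skip the profile).
#' @param top_n Top-peak count for the DHS/blacklist ratios (default 5000).
#' @param promoter_window,flank,bin,max_dist,weight Passed through to the
#'   individual metrics.
#' @return List with `meta`, `dhs_overlap_ratio`, `blacklist_overlap_ratio`,
#'   `profile`, `rp` (each NULL when its input is missing).
#' @export
annotation_layer_metrics <- function(peaks, genes = NULL, dhs = NULL,
                                     blacklist = NULL, conservation = NULL,
                                     top_n = 5000, promoter_window = 2000,
                                     flank = 2000, bin = 50, max_dist = 1e5,
                                     weight = "cistrome") {
  summits <- summit_positions(peaks)
  top <- top_peaks(peaks, n = top_n)
  list(
    meta = if (!is.null(genes)) classify_summits(summits, genes, promoter_window),
    dhs_overlap_ratio = if (!is.null(dhs))
      region_overlap_ratio(top, merge_intervals(dhs)),
    blacklist_overlap_ratio = if (!is.null(blacklist))
      region_overlap_ratio(top, merge_intervals(blacklist)),
    profile = if (!is.null(conservation))
      conservation_profile(summits, conservation, flank = flank, bin = bin),
    rp = if (!is.null(genes))
      regulatory_potential(peaks, genes, max_dist = max_dist, weight = weight)
  )
}
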