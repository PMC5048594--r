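# Read-layer metrics: raw sequence quality, mapping rate, contamination
# screen, and library complexity (NRF / PBC) at a fixed subsample depth so
# libraries of different sequencing depths are comparable.

read_fastq_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) abort(sprintf("empty FASTQ file: %s", path))
  if (length(lines) %% 4 != 0)
    abort(sprintf("truncated FASTQ (line count not a multiple of 4): %s", path))
  n <- length(lines) %/% 4
  list(seq = lines[seq(2, by = 4, length.out = n)],
       qual = lines[seq(4, by = 4, length.out = n)])
}

#' Median base quality of a FASTQ sample
#'
#' Decodes Phred+33 qualities of up to `sample_n` reads (drawn uniformly
#' without replacement under `seed`) and returns the median over all their
#' base calls. Even-sized multisets use the lower median (the element at
#' index `floor((k-1)/2)` of the sorted values), so the result is always an
#' attained Phred score.
#'
#' @param fastq_path 4-line FASTQ with Phred+33 qualities.
#' @param sample_n Maximum number of reads to sample (default 100000).
#' @param seed Integer seed controlling the read sample.
#' @return A single Phred score.
#' @export
median_base_quality <- function(fastq_path, sample_n = 100000, seed = 1) {
  stopifnot(sample_n >= 1)
  rec <- read_fastq_records(fastq_path)
  n <- length(rec$qual)
  idx <- if (n > sample_n)
    with_seed(seed, sort(sample.int(n, sample_n)))
  else seq_len(n)
  quals <- unlist(lapply(rec$qual[idx], utf8ToInt), use.names = FALSE) - 33L
  if (any(quals < 0))
    abort(sprintf("non-Phred+33 quality character in %s", fastq_path))
  if (!length(quals)) abort("no quality values found")
  sorted <- sort(quals)
  sorted[(length(sorted) - 1L) %/% 2L + 1L]
}

#' Uniquely mapped read count and ratio
#'
#' Reads with mapping quality strictly greater than `mapq_gt` (default 1)
#' count as uniquely mapped. A MAPQ of 255 means "unavailable" in SAM and
#' is treated as passing any threshold.
#'
#' @param reads Read tibble from [read_sam_min()].
#' @param mapq_gt Strict lower bound on MAPQ (default 1).
#' @param total_reads Denominator (mapped + unmapped). Defaults to the
#'   `n_total` attribute of `reads` when present, else `nrow(reads)`.
#' @return A one-row tibble with `uniquely_mapped_reads`, `total_reads`
#'   and `uniquely_mapped_ratio`.
#' @export
uniquely_mapped <- function(reads, mapq_gt = 1, total_reads = NULL) {
  total <- total_reads %||% attr(reads, "n_total") %||% nrow(reads)
  if (total == 0) abort("empty library: total reads is 0")
  cnt <- sum(reads$mapq > mapq_gt | reads$mapq == 255L)
  tibble(uniquely_mapped_reads = cnt, total_reads = total,
         uniquely_mapped_ratio = cnt / total)
}

#' Subsample reads to a fixed depth
#'
#' Uniform sample without replacement of `min(n, nrow(reads))` reads,
#' deterministic for a fixed seed (index sampling, no hash ordering).
#' When the library holds fewer than `n` reads the full set is returned
#' and the attribute `below_subsample_depth` is set, mirroring the
#' convention of evaluating shallow samples with all reads.
#'
#' @param reads Read tibble.
#' @param n Target depth (default 4 million uniquely mapped reads).
#' @param seed Integer seed.
#' @return Read tibble with attributes `below_subsample_depth` and
#'   `subsample_depth_used`.
#' @export
subsample_reads <- function(reads, n = 4e6, seed = 1) {
  stopifnot(n >= 1)
  total <- nrow(reads)
  if (total <= n) {
    out <- reads
    attr(out, "below_subsample_depth") <- total < n
    attr(out, "subsample_depth_used") <- total
    return(out)
  }
  idx <- with_seed(seed, sort(sample.int(total, n)))
  out <- reads[idx, , drop = FALSE]
  attr(out, "below_subsample_depth") <- FALSE
  attr(out, "subsample_depth_used") <- as.integer(n)
  out
}

#' Count reads per genomic location
#'
#' A location is a (chrom, pos5, strand) triple: the stranded 5' position,
#' the unit of library-complexity metrics. Input is assumed to be already
#' filtered to uniquely mapped reads and subsampled to the fixed depth.
#'
#' @param reads Read tibble with `chrom`, `pos5`, `strand`.
#' @return Tibble with columns `chrom`, `pos5`, `strand`, `count`;
#'   attribute `n_reads` preserves the total.
#' @export
location_counts <- function(reads) {
  out <- reads %>%
    count(.data$chrom, .data$pos5, .data$strand, name = "count") %>%
    ungroup()
  attr(out, "n_reads") <- nrow(reads)
  out
}

#' Non-redundant fraction (NRF)
#'
#' Number of distinct read locations divided by the number of uniquely
#' mapped reads in the (subsampled) library. 1 means no positional
#' duplicates at all.
#'
#' @param lc Location-count tibble from [location_counts()].
#' @return NRF in (0, 1].
#' @export
compute_nrf <- function(lc) {
  n_reads <- attr(lc, "n_reads") %||% sum(lc$count)
  if (!nrow(lc) || n_reads == 0) abort("no locations: empty read set")
  nrow(lc) / n_reads
}

#' PCR bottleneck coefficient (PBC)
#'
#' Locations covered by exactly one uniquely mapped read divided by all
#' distinct locations. Values near 1 indicate a complex library; low
#' values indicate PCR over-amplification.
#'
#' @param lc Location-count tibble from [location_counts()].
#' @return PBC in [0, 1].
#' @export
compute_pbc <- function(lc) {
  if (!nrow(lc)) abort("no locations: empty read set")
  sum(lc$count == 1L) / nrow(lc)
}

#' Contamination screen over a panel of species
#'
#' Subsamples `n` reads from the FASTQ (the same subsample for every
#' species) and reports, per species, the fraction that maps under the
#' supplied mapper. Mappers are injected functions taking a character
#' vector of read sequences and returning a logical vector (mapped or
#' not): plug in a real aligner wrapper or the exact-substring mapper from
#' [make_exact_mapper()].
#'
#' @param fastq_path FASTQ path.
#' @param mappers Named list of mapping functions, one per species.
#' @param n Subsample size (default 100000 reads).
#' @param seed Integer seed.
#' @return Tibble with columns `species` and `mapped_fraction`.
#' @export
contamination_screen <- function(fastq_path, mappers, n = 1e5, seed = 1) {
  if (!length(mappers)) abort("at least one species mapper is required")
  if (is.null(names(mappers)) || any(!nzchar(names(mappers))))
    abort("mappers must be a named list (species -> function)")
  rec <- read_fastq_records(fastq_path)
  total <- length(rec$seq)
  idx <- if (total > n) with_seed(seed, sort(sample.int(total, n))) else seq_len(total)
  seqs <- rec$seq[idx]
  tibble(
    species = names(mappers),
    mapped_fraction = unname(vapply(mappers,
                                    function(f) mean(as.logical(f(seqs))),
                                    numeric(1)))
  )
}

#' Exact-substring mapper for contamination fixtures
#'
#' Returns a mapper closure that calls a read "mapped" iff its sequence
#' occurs verbatim in the given genome (forward strand). Intended for
#' synthetic contamination fixtures where reads are literal genome
#' substrings; real screens would wrap an aligner instead.
#'
#' @param genome_seq Single character string, the genome sequence.
#' @return Function: character vector of read sequences -> logical vector.
#' @export
make_exact_mapper <- function(genome_seq) {
  force(genome_seq)
  function(seqs) {
    vapply(seqs, function(s) grepl(s, genome_seq, fixed = TRUE), logical(1),
           USE.NAMES = FALSE)
  }
}

#' All read-layer metrics for one library
#'
#' Applies the fixed-depth contract: uniquely mapped reads are subsampled
#' to `subsample_depth` before location counting, so NRF/PBC are
#' comparable across libraries of different depths.
#'
#' @param reads Read tibble from [read_sam_min()].
#' @param fastq_path Optional FASTQ for the median-quality metric.
#' @param mapq_gt Strict MAPQ threshold for "uniquely mapped" (default 1).
#' @param subsample_depth Depth for NRF/PBC (default 4 million).
#' @param seed Integer seed.
#' @param quality_sample_n Reads sampled for the quality median.
#' @return One-row tibble of read-layer metrics.
#' @export
read_layer_metrics <- function(reads, fastq_path = NULL, mapq_gt = 1,
                               subsample_depth = 4e6, seed = 1,
                               quality_sample_n = 100000) {
  um <- uniquely_mapped(reads, mapq_gt = mapq_gt)
  uniq <- reads[reads$mapq > mapq_gt | reads$mapq == 255L, , drop = FALSE]
  sub <- subsample_reads(uniq, n = subsample_depth, seed = seed)
  lc <- location_counts(sub)
  mq <- if (!is.null(fastq_path))
    median_base_quality(fastq_path, sample_n = quality_sample_n, seed = seed)
  else NA_real_
  tibble(
    median_quality = as.numeric(mq),
    total_reads = um$total_reads,
    uniquely_mapped_reads = um$uniquely_mapped_reads,
    uniquely_mapped_ratio = um$uniquely_mapped_ratio,
    subsample_depth_used = attr(sub, "subsample_depth_used"),
    below_subsample_depth = attr(sub, "below_subsample_depth"),
    unique_locations = nrow(lc),
    nrf = compute_nrf(lc),
    pbc = compute_pbc(lc)
  )
}
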