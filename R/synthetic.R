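# Synthetic fixture generator. Every generator draws all randomness from
# an explicit seed and carries an independently bookkept truth record
# (computed from the generation bookkeeping, never by calling the metric
# functions under test), so each metric has an exact or analytic expected
# value.
#
# Duplication model: per-location read counts are zero-truncated
# Poisson(lambda), which gives closed forms for the expected complexity
# metrics: E[NRF] ~ (1 - exp(-lambda)) / lambda and
# E[PBC] = lambda * exp(-lambda) / (1 - exp(-lambda)).

#' Simulation specification
#'
#' Bundles the knobs of the synthetic library generator. Defaults emulate
#' a reasonable-quality transcription-factor ChIP-seq library: 70% of
#' reads uniquely mapped, mild PCR duplication (zero-truncated Poisson
#' rate 0.5), 5% of uniquely mapped reads inside peaks, 1% mitochondrial,
#' 200 peaks of 500 bp on a 3 Mb two-chromosome genome plus a 20 kb chrM.
#'
#' @param seed Master seed; all generator randomness derives from it.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param n_reads Total reads (mapped; non-unique reads get MAPQ 0).
#' @param duplication_lambda Zero-truncated Poisson rate for per-location
#'   read counts.
#' @param in_peak_fraction Fraction of uniquely mapped reads placed inside
#'   peaks (the FRiP signal level).
#' @param mito_fraction Fraction of uniquely mapped reads on chrM.
#' @param mapq_unique_fraction Fraction of reads with MAPQ 30 (uniquely
#'   mapped); the rest get MAPQ 0.
#' @param n_peaks,peak_width Peak set geometry.
#' @param fold_mean Mean of the exponential fold-enrichment distribution.
#' @param read_length Reference span used when reads are written as SAM.
#' @return List of class `epiqc_sim_spec`.
#' @export
simulation_spec <- function(seed = 1,
                            chrom_sizes = c(chr1 = 2e6, chr2 = 1e6, chrM = 2e4),
                            n_reads = 1e5,
                            duplication_lambda = 0.5,
                            in_peak_fraction = 0.05,
                            mito_fraction = 0.01,
                            mapq_unique_fraction = 0.7,
                            n_peaks = 200,
                            peak_width = 500,
                            fold_mean = 8,
                            read_length = 36) {
  stopifnot(duplication_lambda > 0,
            in_peak_fraction >= 0, in_peak_fraction <= 1,
            mito_fraction >= 0, mito_fraction <= 1,
            mapq_unique_fraction >= 0, mapq_unique_fraction <= 1)
  structure(as.list(environment()), class = "epiqc_sim_spec")
}

# zero-truncated Poisson draws by CDF inversion (stable for any lambda,
# including the lambda -> 0+ limit where every count is 1)
rztpois <- function(n, lambda) {
  p0 <- exp(-lambda)
  p <- pmin(p0 + runif(n) * (1 - p0), 1 - .Machine$double.eps)
  as.integer(pmax(stats::qpois(p, lambda), 1L))
}

# counts ~ ZTP(lambda) whose sum is exactly `total` (last draw trimmed)
ztp_counts_exact <- function(total, lambda) {
  if (total == 0) return(integer())
  counts <- integer(0)
  while (sum(counts) < total) {
    need <- total - sum(counts)
    batch <- rztpois(max(ceiling(need / (lambda + 1)), 8L) + 8L, lambda)
    counts <- c(counts, batch)
  }
  cum <- cumsum(counts)
  k <- which(cum >= total)[1]
  counts <- counts[seq_len(k)]
  counts[k] <- counts[k] - (cum[k] - total)
  counts[counts > 0L]
}

# distinct (chrom,pos,strand) locations; `draw(m)` proposes a tibble of m
draw_distinct_locations <- function(n_loc, draw) {
  if (n_loc == 0)
    return(tibble(chrom = character(), pos5 = integer(), strand = character()))
  got <- tibble(chrom = character(), pos5 = integer(), strand = character())
  while (nrow(got) < n_loc) {
    cand <- draw(max(n_loc - nrow(got), 16L))
    got <- distinct(bind_rows(got, cand))
  }
  got[seq_len(n_loc), ]
}

#' Simulate a peak set
#'
#' Non-overlapping fixed-width peaks laid out on a regular grid over the
#' non-mitochondrial chromosomes, with exponential fold enrichments,
#' scores proportional to fold enrichment and centred summits.
#'
#' @param spec [simulation_spec()].
#' @param offset_slots Grid slots skipped before the first peak (used to
#'   build disjoint replicate-specific peaks).
#' @return Peak tibble.
#' @export
simulate_peaks <- function(spec, offset_slots = 0) {
  cs <- as_chrom_sizes(spec$chrom_sizes)
  cs <- cs[!(cs$chrom %in% c("chrM", "MT", "chrMT")), ]
  w <- spec$peak_width
  slot <- 4L * w
  slots_per_chrom <- floor((cs$size - 2000) / slot)
  total_slots <- sum(slots_per_chrom)
  if (spec$n_peaks + offset_slots > total_slots)
    abort("genome too small for the requested peak count")
  idx <- seq_len(spec$n_peaks) + offset_slots - 1L
  chrom_of <- rep(cs$chrom, slots_per_chrom)
  within <- unlist(lapply(slots_per_chrom, seq_len)) - 1L
  start <- 1000L + within * slot
  fold <- stats::rexp(spec$n_peaks, rate = 1 / spec$fold_mean)
  pk_start <- start[idx + 1L]
  tibble(
    chrom = chrom_of[idx + 1L],
    start = pk_start,
    end = pk_start + w,
    name = sprintf("peak_%d", seq_len(spec$n_peaks)),
    score = round(10 * fold, 2),
    strand = ".",
    fold_enrichment = round(fold, 3),
    neglog10_q = round(fold / 2, 3),
    summit_offset = as.integer(w %/% 2L)
  )
}

#' Simulate an aligned sequencing library with known ground truth
#'
#' Emits reads whose per-location count multiset follows a zero-truncated
#' Poisson, with exact numbers of in-peak and mitochondrial uniquely
#' mapped reads, and a truth record carrying the exact NRF, PBC, FRiP and
#' uniquely-mapped ratio of the emitted set (bookkept during generation).
#'
#' @param spec [simulation_spec()].
#' @param peaks Peak tibble; defaults to [simulate_peaks()] under the
#'   same seed. Required (non-empty) when `in_peak_fraction > 0`.
#' @param sam_path Optional path: when given, the library is also written
#'   as SAM text via [write_sam()].
#' @return List with `reads` (tibble, shuffled order), `peaks`, `truth`
#'   (list: `n_reads`, `n_uniquely_mapped`, `uniquely_mapped_ratio`,
#'   `n_locations`, `nrf`, `pbc`, `frip`, `n_in_peak`, `n_mito`) and
#'   `spec`.
#' @export
simulate_library <- function(spec, peaks = NULL, sam_path = NULL) {
  with_seed(spec$seed, {
    if (is.null(peaks)) peaks <- simulate_peaks(spec)
    if (spec$in_peak_fraction > 0 && !nrow(peaks))
      abort("a peak set is required when in_peak_fraction > 0")
    cs <- as_chrom_sizes(spec$chrom_sizes)
    mito <- intersect(cs$chrom, c("chrM", "MT", "chrMT"))
    main <- cs[!(cs$chrom %in% mito), ]
    pad <- spec$read_length + 10L

    n <- spec$n_reads
    n_um <- round(spec$mapq_unique_fraction * n)
    n_mito <- round(spec$mito_fraction * n_um)
    n_in <- round(spec$in_peak_fraction * n_um)
    n_bg <- n_um - n_mito - n_in
    stopifnot(n_bg >= 0)

    lam <- spec$duplication_lambda
    counts_in <- ztp_counts_exact(n_in, lam)
    counts_bg <- ztp_counts_exact(n_bg, lam)
    counts_mito <- ztp_counts_exact(n_mito, lam)

    draw_in_peak <- function(m) {
      i <- sample.int(nrow(peaks), m, replace = TRUE)
      tibble(chrom = peaks$chrom[i],
             pos5 = peaks$start[i] +
               as.integer(floor(runif(m) * (peaks$end[i] - peaks$start[i]))),
             strand = sample(c("+", "-"), m, replace = TRUE))
    }
    draw_bg <- function(m) {
      i <- sample.int(nrow(main), m, replace = TRUE,
                      prob = main$size / sum(main$size))
      cand <- tibble(chrom = main$chrom[i],
                     pos5 = as.integer(floor(runif(m) * (main$size[i] - 2 * pad))) + pad,
                     strand = sample(c("+", "-"), m, replace = TRUE))
      pts <- tibble(chrom = cand$chrom, start = cand$pos5, end = cand$pos5 + 1L)
      cand[!overlaps_any(pts, peaks), , drop = FALSE]
    }
    draw_mito <- function(m) {
      sz <- cs$size[cs$chrom == mito[1]]
      tibble(chrom = mito[1],
             pos5 = as.integer(floor(runif(m) * (sz - 2 * pad))) + pad,
             strand = sample(c("+", "-"), m, replace = TRUE))
    }

    loc_in <- draw_distinct_locations(length(counts_in), draw_in_peak)
    loc_bg <- draw_distinct_locations(length(counts_bg), draw_bg)
    loc_mito <- if (n_mito > 0)
      draw_distinct_locations(length(counts_mito), draw_mito)
    else tibble(chrom = character(), pos5 = integer(), strand = character())
    # background locations must not collide with in-peak/mito ones; peaks
    # and chrM are excluded from the background draw so strata are disjoint
    locs <- bind_rows(loc_in, loc_bg, loc_mito)
    counts <- c(counts_in, counts_bg, counts_mito)

    um_reads <- tibble(
      chrom = rep(locs$chrom, counts),
      pos5 = rep(locs$pos5, counts),
      strand = rep(locs$strand, counts),
      mapq = 30L
    )
    n_multi <- n - n_um
    multi <- if (n_multi > 0) {
      i <- sample.int(nrow(main), n_multi, replace = TRUE,
                      prob = main$size / sum(main$size))
      tibble(chrom = main$chrom[i],
             pos5 = as.integer(floor(runif(n_multi) * (main$size[i] - 2 * pad))) + pad,
             strand = sample(c("+", "-"), n_multi, replace = TRUE),
             mapq = 0L)
    } else NULL
    reads <- bind_rows(um_reads, multi)
    reads <- reads[sample.int(nrow(reads)), ]
    attr(reads, "n_total") <- n

    truth <- list(
      n_reads = n,
      n_uniquely_mapped = n_um,
      uniquely_mapped_ratio = n_um / n,
      n_locations = length(counts),
      nrf = length(counts) / n_um,
      pbc = sum(counts == 1L) / length(counts),
      n_in_peak = n_in,
      n_mito = n_mito,
      frip = if (n_um - n_mito > 0) n_in / (n_um - n_mito) else NA_real_
    )
    if (!is.null(sam_path)) write_sam(reads, cs, sam_path,
                                      read_length = spec$read_length)
    list(reads = reads, peaks = peaks, truth = truth, spec = spec)
  })
}

#' Simulate two replicates with controlled consistency
#'
#' Read sets share a fraction `rho` of positions (identical in both
#' replicates) with the remainder independent, so the expected binned
#' signal correlation increases monotonically with `rho` (1 at `rho = 1`,
#' ~0 at `rho = 0`). Peak sets share exactly
#' `round(shared_peak_fraction * n_peaks)` peaks, the rest being disjoint
#' by construction, so the expected peak-overlap ratio equals
#' `shared_peak_fraction` when the sets have equal size.
#'
#' @param spec [simulation_spec()].
#' @param rho Shared fraction of read positions, in [0, 1].
#' @param shared_peak_fraction Fraction of peaks common to the replicates.
#' @return List with `rep_a`, `rep_b` (each `list(id, reads, peaks)`) and
#'   `truth` (`rho`, `shared_peak_fraction`, `expected_overlap_ratio`).
#' @export
simulate_replicates <- function(spec, rho = 0.8, shared_peak_fraction = 0.6) {
  stopifnot(rho >= 0, rho <= 1,
            shared_peak_fraction >= 0, shared_peak_fraction <= 1)
  with_seed(spec$seed, {
    cs <- as_chrom_sizes(spec$chrom_sizes)
    main <- cs[!(cs$chrom %in% c("chrM", "MT", "chrMT")), ]
    pad <- spec$read_length + 10L
    n <- spec$n_reads
    m <- round(rho * n)

    draw_reads <- function(k) {
      i <- sample.int(nrow(main), k, replace = TRUE,
                      prob = main$size / sum(main$size))
      tibble(chrom = main$chrom[i],
             pos5 = as.integer(floor(runif(k) * (main$size[i] - 2 * pad))) + pad,
             strand = sample(c("+", "-"), k, replace = TRUE),
             mapq = 30L)
    }
    shared <- draw_reads(m)
    reads_a <- bind_rows(shared, draw_reads(n - m))
    reads_b <- bind_rows(shared, draw_reads(n - m))

    n_shared_pk <- round(shared_peak_fraction * spec$n_peaks)
    peaks_a <- simulate_peaks(spec)
    spec_b <- spec
    peaks_b_shared <- peaks_a[seq_len(n_shared_pk), , drop = FALSE]
    peaks_b_own <- simulate_peaks(spec_b,
                                  offset_slots = spec$n_peaks)[
      seq_len(spec$n_peaks - n_shared_pk), , drop = FALSE]
    peaks_b <- bind_rows(peaks_b_shared, peaks_b_own)

    list(
      rep_a = list(id = "rep1", reads = reads_a, peaks = peaks_a),
      rep_b = list(id = "rep2", reads = reads_b, peaks = peaks_b),
      truth = list(rho = rho, shared_peak_fraction = shared_peak_fraction,
                   expected_overlap_ratio = n_shared_pk / spec$n_peaks)
    )
  })
}

#' Simulate a gene annotation, conservation track and region sets
#'
#' Builds a toy transcriptome (fixed-length transcripts with three exons
#' each, alternating strand), a "peaky" conservation bedGraph made of
#' triangular bumps at the peak summits over a flat baseline, and
#' DHS/blacklist region sets constructed to contain exact fractions of
#' the top `top_n` peaks.
#'
#' @param spec [simulation_spec()].
#' @param peaks Peak tibble (default [simulate_peaks()] under the seed).
#' @param n_genes Number of transcripts (default 10).
#' @param dhs_fraction Fraction of the top peaks covered by the DHS set.
#' @param blacklist_fraction Fraction covered by the blacklist set.
#' @param top_n Top-peak count the fractions refer to.
#' @param bump_amplitude,bump_halfwidth Conservation bump shape.
#' @param baseline Conservation baseline value.
#' @return List with `genes`, `conservation`, `dhs`, `blacklist`, `peaks`
#'   and `truth` (`dhs_fraction`, `blacklist_fraction`, `bump_amplitude`,
#'   `baseline`).
#' @export
simulate_annotation_and_tracks <- function(spec, peaks = NULL, n_genes = 10,
                                           dhs_fraction = 0.75,
                                           blacklist_fraction = 0.1,
                                           top_n = 5000,
                                           bump_amplitude = 1,
                                           bump_halfwidth = 300,
                                           baseline = 0.05) {
  with_seed(spec$seed + 1L, {
    if (is.null(peaks)) peaks <- simulate_peaks(spec)
    cs <- as_chrom_sizes(spec$chrom_sizes)
    main <- cs[!(cs$chrom %in% c("chrM", "MT", "chrMT")), ]

    # transcripts laid out on the largest chromosome, 10 kb each
    chrom <- main$chrom[which.max(main$size)]
    tx_len <- 10000L
    gap <- 30000L
    starts <- 5000L + (seq_len(n_genes) - 1L) * (tx_len + gap)
    if (max(starts) + tx_len > main$size[main$chrom == chrom])
      abort("chromosome too small for the requested gene count")
    strand <- rep(c("+", "-"), length.out = n_genes)
    exon_starts <- lapply(starts, function(s) s + c(0L, 4000L, 8000L))
    exon_ends <- lapply(starts, function(s) s + c(1000L, 5000L, 10000L))
    genes <- tibble(
      gene_id = sprintf("gene_%02d", seq_len(n_genes)),
      chrom = chrom, strand = strand,
      tx_start = starts, tx_end = starts + tx_len,
      exon_starts = exon_starts, exon_ends = exon_ends
    ) %>% mutate(tss = ifelse(.data$strand == "+", .data$tx_start,
                              .data$tx_end - 1L))

    # triangular conservation bumps at summits, 1-bp bedGraph steps
    summits <- summit_positions(peaks)
    bump <- purrr::map_dfr(seq_len(nrow(summits)), function(i) {
      off <- seq(-bump_halfwidth, bump_halfwidth)
      tibble(chrom = summits$chrom[i],
             start = summits$position[i] + off,
             end = summits$position[i] + off + 1L,
             value = bump_amplitude * (1 - abs(off) / (bump_halfwidth + 1)))
    })
    base_track <- tibble(chrom = main$chrom, start = 0L,
                         end = as.integer(main$size), value = baseline)
    conservation <- bind_rows(bump, base_track) %>%
      filter(.data$start >= 0)

    top <- top_peaks(peaks, n = top_n)
    n_top <- nrow(top)
    make_regions <- function(frac, from_end = FALSE) {
      k <- round(frac * n_top)
      if (k == 0)
        return(tibble(chrom = character(), start = integer(), end = integer()))
      rows <- if (from_end) n_top - seq_len(k) + 1L else seq_len(k)
      tibble(chrom = top$chrom[rows],
             start = pmax(0L, top$start[rows] - 10L),
             end = top$end[rows] + 10L)
    }
    dhs <- make_regions(dhs_fraction)
    blacklist <- make_regions(blacklist_fraction, from_end = TRUE)
    # overlap of the two sets is possible only when fractions sum > 1

    list(genes = genes, conservation = conservation, dhs = dhs,
         blacklist = blacklist, peaks = peaks,
         truth = list(dhs_fraction = round(dhs_fraction * n_top) / n_top,
                      blacklist_fraction = round(blacklist_fraction * n_top) / n_top,
                      bump_amplitude = bump_amplitude, baseline = baseline))
  })
}

#' Simulate a FASTQ file
#'
#' Constant-quality reads with random bases (or bases supplied by the
#' caller), written as 4-line Phred+33 FASTQ.
#'
#' @param path Output path.
#' @param n_reads Number of reads.
#' @param read_length Read length in bp.
#' @param quality Integer Phred score applied to every base, or a vector
#'   recycled across reads (each read gets one constant score).
#' @param seqs Optional character vector of read sequences overriding the
#'   random bases.
#' @param seed Integer seed.
#' @return `path`, invisibly.
#' @export
simulate_fastq <- function(path, n_reads = 1000, read_length = 36,
                           quality = 25, seed = 1, seqs = NULL) {
  with_seed(seed, {
    if (is.null(seqs)) {
      seqs <- vapply(seq_len(n_reads), function(i)
        paste(sample(c("A", "C", "G", "T"), read_length, replace = TRUE),
              collapse = ""), character(1))
    }
    n_reads <- length(seqs)
    q <- rep_len(as.integer(quality), n_reads)
    quals <- vapply(seq_len(n_reads), function(i)
      strrep(intToUtf8(q[i] + 33L), nchar(seqs[i])), character(1))
    lines <- as.vector(rbind(sprintf("@read_%d", seq_len(n_reads)),
                             seqs, "+", quals))
    writeLines(lines, path)
    invisible(path)
  })
}

#' Simulate a two-species contamination fixture
#'
#' Generates two random genomes and a FASTQ whose reads are verbatim
#' substrings: a fraction `frac_a` from genome A, the rest from genome B.
#' Together with [make_exact_mapper()] this exercises the contamination
#' screen with binomially exact expected fractions.
#'
#' @param path FASTQ output path.
#' @param n_reads Number of reads.
#' @param read_length Read length.
#' @param frac_a Fraction of reads drawn from genome A.
#' @param genome_length Length of each random genome.
#' @param seed Integer seed.
#' @return List with `fastq`, `genome_a`, `genome_b` (sequences) and
#'   `truth` (`frac_a` as emitted, exact).
#' @export
simulate_contamination_fastq <- function(path, n_reads = 2000,
                                         read_length = 36, frac_a = 0.9,
                                         genome_length = 50000, seed = 1) {
  with_seed(seed, {
    rand_genome <- function()
      paste(sample(c("A", "C", "G", "T"), genome_length, replace = TRUE),
            collapse = "")
    ga <- rand_genome()
    gb <- rand_genome()
    n_a <- round(frac_a * n_reads)
    take <- function(g, k) {
      starts <- sample.int(genome_length - read_length + 1L, k, replace = TRUE)
      substring(g, starts, starts + read_length - 1L)
    }
    seqs <- sample(c(take(ga, n_a), take(gb, n_reads - n_a)))
    simulate_fastq(path, quality = 30, seed = seed, seqs = seqs)
    list(fastq = path, genome_a = ga, genome_b = gb,
         truth = list(frac_a = n_a / n_reads))
  })
}
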