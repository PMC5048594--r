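# Coordinate conventions: every interval in this package is 0-based
# half-open [start, end), BED-style. SAM positions are converted on ingest.
# GenomicRanges (1-based closed) is used internally as the overlap engine;
# conversion happens only inside these helpers.

# chrom sizes may arrive as a named vector or a tibble(chrom, size)
as_chrom_sizes <- function(x) {
  if (is_tibble(x) || is.data.frame(x)) {
    stopifnot(all(c("chrom", "size") %in% names(x)))
    out <- tibble(chrom = as.character(x$chrom), size = as.numeric(x$size))
  } else {
    if (is.null(names(x)) || any(names(x) == ""))
      abort("chrom sizes must be a named vector or a tibble(chrom, size)")
    out <- tibble(chrom = names(x), size = as.numeric(x))
  }
  if (any(duplicated(out$chrom))) abort("duplicate chromosome names in chrom sizes")
  if (any(out$size <= 0)) abort("chromosome lengths must be > 0")
  out
}

# tibble(chrom, start, end) [0-based half-open] -> GRanges (1-based closed)
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

check_intervals <- function(x, what = "intervals") {
  if (!all(c("chrom", "start", "end") %in% names(x)))
    abort(sprintf("%s must have columns chrom, start, end", what))
  bad <- which(x$start >= x$end | x$start < 0)
  if (length(bad))
    abort(sprintf("%s: invalid interval at row %d (need 0 <= start < end)",
                  what, bad[1]))
  invisible(x)
}

#' Read a chrom.sizes file
#'
#' @param path Two-column tab-separated file: chromosome name, length in bp.
#' @return A tibble with columns `chrom` and `size`.
#' @export
read_chrom_sizes <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "size"),
                         colClasses = c("character", "numeric"))
  as_chrom_sizes(as_tibble(x))
}

#' Read BED / narrowPeak / broadPeak files into a peak tibble
#'
#' Parses the ENCODE peak dialects into a uniform tibble. `track`,
#' `browser` and `#` comment lines are skipped. Coordinates are kept
#' 0-based half-open. A 10-column file is treated as narrowPeak (column 7
#' fold enrichment, column 9 -log10 q-value, column 10 summit offset from
#' `start`); 9 columns as broadPeak (no summit, `summit_offset = -1`);
#' 3-8 columns as plain BED with default scores.
#'
#' @param path Path to a tab-separated BED-family file.
#' @return Tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `fold_enrichment`, `neglog10_q`, `summit_offset`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track\\b|browser\\b|#)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = numeric(), strand = character(),
                  fold_enrichment = numeric(), neglog10_q = numeric(),
                  summit_offset = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  bad <- which(ncols < 3 | ncols > 10)
  if (length(bad))
    abort(sprintf("malformed line %d in %s: %d columns (expected 3-10)",
                  lineno[bad[1]], path, ncols[bad[1]]))

  col <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, character(1))
  }
  num_or_na <- function(s) suppressWarnings(as.numeric(s))

  start <- num_or_na(col(2, NA_character_))
  end <- num_or_na(col(3, NA_character_))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    abort(sprintf("malformed line %d in %s: non-numeric coordinates",
                  lineno[bad[1]], path))
  bad <- which(start >= end)
  if (length(bad))
    abort(sprintf("malformed line %d in %s: start >= end",
                  lineno[bad[1]], path))

  score <- num_or_na(col(5, "0")); score[is.na(score)] <- 0
  fe <- num_or_na(col(7, "0")); fe[is.na(fe)] <- 0
  q <- num_or_na(col(9, "0")); q[is.na(q)] <- 0
  summit <- ifelse(ncols >= 10, num_or_na(col(10, "-1")), -1)
  summit[is.na(summit)] <- -1

  tibble(
    chrom = col(1, NA_character_),
    start = as.integer(start),
    end = as.integer(end),
    name = col(4, "."),
    score = score,
    strand = col(6, "."),
    fold_enrichment = fe,
    neglog10_q = q,
    summit_offset = as.integer(summit)
  )
}

#' Write a peak tibble as narrowPeak or BED
#'
#' @param peaks Peak tibble as produced by [read_bed()].
#' @param path Output path.
#' @param format `"narrowPeak"` (10 columns; the unused p-value column is
#'   written as -1), `"bed6"` or `"bed3"`.
#' @export
write_bed <- function(peaks, path, format = c("narrowPeak", "bed6", "bed3")) {
  format <- match.arg(format)
  check_intervals(peaks, "peaks")
  pick <- function(col, default) {
    if (col %in% names(peaks)) peaks[[col]] else rep(default, nrow(peaks))
  }
  name <- pick("name", ".")
  score <- pick("score", 0)
  strand <- pick("strand", ".")
  lines <- switch(format,
    narrowPeak = sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%s\t-1\t%s\t%d",
      peaks$chrom, peaks$start, peaks$end, name,
      format(score, trim = TRUE, scientific = FALSE),
      strand,
      format(pick("fold_enrichment", 0), trim = TRUE, scientific = FALSE),
      format(pick("neglog10_q", 0), trim = TRUE, scientific = FALSE),
      as.integer(pick("summit_offset", -1L))),
    bed6 = sprintf("%s\t%d\t%d\t%s\t%s\t%s", peaks$chrom, peaks$start,
      peaks$end, name, format(score, trim = TRUE, scientific = FALSE), strand),
    bed3 = sprintf("%s\t%d\t%d", peaks$chrom, peaks$start, peaks$end)
  )
  writeLines(lines, path)
  invisible(path)
}

# reference-consumed length of a CIGAR string (M, D, N, =, X ops)
cigar_ref_length <- function(cigar) {
  out <- integer(length(cigar))
  m <- gregexpr("\\d+[MDN=X]", cigar)
  for (i in seq_along(cigar)) {
    hit <- regmatches(cigar[i], m[i])[[1]]
    out[i] <- if (length(hit)) sum(as.integer(sub("[MDN=X]$", "", hit))) else 0L
  }
  out
}

#' Read aligned reads from a SAM text file
#'
#' A minimal-field SAM reader: only FLAG, RNAME, POS, MAPQ and CIGAR are
#' consulted. Unmapped (0x4), secondary (0x100) and supplementary (0x800)
#' records are skipped. The 5'-most reference coordinate of each read is
#' computed 0-based: `POS - 1` on the plus strand, and the 3' reference
#' end (`POS - 1 +` reference-consumed CIGAR length `- 1`) on the minus
#' strand, matching the duplicate-location semantics of alignment tools.
#'
#' @param path SAM text file (with or without `@` header lines).
#' @param chrom_sizes Named vector or tibble(chrom, size); reads aligned to
#'   chromosomes absent from it raise an error (genome mismatch).
#' @return Tibble with columns `chrom`, `pos5`, `strand`, `mapq`. The
#'   attribute `n_total` carries the number of primary records (mapped +
#'   unmapped), the denominator of the uniquely-mapped ratio.
#' @export
read_sam_min <- function(path, chrom_sizes) {
  cs <- as_chrom_sizes(chrom_sizes)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (!length(lines)) {
    out <- tibble(chrom = character(), pos5 = integer(),
                  strand = character(), mapq = integer())
    attr(out, "n_total") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(fields, `[[`, character(1), i)
  flag <- as.integer(get(2))
  primary <- bitwAnd(flag, 0x100) == 0L & bitwAnd(flag, 0x800) == 0L
  n_total <- sum(primary)
  keep <- primary & bitwAnd(flag, 0x4) == 0L
  flag <- flag[keep]
  rname <- get(3)[keep]
  keep2 <- rname != "*"
  flag <- flag[keep2]; rname <- rname[keep2]
  pos <- as.integer(get(4)[keep][keep2])
  mapq <- as.integer(get(5)[keep][keep2])
  cigar <- get(6)[keep][keep2]

  missing <- setdiff(unique(rname), cs$chrom)
  if (length(missing))
    abort(sprintf(
      "reads aligned to chromosomes absent from chrom sizes (genome mismatch?): %s",
      paste(missing, collapse = ", ")))

  minus <- bitwAnd(flag, 0x10) != 0L
  reflen <- cigar_ref_length(cigar)
  pos5 <- ifelse(minus, pos - 1L + reflen - 1L, pos - 1L)
  out <- tibble(chrom = rname, pos5 = as.integer(pos5),
                strand = ifelse(minus, "-", "+"), mapq = mapq)
  attr(out, "n_total") <- n_total
  out
}

#' Write reads as a SAM text file
#'
#' Emits one primary single-end record per read with placeholder sequence
#' (`*`) and a fixed-length match CIGAR, the inverse of [read_sam_min()].
#' Minus-strand reads must satisfy `pos5 >= read_length - 1` so the
#' leftmost POS stays on the chromosome.
#'
#' @param reads Tibble with `chrom`, `pos5`, `strand`, `mapq`.
#' @param chrom_sizes Named vector or tibble(chrom, size) for `@SQ` headers.
#' @param path Output path.
#' @param read_length Reference span (bp) written in the CIGAR.
#' @param n_unmapped Additional unmapped records (FLAG 4) to append, so the
#'   uniquely-mapped denominator can exceed the mapped count.
#' @export
write_sam <- function(reads, chrom_sizes, path, read_length = 36L,
                      n_unmapped = 0L) {
  cs <- as_chrom_sizes(chrom_sizes)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", cs$chrom, as.integer(cs$size)))
  minus <- reads$strand == "-"
  pos <- ifelse(minus, reads$pos5 - read_length + 2L, reads$pos5 + 1L)
  if (any(pos < 1L)) abort("minus-strand read too close to chromosome start for read_length")
  body <- sprintf("r%06d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*",
                  seq_len(nrow(reads)), ifelse(minus, 16L, 0L), reads$chrom,
                  as.integer(pos), as.integer(reads$mapq), as.integer(read_length))
  unm <- if (n_unmapped > 0)
    sprintf("u%06d\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*", seq_len(n_unmapped))
  else character()
  writeLines(c(header, body, unm), path)
  invisible(path)
}

#' Merge an interval set into maximal non-overlapping blocks
#'
#' Overlapping and abutting half-open intervals are merged (the union-DHS
#' construction needs maximal covered blocks, so `[a,b)` and `[b,c)`
#' collapse to `[a,c)`). Output is sorted by (chrom, start) and covers
#' exactly the same bases as the input.
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @return Tibble of disjoint, non-abutting intervals.
#' @export
merge_intervals <- function(intervals) {
  check_intervals(intervals)
  if (!nrow(intervals))
    return(tibble(chrom = character(), start = integer(), end = integer()))
  gr <- GenomicRanges::reduce(as_granges(intervals))
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  ) %>% arrange(.data$chrom, .data$start)
}

#' Flag query intervals overlapping any subject interval
#'
#' Overlap means at least one shared base; half-open touching intervals
#' (`[0,10)` vs `[10,20)`) do not overlap.
#'
#' @param query,subject Interval tibbles (`chrom`, `start`, `end`).
#' @return Logical vector, one flag per query row.
#' @export
overlaps_any <- function(query, subject) {
  check_intervals(query, "query")
  check_intervals(subject, "subject")
  if (!nrow(query)) return(logical())
  if (!nrow(subject)) return(rep(FALSE, nrow(query)))
  # disjoint chromosome sets are a legitimate "no overlap" case, not a
  # seqlevel mismatch worth warning about
  suppressWarnings(
    GenomicRanges::countOverlaps(as_granges(query), as_granges(subject),
                                 minoverlap = 1L) > 0L
  )
}

#' Bin read 5' positions into a fixed-bin signal track
#'
#' Each read contributes one count to the bin containing its `pos5`. The
#' result is a dense tibble (every bin of every chromosome is present,
#' zeros included) so two tracks over the same genome align row-for-row.
#'
#' @param reads Tibble with `chrom` and `pos5`.
#' @param chrom_sizes Named vector or tibble(chrom, size).
#' @param bin_size Bin width in bp (default 1000).
#' @return A tibble of class `epiqc_track` with columns `chrom`, `bin`
#'   (0-based bin index) and `value`; attributes `bin_size` and
#'   `total_signal` (= number of reads counted).
#' @export
bin_reads <- function(reads, chrom_sizes, bin_size = 1000) {
  stopifnot(bin_size >= 1)
  cs <- as_chrom_sizes(chrom_sizes)
  per_chrom <- lapply(seq_len(nrow(cs)), function(i) {
    n_bins <- as.integer(ceiling(cs$size[i] / bin_size))
    pos <- reads$pos5[reads$chrom == cs$chrom[i]]
    tibble(chrom = cs$chrom[i], bin = seq_len(n_bins) - 1L,
           value = as.numeric(tabulate(pos %/% bin_size + 1L, nbins = n_bins)))
  })
  out <- bind_rows(per_chrom)
  new_track(out, bin_size = bin_size)
}

new_track <- function(tbl, bin_size) {
  structure(tbl, bin_size = bin_size, total_signal = sum(tbl$value),
            class = c("epiqc_track", class(tibble())))
}

#' @export
print.epiqc_track <- function(x, ...) {
  cat(sprintf("<epiqc_track> bin_size=%g total_signal=%g\n",
              attr(x, "bin_size"), attr(x, "total_signal")))
  NextMethod()
}

#' Read a 4-column bedGraph file
#'
#' @param path bedGraph path (`chrom start end value`, 0-based half-open).
#' @return Tibble with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^(track\\b|browser\\b|#)", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4)) abort("bedGraph needs 4 columns")
  get <- function(i) vapply(fields, `[[`, character(1), i)
  out <- tibble(chrom = get(1), start = as.integer(get(2)),
                end = as.integer(get(3)), value = as.numeric(get(4)))
  check_intervals(out, "bedGraph")
  out
}

#' Write a 4-column bedGraph file
#' @param track Tibble with `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", track$chrom, track$start, track$end,
                     format(track$value, trim = TRUE, scientific = FALSE)),
             path)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Expects a refGene-flat-compatible TSV with columns `gene_id`, `chrom`,
#' `strand`, `tx_start`, `tx_end`, `exon_starts`, `exon_ends` (the last two
#' comma-separated, 0-based half-open). The TSS is derived from strand:
#' `tx_start` on `+`, `tx_end - 1` on `-`.
#'
#' @param path TSV path with a header row.
#' @return Tibble with one row per transcript and list-columns
#'   `exon_starts`/`exon_ends` holding integer vectors, plus a computed
#'   `tss` column.
#' @export
read_gene_table <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = "character")
  need <- c("gene_id", "chrom", "strand", "tx_start", "tx_end",
            "exon_starts", "exon_ends")
  missing <- setdiff(need, names(x))
  if (length(missing))
    abort(sprintf("gene table missing columns: %s", paste(missing, collapse = ", ")))
  split_ints <- function(s) lapply(strsplit(s, ",", fixed = TRUE),
                                   function(v) as.integer(v[nzchar(v)]))
  genes <- tibble(
    gene_id = x$gene_id, chrom = x$chrom, strand = x$strand,
    tx_start = as.integer(x$tx_start), tx_end = as.integer(x$tx_end),
    exon_starts = split_ints(x$exon_starts),
    exon_ends = split_ints(x$exon_ends)
  )
  mutate(genes, tss = ifelse(.data$strand == "+", .data$tx_start,
                             .data$tx_end - 1L))
}

#' Write a gene annotation table
#' @param genes Gene tibble as returned by [read_gene_table()].
#' @param path Output path.
#' @export
write_gene_table <- function(genes, path) {
  join <- function(l) vapply(l, function(v) paste(v, collapse = ","), character(1))
  df <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                   strand = genes$strand, tx_start = genes$tx_start,
                   tx_end = genes$tx_end,
                   exon_starts = join(genes$exon_starts),
                   exon_ends = join(genes$exon_ends))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
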