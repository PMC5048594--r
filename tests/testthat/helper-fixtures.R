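# fixture builders and independent brute-force oracles (the oracles never
# call the implementation paths they are used to check)

iv <- function(chrom, start, end) {
  tibble::tibble(chrom = chrom, start = as.integer(start), end = as.integer(end))
}

make_peaks <- function(chrom, start, end, score = 0, fold = 0, q = 0,
                       offset = -1L) {
  n <- length(start)
  tibble::tibble(
    chrom = rep_len(chrom, n), start = as.integer(start), end = as.integer(end),
    name = sprintf("p%d", seq_len(n)), score = rep_len(score, n),
    strand = ".", fold_enrichment = rep_len(fold, n),
    neglog10_q = rep_len(q, n), summit_offset = as.integer(rep_len(offset, n))
  )
}

make_reads <- function(chrom, pos5, strand = "+", mapq = 30L) {
  n <- length(pos5)
  tibble::tibble(chrom = rep_len(chrom, n), pos5 = as.integer(pos5),
                 strand = rep_len(strand, n), mapq = as.integer(rep_len(mapq, n)))
}

# O(n*m) all-pairs overlap oracle over half-open intervals
oracle_overlaps_any <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    any(subject$chrom == query$chrom[i] &
          subject$start < query$end[i] &
          subject$end > query$start[i])
  }, logical(1))
}

# per-base boolean bitmap of the covered bases on one toy chromosome
oracle_cover_mask <- function(intervals, chrom, len) {
  mask <- logical(len)
  rows <- which(intervals$chrom == chrom)
  for (i in rows) {
    mask[(intervals$start[i] + 1):intervals$end[i]] <- TRUE
  }
  mask
}

random_intervals <- function(n, chroms = c("chrA", "chrB"), len = 10000,
                             max_width = 500) {
  start <- sample.int(len - max_width, n, replace = TRUE) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  iv(sample(chroms, n, replace = TRUE), start, start + width)
}

# mid-rank percentile by explicit sort-and-count
oracle_percentile <- function(values, v) {
  100 * (sum(values < v) + 0.5 * sum(values == v)) / length(values)
}

write_sam_text <- function(lines, chroms = c(chr1 = 100000)) {
  path <- tempfile(fileext = ".sam")
  header <- c("@HD\tVN:1.6",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chroms), as.integer(chroms)))
  writeLines(c(header, lines), path)
  path
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# a complete synthetic dataset on disk (reads, peaks, annotation, tracks)
make_dataset <- function(dir, seed = 5, n_reads = 20000) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- simulation_spec(seed = seed, n_reads = n_reads)
  sim <- simulate_library(spec, sam_path = file.path(dir, "rep1.sam"))
  rep2 <- simulate_library(simulation_spec(seed = seed + 1, n_reads = n_reads),
                           peaks = sim$peaks,
                           sam_path = file.path(dir, "rep2.sam"))
  write_bed(sim$peaks, file.path(dir, "rep1.narrowPeak"))
  write_bed(rep2$peaks, file.path(dir, "rep2.narrowPeak"))
  cs <- spec$chrom_sizes
  writeLines(sprintf("%s\t%d", names(cs), as.integer(cs)),
             file.path(dir, "genome.chrom.sizes"))
  ann <- simulate_annotation_and_tracks(spec, peaks = sim$peaks)
  write_gene_table(ann$genes, file.path(dir, "genes.tsv"))
  write_bedgraph(ann$conservation, file.path(dir, "cons.bedGraph"))
  write_bed(ann$dhs, file.path(dir, "dhs.bed"), format = "bed3")
  write_bed(ann$blacklist, file.path(dir, "blacklist.bed"), format = "bed3")
  simulate_fastq(file.path(dir, "reads.fastq"), n_reads = 500, quality = 30,
                 seed = seed)
  list(dir = dir, spec = spec, sim = sim, ann = ann)
}

dataset_config <- function(d, out = file.path(d$dir, "out"), seed = 5) {
  list(
    reads = file.path(d$dir, c("rep1.sam", "rep2.sam")),
    peaks = file.path(d$dir, c("rep1.narrowPeak", "rep2.narrowPeak")),
    chrom_sizes = file.path(d$dir, "genome.chrom.sizes"),
    genes = file.path(d$dir, "genes.tsv"),
    dhs = file.path(d$dir, "dhs.bed"),
    blacklist = file.path(d$dir, "blacklist.bed"),
    conservation = file.path(d$dir, "cons.bedGraph"),
    fastq = file.path(d$dir, "reads.fastq"),
    seed = seed, output_dir = out
  )
}
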