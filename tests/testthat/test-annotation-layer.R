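toy_genes <- function() {
  # two genes on chr1: gene_a [10000,20000) on +, exons [10000,11000) and
  # [15000,16000); gene_b [40000,50000) on -, exon [48000,50000)
  tibble::tibble(
    gene_id = c("gene_a", "gene_b"),
    chrom = "chr1",
    strand = c("+", "-"),
    tx_start = c(10000L, 40000L),
    tx_end = c(20000L, 50000L),
    exon_starts = list(c(10000L, 15000L), 48000L),
    exon_ends = list(c(11000L, 16000L), 50000L),
    tss = c(10000L, 49999L)
  )
}

# linear scan over one summit: same rules, written independently
oracle_classify <- function(chrom, pos, genes, w = 2000) {
  for (i in seq_len(nrow(genes))) {
    if (genes$chrom[i] == chrom && abs(pos - genes$tss[i]) <= w) return("promoter")
  }
  for (i in seq_len(nrow(genes))) {
    if (genes$chrom[i] != chrom) next
    s <- genes$exon_starts[[i]]; e <- genes$exon_ends[[i]]
    if (any(pos >= s & pos < e)) return("exon")
  }
  for (i in seq_len(nrow(genes))) {
    if (genes$chrom[i] == chrom && pos >= genes$tx_start[i] &&
        pos < genes$tx_end[i]) return("intron")
  }
  "intergenic"
}

test_that("summit positions use the offset or the midpoint fallback", {
  peaks <- make_peaks("chr1", c(100, 100, 101), c(200, 200, 200),
                      offset = c(50L, -1L, -1L))
  s <- summit_positions(peaks)
  expect_equal(s$position, c(150L, 150L, 150L))  # (101+200)%/%2 = 150
})

test_that("summit classification applies promoter > exon > intron > intergenic", {
  genes <- toy_genes()
  # summit exactly at the TSS of gene_a, which is also inside its first exon
  at_tss <- tibble::tibble(chrom = "chr1", position = 10000L)
  meta <- classify_summits(at_tss, genes)
  expect_equal(meta$promoter, 1)
  expect_equal(attr(meta, "labels"), "promoter")

  exonic <- tibble::tibble(chrom = "chr1", position = 15500L)
  expect_equal(attr(classify_summits(exonic, genes), "labels"), "exon")

  intronic <- tibble::tibble(chrom = "chr1", position = 13000L)
  expect_equal(attr(classify_summits(intronic, genes), "labels"), "intron")

  off_chrom <- tibble::tibble(chrom = "chr9", position = 15500L)
  expect_equal(classify_summits(off_chrom, genes)$intergenic, 1)

  expect_error(classify_summits(at_tss[0, ], genes), "no summits")
})

test_that("meta-region fractions match the scan oracle and sum to one", {
  genes <- toy_genes()
  set.seed(19)
  summits <- tibble::tibble(chrom = "chr1",
                            position = sample.int(60000, 1000) - 1L)
  meta <- classify_summits(summits, genes)
  expect_equal(meta$promoter + meta$exon + meta$intron + meta$intergenic, 1,
               tolerance = 1e-9)
  labels <- vapply(seq_len(1000), function(i)
    oracle_classify(summits$chrom[i], summits$position[i], genes), character(1))
  expect_equal(attr(meta, "labels"), labels)

  perm <- classify_summits(summits[sample.int(1000), ], genes)
  expect_equal(perm$promoter, meta$promoter)
})

test_that("top peaks sort by score with deterministic tie-breaks", {
  peaks <- make_peaks("chr1", c(100, 300, 200), c(150, 350, 250),
                      score = c(5, 9, 7))
  expect_equal(top_peaks(peaks, 2)$score, c(9, 7))
  expect_equal(nrow(top_peaks(peaks, 10)), 3)

  tied <- make_peaks("chr1", c(300, 100, 200), c(350, 150, 250), score = 4)
  expect_equal(top_peaks(tied, 3)$start, c(100L, 200L, 300L))
})

test_that("region overlap ratio is exact and monotone in the region set", {
  peaks <- make_peaks("chr1", seq(0, by = 1000, length.out = 100),
                      seq(300, by = 1000, length.out = 100))
  everything <- iv("chr1", 0, 1e6)
  expect_equal(region_overlap_ratio(peaks, everything), 1.0)

  sixty <- merge_intervals(iv("chr1", peaks$start[1:60], peaks$end[1:60]))
  expect_equal(region_overlap_ratio(peaks, sixty), 0.60)

  # abutting region ends (half-open) do not count
  abut <- iv("chr1", peaks$end[1], peaks$end[1] + 10)
  expect_equal(region_overlap_ratio(peaks[1, ], abut), 0)

  grown <- dplyr::bind_rows(sixty, iv("chr1", 61000, 61100))
  expect_gte(region_overlap_ratio(peaks, grown),
             region_overlap_ratio(peaks, sixty))

  expect_error(region_overlap_ratio(peaks[0, ], everything), "empty")
})

test_that("conservation profile averages the track around summits", {
  const <- tibble::tibble(chrom = "chr1", start = 0L, end = 50000L,
                          value = 0.37)
  summits <- tibble::tibble(chrom = "chr1", position = c(10000L, 30000L))
  prof <- conservation_profile(summits, const, flank = 2000, bin = 50)
  expect_equal(nrow(prof), 80)
  expect_true(all(abs(prof$value - 0.37) < 1e-12))
  expect_equal(attr(prof, "n_truncated"), 0L)

  # single summit on a triangular bump reproduces the bump
  off <- -500:499
  bump <- tibble::tibble(chrom = "chr1", start = 20000L + off,
                         end = 20001L + off, value = 1 - abs(off) / 500)
  one <- tibble::tibble(chrom = "chr1", position = 20000L)
  suppressWarnings(
    prof2 <- conservation_profile(one, bump, flank = 500, bin = 1))
  expect_equal(prof2$value, 1 - abs(off) / 500, tolerance = 1e-12)
})

test_that("conservation profile equals the direct per-offset mean oracle", {
  set.seed(29)
  vals <- runif(20000)
  track <- tibble::tibble(chrom = "chr1", start = 0:19999, end = 1:20000,
                          value = vals)
  summits <- tibble::tibble(chrom = "chr1",
                            position = sample(500:19500, 100))
  prof <- conservation_profile(summits, track, flank = 400, bin = 40)
  oracle <- vapply(seq_len(20), function(b) {
    offs <- (-400 + (b - 1) * 40):(-400 + b * 40 - 1)
    mean(vapply(summits$position, function(p) mean(vals[p + offs + 1]),
                numeric(1)))
  }, numeric(1))
  expect_equal(prof$value, oracle, tolerance = 1e-12)
})

test_that("profile of a symmetric track around symmetric summits is symmetric", {
  off <- -300:299
  tri <- tibble::tibble(chrom = "chr1", start = 10000L + off,
                        end = 10001L + off,
                        value = 1 - abs(off + 0.5) / 300)
  s <- tibble::tibble(chrom = "chr1", position = 10000L)
  suppressWarnings(p <- conservation_profile(s, tri, flank = 300, bin = 20))
  expect_equal(p$value, rev(p$value), tolerance = 1e-12)
})

test_that("regulatory potential follows the exponential decay weight", {
  genes <- toy_genes()
  at_tss <- make_peaks("chr1", 9900L, 10100L, offset = 100L)  # summit = TSS
  rp <- regulatory_potential(at_tss, genes)
  expect_equal(rp$score[rp$gene_id == "gene_a"], exp(-0.5))
  # the same summit sits 39999 bp from gene_b's TSS, still inside 100 kb
  expect_equal(rp$score[rp$gene_id == "gene_b"],
               exp(-(0.5 + 4 * 39999 / 1e5)), tolerance = 1e-12)

  # hard cutoff at max_dist, on a single-gene annotation
  g1 <- genes[1, ]
  far <- make_peaks("chr1", 110100L, 110300L, offset = 1L)  # d = 100101
  expect_equal(sum(regulatory_potential(far, g1)$score), 0)
  at_edge <- make_peaks("chr1", 109900L, 110100L, offset = 100L)  # d = 1e5
  expect_equal(regulatory_potential(at_edge, g1)$score[1],
               exp(-(0.5 + 4)), tolerance = 1e-12)
})

test_that("regulatory potential equals a hand-summed oracle and is additive", {
  genes <- toy_genes()
  pos <- c(10000L, 12000L, 49000L, 51000L, 200000L)
  peaks <- make_peaks("chr1", pos - 100L, pos + 100L, offset = 100L)
  w <- function(d) exp(-(0.5 + 4 * d / 1e5))
  # gene_a TSS = 10000: summits at d = 0, 2000, 39000, 41000 qualify
  hand_a <- w(0) + w(2000) + w(39000) + w(41000)
  hand_b <- w(abs(49000 - 49999)) + w(abs(51000 - 49999)) +
    w(abs(12000 - 49999)) + w(abs(10000 - 49999))  # all within 100 kb
  rp <- regulatory_potential(peaks, genes)
  expect_equal(rp$score[rp$gene_id == "gene_a"], hand_a, tolerance = 1e-12)
  expect_equal(rp$score[rp$gene_id == "gene_b"], hand_b, tolerance = 1e-12)

  p1 <- peaks[1:2, ]; p2 <- peaks[3:5, ]
  r_all <- regulatory_potential(peaks, genes)
  r1 <- regulatory_potential(p1, genes)
  r2 <- regulatory_potential(p2, genes)
  expect_equal(r_all$score[order(r_all$gene_id)],
               r1$score[order(r1$gene_id)] + r2$score[order(r2$gene_id)])
})

test_that("multi-transcript genes keep the best-scoring TSS", {
  genes <- dplyr::bind_rows(toy_genes(), toy_genes()[1, ])
  genes$tss[3] <- 12000L
  peak <- make_peaks("chr1", 11900L, 12100L, offset = 100L)  # at tss 12000
  rp <- regulatory_potential(peak, genes)
  expect_equal(rp$score[rp$gene_id == "gene_a"], exp(-0.5))
})
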