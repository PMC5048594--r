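test_that("peak census applies inclusive fold-enrichment cutoffs", {
  peaks <- make_peaks("chr1", c(0, 100, 200), c(50, 150, 250),
                      fold = c(5, 10, 25))
  cs <- peak_census(peaks)
  expect_equal(unlist(cs), c(n_peaks = 3, n_fc10 = 2, n_fc20 = 1))

  expect_equal(unlist(peak_census(make_peaks("chr1", integer(), integer()))),
               c(n_peaks = 0, n_fc10 = 0, n_fc20 = 0))

  set.seed(13)
  folds <- rexp(1000, rate = 1 / 8)
  big <- make_peaks("chr1", seq(0, by = 100, length.out = 1000) ,
                    seq(50, by = 100, length.out = 1000), fold = folds)
  cs2 <- peak_census(big)
  expect_equal(cs2$n_fc10, sum(folds >= 10))  # linear-scan oracle
  expect_equal(cs2$n_fc20, sum(folds >= 20))
})

test_that("FRiP is exact on a constructed fixture with half-open boundaries", {
  peaks <- make_peaks("chr1", c(1000, 5000), c(1500, 5500))
  in_pos <- c(seq(1000, 1499, length.out = 150), seq(5000, 5499, length.out = 150))
  out_pos <- seq(10000, by = 7, length.out = 700)
  reads <- make_reads("chr1", round(c(in_pos, out_pos)))
  res <- compute_frip(reads, peaks, subsample = 4e6, seed = 1)
  expect_equal(res$frip, 0.3)
  expect_true(res$below_subsample_depth)

  # boundary semantics: pos5 == start is in, pos5 == end is out
  at_start <- make_reads("chr1", 1000)
  at_end <- make_reads("chr1", 1500)
  expect_equal(compute_frip(at_start, peaks)$frip, 1)
  expect_equal(compute_frip(at_end, peaks)$frip, 0)
})

test_that("FRiP drops mitochondrial reads and degenerates loudly", {
  peaks <- make_peaks("chr1", 100, 200)
  mito <- make_reads("chrM", c(10, 20, 150))
  expect_error(compute_frip(mito, peaks), "mitochondrial")

  mixed <- dplyr::bind_rows(make_reads("chr1", c(150, 5000)),
                            make_reads("chrM", c(150, 160)))
  expect_equal(compute_frip(mixed, peaks)$frip, 0.5)

  expect_warning(
    res <- compute_frip(make_reads("chr1", 1:10),
                        make_peaks("chr1", integer(), integer())),
    "empty peak")
  expect_equal(res$frip, 0)
})

test_that("FRiP is order invariant and monotone in the peak set", {
  set.seed(17)
  peaks <- make_peaks("chr1", seq(0, by = 1000, length.out = 10),
                      seq(200, by = 1000, length.out = 10))
  reads <- make_reads("chr1", sample.int(20000, 2000) - 1L)
  base <- compute_frip(reads, peaks)$frip
  expect_equal(compute_frip(reads[sample.int(2000), ], peaks)$frip, base)
  expect_equal(compute_frip(reads, peaks[sample.int(10), ])$frip, base)
  grown <- dplyr::bind_rows(peaks, make_peaks("chr1", 15000, 15200))
  expect_gte(compute_frip(reads, grown)$frip, base)
})

test_that("wiggle correlation is RPM-scale-invariant and exact on constructed bins", {
  reads <- make_reads("chr1", c(100, 1100, 1200, 2300))
  a <- bin_reads(reads, c(chr1 = 4000), 1000)
  b <- bin_reads(dplyr::bind_rows(reads, reads, reads), c(chr1 = 4000), 1000)
  expect_equal(wiggle_correlation(a, b), 1.0)  # B = 3x A

  mk <- function(counts) {
    pos <- rep((seq_along(counts) - 1L) * 1000L, counts)
    bin_reads(make_reads("chr1", pos), c(chr1 = 4000), 1000)
  }
  expect_equal(wiggle_correlation(mk(c(1, 2, 3, 4)), mk(c(4, 3, 2, 1))), -1.0)
})

test_that("wiggle correlation matches the textbook Pearson formula", {
  set.seed(23)
  z <- rpois(200, 5)
  noise <- rpois(200, 2)
  mk <- function(counts) {
    pos <- rep((seq_along(counts) - 1L) * 100L, counts)
    bin_reads(make_reads("chr1", pos), c(chr1 = 20000), 100)
  }
  ta <- mk(z); tb <- mk(z + noise)
  va <- ta$value * 1e6 / sum(ta$value)
  vb <- tb$value * 1e6 / sum(tb$value)
  oracle <- sum((va - mean(va)) * (vb - mean(vb))) /
    sqrt(sum((va - mean(va))^2) * sum((vb - mean(vb))^2))
  expect_equal(wiggle_correlation(ta, tb), oracle, tolerance = 1e-12)
})

test_that("flat tracks yield NaN with a warning", {
  flat <- bin_reads(make_reads("chr1", integer()), c(chr1 = 4000), 1000)
  busy <- bin_reads(make_reads("chr1", c(1, 2500)), c(chr1 = 4000), 1000)
  expect_warning(r <- wiggle_correlation(flat, busy), "flat")
  expect_true(is.nan(r))
})

test_that("peak overlap consistency uses the larger set as denominator", {
  peaks <- make_peaks("chr1", seq(0, by = 1000, length.out = 100),
                      seq(400, by = 1000, length.out = 100))
  expect_equal(peak_overlap_consistency(peaks, peaks), 1.0)

  far <- make_peaks("chr2", seq(0, by = 1000, length.out = 50),
                    seq(400, by = 1000, length.out = 50))
  expect_equal(peak_overlap_consistency(peaks, far), 0.0)

  # B = 60 of A's 100 peaks, each shifted within +/-10 bp
  set.seed(3)
  b <- peaks[2:61, ]
  shift <- sample(-10:10, nrow(b), replace = TRUE)
  b$start <- b$start + shift; b$end <- b$end + shift
  expect_equal(peak_overlap_consistency(peaks, b), 0.60)

  expect_error(peak_overlap_consistency(peaks, peaks[0, ]), "at least one")
})

test_that("pairwise consistency enumerates unordered pairs compositionally", {
  spec <- simulation_spec(seed = 8, n_reads = 5000, n_peaks = 40,
                          chrom_sizes = c(chr1 = 2e5))
  sim <- simulate_replicates(spec, rho = 0.7, shared_peak_fraction = 0.5)
  reps2 <- list(sim$rep_a, sim$rep_b)
  out2 <- pairwise_consistency(reps2, spec$chrom_sizes, bin_size = 1000)
  expect_equal(nrow(out2), 1)

  reps4 <- list(sim$rep_a, sim$rep_b, sim$rep_a, sim$rep_b)
  out4 <- pairwise_consistency(reps4, spec$chrom_sizes, bin_size = 1000)
  expect_equal(nrow(out4), 6)  # C(4,2)

  # pair metrics equal the single-pair operations applied directly
  ta <- bin_reads(sim$rep_a$reads, spec$chrom_sizes, 1000)
  tb <- bin_reads(sim$rep_b$reads, spec$chrom_sizes, 1000)
  expect_equal(out2$wiggle_correlation, wiggle_correlation(ta, tb))
  expect_equal(out2$peak_overlap_ratio,
               peak_overlap_consistency(sim$rep_a$peaks, sim$rep_b$peaks))

  expect_message(none <- pairwise_consistency(reps2[1], spec$chrom_sizes),
                 "fewer than 2")
  expect_equal(nrow(none), 0)
})
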