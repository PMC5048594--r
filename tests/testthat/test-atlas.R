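write_metrics_json <- function(sample_id, frip = 0.05, pbc = 0.85,
                               category = "transcription factor",
                               input = FALSE, drop_frip = FALSE) {
  x <- list(
    schema_version = "1.0", sample_id = sample_id,
    dataset_id = paste0("ds_", sample_id), species = "hs",
    assay_category = category, is_input_control = input,
    read_layer = list(median_quality = 30, uniquely_mapped_ratio = 0.7,
                      nrf = 0.9, pbc = pbc),
    chip_layer = if (drop_frip) list(n_peaks = 100)
                 else list(n_peaks = 100, frip = frip),
    annotation_layer = list(promoter = 0.2)
  )
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  path
}

test_that("compile_atlas builds one row per sample and round-trips via TSV", {
  paths <- c(write_metrics_json("s1", frip = 0.02),
             write_metrics_json("s2", frip = 0.08),
             write_metrics_json("s3", drop_frip = TRUE))
  atlas <- compile_atlas(paths)
  expect_equal(nrow(atlas), 3)
  expect_true(is.na(atlas$frip[atlas$sample_id == "s3"]))

  tsv <- tempfile(fileext = ".tsv")
  write_atlas(atlas, tsv)
  back <- read_atlas(tsv)
  expect_equal(as.data.frame(back), as.data.frame(atlas))
})

test_that("compile_atlas rejects duplicates and schema violations by name", {
  p <- write_metrics_json("dup")
  expect_error(compile_atlas(c(p, p)), "duplicate sample_id")

  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(dataset_id = "d", assay_category = "x"),
                       bad, auto_unbox = TRUE)
  expect_error(compile_atlas(bad), "sample_id")
})

test_that("samples missing a metric are excluded from its percentile pool", {
  paths <- c(write_metrics_json("s1", frip = 0.02),
             write_metrics_json("s2", drop_frip = TRUE))
  atlas <- compile_atlas(paths)
  # pool for frip has a single value: the query equal to it sits at 50
  expect_equal(atlas_percentile(atlas, 0.02, "frip", "transcription factor"), 50)
})

test_that("mid-rank percentile follows its definition", {
  recs <- tibble::tibble(
    sample_id = sprintf("s%03d", 1:101), dataset_id = "d",
    assay_category = "transcription factor", pbc = (1:101) / 101
  )
  atlas <- compile_atlas(recs)
  expect_equal(atlas_percentile(atlas, 51 / 101, "pbc", "transcription factor"),
               50)  # percentile of the median
  expect_equal(atlas_percentile(atlas, 2, "pbc", "transcription factor"), 100)

  one <- compile_atlas(recs[1, ])
  expect_equal(atlas_percentile(one, recs$pbc[1], "pbc", "transcription factor"),
               50)

  expect_error(atlas_percentile(atlas, 0.5, "frip", "transcription factor"),
               "no historical values")
  expect_error(atlas_percentile(atlas, 0.5, "pbc", "nonexistent category"),
               "no historical values")
})

test_that("percentile is monotone and matches the sort-count oracle", {
  set.seed(37)
  for (case in 1:10) {
    vals <- round(runif(50), 2)  # duplicates likely
    recs <- tibble::tibble(sample_id = sprintf("c%d_s%d", case, 1:50),
                           dataset_id = "d", assay_category = "tf",
                           frip = vals, is_input_control = FALSE)
    atlas <- compile_atlas(recs)
    queries <- sort(runif(20))
    got <- vapply(queries, function(v)
      atlas_percentile(atlas, v, "frip", "tf"), numeric(1))
    expect_equal(got, vapply(queries, function(v)
      oracle_percentile(vals, v), numeric(1)))
    expect_true(all(diff(got) >= 0))
    expect_true(all(got >= 0 & got <= 100))
  }
})

test_that("input controls are excluded from ChIP-enrichment pools by default", {
  recs <- tibble::tibble(
    sample_id = c("chip1", "chip2", "inp1"), dataset_id = "d",
    assay_category = "tf", frip = c(0.10, 0.20, 0.001),
    is_input_control = c(FALSE, FALSE, TRUE)
  )
  atlas <- compile_atlas(recs)
  expect_equal(atlas_percentile(atlas, 0.05, "frip", "tf"), 0)
  expect_equal(atlas_percentile(atlas, 0.05, "frip", "tf",
                                exclude_input = FALSE), 100 / 3)
})

test_that("threshold flags follow the published cutoffs", {
  good <- list(median_quality = 26, uniquely_mapped_ratio = 0.51, pbc = 0.81,
               frip = 0.011, wiggle_correlation = 0.61,
               peak_overlap_ratio = 0.61)
  f <- flag_metrics(good)
  expect_true(all(f$status == "good"))

  # stepping each value to or below its threshold flips it to bad
  flips <- list(median_quality = 25, uniquely_mapped_ratio = 0.5, pbc = 0.8,
                frip = 0.009, wiggle_correlation = 0.6,
                peak_overlap_ratio = 0.6)
  for (m in names(flips)) {
    rec <- good; rec[[m]] <- flips[[m]]
    f2 <- flag_metrics(rec)
    expect_equal(f2$status[f2$metric == m], "bad")
    expect_true(all(f2$status[f2$metric != m] == "good"))
  }

  # FRiP threshold is inclusive: exactly 1% is good
  at_one_pct <- good; at_one_pct$frip <- 0.01
  f3 <- flag_metrics(at_one_pct)
  expect_equal(f3$status[f3$metric == "frip"], "good")
})

test_that("missing metrics and input controls are not applicable", {
  rec <- list(median_quality = 30, frip = NA_real_)
  f <- flag_metrics(rec)
  expect_equal(f$status[f$metric == "frip"], "not_applicable")
  expect_equal(f$status[f$metric == "pbc"], "not_applicable")

  inp <- list(frip = 0.004, is_input_control = TRUE)
  expect_equal(flag_metrics(inp)$status[1:4],
               c("not_applicable", "not_applicable", "not_applicable",
                 "not_applicable"))

  chip <- list(frip = 0.004, is_input_control = FALSE)
  expect_equal(flag_metrics(chip)$status[flag_metrics(chip)$metric == "frip"],
               "bad")

  # pure function: identical inputs give identical outputs
  expect_identical(flag_metrics(rec), flag_metrics(rec))
})

test_that("thresholds are overridable", {
  rec <- list(pbc = 0.65)
  expect_equal(flag_metrics(rec)$status[flag_metrics(rec)$metric == "pbc"],
               "bad")
  f <- flag_metrics(rec, thresholds = list(pbc = 0.6))
  expect_equal(f$status[f$metric == "pbc"], "good")
})
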