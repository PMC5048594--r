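# The QC atlas: historical metric records stratified by assay category,
# used to place a new sample's metrics on the distribution of previously
# processed public data, plus the good/bad threshold flags.

#' Default assay categories
#'
#' Eight literature-based experiment classes used to stratify the atlas.
#' The set is configurable everywhere it is consumed.
#' @export
default_assay_categories <- function() {
  c("transcription factor", "narrow histone mark", "broad histone mark",
    "chromatin regulator", "chromatin accessibility", "RNA polymerase",
    "CTCF/insulator", "other")
}

atlas_metric_columns <- function() {
  c("median_quality", "total_reads", "uniquely_mapped_reads",
    "uniquely_mapped_ratio", "unique_locations", "nrf", "pbc",
    "subsample_depth_used", "frip", "n_peaks", "n_fc10", "n_fc20",
    "wiggle_correlation", "peak_overlap_ratio",
    "promoter", "exon", "intron", "intergenic",
    "dhs_overlap_ratio", "blacklist_overlap_ratio")
}

atlas_id_columns <- function() {
  c("sample_id", "dataset_id", "species", "assay_category",
    "is_input_control")
}

record_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("sample_id", "dataset_id", "assay_category")) {
    if (is.null(x[[f]]) || !nzchar(as.character(x[[f]])))
      abort(sprintf("metrics JSON %s: missing required field '%s'", path, f))
  }
  flat <- c(
    x[intersect(atlas_id_columns(), names(x))],
    as.list(x$read_layer %||% list()),
    as.list(x$chip_layer %||% list()),
    as.list(x$annotation_layer %||% list())
  )
  row <- lapply(atlas_metric_columns(), function(m) {
    v <- flat[[m]]
    if (is.null(v) || !length(v) || all(is.na(v))) NA_real_ else as.numeric(v[1])
  })
  names(row) <- atlas_metric_columns()
  tibble(
    sample_id = as.character(flat$sample_id),
    dataset_id = as.character(flat$dataset_id),
    species = as.character(flat$species %||% NA_character_),
    assay_category = as.character(flat$assay_category),
    is_input_control = isTRUE(flat$is_input_control),
    !!!row
  )
}

#' Compile a QC atlas from per-sample metrics
#'
#' Builds the historical reference table from metrics JSON files (as
#' written by [run_qc()]) or from an already-tabular record set. One row
#' per sample; metrics a sample does not have are stored as NA and are
#' excluded from percentile pools.
#'
#' @param x Character vector of metrics-JSON paths, or a data frame of
#'   conforming rows.
#' @return Tibble of class `epiqc_atlas`.
#' @export
compile_atlas <- function(x) {
  if (is.character(x)) {
    rows <- purrr::map_dfr(x, record_from_json)
  } else if (is.data.frame(x)) {
    missing <- setdiff(atlas_id_columns()[c(1, 2, 4)], names(x))
    if (length(missing))
      abort(sprintf("atlas records missing field '%s'", missing[1]))
    rows <- as_tibble(x)
    if (!"species" %in% names(rows)) rows$species <- NA_character_
    if (!"is_input_control" %in% names(rows)) rows$is_input_control <- FALSE
    for (m in setdiff(atlas_metric_columns(), names(rows))) rows[[m]] <- NA_real_
    rows <- rows[, c(atlas_id_columns(), atlas_metric_columns())]
    rows$is_input_control <- as.logical(rows$is_input_control)
    for (m in atlas_metric_columns()) rows[[m]] <- as.numeric(rows[[m]])
  } else {
    abort("x must be JSON paths or a data frame of records")
  }
  dup <- rows$sample_id[duplicated(rows$sample_id)]
  if (length(dup))
    abort(sprintf("duplicate sample_id in atlas: %s",
                  paste(unique(dup), collapse = ", ")))
  structure(rows, class = c("epiqc_atlas", class(tibble())))
}

#' Write / read an atlas as TSV
#'
#' One header row, one row per sample, `NA` for missing metrics; the
#' round trip is lossless.
#'
#' @param atlas `epiqc_atlas` tibble.
#' @param path TSV path.
#' @export
write_atlas <- function(atlas, path) {
  utils::write.table(as.data.frame(atlas), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = "NA",
                         colClasses = c(sample_id = "character",
                                        dataset_id = "character",
                                        species = "character",
                                        assay_category = "character"),
                         check.names = FALSE)
  compile_atlas(as_tibble(x))
}

#' Percentile of a metric value against the atlas
#'
#' Mid-rank percentile of `value` among the non-missing historical values
#' of `metric` within `category`:
#' `100 * (#\{x < v\} + 0.5 * #\{x = v\}) / N`. Input-control samples are
#' excluded from ChIP-enrichment pools (`frip`, peak counts) by default.
#'
#' @param atlas `epiqc_atlas` tibble.
#' @param value Query value.
#' @param metric Metric column name.
#' @param category Assay category to compare against.
#' @param exclude_input Drop input controls from the pool (default TRUE
#'   for ChIP-enrichment metrics, FALSE otherwise).
#' @return Percentile in [0, 100].
#' @export
atlas_percentile <- function(atlas, value, metric,
                             category,
                             exclude_input = metric %in%
                               c("frip", "n_peaks", "n_fc10", "n_fc20")) {
  if (!metric %in% names(atlas))
    abort(sprintf("unknown metric '%s'", metric))
  pool <- atlas[atlas$assay_category == category, , drop = FALSE]
  if (exclude_input) pool <- pool[!pool$is_input_control, , drop = FALSE]
  x <- pool[[metric]]
  x <- x[!is.na(x)]
  if (!length(x))
    abort(sprintf("no historical values for metric '%s' in category '%s'",
                  metric, category))
  100 * (sum(x < value) + 0.5 * sum(x == value)) / length(x)
}

#' Default good/bad thresholds
#'
#' The empirical cutoffs under which most public samples fall: median
#' sequence quality > 25, uniquely mapped ratio > 0.5, PBC > 0.8, FRiP
#' >= 1% (ChIP samples only; a low FRiP on an input control is expected),
#' and replicate consistency (both wiggle correlation and peak overlap
#' ratio) > 0.6.
#' @export
default_thresholds <- function() {
  list(median_quality = 25, uniquely_mapped_ratio = 0.5, pbc = 0.8,
       frip = 0.01, consistency = 0.6)
}

#' Flag metrics as good / bad / not applicable
#'
#' Pure function of the record and the thresholds. Missing (NA) metrics
#' are `not_applicable`; FRiP is `not_applicable` on input controls.
#' Quality, ratio, PBC and consistency use strict `>`; FRiP uses `>=`
#' (the 1% reference is inclusive).
#'
#' @param record One-row data frame or named list of metric values
#'   (optionally with `is_input_control`).
#' @param thresholds Named list overriding [default_thresholds()].
#' @return Tibble with columns `metric`, `value`, `status`.
#' @export
flag_metrics <- function(record, thresholds = default_thresholds()) {
  th <- utils::modifyList(default_thresholds(), as.list(thresholds))
  rec <- as.list(record)
  val <- function(m) {
    v <- rec[[m]]
    if (is.null(v) || !length(v) || is.na(v)) NA_real_ else as.numeric(v)
  }
  is_input <- isTRUE(rec$is_input_control) ||
    identical(rec$is_input_control, 1) || identical(rec$is_input_control, "TRUE")
  status <- function(v, cut, strict = TRUE, applicable = TRUE) {
    if (!applicable || is.na(v)) return("not_applicable")
    ok <- if (strict) v > cut else v >= cut
    if (ok) "good" else "bad"
  }
  rows <- list(
    c("median_quality", val("median_quality"),
      status(val("median_quality"), th$median_quality)),
    c("uniquely_mapped_ratio", val("uniquely_mapped_ratio"),
      status(val("uniquely_mapped_ratio"), th$uniquely_mapped_ratio)),
    c("pbc", val("pbc"), status(val("pbc"), th$pbc)),
    c("frip", val("frip"),
      status(val("frip"), th$frip, strict = FALSE, applicable = !is_input)),
    c("wiggle_correlation", val("wiggle_correlation"),
      status(val("wiggle_correlation"), th$consistency)),
    c("peak_overlap_ratio", val("peak_overlap_ratio"),
      status(val("peak_overlap_ratio"), th$consistency))
  )
  tibble(
    metric = vapply(rows, `[[`, character(1), 1),
    value = as.numeric(vapply(rows, `[[`, character(1), 2)),
    status = vapply(rows, `[[`, character(1), 3)
  )
}
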