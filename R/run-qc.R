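# One-command QC run over a dataset: read layer -> ChIP layer ->
# annotation layer in dependency order, then percentile lookup and
# threshold flags, a metrics JSON (stable key order, fixed float
# precision) and a markdown report.

config_defaults <- function() {
  list(
    sample_id = "sample", dataset_id = "dataset", species = NA_character_,
    assay_category = "transcription factor", is_input_control = FALSE,
    reads = NULL, peaks = NULL, control_reads = NULL, fastq = NULL,
    chrom_sizes = NULL, genes = NULL, dhs = NULL, blacklist = NULL,
    conservation = NULL, atlas = NULL,
    seed = 1, output_dir = ".",
    subsample_depth = 4e6, frip_depth = 4e6, contam_sample = 1e5,
    mapq_gt = 1, top_n = 5000, promoter_flank = 2000, rp_dist = 1e5,
    rp_weight = "cistrome", corr_bin = 1000, fc_thresholds = c(10, 20),
    mito_names = c("chrM", "MT", "chrMT"),
    conservation_flank = 2000, conservation_bin = 50,
    quality_sample_n = 1e5
  )
}

#' Validate a QC run configuration
#'
#' Accepts a JSON/YAML file path or a named list. Applies defaults,
#' rejects unknown keys (suggesting the nearest valid one), checks
#' parameter ranges and that every referenced input file exists; all
#' problems are reported together.
#'
#' @param config Path to a `.json`/`.yaml`/`.yml` config, or a named list.
#' @return Validated config list of class `epiqc_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) abort("config must be a file path or a named list")
  defaults <- config_defaults()
  errors <- character()

  unknown <- setdiff(names(config), names(defaults))
  for (k in unknown) {
    d <- adist(k, names(defaults))
    near <- names(defaults)[which.min(d)]
    hint <- if (min(d) <= 3) sprintf(" (did you mean '%s'?)", near) else ""
    errors <- c(errors, sprintf("unknown config key '%s'%s", k, hint))
  }
  cfg <- utils::modifyList(defaults, config[setdiff(names(config), unknown)])

  if (is.null(cfg$reads) && is.null(cfg$peaks))
    errors <- c(errors,
      "config needs at least one of: reads (SAM paths), peaks (peak files)")
  if (!is.null(cfg$reads) && is.null(cfg$chrom_sizes))
    errors <- c(errors, "chrom_sizes is required when reads are given")
  for (key in c("reads", "peaks", "control_reads", "fastq", "chrom_sizes",
                "genes", "dhs", "blacklist", "conservation", "atlas")) {
    for (p in cfg[[key]]) {
      if (!is.na(p) && !file.exists(p))
        errors <- c(errors, sprintf("%s: file not found: %s", key, p))
    }
  }
  for (key in c("subsample_depth", "frip_depth", "contam_sample", "top_n",
                "promoter_flank", "rp_dist", "corr_bin")) {
    if (!is.numeric(cfg[[key]]) || cfg[[key]] < 1)
      errors <- c(errors, sprintf("%s must be a positive number", key))
  }
  if (length(errors))
    abort(paste(c("invalid configuration:", paste0("  - ", errors)),
                collapse = "\n"))
  structure(cfg, class = "epiqc_config")
}

round6 <- function(x) {
  if (is.numeric(x)) round(x, 6) else x
}

#' Run the full QC workflow over one dataset
#'
#' Executes the three metric layers in dependency order over one or more
#' replicates, applies the good/bad thresholds, annotates percentiles
#' when an atlas is configured, and writes `metrics.json` (stable key
#' order, floats at 1e-6 precision so reruns are byte-identical) and
#' `report.md` to the output directory. Layers whose inputs are missing
#' are skipped and reported as NA. Read-layer and ChIP-layer scalar
#' metrics in the flattened record refer to the first (primary)
#' replicate; replicate-pair metrics cover every unordered pair.
#'
#' @param config A validated config (see [validate_config()]), a config
#'   path, or a named list.
#' @return List of class `epiqc_qc` with elements `record` (one-row
#'   tibble, the atlas row), `flags`, `replicate_pairs`, `percentiles`,
#'   `json` (the nested metric list), `report_md`, and the written
#'   `json_path` / `report_path`.
#' @export
run_qc <- function(config) {
  cfg <- if (inherits(config, "epiqc_config")) config else validate_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)

  cs <- if (!is.null(cfg$chrom_sizes)) read_chrom_sizes(cfg$chrom_sizes)
  replicates <- list()
  if (!is.null(cfg$reads)) {
    for (i in seq_along(cfg$reads)) {
      replicates[[i]] <- list(
        id = sprintf("rep%d", i),
        reads = read_sam_min(cfg$reads[i], cs),
        peaks = if (!is.null(cfg$peaks) && length(cfg$peaks) >= i)
          read_bed(cfg$peaks[i]) else NULL
      )
    }
  } else {
    for (i in seq_along(cfg$peaks)) {
      replicates[[i]] <- list(id = sprintf("rep%d", i), reads = NULL,
                              peaks = read_bed(cfg$peaks[i]))
    }
  }
  primary <- replicates[[1]]

  # --- read layer ---------------------------------------------------------
  read_layer <- if (!is.null(primary$reads)) {
    rl <- read_layer_metrics(primary$reads, fastq_path = cfg$fastq,
                             mapq_gt = cfg$mapq_gt,
                             subsample_depth = cfg$subsample_depth,
                             seed = cfg$seed,
                             quality_sample_n = cfg$quality_sample_n)
    as.list(rl)
  } else NULL

  uniq_reads <- if (!is.null(primary$reads))
    primary$reads[primary$reads$mapq > cfg$mapq_gt |
                    primary$reads$mapq == 255L, , drop = FALSE]
  else NULL

  # --- ChIP layer ---------------------------------------------------------
  chip_layer <- NULL
  pairs <- tibble(id_a = character(), id_b = character(),
                  wiggle_correlation = numeric(),
                  peak_overlap_ratio = numeric())
  if (!is.null(primary$peaks)) {
    census <- peak_census(primary$peaks, fc_thresholds = cfg$fc_thresholds)
    frip <- if (!is.null(uniq_reads))
      compute_frip(uniq_reads, primary$peaks, subsample = cfg$frip_depth,
                   mito_names = cfg$mito_names, seed = cfg$seed)
    else NULL
    have_pairs <- length(replicates) >= 2 &&
      all(vapply(replicates, function(r)
        !is.null(r$reads) && !is.null(r$peaks), logical(1)))
    if (have_pairs)
      pairs <- pairwise_consistency(replicates, cs, bin_size = cfg$corr_bin)
    chip_layer <- c(as.list(census),
                    if (!is.null(frip)) as.list(frip)
                    else list(frip = NA_real_))
  }

  # --- annotation layer ---------------------------------------------------
  ann <- NULL
  ann_layer <- NULL
  if (!is.null(primary$peaks)) {
    genes <- if (!is.null(cfg$genes)) read_gene_table(cfg$genes)
    dhs <- if (!is.null(cfg$dhs)) read_bed(cfg$dhs)[, c("chrom", "start", "end")]
    bl <- if (!is.null(cfg$blacklist))
      read_bed(cfg$blacklist)[, c("chrom", "start", "end")]
    cons <- if (!is.null(cfg$conservation)) read_bedgraph(cfg$conservation)
    ann <- annotation_layer_metrics(primary$peaks, genes = genes, dhs = dhs,
                                    blacklist = bl, conservation = cons,
                                    top_n = cfg$top_n,
                                    promoter_window = cfg$promoter_flank,
                                    flank = cfg$conservation_flank,
                                    bin = cfg$conservation_bin,
                                    max_dist = cfg$rp_dist,
                                    weight = cfg$rp_weight)
    ann_layer <- list(
      promoter = if (!is.null(ann$meta)) ann$meta$promoter else NA_real_,
      exon = if (!is.null(ann$meta)) ann$meta$exon else NA_real_,
      intron = if (!is.null(ann$meta)) ann$meta$intron else NA_real_,
      intergenic = if (!is.null(ann$meta)) ann$meta$intergenic else NA_real_,
      dhs_overlap_ratio = ann$dhs_overlap_ratio %||% NA_real_,
      blacklist_overlap_ratio = ann$blacklist_overlap_ratio %||% NA_real_
    )
  }

  # --- flattened record (the atlas row) ----------------------------------
  record <- tibble(
    sample_id = cfg$sample_id, dataset_id = cfg$dataset_id,
    species = as.character(cfg$species),
    assay_category = cfg$assay_category,
    is_input_control = isTRUE(cfg$is_input_control),
    median_quality = read_layer$median_quality %||% NA_real_,
    total_reads = read_layer$total_reads %||% NA_real_,
    uniquely_mapped_reads = read_layer$uniquely_mapped_reads %||% NA_real_,
    uniquely_mapped_ratio = read_layer$uniquely_mapped_ratio %||% NA_real_,
    unique_locations = read_layer$unique_locations %||% NA_real_,
    nrf = read_layer$nrf %||% NA_real_,
    pbc = read_layer$pbc %||% NA_real_,
    subsample_depth_used = read_layer$subsample_depth_used %||% NA_real_,
    frip = chip_layer$frip %||% NA_real_,
    n_peaks = chip_layer$n_peaks %||% NA_real_,
    n_fc10 = chip_layer$n_fc10 %||% NA_real_,
    n_fc20 = chip_layer$n_fc20 %||% NA_real_,
    wiggle_correlation = if (nrow(pairs)) mean(pairs$wiggle_correlation)
      else NA_real_,
    peak_overlap_ratio = if (nrow(pairs)) mean(pairs$peak_overlap_ratio)
      else NA_real_,
    promoter = ann_layer$promoter %||% NA_real_,
    exon = ann_layer$exon %||% NA_real_,
    intron = ann_layer$intron %||% NA_real_,
    intergenic = ann_layer$intergenic %||% NA_real_,
    dhs_overlap_ratio = ann_layer$dhs_overlap_ratio %||% NA_real_,
    blacklist_overlap_ratio = ann_layer$blacklist_overlap_ratio %||% NA_real_
  )

  flags <- flag_metrics(record)

  percentiles <- NULL
  if (!is.null(cfg$atlas)) {
    atlas <- read_atlas(cfg$atlas)
    pct_of <- function(metric) {
      v <- record[[metric]]
      if (is.na(v)) return(NA_real_)
      tryCatch(atlas_percentile(atlas, v, metric, cfg$assay_category),
               error = function(e) NA_real_)
    }
    pm <- c("median_quality", "uniquely_mapped_ratio", "pbc", "frip",
            "n_peaks", "dhs_overlap_ratio")
    percentiles <- tibble(metric = pm,
                          percentile = unname(vapply(pm, pct_of, numeric(1))))
  }

  json <- list(
    schema_version = "1.0",
    sample_id = cfg$sample_id, dataset_id = cfg$dataset_id,
    species = cfg$species, assay_category = cfg$assay_category,
    is_input_control = isTRUE(cfg$is_input_control),
    seed = cfg$seed,
    read_layer = lapply(read_layer, round6),
    chip_layer = c(lapply(chip_layer, round6),
                   list(replicate_pairs = lapply(
                     seq_len(nrow(pairs)), function(j)
                       lapply(as.list(pairs[j, ]), round6)))),
    annotation_layer = lapply(ann_layer, round6)
  )
  json_path <- file.path(cfg$output_dir, "metrics.json")
  jsonlite::write_json(json, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")

  report_md <- render_report(cfg, record, flags, pairs, percentiles, ann)
  report_path <- file.path(cfg$output_dir, "report.md")
  writeLines(report_md, report_path)

  structure(
    list(record = record, flags = flags, replicate_pairs = pairs,
         percentiles = percentiles, annotation = ann, json = json,
         report_md = report_md, json_path = json_path,
         report_path = report_path, config = cfg),
    class = "epiqc_qc"
  )
}

fmt <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(x == round(x), format(x, scientific = FALSE, trim = TRUE),
                format(round(x, 4), scientific = FALSE, trim = TRUE)))
}

render_report <- function(cfg, record, flags, pairs, percentiles, ann) {
  badge <- function(metric) {
    s <- flags$status[flags$metric == metric]
    if (!length(s) || s == "not_applicable") "" else paste0(" [", s, "]")
  }
  lines <- c(
    sprintf("# QC report: %s (%s)", cfg$sample_id, cfg$dataset_id),
    "",
    sprintf("- assay category: %s", cfg$assay_category),
    sprintf("- input control: %s", isTRUE(cfg$is_input_control)),
    sprintf("- seed: %d", as.integer(cfg$seed)),
    "",
    "## Read layer",
    ""
  )
  if (!is.na(record$total_reads)) {
    lines <- c(lines,
      sprintf("- median base quality: %s%s", fmt(record$median_quality),
              badge("median_quality")),
      sprintf("- total reads: %s", fmt(record$total_reads)),
      sprintf("- uniquely mapped: %s (ratio %s)%s",
              fmt(record$uniquely_mapped_reads),
              fmt(record$uniquely_mapped_ratio), badge("uniquely_mapped_ratio")),
      sprintf("- subsample depth used: %s%s", fmt(record$subsample_depth_used),
              if (record$subsample_depth_used < cfg$subsample_depth)
                " (below target depth; all reads used)" else ""),
      sprintf("- unique locations: %s; NRF %s; PBC %s%s",
              fmt(record$unique_locations), fmt(record$nrf),
              fmt(record$pbc), badge("pbc")))
  } else lines <- c(lines, "- skipped (no aligned reads supplied)")
  lines <- c(lines, "", "## ChIP layer", "")
  if (!is.na(record$n_peaks)) {
    lines <- c(lines,
      sprintf("- peaks: %s (>=10x: %s, >=20x: %s)", fmt(record$n_peaks),
              fmt(record$n_fc10), fmt(record$n_fc20)),
      sprintf("- FRiP: %s%s", fmt(record$frip), badge("frip")))
    if (nrow(pairs)) {
      lines <- c(lines, "- replicate consistency:")
      for (j in seq_len(nrow(pairs)))
        lines <- c(lines, sprintf(
          "    - %s vs %s: wiggle correlation %s, peak overlap ratio %s",
          pairs$id_a[j], pairs$id_b[j], fmt(pairs$wiggle_correlation[j]),
          fmt(pairs$peak_overlap_ratio[j])))
    }
  } else lines <- c(lines, "- skipped (no peaks supplied)")
  lines <- c(lines, "", "## Annotation layer", "")
  if (!is.na(record$promoter) || !is.na(record$dhs_overlap_ratio)) {
    if (!is.na(record$promoter))
      lines <- c(lines, sprintf(
        "- summit distribution: promoter %s, exon %s, intron %s, intergenic %s",
        fmt(record$promoter), fmt(record$exon), fmt(record$intron),
        fmt(record$intergenic)))
    if (!is.na(record$dhs_overlap_ratio))
      lines <- c(lines, sprintf("- union DHS overlap ratio (top %d peaks): %s",
                                as.integer(cfg$top_n),
                                fmt(record$dhs_overlap_ratio)))
    if (!is.na(record$blacklist_overlap_ratio))
      lines <- c(lines, sprintf("- blacklist overlap ratio: %s",
                                fmt(record$blacklist_overlap_ratio)))
    if (!is.null(ann$profile))
      lines <- c(lines, sprintf(
        "- conservation profile: %d bins over +/-%d bp (%d truncated summits)",
        nrow(ann$profile), attr(ann$profile, "flank"),
        attr(ann$profile, "n_truncated")))
    if (!is.null(ann$rp))
      lines <- c(lines, sprintf("- top putative target gene: %s (RP %s)",
                                ann$rp$gene_id[1], fmt(ann$rp$score[1])))
  } else lines <- c(lines, "- skipped (no annotation inputs supplied)")
  if (!is.null(percentiles)) {
    lines <- c(lines, "", "## Atlas percentiles", "")
    for (j in seq_len(nrow(percentiles)))
      if (!is.na(percentiles$percentile[j]))
        lines <- c(lines, sprintf("- %s: %s%%", percentiles$metric[j],
                                  fmt(percentiles$percentile[j])))
  }
  lines
}

#' @export
print.epiqc_qc <- function(x, ...) {
  cat(x$report_md, sep = "\n")
  invisible(x)
}
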