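# broom-style accessors and ggplot2 autoplot methods for the result types

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a QC run into a long metric table
#'
#' One row per metric with its value and good/bad/not_applicable status.
#'
#' @param x `epiqc_qc` object from [run_qc()].
#' @param ... Unused.
#' @return Tibble with columns `metric`, `value`, `status`.
#' @export
tidy.epiqc_qc <- function(x, ...) {
  long <- x$record %>%
    select(-dplyr::any_of(c("sample_id", "dataset_id", "species",
                            "assay_category", "is_input_control"))) %>%
    tidyr::pivot_longer(dplyr::everything(), names_to = "metric",
                        values_to = "value")
  left_join(long, select(x$flags, "metric", "status"), by = "metric") %>%
    mutate(status = tidyr::replace_na(.data$status, "unflagged"))
}

#' One-row summary of a QC run
#'
#' The flattened sample record (the atlas row).
#'
#' @param x `epiqc_qc` object.
#' @param ... Unused.
#' @export
glance.epiqc_qc <- function(x, ...) x$record

#' Plot a summit-centred conservation profile
#'
#' @param object `epiqc_profile` from [conservation_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.epiqc_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$offset, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "distance from summit (bp)",
                  y = "mean conservation",
                  title = sprintf("conservation profile (%d summits)",
                                  attr(object, "n_summits"))) +
    ggplot2::theme_minimal()
}

#' Plot a binned signal track
#'
#' @param object `epiqc_track` from [bin_reads()].
#' @param ... Unused.
#' @return A ggplot, faceted by chromosome.
#' @export
autoplot.epiqc_track <- function(object, ...) {
  bs <- attr(object, "bin_size")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$bin * bs, y = .data$value)) +
    ggplot2::geom_col(width = bs) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "reads per bin") +
    ggplot2::theme_minimal()
}

#' Plot a metric distribution from the atlas with a sample's value
#'
#' Histogram of the historical values of `metric` in `category`, with a
#' vertical line at the queried value and its mid-rank percentile in the
#' title.
#'
#' @param atlas `epiqc_atlas`.
#' @param metric Metric column name.
#' @param category Assay category.
#' @param value Optional sample value to mark.
#' @return A ggplot.
#' @export
plot_atlas_metric <- function(atlas, metric, category, value = NULL) {
  pool <- atlas[atlas$assay_category == category, , drop = FALSE]
  x <- pool[[metric]]
  df <- tibble(value = x[!is.na(x)])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::labs(x = metric, y = "samples",
                  title = sprintf("%s in '%s' (n=%d)", metric, category,
                                  nrow(df))) +
    ggplot2::theme_minimal()
  if (!is.null(value)) {
    pct <- atlas_percentile(atlas, value, metric, category)
    p <- p +
      ggplot2::geom_vline(xintercept = value, colour = "red") +
      ggplot2::labs(subtitle = sprintf("sample value %.4g = percentile %.1f",
                                       value, pct))
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
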