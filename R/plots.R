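# ggplot2 presentation methods for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_histogram
#'   geom_tile geom_point geom_hline labs scale_x_continuous theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a mapping-accuracy curve
#'
#' Fraction of all simulated reads that are mapped, pass the mapq
#' threshold and are correct, per threshold.
#'
#' @param object An `accuracy_curve` from [evaluate_alignments()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.accuracy_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$mapq_threshold, y = .data$accuracy)) +
    geom_line() +
    labs(x = "minimum mapping quality", y = "fraction of all reads correct") +
    theme_minimal()
}

#' Plot a variant summary
#'
#' Per-kind counts and cumulative affected sequence.
#'
#' @param object A `variant_summary` from [summarize_variants()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.variant_summary <- function(object, ...) {
  d <- tidyr::pivot_longer(object$by_kind, c("n", "total_bp"),
                           names_to = "measure", values_to = "value")
  ggplot(d, aes(x = .data$kind, y = .data$value)) +
    geom_col() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}

#' Plot per-sample concordance distribution
#'
#' @param object A `concordance_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.concordance_report <- function(object, ...) {
  ggplot(object$per_sample, aes(x = .data$agreement_pct)) +
    geom_histogram(bins = 20, boundary = 100) +
    labs(x = "per-sample agreement (%)", y = "samples") +
    theme_minimal()
}

#' Plot accessory-sequence attribution
#'
#' @param object An `accessory_attribution` from [attribute_accessory()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.accessory_attribution <- function(object, ...) {
  d <- mutate(as_tibble(object),
              sample = factor(.data$sample, levels = .data$sample))
  ggplot(d, aes(x = .data$sample, y = .data$contributed_bp)) +
    geom_col() +
    labs(x = NULL, y = "contributed bp") +
    theme_minimal()
}

#' Plot node path coverage along the reference
#'
#' One tile per (reference segment, path), coloured by traversal count;
#' a count of 2 in a haplotype marks a duplication.
#'
#' @param coverage Output of [node_path_coverage()].
#' @param g The [pangenome].
#' @return A ggplot.
#' @export
plot_path_coverage <- function(coverage, g) {
  cmap <- reference_coord_map(g)
  d <- dplyr::inner_join(coverage, select(cmap, "segment_id", "start", "end"),
                         by = "segment_id")
  ggplot(d, aes(xmin = .data$start, xmax = .data$end + 1,
                ymin = as.integer(factor(.data$path_name)) - 0.45,
                ymax = as.integer(factor(.data$path_name)) + 0.45,
                fill = factor(.data$count))) +
    ggplot2::geom_rect() +
    ggplot2::scale_y_continuous(
      breaks = seq_along(levels(factor(d$path_name))),
      labels = levels(factor(d$path_name))) +
    labs(x = "reference position (bp)", y = NULL, fill = "path coverage") +
    theme_minimal()
}
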