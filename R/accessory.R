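# Iterative greedy attribution of accessory (non-base) graph sequence.

#' Attribute accessory sequence to samples by greedy removal
#'
#' Quantifies how much sequence each sample adds to the graph beyond a
#' base assembly. Step 0 removes every segment traversed by any path of
#' the base sample. Each subsequent iteration computes, for every
#' remaining sample, the summed length of the remaining segments traversed
#' by any of its haplotype paths, records the sample with the largest sum
#' as the next contributor, removes its segments, and repeats until no
#' samples remain. Ties are broken lexicographically by sample name.
#' Segments traversed by no path at all are reported as residual.
#'
#' @param g A [pangenome].
#' @param base_sample Sample whose traversed segments are removed first.
#' @return An `accessory_attribution` tibble with columns `rank`,
#'   `sample`, `contributed_bp`, and attributes `base_sample`,
#'   `base_traversed_bp`, `residual_bp`, `total_length`.
#' @export
attribute_accessory <- function(g, base_sample) {
  if (!base_sample %in% g$paths$sample) {
    abort(paste0("unknown base sample: ", base_sample))
  }
  lens <- segment_lengths(g)
  sample_segs <- g$paths |>
    mutate(seg = purrr::map(.data$steps, ~ unique(.x$segment_id))) |>
    group_by(.data$sample) |>
    summarise(seg = list(unique(unlist(.data$seg)))) |>
    ungroup()
  seg_sets <- setNames(sample_segs$seg, sample_segs$sample)
  base_segs <- seg_sets[[base_sample]]
  base_bp <- sum(lens[base_segs])
  remaining_segs <- setdiff(names(lens), base_segs)
  remaining_samples <- sort(setdiff(names(seg_sets), base_sample))
  rows <- list()
  rank <- 0L
  while (length(remaining_samples) > 0) {
    sums <- vapply(remaining_samples, function(s) {
      sum(lens[intersect(seg_sets[[s]], remaining_segs)])
    }, numeric(1))
    best <- remaining_samples[which.max(sums)]  # ties: first in sorted order
    rank <- rank + 1L
    rows[[rank]] <- tibble(rank = rank, sample = best,
                           contributed_bp = unname(sums[[best]]))
    remaining_segs <- setdiff(remaining_segs, seg_sets[[best]])
    remaining_samples <- setdiff(remaining_samples, best)
  }
  res <- if (length(rows) > 0) bind_rows(rows) else {
    tibble(rank = integer(), sample = character(), contributed_bp = numeric())
  }
  residual <- sum(lens[remaining_segs])
  structure(res, base_sample = base_sample, base_traversed_bp = base_bp,
            residual_bp = residual, total_length = sum(lens),
            class = c("accessory_attribution", class(res)))
}

#' @rdname attribute_accessory
#' @param x An `accessory_attribution`.
#' @param ... Unused.
#' @export
glance.accessory_attribution <- function(x, ...) {
  tibble(base_sample = attr(x, "base_sample"),
         base_traversed_bp = attr(x, "base_traversed_bp"),
         n_samples = nrow(x),
         attributed_bp = sum(x$contributed_bp),
         residual_bp = attr(x, "residual_bp"),
         total_length = attr(x, "total_length"))
}
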