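# Path-coverage duplication detection and edge-support genotyping of
# declared complex structural-variant events from graph alignments.

#' Per-segment, per-path traversal counts
#'
#' Path coverage of a node is the number of times a haplotype path passes
#' through it; a count of 2 or more in a single haplotype indicates a
#' duplication in that haplotype.
#'
#' @param g A [pangenome].
#' @return Tibble `segment_id`, `path_name`, `count` (only nonzero rows).
#' @export
node_path_coverage <- function(g) {
  purrr::map2_dfr(g$paths$path_name, g$paths$steps, function(nm, st) {
    tab <- table(st$segment_id)
    tibble(segment_id = names(tab), path_name = nm, count = as.integer(tab))
  })
}

#' Detect duplicated segment runs from path coverage
#'
#' For each path, segments with traversal count at least `min_count` are
#' grouped into maximal runs of consecutive reference-path segments, and
#' each run is reported with its projected reference interval. Duplicated
#' segments that do not lie on a reference path are reported as
#' single-segment runs anchored at their projected position.
#'
#' @param coverage Output of [node_path_coverage()].
#' @param g The [pangenome] the coverage was computed from.
#' @param min_count Minimum traversal count (default 2).
#' @return Tibble `path_name`, `run_id`, `contig`, `ref_start`, `ref_end`,
#'   `segments` (list column), `max_count`.
#' @export
detect_duplications <- function(coverage, g, min_count = 2L) {
  dup <- filter(coverage, .data$count >= min_count)
  empty <- tibble(path_name = character(), run_id = integer(),
                  contig = character(), ref_start = integer(),
                  ref_end = integer(), segments = list(), max_count = integer())
  if (nrow(dup) == 0) return(empty)
  cmap <- reference_coord_map(g)
  dup <- left_join(dup, select(cmap, "segment_id", "contig", "start", "end",
                               "ref_index"),
                   by = "segment_id")
  rows <- list()
  for (pn in unique(dup$path_name)) {
    d <- filter(dup, .data$path_name == pn)
    onref <- arrange(filter(d, !is.na(.data$ref_index)), .data$ref_index)
    if (nrow(onref) > 0) {
      brk <- c(0, cumsum(diff(onref$ref_index) != 1))
      for (b in unique(brk)) {
        run <- onref[brk == b, ]
        rows[[length(rows) + 1]] <- tibble(
          path_name = pn, contig = run$contig[[1]],
          ref_start = min(run$start), ref_end = max(run$end),
          segments = list(run$segment_id), max_count = max(run$count))
      }
    }
    offref <- filter(d, is.na(.data$ref_index))
    for (i in seq_len(nrow(offref))) {
      pr <- project_to_reference(g, offref$segment_id[[i]], 0L)
      rows[[length(rows) + 1]] <- tibble(
        path_name = pn, contig = pr$contig,
        ref_start = pr$position, ref_end = pr$position,
        segments = list(offref$segment_id[[i]]), max_count = offref$count[[i]])
    }
  }
  bind_rows(rows) |>
    arrange(.data$path_name, .data$contig, .data$ref_start) |>
    group_by(.data$path_name) |>
    mutate(run_id = row_number(), .after = 1) |>
    ungroup()
}

#' Parse an oriented edge specification
#'
#' Edges are written `"A+>B-"`: oriented source, `>`, oriented target.
#'
#' @param spec Character vector of edge specifications.
#' @return Tibble `from_id`, `from_orient`, `to_id`, `to_orient`.
#' @export
parse_edge <- function(spec) {
  m <- stringr::str_match(spec, "^(.+)([+-])>(.+)([+-])$")
  if (anyNA(m[, 1])) abort("edge spec must look like 'A+>B+'")
  tibble(from_id = m[, 2], from_orient = m[, 3], to_id = m[, 4], to_orient = m[, 5])
}

edge_spec_key <- function(x) {
  e <- if (is.character(x)) parse_edge(x) else x
  edge_key(e$from_id, e$from_orient, e$to_id, e$to_orient)
}

#' Declare a structural-variant event model for edge-support genotyping
#'
#' An event is genotyped from the read support of diagnostic junction
#' edges: `presence_edges` are traversed by haplotypes carrying the event
#' and `absence_edges` by haplotypes lacking it. Under the
#' carrier hypothesis a fraction `theta_present` of the informative reads
#' is expected on the presence edges (about 0.98 for a hemizygous
#' insertion, 0.5 for a hemizygous tandem duplication whose carrier
#' chromosome traverses the loop-back and the exit edge once each); under
#' the non-carrier hypothesis only a noise fraction `theta_absent` is.
#'
#' @param name Event name.
#' @param presence_edges,absence_edges Edge specs (`"A+>B+"` strings or
#'   tibbles from [parse_edge()]). With several presence edges the
#'   bottleneck rule applies: the minimum per-edge count is used.
#' @param theta_present,theta_absent Expected presence-edge read fractions
#'   under the two hypotheses; must satisfy 0 < theta_absent <
#'   theta_present < 1.
#' @param alpha Binomial test level (default 0.05).
#' @param min_reads Minimum informative reads; below it the call is
#'   `no_data` (default 4).
#' @return An `sv_event` list.
#' @export
sv_event <- function(name, presence_edges, absence_edges,
                     theta_present = 0.98, theta_absent = 0.02,
                     alpha = 0.05, min_reads = 4L) {
  if (!(0 < theta_absent && theta_absent < theta_present && theta_present < 1)) {
    abort("need 0 < theta_absent < theta_present < 1")
  }
  pe <- if (is.character(presence_edges)) parse_edge(presence_edges) else presence_edges
  ae <- if (is.character(absence_edges)) parse_edge(absence_edges) else absence_edges
  structure(list(name = name, presence_edges = pe, absence_edges = ae,
                 theta_present = theta_present, theta_absent = theta_absent,
                 alpha = alpha, min_reads = as.integer(min_reads)),
            class = "sv_event")
}

#' Count read support for diagnostic edges from graph alignments
#'
#' A read supports an edge if its walk contains the oriented segment pair
#' (in canonical form) and its aligned interval covers at least one base
#' on each side of the junction: a read ending exactly at the junction
#' does not support it.
#'
#' @param gaf Graph alignments as returned by [read_gaf()].
#' @param g The [pangenome] (for segment lengths).
#' @param events List of [sv_event()]s (or a single one).
#' @return Tibble `event`, `role` (`presence`/`absence`), `edge_key`,
#'   `count`; reads whose walks name unknown segments are skipped and
#'   tallied in attribute `n_skipped`.
#' @export
count_edge_support <- function(gaf, g, events) {
  if (inherits(events, "sv_event")) events <- list(events)
  lens <- segment_lengths(g)
  wanted <- purrr::map_dfr(events, function(ev) {
    bind_rows(
      mutate(ev$presence_edges, event = ev$name, role = "presence"),
      mutate(ev$absence_edges, event = ev$name, role = "absence")
    )
  })
  wanted$edge_key <- edge_key(wanted$from_id, wanted$from_orient,
                              wanted$to_id, wanted$to_orient)
  counts <- setNames(rep(0L, nrow(wanted)), wanted$edge_key)
  n_skipped <- 0L
  for (i in seq_len(nrow(gaf))) {
    w <- gaf$walk[[i]]
    if (nrow(w) == 0) next
    if (any(!w$segment_id %in% names(lens))) {
      n_skipped <- n_skipped + 1L
      next
    }
    if (nrow(w) < 2) next
    ek <- path_edge_keys(w)
    junctions <- cumsum(lens[w$segment_id])[-nrow(w)]  # 0-based offsets
    hit <- ek %in% names(counts) &
      gaf$path_start[[i]] <= junctions - 1 &
      gaf$path_end[[i]] >= junctions + 1
    for (k in ek[hit]) counts[[k]] <- counts[[k]] + 1L
  }
  if (n_skipped > 0) {
    warn(paste0(n_skipped, " reads skipped: walk names unknown segments"))
  }
  wanted$count <- as.integer(counts[wanted$edge_key])
  res <- select(wanted, "event", "role", "edge_key", "count")
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Genotype a structural-variant event from edge support
#'
#' Uses the bottleneck rule (minimum count over an event's presence edges,
#' likewise for absence edges) to form `k_presence` and `k_absence`, then
#' performs two exact two-sided binomial tests of `k_presence` out of
#' `n = k_presence + k_absence`: one under `theta_present`, one under
#' `theta_absent`. The call is `present` when the carrier hypothesis is
#' retained and the non-carrier hypothesis rejected at `alpha`, `absent`
#' in the reverse case, `inconclusive` when both are retained or both
#' rejected, and `no_data` when fewer than `min_reads` informative reads
#' are available.
#'
#' @param support Output of [count_edge_support()], or a list/tibble
#'   giving `k_presence` and `k_absence` directly.
#' @param event An [sv_event()].
#' @param sample Optional sample label carried into the result.
#' @return An `sv_call` tibble with one row: `event`, `sample`,
#'   `k_presence`, `k_absence`, `p_present`, `p_absent`, `call`.
#' @export
genotype_sv <- function(support, event, sample = NA_character_) {
  if (is.data.frame(support) && "role" %in% names(support)) {
    s <- filter(support, .data$event == !!event$name)
    k_p <- min(filter(s, .data$role == "presence")$count)
    k_a <- min(filter(s, .data$role == "absence")$count)
  } else {
    k_p <- support$k_presence
    k_a <- support$k_absence
  }
  n <- k_p + k_a
  if (n < event$min_reads) {
    p_present <- NA_real_; p_absent <- NA_real_; call <- "no_data"
  } else {
    p_present <- stats::binom.test(k_p, n, event$theta_present)$p.value
    p_absent <- stats::binom.test(k_p, n, event$theta_absent)$p.value
    keep_p <- p_present > event$alpha
    keep_a <- p_absent > event$alpha
    call <- if (keep_p && !keep_a) "present"
            else if (keep_a && !keep_p) "absent"
            else "inconclusive"
  }
  structure(
    tibble(event = event$name, sample = sample,
           k_presence = as.integer(k_p), k_absence = as.integer(k_a),
           p_present = p_present, p_absent = p_absent, call = call),
    class = c("sv_call", class(tibble())))
}

#' Genotype one or more events for one or more samples of aligned reads
#'
#' Convenience wrapper: counts edge support per sample and genotypes each
#' event.
#'
#' @param gaf_by_sample Named list of GAF alignment tibbles.
#' @param g The [pangenome].
#' @param events List of [sv_event()]s.
#' @return An `sv_call` tibble with one row per sample and event.
#' @export
genotype_sv_samples <- function(gaf_by_sample, g, events) {
  if (inherits(events, "sv_event")) events <- list(events)
  purrr::imap_dfr(gaf_by_sample, function(gaf, sm) {
    sup <- count_edge_support(gaf, g, events)
    purrr::map_dfr(events, ~ genotype_sv(sup, .x, sample = sm))
  })
}
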