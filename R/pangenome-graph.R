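#' @importFrom rlang .data %||% abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows distinct n rename row_number pull across all_of
#' @importFrom stats rbinom rnorm rgeom runif setNames sd rbeta
#' @importFrom utils head tail
NULL

# ---- small sequence helpers -------------------------------------------------

#' Reverse complement of DNA strings
#'
#' Vectorised wrapper around [Biostrings::reverseComplement()] for plain
#' character vectors over the alphabet A/C/G/T/N.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  if (length(x) == 0) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# ---- PanSN names ------------------------------------------------------------

#' Parse PanSN-style path names
#'
#' PanSN names have the form `sample#haplotype#contig`. Names without a
#' `#` are tolerated as plain contig names: sample and contig are set to
#' the full name and the haplotype to `"0"`, so reference FASTA contig
#' names can be used directly as path names.
#'
#' @param name Character vector of path names.
#' @return Tibble with columns `path_name`, `sample`, `haplotype`, `contig`.
#' @export
parse_pansn <- function(name) {
  parts <- stringr::str_split(name, stringr::fixed("#"))
  tibble(
    path_name = name,
    sample = purrr::map2_chr(parts, name, ~ if (length(.x) >= 3) .x[[1]] else .y),
    haplotype = purrr::map_chr(parts, ~ if (length(.x) >= 3) .x[[2]] else "0"),
    contig = purrr::map_chr(parts, ~ if (length(.x) >= 3) paste(.x[-(1:2)], collapse = "#") else .x[[1]])
  )
}

pansn_name <- function(sample, haplotype, contig) {
  paste(sample, haplotype, contig, sep = "#")
}

# ---- links: canonical set semantics -----------------------------------------

flip_orient <- function(o) ifelse(o == "+", "-", "+")

#' Canonicalise oriented links
#'
#' A link and its reverse-complement traversal denote the same edge. Links
#' are stored with the lexicographically smaller oriented endpoint first so
#' that the link table has set semantics.
#'
#' @param links Tibble with columns `from_id`, `from_orient`, `to_id`,
#'   `to_orient`.
#' @return Tibble of canonical, de-duplicated links.
#' @export
canonical_links <- function(links) {
  if (nrow(links) == 0) {
    return(tibble(from_id = character(), from_orient = character(),
                  to_id = character(), to_orient = character()))
  }
  fwd <- paste(links$from_id, links$from_orient, links$to_id, links$to_orient)
  rev <- paste(links$to_id, flip_orient(links$to_orient),
               links$from_id, flip_orient(links$from_orient))
  take_rev <- rev < fwd
  out <- tibble(
    from_id = ifelse(take_rev, links$to_id, links$from_id),
    from_orient = ifelse(take_rev, flip_orient(links$to_orient), links$from_orient),
    to_id = ifelse(take_rev, links$from_id, links$to_id),
    to_orient = ifelse(take_rev, flip_orient(links$from_orient), links$to_orient)
  )
  distinct(arrange(out, .data$from_id, .data$from_orient, .data$to_id, .data$to_orient))
}

edge_key <- function(from_id, from_orient, to_id, to_orient) {
  fwd <- paste(from_id, from_orient, to_id, to_orient)
  rev <- paste(to_id, flip_orient(to_orient), from_id, flip_orient(from_orient))
  ifelse(rev < fwd, rev, fwd)
}

#' Build a step table
#'
#' A path's steps are stored as a tibble with columns `segment_id` and
#' `orient`; this helper builds one (orientations default to `"+"`).
#'
#' @param segment_id Character vector of segment ids.
#' @param orient Orientations, `"+"` or `"-"`.
#' @return A step tibble.
#' @export
steps_tbl <- function(segment_id, orient = rep("+", length(segment_id))) {
  tibble(segment_id = as.character(segment_id), orient = as.character(orient))
}

# consecutive-step edge keys along a path
path_edge_keys <- function(steps) {
  k <- nrow(steps)
  if (k < 2) return(character())
  edge_key(steps$segment_id[-k], steps$orient[-k],
           steps$segment_id[-1], steps$orient[-1])
}

# ---- pangenome object -------------------------------------------------------

#' Construct a pangenome graph
#'
#' A pangenome graph bundles segments (nodes carrying DNA), links
#' (oriented edges, stored canonically with set semantics) and named
#' haplotype paths. One sample is designated the reference; its paths
#' define the coordinate system used by variant calling and projection.
#'
#' @param segments Tibble with columns `segment_id`, `sequence`.
#' @param links Tibble with columns `from_id`, `from_orient`, `to_id`,
#'   `to_orient` (orientations `"+"`/`"-"`).
#' @param paths Tibble with columns `path_name` and `steps` (a list column
#'   of step tables with columns `segment_id`, `orient`). PanSN fields are
#'   derived from `path_name`.
#' @param reference_sample Sample name owning the reference path(s).
#' @param validate Check all invariants (default `TRUE`).
#' @return An object of class `pangenome`.
#' @export
pangenome <- function(segments, links, paths, reference_sample, validate = TRUE) {
  segments <- arrange(as_tibble(segments)[, c("segment_id", "sequence")], .data$segment_id)
  links <- canonical_links(as_tibble(links))
  paths <- as_tibble(paths)
  pansn <- parse_pansn(paths$path_name)
  paths <- tibble(
    path_name = paths$path_name,
    sample = pansn$sample,
    haplotype = pansn$haplotype,
    contig = pansn$contig,
    steps = paths$steps
  )
  paths <- arrange(paths, .data$path_name)
  g <- structure(
    list(segments = segments, links = links, paths = paths,
         reference_sample = reference_sample),
    class = "pangenome"
  )
  if (validate) validate_pangenome(g)
  g
}

#' Validate a pangenome graph
#'
#' Checks segment id uniqueness, non-empty sequences, link endpoints,
#' step references, that every consecutive step pair is backed by a link,
#' and that at least one path belongs to the reference sample.
#'
#' @param g A `pangenome`.
#' @return `g`, invisibly; aborts with a message on the first violation.
#' @export
validate_pangenome <- function(g) {
  segs <- g$segments
  if (anyDuplicated(segs$segment_id)) abort("duplicate segment ids")
  if (nrow(segs) > 0 && any(nchar(segs$sequence) < 1)) abort("zero-length segment sequence")
  if (nrow(segs) > 0 && any(grepl("[^ACGTN]", segs$sequence))) {
    abort("segment sequences must be A/C/G/T/N")
  }
  ids <- segs$segment_id
  bad <- setdiff(c(g$links$from_id, g$links$to_id), ids)
  if (length(bad) > 0) abort(paste0("link endpoint references unknown segment: ", bad[[1]]))
  link_keys <- edge_key(g$links$from_id, g$links$from_orient, g$links$to_id, g$links$to_orient)
  for (i in seq_len(nrow(g$paths))) {
    st <- g$paths$steps[[i]]
    miss <- setdiff(st$segment_id, ids)
    if (length(miss) > 0) {
      abort(paste0("path ", g$paths$path_name[[i]], " references unknown segment ", miss[[1]]))
    }
    ek <- path_edge_keys(st)
    nolink <- setdiff(ek, link_keys)
    if (length(nolink) > 0) {
      abort(paste0("path ", g$paths$path_name[[i]], " uses step pair without a link: ", nolink[[1]]))
    }
  }
  if (!g$reference_sample %in% g$paths$sample) {
    abort(paste0("no path belongs to reference sample '", g$reference_sample, "'"))
  }
  invisible(g)
}

#' @export
print.pangenome <- function(x, ...) {
  cat("<pangenome> ", nrow(x$segments), " segments, ", nrow(x$links), " links, ",
      nrow(x$paths), " paths (reference sample: ", x$reference_sample, ")\n", sep = "")
  invisible(x)
}

segment_lengths <- function(g) {
  setNames(nchar(g$segments$sequence), g$segments$segment_id)
}

segment_sequences <- function(g) {
  setNames(g$segments$sequence, g$segments$segment_id)
}

#' Reconstruct the DNA sequence spelled by a haplotype path
#'
#' Concatenates step sequences in order; steps traversed in `-`
#' orientation contribute their reverse complement. A path may traverse
#' the same segment several times (e.g. across a tandem duplication), in
#' which case the segment's sequence is included once per traversal, so a
#' haplotype carrying a duplicated block B has path length A + 2B + C
#' while the graph holds only A + B + C of sequence.
#'
#' @param g A `pangenome`.
#' @param path_name Name of the path.
#' @return A single DNA string.
#' @export
path_sequence <- function(g, path_name) {
  i <- match(path_name, g$paths$path_name)
  if (is.na(i)) abort(paste0("unknown path: ", path_name))
  st <- g$paths$steps[[i]]
  seqs <- segment_sequences(g)[st$segment_id]
  neg <- st$orient == "-"
  if (any(neg)) seqs[neg] <- reverse_complement(seqs[neg])
  paste(seqs, collapse = "")
}

#' Mean degree of a graph from its node and link counts
#'
#' Uses the convention links / segments (not the graph-theoretic 2E/N):
#' this is the "number of edges attached to a node" ratio used when
#' summarising assembled pangenome graphs.
#'
#' @param n_links,n_segments Counts.
#' @return The ratio `n_links / n_segments` (unrounded).
#' @export
mean_degree <- function(n_links, n_segments) {
  if (n_segments <= 0) abort("mean_degree undefined for an empty graph")
  n_links / n_segments
}

#' Graph and path length statistics
#'
#' Computes node/edge counts, mean degree (links per segment), the total
#' length of sequence in the graph (sum of segment lengths, independent of
#' paths), per-path lengths counting repeated traversals, and per-sample
#' traversed lengths over the union of touched segments. The distinction
#' between path length and traversed length is what separates "A + 2B + C"
#' (a haplotype with a duplicated block) from "A + B + C" (the sequence
#' actually present in the graph).
#'
#' @param g A `pangenome`.
#' @return An object of class `pangenome_stats`: a list with scalar fields
#'   `n_segments`, `n_links`, `mean_degree`, `total_length` and tibbles
#'   `path_lengths` (`path_name`, `sample`, `path_length`) and
#'   `sample_lengths` (`sample`, `traversed_length`).
#' @export
pangenome_stats <- function(g) {
  if (nrow(g$segments) == 0) abort("empty graph")
  lens <- segment_lengths(g)
  path_lengths <- purrr::map2_dfr(g$paths$path_name, g$paths$steps, function(nm, st) {
    tibble(path_name = nm, path_length = sum(lens[st$segment_id]))
  })
  path_lengths <- left_join(path_lengths,
                            select(g$paths, "path_name", "sample"),
                            by = "path_name")[, c("path_name", "sample", "path_length")]
  path_lengths$path_length <- as.numeric(path_lengths$path_length)
  sample_lengths <- g$paths |>
    mutate(seg = purrr::map(.data$steps, ~ unique(.x$segment_id))) |>
    group_by(.data$sample) |>
    summarise(traversed_length = as.numeric(sum(lens[unique(unlist(.data$seg))]))) |>
    ungroup()
  structure(
    list(
      n_segments = nrow(g$segments),
      n_links = nrow(g$links),
      mean_degree = mean_degree(nrow(g$links), nrow(g$segments)),
      total_length = as.numeric(sum(lens)),
      path_lengths = path_lengths,
      sample_lengths = sample_lengths
    ),
    class = "pangenome_stats"
  )
}

#' @export
print.pangenome_stats <- function(x, ...) {
  cat("<pangenome_stats>\n",
      "  segments: ", x$n_segments, "  links: ", x$n_links,
      "  mean degree: ", sprintf("%.1f", x$mean_degree), "\n",
      "  total length: ", x$total_length, " bp over ",
      nrow(x$path_lengths), " paths\n", sep = "")
  invisible(x)
}

#' @rdname pangenome_stats
#' @param x A `pangenome_stats` object.
#' @param ... Unused.
#' @export
glance.pangenome_stats <- function(x, ...) {
  tibble(n_segments = x$n_segments, n_links = x$n_links,
         mean_degree = x$mean_degree, total_length = x$total_length,
         n_paths = nrow(x$path_lengths))
}

#' @rdname pangenome_stats
#' @export
tidy.pangenome_stats <- function(x, ...) {
  left_join(x$path_lengths, x$sample_lengths, by = "sample")
}

#' @rdname pangenome
#' @param x A `pangenome`.
#' @param ... Unused.
#' @export
glance.pangenome <- function(x, ...) {
  glance(pangenome_stats(x))
}

#' @rdname pangenome
#' @export
tidy.pangenome <- function(x, ...) {
  mutate(select(x$paths, -"steps"),
         n_steps = purrr::map_int(x$paths$steps, nrow))
}

# ---- reference coordinates --------------------------------------------------

# Map of segments onto the reference path(s): 1-based position of the first
# base of each segment in path orientation; first traversal wins.
reference_coord_map <- function(g) {
  ref_paths <- filter(g$paths, .data$sample == g$reference_sample)
  if (nrow(ref_paths) == 0) abort("graph has no reference path")
  lens <- segment_lengths(g)
  maps <- purrr::pmap_dfr(
    list(ref_paths$path_name, ref_paths$contig, ref_paths$steps),
    function(nm, contig, st) {
      l <- lens[st$segment_id]
      tibble(
        segment_id = st$segment_id,
        orient = st$orient,
        contig = contig,
        start = c(1L, head(cumsum(l), -1) + 1L),
        end = cumsum(l),
        ref_index = seq_len(nrow(st))
      )
    }
  )
  maps[!duplicated(maps$segment_id), ]
}

#' Project a position inside a segment onto reference coordinates
#'
#' If the segment lies on a reference path, returns the 1-based reference
#' position of that base (the first reference traversal wins, honouring
#' the traversal orientation). Otherwise the graph is walked backwards
#' along any haplotype path through the segment until a reference segment
#' is met, and the position of the last reference base preceding the
#' segment is returned with `on_reference = FALSE` — the convention used
#' to anchor insertion-only nodes, e.g. when translating coordinates of
#' retroviral insertions back to the linear reference.
#'
#' @param g A `pangenome`.
#' @param segment_id Segment identifier.
#' @param offset 0-based offset within the segment.
#' @return Tibble with one row: `contig`, `position` (1-based),
#'   `on_reference`.
#' @export
project_to_reference <- function(g, segment_id, offset = 0L) {
  lens <- segment_lengths(g)
  if (!segment_id %in% names(lens)) abort(paste0("unknown segment: ", segment_id))
  if (offset < 0 || offset >= lens[[segment_id]]) abort("offset outside segment")
  cmap <- reference_coord_map(g)
  hit <- cmap[cmap$segment_id == segment_id, ]
  if (nrow(hit) == 1) {
    pos <- if (hit$orient == "+") hit$start + offset else hit$end - offset
    return(tibble(contig = hit$contig, position = as.integer(pos), on_reference = TRUE))
  }
  # off-reference: scan haplotype paths containing the segment backwards
  on_ref <- setNames(rep(FALSE, length(lens)), names(lens))
  on_ref[cmap$segment_id] <- TRUE
  for (i in seq_len(nrow(g$paths))) {
    st <- g$paths$steps[[i]]
    occ <- which(st$segment_id == segment_id)
    for (j in occ) {
      k <- j - 1
      while (k >= 1 && !on_ref[[st$segment_id[[k]]]]) k <- k - 1
      if (k >= 1) {
        prev <- cmap[cmap$segment_id == st$segment_id[[k]], ]
        # reference position of the path-direction-last base of the anchor
        pos <- if (st$orient[[k]] == "+") {
          if (prev$orient == "+") prev$end else prev$start
        } else {
          if (prev$orient == "+") prev$start else prev$end
        }
        return(tibble(contig = prev$contig, position = as.integer(pos),
                      on_reference = FALSE))
      }
    }
  }
  abort(paste0("segment ", segment_id, " is unreachable from any reference path"))
}

#' Project a 0-based offset on a path's sequence to reference coordinates
#'
#' Locates the step containing the offset and projects that base with
#' [project_to_reference()]. Used to express simulated-read truth origins
#' (recorded on haplotype-path coordinates) in linear reference
#' coordinates, so graph- and linear-derived alignments can be compared on
#' the same scale.
#'
#' @param g A `pangenome`.
#' @param path_name Path name.
#' @param pos0 0-based offset on the path's concatenated sequence.
#' @return Tibble with `contig`, `position`, `on_reference`.
#' @export
project_path_position <- function(g, path_name, pos0) {
  i <- match(path_name, g$paths$path_name)
  if (is.na(i)) abort(paste0("unknown path: ", path_name))
  st <- g$paths$steps[[i]]
  lens <- segment_lengths(g)[st$segment_id]
  ends <- cumsum(lens)
  k <- findInterval(pos0, c(0, ends), rightmost.closed = FALSE)
  if (pos0 < 0 || k > length(lens)) abort("offset outside path")
  within <- pos0 - c(0, ends)[k]
  off <- if (st$orient[[k]] == "+") within else lens[[k]] - 1 - within
  project_to_reference(g, st$segment_id[[k]], off)
}
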