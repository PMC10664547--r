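# GFA v1.0 / v1.1 and GAF text I/O. No installed R package parses these
# graph formats, so the (simple, tab-separated) records are handled here.

gfa_abort <- function(lineno, msg) {
  abort(paste0("GFA parse error at line ", lineno, ": ", msg))
}

#' Read a pangenome graph from GFA
#'
#' Accepts GFA v1.0 (`S`/`L`/`P` lines) and v1.1 (`W` walk lines). W-line
#' sample, haplotype and sequence-id fields are combined into PanSN path
#' names (`sample#haplotype#contig`); P-line names are kept verbatim.
#'
#' @param path File path, or a character vector of GFA lines.
#' @param reference_sample Sample designated as reference. Defaults to the
#'   sample of the first path in the file.
#' @param validate Validate the resulting graph (default `TRUE`).
#' @return A [pangenome].
#' @export
read_gfa <- function(path, reference_sample = NULL, validate = TRUE) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  seg_id <- character(); seg_seq <- character()
  lk <- list(); pnames <- character(); psteps <- list()
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (line == "" || startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    tag <- f[[1]]
    if (tag == "H") next
    if (tag == "S") {
      if (length(f) < 3 || f[[2]] == "" || f[[3]] == "") gfa_abort(i, "S line needs id and sequence")
      seg_id <- c(seg_id, f[[2]]); seg_seq <- c(seg_seq, toupper(f[[3]]))
    } else if (tag == "L") {
      if (length(f) < 5) gfa_abort(i, "L line needs from, orient, to, orient")
      if (!f[[3]] %in% c("+", "-") || !f[[5]] %in% c("+", "-")) gfa_abort(i, "bad orientation")
      lk[[length(lk) + 1]] <- c(f[[2]], f[[3]], f[[4]], f[[5]])
    } else if (tag == "P") {
      if (length(f) < 3) gfa_abort(i, "P line needs name and steps")
      toks <- strsplit(f[[3]], ",", fixed = TRUE)[[1]]
      ors <- substr(toks, nchar(toks), nchar(toks))
      if (!all(ors %in% c("+", "-"))) gfa_abort(i, "P step without +/- orientation")
      pnames <- c(pnames, f[[2]])
      psteps[[length(psteps) + 1]] <- steps_tbl(substr(toks, 1, nchar(toks) - 1), ors)
    } else if (tag == "W") {
      if (length(f) < 7) gfa_abort(i, "W line needs 7 fields")
      st <- parse_walk(f[[7]])
      if (nrow(st) == 0) gfa_abort(i, "empty walk")
      pnames <- c(pnames, pansn_name(f[[2]], f[[3]], f[[4]]))
      psteps[[length(psteps) + 1]] <- st
    } else {
      gfa_abort(i, paste0("unknown record type '", tag, "'"))
    }
  }
  segments <- tibble(segment_id = seg_id, sequence = seg_seq)
  links <- if (length(lk) > 0) {
    m <- do.call(rbind, lk)
    tibble(from_id = m[, 1], from_orient = m[, 2], to_id = m[, 3], to_orient = m[, 4])
  } else {
    tibble(from_id = character(), from_orient = character(),
           to_id = character(), to_orient = character())
  }
  paths <- tibble(path_name = pnames, steps = psteps)
  unknown <- setdiff(unlist(lapply(psteps, `[[`, "segment_id")), seg_id)
  if (length(unknown) > 0) {
    abort(paste0("path step references unknown segment: ", unknown[[1]]))
  }
  if (is.null(reference_sample)) {
    if (nrow(paths) == 0) abort("GFA contains no paths; supply reference_sample explicitly")
    reference_sample <- parse_pansn(pnames[[1]])$sample
  }
  pangenome(segments, links, paths, reference_sample, validate = validate)
}

#' Write a pangenome graph as GFA
#'
#' Output ordering is deterministic (segments by id, links lexicographic,
#' paths by name) so writing the same graph twice gives identical bytes.
#' Version "1.0" writes P lines with PanSN path names and "0M" overlaps;
#' version "1.1" writes one W line per path with the PanSN fields split
#' back out.
#'
#' @param g A [pangenome].
#' @param path Output file path, or `NULL` to return the lines.
#' @param version `"1.0"` or `"1.1"`.
#' @return The GFA lines, invisibly when written to a file.
#' @export
write_gfa <- function(g, path = NULL, version = c("1.0", "1.1")) {
  version <- match.arg(version)
  lens <- segment_lengths(g)
  out <- paste0("H\tVN:Z:", version)
  segs <- arrange(g$segments, .data$segment_id)
  out <- c(out, sprintf("S\t%s\t%s", segs$segment_id, segs$sequence))
  lk <- arrange(g$links, .data$from_id, .data$from_orient, .data$to_id, .data$to_orient)
  out <- c(out, sprintf("L\t%s\t%s\t%s\t%s\t0M",
                        lk$from_id, lk$from_orient, lk$to_id, lk$to_orient))
  pp <- arrange(g$paths, .data$path_name)
  for (i in seq_len(nrow(pp))) {
    st <- pp$steps[[i]]
    if (version == "1.0") {
      out <- c(out, sprintf("P\t%s\t%s\t*", pp$path_name[[i]],
                            paste0(st$segment_id, st$orient, collapse = ",")))
    } else {
      walk <- paste0(ifelse(st$orient == "+", ">", "<"), st$segment_id, collapse = "")
      plen <- sum(lens[st$segment_id])
      out <- c(out, sprintf("W\t%s\t%s\t%s\t0\t%d\t%s",
                            pp$sample[[i]], pp$haplotype[[i]], pp$contig[[i]],
                            plen, walk))
    }
  }
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

#' Parse an oriented walk string
#'
#' Walk strings of the form `">s1<s2>s3"` appear in GFA W lines and in the
#' path column of GAF records: `>` means forward traversal, `<` reverse.
#'
#' @param walk A single walk string.
#' @return A step table (`segment_id`, `orient`).
#' @export
parse_walk <- function(walk) {
  if (is.na(walk) || walk == "" || !grepl("^[><]", walk)) {
    return(steps_tbl(character()))
  }
  toks <- regmatches(walk, gregexpr("[><][^><]+", walk))[[1]]
  steps_tbl(substr(toks, 2, nchar(toks)),
            ifelse(substr(toks, 1, 1) == ">", "+", "-"))
}

format_walk <- function(steps) {
  paste0(ifelse(steps$orient == "+", ">", "<"), steps$segment_id, collapse = "")
}

#' Read graph alignments from GAF
#'
#' Parses the 12 core tab-separated GAF columns. The path column must be
#' an oriented walk string (`">id<id..."`); offsets `path_start` and
#' `path_end` are 0-based with the end exclusive, so an alignment covers
#' bases `[path_start, path_end)` of the walk's concatenated sequence.
#'
#' @param path File path, or a character vector of GAF lines.
#' @return Tibble with columns `read_id`, `read_length`, `read_start`,
#'   `read_end`, `strand`, `walk` (list column of step tables),
#'   `path_length`, `path_start`, `path_end`, `n_match`, `aln_length`,
#'   `mapq`.
#' @export
read_gaf <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  lines <- lines[lines != ""]
  if (length(lines) == 0) {
    return(tibble(read_id = character(), read_length = integer(),
                  read_start = integer(), read_end = integer(),
                  strand = character(), walk = list(),
                  path_length = integer(), path_start = integer(),
                  path_end = integer(), n_match = integer(),
                  aln_length = integer(), mapq = integer()))
  }
  m <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  if (ncol(m) < 12) abort("GAF records need at least 12 columns")
  tibble(
    read_id = m[, 1],
    read_length = as.integer(m[, 2]),
    read_start = as.integer(m[, 3]),
    read_end = as.integer(m[, 4]),
    strand = m[, 5],
    walk = purrr::map(m[, 6], parse_walk),
    path_length = as.integer(m[, 7]),
    path_start = as.integer(m[, 8]),
    path_end = as.integer(m[, 9]),
    n_match = as.integer(m[, 10]),
    aln_length = as.integer(m[, 11]),
    mapq = as.integer(m[, 12])
  )
}

#' Write graph alignments as GAF
#'
#' @param gaf Tibble in the layout returned by [read_gaf()].
#' @param path Output file, or `NULL` to return the lines.
#' @return The GAF lines, invisibly when written to a file.
#' @export
write_gaf <- function(gaf, path = NULL) {
  out <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d",
                 gaf$read_id, gaf$read_length, gaf$read_start, gaf$read_end,
                 gaf$strand, purrr::map_chr(gaf$walk, format_walk),
                 gaf$path_length, gaf$path_start, gaf$path_end,
                 gaf$n_match, gaf$aln_length, gaf$mapq)
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}
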