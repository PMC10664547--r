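# Short-read simulation from haplotype paths with an error model, truth
# origins, and mapping-accuracy evaluation against those origins.

#' Sequencing error model
#'
#' Defaults follow published short-read error estimates used for graph
#' read simulation: substitution rate 0.24% per base and indel event rate
#' 0.029% per base, with geometric indel lengths.
#'
#' @param sub_rate Per-base substitution probability.
#' @param indel_rate Per-base indel-event probability.
#' @param indel_geom_p Geometric parameter: event length = 1 + Geom(p).
#' @return An `error_model` list.
#' @export
error_model <- function(sub_rate = 0.0024, indel_rate = 0.00029,
                        indel_geom_p = 0.5) {
  if (any(c(sub_rate, indel_rate) < 0) || any(c(sub_rate, indel_rate) >= 0.5)) {
    abort("error rates must lie in [0, 0.5)")
  }
  structure(list(sub_rate = sub_rate, indel_rate = indel_rate,
                 indel_geom_p = indel_geom_p), class = "error_model")
}

#' Simulate paired-end reads from haplotype paths
#'
#' Fragments are sampled uniformly over valid start positions of the
#' selected paths (paths weighted by length); mate 1 is the forward
#' prefix and mate 2 the reverse-complemented suffix of the fragment.
#' Substitutions are applied independently per base (uniform among the
#' three alternatives); indel events are drawn per base with geometric
#' lengths, insertions and deletions equiprobable. The truth table
#' records the pre-error origin of each mate; the event log records every
#' injected error. Fragments are wholly contained in their path (no
#' clipping), so truth origins are unambiguous.
#'
#' @param g A [pangenome].
#' @param n_pairs Number of read pairs.
#' @param path_names Paths to sample from (default: all non-reference
#'   haplotype paths; falls back to all paths).
#' @param read_length Read length in bp (default 150).
#' @param fragment_mean,fragment_sd Normal fragment-length parameters
#'   (default 400 +- 50); fragments are clamped to at least `read_length`
#'   and at most the path length.
#' @param model An [error_model()].
#' @param seed Integer seed.
#' @return A list with `reads` (tibble `read_id`, `mate`, `sequence`,
#'   `path_name`, `start0` (0-based on the path), `strand`,
#'   `fragment_length`), `events` (tibble `read_id`, `mate`, `type`,
#'   `pos`, `length`), and `truth` (per-mate tibble `read_id` with `/1`
#'   `/2` suffixes, `path_name`, `start0`, `strand`).
#' @export
simulate_reads <- function(g, n_pairs, path_names = NULL, read_length = 150L,
                           fragment_mean = 400, fragment_sd = 50,
                           model = error_model(), seed = 1L) {
  set.seed(seed)
  if (is.null(path_names)) {
    path_names <- filter(g$paths, .data$sample != g$reference_sample)$path_name
    if (length(path_names) == 0) path_names <- g$paths$path_name
  }
  plen <- purrr::map_int(path_names, function(p) {
    i <- match(p, g$paths$path_name)
    sum(segment_lengths(g)[g$paths$steps[[i]]$segment_id])
  })
  if (any(plen < read_length)) abort("path shorter than the read length")
  pseq <- setNames(purrr::map_chr(path_names, ~ path_sequence(g, .x)), path_names)
  pick <- sample.int(length(path_names), n_pairs, replace = TRUE,
                     prob = plen / sum(plen))
  flen <- pmin(pmax(round(rnorm(n_pairs, fragment_mean, fragment_sd)),
                    read_length), plen[pick])
  fstart0 <- floor(runif(n_pairs) * (plen[pick] - flen + 1))
  read_id <- sprintf("r%06d", seq_len(n_pairs))
  m1 <- substr(pseq[pick], fstart0 + 1, fstart0 + read_length)
  m2 <- reverse_complement(substr(pseq[pick], fstart0 + flen - read_length + 1,
                                  fstart0 + flen))
  reads <- tibble(
    read_id = rep(read_id, 2),
    mate = rep(c(1L, 2L), each = n_pairs),
    sequence = c(m1, m2),
    path_name = rep(path_names[pick], 2),
    start0 = as.integer(c(fstart0, fstart0 + flen - read_length)),
    strand = rep(c("+", "-"), each = n_pairs),
    fragment_length = rep(as.integer(flen), 2)
  )
  injected <- inject_errors(reads$sequence, model)
  reads$sequence <- injected$sequences
  events <- injected$events
  events$read_id <- reads$read_id[events$seq_index]
  events$mate <- reads$mate[events$seq_index]
  events <- select(events, "read_id", "mate", "type", "pos", "length")
  truth <- tibble(
    read_id = paste0(reads$read_id, "/", reads$mate),
    path_name = reads$path_name,
    start0 = reads$start0,
    strand = reads$strand
  )
  list(reads = reads, events = events, truth = truth,
       model = model, read_length = as.integer(read_length))
}

# vectorised error injection over equal-length sequences
inject_errors <- function(sequences, model) {
  n <- length(sequences)
  if (n == 0) {
    return(list(sequences = sequences,
                events = tibble(seq_index = integer(), type = character(),
                                pos = integer(), length = integer())))
  }
  rl <- nchar(sequences[[1]])
  stopifnot(all(nchar(sequences) == rl))
  chars <- matrix(unlist(strsplit(sequences, "", fixed = TRUE)), nrow = rl)
  total <- rl * n
  bases <- c("A", "C", "G", "T")
  # substitutions: uniform among the three alternatives
  sub_idx <- which(runif(total) < model$sub_rate)
  if (length(sub_idx) > 0) {
    old <- chars[sub_idx]
    shift <- sample.int(3, length(sub_idx), replace = TRUE)
    chars[sub_idx] <- bases[(match(old, bases) - 1 + shift) %% 4 + 1]
  }
  sequences <- apply(chars, 2, paste, collapse = "")
  sub_events <- tibble(
    seq_index = as.integer((sub_idx - 1) %/% rl + 1),
    type = "sub",
    pos = as.integer((sub_idx - 1) %% rl + 1),
    length = 1L
  )
  # indel events
  ind_idx <- which(runif(total) < model$indel_rate)
  ind_events <- tibble(
    seq_index = as.integer((ind_idx - 1) %/% rl + 1),
    type = sample(c("ins", "del"), length(ind_idx), replace = TRUE),
    pos = as.integer((ind_idx - 1) %% rl + 1),
    length = 1L + rgeom(length(ind_idx), model$indel_geom_p)
  )
  if (nrow(ind_events) > 0) {
    by_seq <- split(seq_len(nrow(ind_events)), ind_events$seq_index)
    for (si in names(by_seq)) {
      i <- as.integer(si)
      s <- sequences[[i]]
      ev <- ind_events[by_seq[[si]], ]
      ev <- ev[order(-ev$pos), ]
      for (j in seq_len(nrow(ev))) {
        p <- ev$pos[[j]]; len <- ev$length[[j]]
        if (ev$type[[j]] == "ins") {
          s <- paste0(substr(s, 1, p), random_dna(len),
                      substr(s, p + 1, nchar(s)))
        } else {
          s <- paste0(substr(s, 1, p - 1), substr(s, p + len, nchar(s)))
        }
      }
      sequences[[i]] <- s
    }
  }
  list(sequences = sequences, events = bind_rows(sub_events, ind_events))
}

#' Write simulated reads as a FASTQ pair
#'
#' Base qualities are a constant Q30 placeholder.
#'
#' @param sim Output of [simulate_reads()].
#' @param r1_path,r2_path Output paths for mates 1 and 2.
#' @return Invisibly, `c(r1_path, r2_path)`.
#' @export
write_fastq_pair <- function(sim, r1_path, r2_path) {
  for (m in 1:2) {
    r <- filter(sim$reads, .data$mate == m)
    dna <- Biostrings::DNAStringSet(setNames(r$sequence,
                                             paste0(r$read_id, "/", m)))
    qual <- Biostrings::BStringSet(strrep("?", nchar(r$sequence)))
    x <- Biostrings::QualityScaledDNAStringSet(
      dna, Biostrings::PhredQuality(qual))
    Biostrings::writeQualityScaledXStringSet(x, if (m == 1) r1_path else r2_path)
  }
  invisible(c(r1_path, r2_path))
}

#' Convert simulated-read truth origins to perfect graph alignments
#'
#' Produces, for each simulated mate, the GAF record a perfect graph
#' aligner would emit: the sub-walk of the source path overlapped by the
#' read, with path offsets relative to that sub-walk and mapq 60. Useful
#' for exercising edge-support genotyping without an aligner.
#'
#' @param sim Output of [simulate_reads()].
#' @param g The [pangenome] reads were simulated from.
#' @return A GAF tibble as from [read_gaf()].
#' @export
truth_gaf <- function(sim, g) {
  lens <- segment_lengths(g)
  steps_by_path <- setNames(g$paths$steps, g$paths$path_name)
  rl <- nchar(sim$reads$sequence)
  purrr::map_dfr(seq_len(nrow(sim$reads)), function(i) {
    r <- sim$reads[i, ]
    st <- steps_by_path[[r$path_name]]
    ends <- cumsum(lens[st$segment_id])
    starts <- c(0, head(ends, -1))
    len_i <- r$start0 + sim$read_length  # pre-error span on the path
    k0 <- findInterval(r$start0, starts, rightmost.closed = FALSE)
    k1 <- findInterval(len_i - 1, starts)
    sub <- st[k0:k1, ]
    tibble(
      read_id = paste0(r$read_id, "/", r$mate),
      read_length = nchar(r$sequence),
      read_start = 0L, read_end = nchar(r$sequence),
      strand = r$strand,
      walk = list(sub),
      path_length = as.integer(sum(lens[sub$segment_id])),
      path_start = as.integer(r$start0 - starts[[k0]]),
      path_end = as.integer(len_i - starts[[k0]]),
      n_match = sim$read_length, aln_length = sim$read_length,
      mapq = 60L
    )
  })
}

#' Score alignments against simulated-read truth origins
#'
#' A read is correct iff it is mapped to the same reference name as its
#' truth origin and its start is within `tolerance_bp` of the truth
#' start. The accuracy curve reports, for every mapq threshold 0..60, the
#' fraction of ALL truth reads that are mapped, pass the threshold and
#' are correct; unmapped and missing reads count as incorrect at every
#' threshold, so the curve is monotone non-increasing.
#'
#' @param truth Tibble `read_id`, `refname`, `start0` (use
#'   [truth_to_reference()] to express path-space truth in reference
#'   coordinates).
#' @param alignments Tibble `read_id`, `refname`, `start0`, `mapq`,
#'   `mapped`.
#' @param tolerance_bp Maximum start deviation still counted correct
#'   (default 100).
#' @return An `accuracy_curve` tibble (`mapq_threshold`, `accuracy`) with
#'   attributes `n_reads`, `n_missing`, `n_correct`.
#' @export
evaluate_alignments <- function(truth, alignments, tolerance_bp = 100) {
  stopifnot(!anyDuplicated(truth$read_id))
  aln <- alignments[!duplicated(alignments$read_id), ]
  j <- left_join(truth, aln, by = "read_id", suffix = c("_truth", "_aln"))
  missing <- is.na(j$mapped)
  mapped <- !missing & j$mapped
  correct <- mapped & j$refname_aln == j$refname_truth &
    abs(j$start0_aln - j$start0_truth) <= tolerance_bp
  correct[is.na(correct)] <- FALSE
  mapq <- ifelse(mapped, j$mapq, -1L)
  thresholds <- 0:60
  acc <- vapply(thresholds,
                function(t) sum(correct & mapq >= t) / nrow(truth),
                numeric(1))
  structure(tibble(mapq_threshold = thresholds, accuracy = acc),
            n_reads = nrow(truth), n_missing = sum(missing),
            n_correct = sum(correct),
            class = c("accuracy_curve", class(tibble())))
}

#' Express path-space truth origins in reference coordinates
#'
#' Projects each truth origin (path name + 0-based offset) to the linear
#' reference with [project_path_position()] semantics, vectorised.
#'
#' @param truth Truth tibble from [simulate_reads()].
#' @param g The [pangenome].
#' @return Tibble `read_id`, `refname`, `start0`, `on_reference`.
#' @export
truth_to_reference <- function(truth, g) {
  lens <- segment_lengths(g)
  cmap <- reference_coord_map(g)
  anchor_cache <- new.env(parent = emptyenv())
  out <- vector("list", length(unique(truth$path_name)))
  names(out) <- unique(truth$path_name)
  res_contig <- character(nrow(truth))
  res_pos <- integer(nrow(truth))
  res_onref <- logical(nrow(truth))
  for (pn in unique(truth$path_name)) {
    sel <- which(truth$path_name == pn)
    st <- g$paths$steps[[match(pn, g$paths$path_name)]]
    l <- lens[st$segment_id]
    ends <- cumsum(l)
    starts <- c(0, head(ends, -1))
    k <- findInterval(truth$start0[sel], starts)
    within <- truth$start0[sel] - starts[k]
    off <- ifelse(st$orient[k] == "+", within, l[k] - 1 - within)
    seg <- st$segment_id[k]
    hit <- match(seg, cmap$segment_id)
    onref <- !is.na(hit)
    pos <- integer(length(sel))
    ctg <- character(length(sel))
    if (any(onref)) {
      h <- hit[onref]
      pos[onref] <- ifelse(cmap$orient[h] == "+",
                           cmap$start[h] + off[onref],
                           cmap$end[h] - off[onref])
      ctg[onref] <- cmap$contig[h]
    }
    for (i in which(!onref)) {
      sid <- seg[[i]]
      if (is.null(anchor_cache[[sid]])) {
        anchor_cache[[sid]] <- project_to_reference(g, sid, 0L)
      }
      pr <- anchor_cache[[sid]]
      pos[[i]] <- pr$position
      ctg[[i]] <- pr$contig
    }
    res_contig[sel] <- ctg
    res_pos[sel] <- pos
    res_onref[sel] <- onref
  }
  tibble(read_id = truth$read_id, refname = res_contig,
         start0 = res_pos - 1L, on_reference = res_onref)
}

#' Measure empirical error rates of simulated reads
#'
#' The substitution rate is measured from scratch by comparing each
#' indel-free read (per the simulator's event log) against the
#' corresponding source-path substring; the indel event rate comes from
#' the event log itself. Both are per simulated base.
#'
#' @param sim Output of [simulate_reads()].
#' @param g The [pangenome].
#' @return One-row tibble: `sub_rate`, `indel_rate`, `n_bases`,
#'   `n_mismatch`, `n_indel_events`, `n_bases_sub_denominator`.
#' @export
measure_error_rates <- function(sim, g) {
  pseq <- setNames(purrr::map_chr(unique(sim$reads$path_name),
                                  ~ path_sequence(g, .x)),
                   unique(sim$reads$path_name))
  rl <- sim$read_length
  has_indel <- paste(sim$events$read_id[sim$events$type != "sub"],
                     sim$events$mate[sim$events$type != "sub"])
  key <- paste(sim$reads$read_id, sim$reads$mate)
  clean <- !(key %in% has_indel)
  r <- sim$reads[clean, ]
  src <- substr(pseq[r$path_name], r$start0 + 1, r$start0 + rl)
  src[r$strand == "-"] <- reverse_complement(src[r$strand == "-"])
  mism <- mapply(function(a, b) {
    sum(utf8ToInt(a) != utf8ToInt(b))
  }, r$sequence, src, USE.NAMES = FALSE)
  n_total <- as.numeric(nrow(sim$reads)) * rl
  n_clean <- as.numeric(nrow(r)) * rl
  n_indel <- sum(sim$events$type != "sub")
  tibble(sub_rate = sum(mism) / n_clean,
         indel_rate = n_indel / n_total,
         n_bases = n_total, n_mismatch = sum(mism),
         n_indel_events = n_indel, n_bases_sub_denominator = n_clean)
}
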