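# Reference-bias quantification from linear alignments: pileup with
# mapq/flag/depth filters, putative-heterozygous-site detection,
# alt-allele-fraction statistics, and the paired bias-reduction measure.

#' Write alignment records as SAM
#'
#' Minimal SAM v1.6 writer for fabricated/simulated alignments. Records
#' need `qname`, `flag`, `rname`, `pos` (1-based), `mapq`, `cigar`,
#' `seq`; `qual` defaults to constant Q30.
#'
#' @param records Tibble of alignment records.
#' @param contigs Named integer vector of contig lengths for `@SQ` lines.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, contigs, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), as.integer(contigs)))
  qual <- if ("qual" %in% names(records)) records$qual else strrep("?", nchar(records$seq))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  records$qname, as.integer(records$flag), records$rname,
                  as.integer(records$pos), as.integer(records$mapq),
                  records$cigar, records$seq, qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

# SAM/BAM path -> sorted, indexed BAM path
as_sorted_bam <- function(path) {
  if (grepl("\\.bam$", path)) return(path)
  dest <- tempfile(fileext = "")
  Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = TRUE)
}

#' Read linear alignments for accuracy evaluation
#'
#' Reads a SAM or BAM file (secondary and supplementary records are
#' dropped) into the layout [evaluate_alignments()] expects. Mate
#' suffixes `/1` and `/2` are appended to paired read names from the
#' flag bits so ids match simulated-read truth tables.
#'
#' @param path SAM or BAM file.
#' @return Tibble `read_id`, `refname`, `start0`, `mapq`, `mapped`.
#' @export
read_sam_alignments <- function(path) {
  bam <- as_sorted_bam(path)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq"),
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  mate <- dplyr::case_when(
    bitwAnd(x$flag, 0x40) > 0 ~ "/1",
    bitwAnd(x$flag, 0x80) > 0 ~ "/2",
    .default = ""
  )
  tibble(read_id = paste0(x$qname, mate),
         refname = as.character(x$rname),
         start0 = x$pos - 1L,
         mapq = as.integer(x$mapq),
         mapped = bitwAnd(x$flag, 0x4) == 0)
}

#' Pileup with mapping-quality, flag and depth filters
#'
#' Builds per-position base counts from aligned (match/mismatch) bases
#' only: low-mapq reads are removed, secondary/supplementary records are
#' excluded, read insertions are skipped, deletions contribute no base,
#' and depth is capped per position (cap applied in read order by the
#' pileup engine, before any downstream filtering). Base qualities are
#' ignored.
#'
#' @param alignments SAM or BAM file path.
#' @param reference Reference FASTA path, or a named character vector of
#'   contig sequences.
#' @param min_mapq Minimum mapping quality (default 10).
#' @param exclude_secondary_supplementary Drop flag-0x100/0x800 records
#'   (default `TRUE`).
#' @param depth_cap Maximum pileup depth per position (default 100).
#' @return Tibble `contig`, `pos`, `ref_base`, `A`, `C`, `G`, `T`,
#'   `depth`.
#' @export
pileup_sites <- function(alignments, reference, min_mapq = 10L,
                         exclude_secondary_supplementary = TRUE,
                         depth_cap = 100L) {
  bam <- as_sorted_bam(alignments)
  ref <- if (is.character(reference) && length(reference) == 1 &&
             file.exists(reference)) {
    s <- Biostrings::readDNAStringSet(reference)
    names(s) <- sub("\\s.*$", "", names(s))
    setNames(as.character(s), names(s))
  } else {
    reference
  }
  flag <- if (exclude_secondary_supplementary) {
    Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                           isSecondaryAlignment = FALSE,
                           isSupplementaryAlignment = FALSE)
  } else {
    Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  }
  x <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("rname", "pos", "mapq", "cigar", "seq"), flag = flag))[[1]]
  keep <- !is.na(x$pos) & !is.na(x$mapq) & x$mapq >= min_mapq
  rname <- as.character(x$rname)[keep]
  pos <- x$pos[keep]
  mq <- x$mapq[keep]
  cigar <- x$cigar[keep]
  seqs <- as.character(x$seq)[keep]
  missing_ctg <- setdiff(unique(rname), names(ref))
  if (length(missing_ctg) > 0) {
    abort(paste0("contig absent from reference: ", missing_ctg[[1]]))
  }
  bases <- c("A", "C", "G", "T")
  out <- list()
  for (ctg in unique(rname)) {
    L <- nchar(ref[[ctg]])
    sel <- which(rname == ctg)
    cov <- integer(L)
    pos_chunks <- list(); base_chunks <- list()
    # reads are in coordinate order (sorted BAM); the depth cap keeps the
    # first `depth_cap` reads overlapping a position and drops later ones
    for (i in sel) {
      runs <- cigar_aligned_runs(cigar[[i]], pos[[i]])
      nruns <- length(runs$ref_start)
      if (nruns == 0) next
      span <- seq2(max(1L, min(runs$ref_start)), min(L, max(runs$ref_end)))
      if (length(span) == 0 || max(cov[span]) >= depth_cap) next
      cov[span] <- cov[span] + 1L
      for (r in seq_len(nruns)) {
        rs <- runs$ref_start[[r]]; re <- runs$ref_end[[r]]
        if (re < 1 || rs > L) next
        clip_lo <- max(1L, rs); clip_hi <- min(L, re)
        qoff <- runs$query_start[[r]] + (clip_lo - rs)
        pos_chunks[[length(pos_chunks) + 1]] <- clip_lo:clip_hi
        base_chunks[[length(base_chunks) + 1]] <-
          substr(seqs[[i]], qoff, qoff + (clip_hi - clip_lo))
      }
    }
    if (length(pos_chunks) == 0) next
    P <- unlist(pos_chunks)
    B <- unlist(strsplit(paste(unlist(base_chunks), collapse = ""), "",
                         fixed = TRUE))
    counts <- vapply(bases, function(b) tabulate(P[B == b], nbins = L),
                     integer(L))
    covered <- which(rowSums(counts) > 0)
    if (length(covered) == 0) next
    out[[ctg]] <- tibble(
      contig = ctg, pos = covered,
      ref_base = substring(ref[[ctg]], covered, covered),
      A = counts[covered, "A"], C = counts[covered, "C"],
      G = counts[covered, "G"], T = counts[covered, "T"])
  }
  if (length(out) == 0) {
    return(tibble(contig = character(), pos = integer(), ref_base = character(),
                  A = integer(), C = integer(), G = integer(), T = integer(),
                  depth = integer()))
  }
  bind_rows(out) |>
    mutate(depth = .data$A + .data$C + .data$G + .data$T) |>
    arrange(.data$contig, .data$pos)
}

# aligned (match/mismatch) runs of a CIGAR: reference and query intervals.
# I and S consume query only; D and N consume reference only; H/P nothing.
cigar_aligned_runs <- function(cigar, pos) {
  if (grepl("^\\d+M$", cigar)) {  # fast path for plain matches
    n <- as.integer(sub("M$", "", cigar))
    return(list(ref_start = pos, ref_end = pos + n - 1L, query_start = 1L))
  }
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^\\d+", "", ops)
  ref_cur <- pos; q_cur <- 1L
  rs <- integer(); re <- integer(); qs <- integer()
  for (k in seq_along(op)) {
    if (op[[k]] %in% c("M", "=", "X")) {
      rs <- c(rs, ref_cur); re <- c(re, ref_cur + n[[k]] - 1L); qs <- c(qs, q_cur)
      ref_cur <- ref_cur + n[[k]]; q_cur <- q_cur + n[[k]]
    } else if (op[[k]] %in% c("I", "S")) {
      q_cur <- q_cur + n[[k]]
    } else if (op[[k]] %in% c("D", "N")) {
      ref_cur <- ref_cur + n[[k]]
    }
  }
  list(ref_start = rs, ref_end = re, query_start = qs)
}

#' Detect putative heterozygous sites in a pileup
#'
#' A site is kept iff its (capped) depth is at least `min_depth` and the
#' second-most-common base — the minor allele, whether or not it is the
#' reference base — accounts for at least `min_minor_frac` of the depth.
#' The alternate allele is the most frequent non-reference base (ties
#' broken in A<C<G<T order); the alt fraction is alt / (ref + alt).
#'
#' @param pileup Output of [pileup_sites()].
#' @param min_depth Minimum depth (default 10).
#' @param min_minor_frac Minimum minor-allele fraction (default 0.25).
#' @return The qualifying rows with `alt_base`, `alt_count`, `ref_count`,
#'   `alt_fraction` added.
#' @export
find_het_sites <- function(pileup, min_depth = 10L, min_minor_frac = 0.25) {
  if (nrow(pileup) == 0) {
    return(mutate(pileup, alt_base = character(), alt_count = integer(),
                  ref_count = integer(), alt_fraction = numeric()))
  }
  m <- as.matrix(pileup[, c("A", "C", "G", "T")])
  top2 <- apply(m, 1, function(x) sort(x, decreasing = TRUE)[1:2])
  minor <- top2[2, ]
  keep <- pileup$depth >= min_depth & minor / pileup$depth >= min_minor_frac
  bases <- c("A", "C", "G", "T")
  ref_ix <- match(pileup$ref_base, bases)
  alt_m <- m
  alt_m[cbind(seq_len(nrow(m)), ref_ix)] <- -1L
  alt_ix <- max.col(alt_m, ties.method = "first")
  out <- pileup[keep, ]
  out$alt_base <- bases[alt_ix[keep]]
  out$alt_count <- m[cbind(which(keep), alt_ix[keep])]
  out$ref_count <- m[cbind(which(keep), ref_ix[keep])]
  out$alt_fraction <- out$alt_count / (out$ref_count + out$alt_count)
  out
}

#' Alt-allele-fraction bias statistics over heterozygous sites
#'
#' Reference bias is the difference between the mean fraction of reads
#' carrying the alternate allele and the expected fraction of 0.5 at a
#' heterozygous site; the magnitude is reported as `bias` with the sign
#' kept separately in `direction` (-1 when the mean is below 0.5, i.e.
#' reads favour the reference allele).
#'
#' @param het_sites Output of [find_het_sites()], or any tibble with an
#'   `alt_fraction` column.
#' @return A `bias_report`: list with `n_sites`, `mean_alt_fraction`,
#'   `bias`, `direction`.
#' @export
alt_fraction_stats <- function(het_sites) {
  if (nrow(het_sites) == 0) abort("no heterozygous sites")
  m <- mean(het_sites$alt_fraction)
  structure(list(n_sites = nrow(het_sites), mean_alt_fraction = m,
                 bias = abs(m - 0.5), direction = sign(m - 0.5)),
            class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  cat(sprintf("<bias_report> %d sites, mean alt fraction %.4f, bias %.4f\n",
              x$n_sites, x$mean_alt_fraction, x$bias))
  invisible(x)
}

#' @rdname alt_fraction_stats
#' @param x A `bias_report`.
#' @param ... Unused.
#' @export
glance.bias_report <- function(x, ...) {
  tibble(n_sites = x$n_sites, mean_alt_fraction = x$mean_alt_fraction,
         bias = x$bias, direction = x$direction)
}

#' Percent bias reduction between two alignment methods
#'
#' @param bias_linear Bias magnitude under linear-reference alignment
#'   (must be > 0).
#' @param bias_graph Bias magnitude under graph alignment.
#' @return `100 * (bias_linear - bias_graph) / bias_linear`.
#' @export
bias_reduction <- function(bias_linear, bias_graph) {
  if (inherits(bias_linear, "bias_report")) bias_linear <- bias_linear$bias
  if (inherits(bias_graph, "bias_report")) bias_graph <- bias_graph$bias
  if (bias_linear <= 0) abort("bias reduction undefined when the linear bias is 0")
  100 * (bias_linear - bias_graph) / bias_linear
}

#' Fabricate alignments over heterozygous sites with a set alt probability
#'
#' Simulates, for each requested site, `depth` single-end reads spanning
#' the site; each read carries the alternate base with probability
#' `alt_prob` and the reference base otherwise. Used to emulate the
#' allele sampling behaviour of an aligner with a known degree of
#' reference bias (alt_prob 0.5 = unbiased).
#'
#' @param ref_seq Reference contig sequence.
#' @param positions 1-based site positions (kept at least `read_length`
#'   apart by the caller for single-site reads).
#' @param depth Reads per site.
#' @param alt_prob Probability a read carries the alternate allele.
#' @param contig Contig name.
#' @param read_length Read length (default 50).
#' @param mapq Mapping quality for all reads (default 60).
#' @param seed Integer seed.
#' @return List with `records` (SAM record tibble for [write_sam()]),
#'   `sites` (tibble `pos`, `ref_base`, `alt_base`, `n_alt`) and
#'   `contigs` (for the SAM header).
#' @export
simulate_het_alignments <- function(ref_seq, positions, depth, alt_prob,
                                    contig = "chr1", read_length = 50L,
                                    mapq = 60L, seed = 1L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  recs <- list(); sites <- list()
  for (s in seq_along(positions)) {
    p <- positions[[s]]
    start <- max(1L, p - read_length %/% 2L)
    tmpl <- substr(ref_seq, start, start + read_length - 1L)
    off <- p - start + 1L
    ref_b <- substr(ref_seq, p, p)
    alt_b <- sample(setdiff(bases, ref_b), 1L)
    is_alt <- runif(depth) < alt_prob
    seqs <- ifelse(is_alt,
                   paste0(substr(tmpl, 1, off - 1), alt_b,
                          substr(tmpl, off + 1, read_length)),
                   tmpl)
    recs[[s]] <- tibble(
      qname = sprintf("site%05d_rd%03d", s, seq_len(depth)),
      flag = 0L, rname = contig, pos = start, mapq = as.integer(mapq),
      cigar = paste0(read_length, "M"), seq = seqs)
    sites[[s]] <- tibble(pos = p, ref_base = ref_b, alt_base = alt_b,
                         n_alt = sum(is_alt))
  }
  list(records = bind_rows(recs), sites = bind_rows(sites),
       contigs = setNames(nchar(ref_seq), contig))
}
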