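# VCF 4.2 output of variant records and tabular VCF input (via vcfR).

#' Write variant records as VCF 4.2
#'
#' One data line per record, `GT` FORMAT, one sample column per
#' haplotype path (haploid genotypes). Insertions/deletions are anchored
#' on the preceding reference base (already the case for normalised
#' records); nesting is encoded in INFO as `PARENT=` and `SUBPOS=`,
#' the classified kind as `KIND=`.
#'
#' @param records Variant record tibble ([call_variants()] or generator
#'   truth). Must be sorted by contig and position.
#' @param path Output file, or `NULL` to return the lines.
#' @param samples Sample column names; defaults to the names of the
#'   `genotypes` entries, or the union of carriers.
#' @param contig_lengths Optional named lengths for `##contig` lines.
#' @return The VCF lines, invisibly when written to a file.
#' @export
write_vcf <- function(records, path = NULL, samples = NULL,
                      contig_lengths = NULL) {
  if (nrow(records) > 1) {
    o <- order(records$contig, records$pos)
    if (any(o != seq_len(nrow(records)))) abort("records must be sorted by contig, pos")
  }
  if (is.null(samples)) {
    samples <- if ("genotypes" %in% names(records) && nrow(records) > 0) {
      names(records$genotypes[[1]])
    } else {
      sort(unique(unlist(records$carriers)))
    }
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(contig_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
              as.integer(contig_lengths))
    },
    "##INFO=<ID=KIND,Number=1,Type=String,Description=\"Variant kind\">",
    "##INFO=<ID=EVENT,Number=1,Type=String,Description=\"Generating event kind\">",
    "##INFO=<ID=PARENT,Number=1,Type=String,Description=\"Id of enclosing variant\">",
    "##INFO=<ID=SUBPOS,Number=1,Type=Integer,Description=\"1-based offset within the parent alt allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t")
  )
  body <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    info <- paste0("KIND=", r$kind)
    if ("event" %in% names(records) && !is.na(r$event) && r$event != r$kind) {
      info <- paste0(info, ";EVENT=", r$event)
    }
    if (!is.na(r$parent_id)) {
      info <- paste0(info, ";PARENT=", r$parent_id, ";SUBPOS=", r$sub_pos)
    }
    gt <- if ("genotypes" %in% names(records)) {
      g <- r$genotypes[[1]][samples]
      ifelse(is.na(g), ".", as.character(g))
    } else {
      ifelse(samples %in% r$carriers[[1]], "1", "0")
    }
    qual <- if ("qual" %in% names(records)) format(r$qual) else "."
    body[[i]] <- paste(c(r$contig, r$pos, r$variant_id, r$ref, r$alt, qual,
                         "PASS", info, "GT", gt), collapse = "\t")
  }
  out <- c(hdr, body)
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

#' Read a VCF into a genotype table
#'
#' Parses a VCF 4.2 file with vcfR and returns one row per record with
#' raw `GT` strings per sample in a list column.
#'
#' @param path VCF file path.
#' @return Tibble `contig`, `pos`, `id`, `ref`, `alt` (list column of alt
#'   allele vectors), `qual`, `info`, `gt` (list column of named GT
#'   strings). Sample names are kept in attribute `samples`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  fix <- matrix(fix, ncol = 8, dimnames = list(NULL, colnames(fix)))
  gt_mat <- v@gt
  samples <- colnames(gt_mat)[-1]
  fmt <- gt_mat[, 1]
  gt_field <- function(i) {
    ix <- match("GT", strsplit(fmt[[i]], ":", fixed = TRUE)[[1]])
    vapply(gt_mat[i, -1], function(x) {
      if (is.na(x)) return(NA_character_)
      strsplit(x, ":", fixed = TRUE)[[1]][[ix]]
    }, character(1))
  }
  n <- nrow(fix)
  res <- tibble(
    contig = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    id = fix[, "ID"],
    ref = fix[, "REF"],
    alt = purrr::map(fix[, "ALT"], ~ strsplit(.x, ",", fixed = TRUE)[[1]]),
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    info = fix[, "INFO"],
    gt = purrr::map(seq_len(n), ~ setNames(gt_field(.x), samples))
  )
  attr(res, "samples") <- samples
  res
}
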