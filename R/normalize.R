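# Variant normalisation (VCF-style left alignment with anchor base).

#' Normalise a variant to left-aligned, anchored VCF form
#'
#' Applies the standard normalisation algorithm: shared trailing bases are
#' trimmed (extending to the left with the preceding reference base when
#' an allele empties), then shared leading bases are trimmed while both
#' alleles keep at least one base. SNVs pass through unchanged;
#' length-changing variants end up anchored on the reference base
#' preceding the event and shifted as far left as the reference sequence
#' allows, so e.g. a tandem-duplication edit is reported as an insertion
#' left-aligned to the start of the first copy.
#'
#' @param ref_seq Reference contig sequence (a single string).
#' @param pos 1-based position of the first base of `ref` on `ref_seq`.
#' @param ref,alt Allele strings (either may be empty).
#' @return A list with `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(ref_seq, pos, ref, alt) {
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 0 && na > 0 &&
        substr(ref, nr, nr) == substr(alt, na, na) &&
        !(nr == 1 && na == 1)) {
      ref <- substr(ref, 1, nr - 1)
      alt <- substr(alt, 1, na - 1)
    } else if (nr == 0 || na == 0) {
      if (pos <= 1) abort("cannot left-extend past the start of the reference")
      pos <- pos - 1
      b <- substr(ref_seq, pos, pos)
      ref <- paste0(b, ref)
      alt <- paste0(b, alt)
    } else {
      break
    }
  }
  while (nchar(ref) >= 2 && nchar(alt) >= 2 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1
  }
  list(pos = as.integer(pos), ref = ref, alt = alt)
}

#' Classify a normalised allele pair
#'
#' `SNV` for two single bases; `INS`/`DEL` for anchored pure
#' length changes; `COMPLEX` otherwise.
#'
#' @param ref,alt Normalised allele strings.
#' @return One of `"SNV"`, `"INS"`, `"DEL"`, `"COMPLEX"`.
#' @export
classify_alleles <- function(ref, alt) {
  dplyr::case_when(
    nchar(ref) == 1 & nchar(alt) == 1 ~ "SNV",
    nchar(ref) == 1 & nchar(alt) > 1 & substr(alt, 1, 1) == ref ~ "INS",
    nchar(alt) == 1 & nchar(ref) > 1 & substr(ref, 1, 1) == alt ~ "DEL",
    .default = "COMPLEX"
  )
}

#' Apply a haplotype's variant alleles to the reference sequence
#'
#' Splices each variant carried by `path_name` into `ref_seq`, replacing
#' the reference allele region with the alternate allele. Nested records
#' (those with a `parent_id`) are first substituted into their parent's
#' alternate allele at `sub_pos` (a 1-based offset within the parent alt
#' allele string). Edits are applied right to left so positions stay
#' valid. This is the string-editing view of a haplotype: the result must
#' equal the haplotype's graph path sequence.
#'
#' @param ref_seq Reference contig sequence.
#' @param records Variant record tibble (truth set or [call_variants()]
#'   output) with columns `variant_id`, `pos`, `ref`, `alt`, `carriers`,
#'   `parent_id`, `sub_pos`.
#' @param path_name Haplotype path whose alleles should be applied.
#' @return The edited sequence.
#' @export
apply_variants <- function(ref_seq, records, path_name) {
  carried <- purrr::map_lgl(records$carriers, ~ path_name %in% .x)
  top <- records[carried & is.na(records$parent_id), ]
  kids <- records[carried & !is.na(records$parent_id), ]
  top <- arrange(top, dplyr::desc(.data$pos))
  for (i in seq_len(nrow(top))) {
    alt_eff <- top$alt[[i]]
    ch <- kids[kids$parent_id == top$variant_id[[i]], ]
    if (nrow(ch) > 0) {
      ch <- arrange(ch, dplyr::desc(.data$sub_pos))
      for (j in seq_len(nrow(ch))) {
        sp <- ch$sub_pos[[j]]
        stopifnot(substr(alt_eff, sp, sp + nchar(ch$ref[[j]]) - 1) == ch$ref[[j]])
        alt_eff <- paste0(substr(alt_eff, 1, sp - 1), ch$alt[[j]],
                          substr(alt_eff, sp + nchar(ch$ref[[j]]), nchar(alt_eff)))
      }
    }
    p <- top$pos[[i]]
    ref_seq <- paste0(substr(ref_seq, 1, p - 1), alt_eff,
                      substr(ref_seq, p + nchar(top$ref[[i]]), nchar(ref_seq)))
  }
  ref_seq
}
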