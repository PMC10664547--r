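# Genotype-set comparison between two variant-calling pipelines:
# partition into exclusive/shared records and per-sample / per-variant
# agreement over the shared ones.

vcf_variant_type <- function(ref, alt) {
  ifelse(nchar(ref) == 1 & purrr::map_lgl(alt, ~ all(nchar(.x) == 1)),
         "snp", "indel")
}

#' Intersect two genotype sets
#'
#' Mirrors `bcftools isec -c some` semantics: records with QUAL below
#' `qual_min` are dropped first; two records match iff they share contig,
#' position and reference allele and have at least one alternate allele
#' in common. Produces the four-way partition: records only in A, only
#' in B, and the A-side and B-side versions of the shared records.
#'
#' @param a,b Genotype tables from [read_vcf()] (same sample set).
#' @param qual_min Minimum QUAL (default 10); records with missing QUAL
#'   are dropped when `qual_min > 0`, kept when it is 0.
#' @param type Optional subset: `"snp"` (all alleles single bases) or
#'   `"indel"` (anything else).
#' @return A `vcf_intersection`: list with tibbles `a_only`, `b_only`,
#'   `shared_a`, `shared_b` (row-aligned) and the retained input sizes
#'   `n_a`, `n_b`.
#' @export
intersect_vcfs <- function(a, b, qual_min = 10, type = NULL) {
  sa <- attr(a, "samples"); sb <- attr(b, "samples")
  if (!is.null(sa) && !is.null(sb) && !identical(sort(sa), sort(sb))) {
    abort("the two genotype sets have different sample columns")
  }
  prep <- function(x) {
    if (qual_min > 0) {
      x <- filter(x, !is.na(.data$qual) & .data$qual >= qual_min)
    }
    if (!is.null(type)) {
      x <- filter(x, vcf_variant_type(.data$ref, .data$alt) == !!type)
    }
    mutate(x, .key = paste(.data$contig, .data$pos, .data$ref))
  }
  a <- prep(a); b <- prep(b)
  some_match <- function(x, y) length(intersect(x, y)) > 0
  b_by_key <- split(seq_len(nrow(b)), b$.key)
  ib <- rep(NA_integer_, nrow(a))
  for (i in seq_len(nrow(a))) {
    for (j in b_by_key[[a$.key[[i]]]]) {
      if (some_match(a$alt[[i]], b$alt[[j]])) { ib[[i]] <- j; break }
    }
  }
  shared_in_a <- !is.na(ib)
  a_by_key <- split(seq_len(nrow(a)), a$.key)
  shared_in_b <- vapply(seq_len(nrow(b)), function(j) {
    any(vapply(a_by_key[[b$.key[[j]]]],
               function(i) some_match(b$alt[[j]], a$alt[[i]]), logical(1)))
  }, logical(1))
  shared_a <- a[shared_in_a, ]
  shared_b <- b[ib[shared_in_a], ]
  drop_key <- function(x) select(x, -".key")
  structure(list(a_only = drop_key(a[!shared_in_a, ]),
                 b_only = drop_key(b[!shared_in_b, ]),
                 shared_a = drop_key(shared_a),
                 shared_b = drop_key(shared_b),
                 n_a = nrow(a), n_b = nrow(b)),
            class = "vcf_intersection")
}

#' @export
print.vcf_intersection <- function(x, ...) {
  cat(sprintf("<vcf_intersection> a_only %d, b_only %d, shared %d (of %d / %d)\n",
              nrow(x$a_only), nrow(x$b_only), nrow(x$shared_a), x$n_a, x$n_b))
  invisible(x)
}

# GT string -> sorted allele-sequence multiset, or NULL when missing
resolve_gt <- function(gt, ref, alt) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NULL)
  idx <- strsplit(gt, "[/|]")[[1]]
  if (any(idx == ".")) return(NULL)
  alleles <- c(ref, alt)[as.integer(idx) + 1L]
  sort(alleles)
}

#' Per-sample and per-variant genotype concordance over shared records
#'
#' For each shared record pair and sample, the unordered multisets of
#' allele sequences implied by the two GT strings are compared (phase is
#' ignored; alleles are resolved to sequences so matching survives
#' allele reordering between files). A missing genotype compared with a
#' called one counts as disagreement; two missing genotypes agree.
#' Agreement is summarised per sample over shared sites (mean and SD
#' across samples) and per variant over samples.
#'
#' @param isec A `vcf_intersection`, or `shared_a` given with `shared_b`.
#' @param shared_b Second shared table when `isec` is a tibble.
#' @return A `concordance_report`: list with `per_sample` (tibble
#'   `sample`, `n_sites`, `agreement_pct`), `per_variant` (tibble
#'   `contig`, `pos`, `ref`, `agreement_pct`), `mean_agreement`,
#'   `sd_agreement`.
#' @export
genotype_concordance <- function(isec, shared_b = NULL) {
  if (inherits(isec, "vcf_intersection")) {
    a <- isec$shared_a; b <- isec$shared_b
  } else {
    a <- isec; b <- shared_b
  }
  if (nrow(a) == 0) abort("no shared records to compare")
  samples <- names(a$gt[[1]])
  agree <- matrix(NA, nrow = nrow(a), ncol = length(samples),
                  dimnames = list(NULL, samples))
  for (i in seq_len(nrow(a))) {
    for (s in samples) {
      ga <- resolve_gt(a$gt[[i]][[s]], a$ref[[i]], a$alt[[i]])
      gb <- resolve_gt(b$gt[[i]][[s]], b$ref[[i]], b$alt[[i]])
      agree[i, s] <- if (is.null(ga) && is.null(gb)) TRUE
                     else if (is.null(ga) || is.null(gb)) FALSE
                     else identical(ga, gb)
    }
  }
  per_sample <- tibble(
    sample = samples,
    n_sites = unname(colSums(!is.na(agree))),
    agreement_pct = unname(100 * colMeans(agree))
  )
  per_variant <- tibble(
    contig = a$contig, pos = a$pos, ref = a$ref,
    agreement_pct = 100 * rowMeans(agree)
  )
  ok <- !is.na(per_sample$agreement_pct) & per_sample$n_sites > 0
  structure(list(per_sample = per_sample, per_variant = per_variant,
                 mean_agreement = mean(per_sample$agreement_pct[ok]),
                 sd_agreement = sd(per_sample$agreement_pct[ok])),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report> %d samples, mean agreement %.1f%% (sd %.1f)\n",
              nrow(x$per_sample), x$mean_agreement,
              ifelse(is.na(x$sd_agreement), 0, x$sd_agreement)))
  invisible(x)
}

#' @rdname genotype_concordance
#' @param x A `concordance_report`.
#' @param ... Unused.
#' @export
glance.concordance_report <- function(x, ...) {
  tibble(n_samples = nrow(x$per_sample),
         n_shared = nrow(x$per_variant),
         mean_agreement = x$mean_agreement,
         sd_agreement = x$sd_agreement)
}

#' @rdname genotype_concordance
#' @export
tidy.concordance_report <- function(x, ...) x$per_sample
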