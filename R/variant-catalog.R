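# Bubble-based variant cataloguing from haplotype paths against the
# designated reference path.

# indices of one longest strictly increasing subsequence (patience method)
lis_indices <- function(x) {
  n <- length(x)
  if (n == 0) return(integer())
  tails <- numeric(0)    # smallest tail value per subsequence length
  tails_i <- integer(0)  # index achieving it
  prev <- integer(n)
  for (i in seq_len(n)) {
    j <- findInterval(x[[i]] - 0.5, tails) + 1L  # first tail >= x[i]
    tails[j] <- x[[i]]
    tails_i[j] <- i
    prev[i] <- if (j > 1) tails_i[[j - 1]] else 0L
  }
  out <- integer(0)
  k <- tails_i[[length(tails_i)]]
  while (k > 0) { out <- c(k, out); k <- prev[[k]] }
  out
}

steps_key <- function(st) paste(paste0(st$segment_id, st$orient), collapse = ",")

steps_seq <- function(st, seqs) {
  if (nrow(st) == 0) return("")
  s <- seqs[st$segment_id]
  neg <- st$orient == "-"
  if (any(neg)) s[neg] <- reverse_complement(s[neg])
  paste(s, collapse = "")
}

# anchors (node ids traversed exactly once, in consistent order and
# orientation) between the reference step table and one haplotype
pairwise_anchors <- function(ref_steps, hap_steps) {
  r_once <- names(which(table(ref_steps$segment_id) == 1))
  h_once <- names(which(table(hap_steps$segment_id) == 1))
  cand <- intersect(r_once, h_once)
  if (length(cand) == 0) return(character())
  pr <- match(cand, ref_steps$segment_id)
  ph <- match(cand, hap_steps$segment_id)
  same_or <- ref_steps$orient[pr] == hap_steps$orient[ph]
  cand <- cand[same_or]; pr <- pr[same_or]; ph <- ph[same_or]
  if (length(cand) == 0) return(character())
  o <- order(pr)
  cand <- cand[o]; ph <- ph[o]
  cand[lis_indices(ph)]
}

#' Detect bubbles between the reference path and the haplotype paths
#'
#' Anchors are the ordered nodes shared single-copy (and in consistent
#' orientation) between the reference path and every haplotype path of the
#' same contig, matched by a longest-increasing-subsequence alignment of
#' node positions and then intersected across haplotypes. Maximal
#' deviating intervals between consecutive anchors become bubbles; a
#' haplotype whose walk between the anchors equals the reference walk
#' carries the reference allele there. Haplotypes sharing no anchors with
#' the reference are reported as uncalled (with a warning), not an error.
#'
#' @param g A [pangenome].
#' @param contig Restrict to one reference contig (default: all).
#' @return Tibble with columns `bubble_id`, `contig`, `source`, `sink`
#'   (anchor segment ids), `ref_walk` (list of step tables) and
#'   `hap_walks` (list of named lists of step tables, one per non-reference
#'   haplotype path). The tibble carries the uncalled path names in
#'   attribute `uncalled`.
#' @export
detect_bubbles <- function(g, contig = NULL) {
  ref_paths <- filter(g$paths, .data$sample == g$reference_sample)
  if (!is.null(contig)) ref_paths <- filter(ref_paths, .data$contig %in% !!contig)
  out <- list()
  uncalled <- character()
  for (ri in seq_len(nrow(ref_paths))) {
    rp <- ref_paths[ri, ]
    ref_steps <- rp$steps[[1]]
    if (anyDuplicated(ref_steps$segment_id)) {
      abort("reference path must traverse each of its segments exactly once")
    }
    haps <- filter(g$paths, .data$contig == rp$contig,
                   .data$path_name != rp$path_name)
    anchor_sets <- list()
    keep <- character()
    for (hi in seq_len(nrow(haps))) {
      a <- pairwise_anchors(ref_steps, haps$steps[[hi]])
      if (length(a) == 0) {
        uncalled <- c(uncalled, haps$path_name[[hi]])
      } else {
        keep <- c(keep, haps$path_name[[hi]])
        anchor_sets[[haps$path_name[[hi]]]] <- a
      }
    }
    haps <- filter(haps, .data$path_name %in% keep)
    if (nrow(haps) == 0) next
    anchors <- ref_steps$segment_id
    for (a in anchor_sets) anchors <- anchors[anchors %in% a]
    if (length(anchors) < 2) {
      warn(paste0("fewer than two global anchors on contig ", rp$contig))
      next
    }
    ref_idx <- match(anchors, ref_steps$segment_id)
    hap_idx <- purrr::map(haps$steps, ~ match(anchors, .x$segment_id))
    names(hap_idx) <- haps$path_name
    for (k in seq_len(length(anchors) - 1)) {
      i0 <- ref_idx[[k]]; i1 <- ref_idx[[k + 1]]
      ref_mid <- ref_steps[seq2(i0 + 1, i1 - 1), ]
      walks <- purrr::imap(hap_idx, function(ix, nm) {
        haps$steps[[match(nm, haps$path_name)]][seq2(ix[[k]] + 1, ix[[k + 1]] - 1), ]
      })
      rkey <- steps_key(ref_mid)
      if (all(purrr::map_chr(walks, steps_key) == rkey)) next
      out[[length(out) + 1]] <- tibble(
        contig = rp$contig,
        source = anchors[[k]], sink = anchors[[k + 1]],
        ref_walk = list(ref_mid), hap_walks = list(walks)
      )
    }
  }
  res <- if (length(out) > 0) bind_rows(out) else {
    tibble(contig = character(), source = character(), sink = character(),
           ref_walk = list(), hap_walks = list())
  }
  res <- mutate(res, bubble_id = sprintf("b%04d", row_number()),
                .before = 1)
  attr(res, "uncalled") <- unique(uncalled)
  res
}

seq2 <- function(from, to) if (to < from) integer() else seq.int(from, to)

# decompose a multi-walk bubble into a consensus allele plus nested
# deviations; returns NULL when no clean nesting structure exists
nest_decompose <- function(alt_walks_by_hap, seqs) {
  keys <- purrr::map_chr(alt_walks_by_hap, steps_key)
  walks <- alt_walks_by_hap[!duplicated(keys)]
  if (any(purrr::map_int(walks, nrow) == 0)) return(NULL)
  once_all <- purrr::map(walks, function(w) names(which(table(w$segment_id) == 1)))
  sub_anchors <- purrr::reduce(once_all, intersect)
  # keep only anchors occurring in consistent (increasing) order everywhere
  ord <- match(sub_anchors, walks[[1]]$segment_id)
  sub_anchors <- sub_anchors[order(ord)]
  for (w in walks) {
    if (is.unsorted(match(sub_anchors, w$segment_id), strictly = TRUE)) return(NULL)
  }
  if (length(sub_anchors) == 0) return(NULL)
  bounds <- function(w) {
    ix <- match(sub_anchors, w$segment_id)
    m <- length(ix)
    list(starts = c(1L, ix + 1L), ends = c(ix - 1L, nrow(w)), anchor_ix = ix)
  }
  n_slot <- length(sub_anchors) + 1L
  # per-haplotype slot walks
  slot_walks <- purrr::map(alt_walks_by_hap, function(w) {
    b <- bounds(w)
    purrr::map(seq_len(n_slot), ~ w[seq2(b$starts[[.x]], b$ends[[.x]]), ])
  })
  # consensus per slot: allele carried by most haplotypes, ties by sequence
  consensus <- vector("list", n_slot)
  for (s in seq_len(n_slot)) {
    sw <- purrr::map(slot_walks, s)
    k <- purrr::map_chr(sw, steps_key)
    tab <- sort(table(k), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1) {
      sq <- purrr::map_chr(top, ~ steps_seq(sw[[match(.x, k)]], seqs))
      top <- top[order(sq)][1]
    } else top <- top[[1]]
    consensus[[s]] <- sw[[match(top, k)]]
  }
  # consensus full walk and sequence offsets of each slot
  anchor_steps <- purrr::map(sub_anchors, function(a) {
    w <- walks[[1]]
    w[match(a, w$segment_id), ]
  })
  parts <- list()
  for (s in seq_len(n_slot)) {
    parts <- c(parts, list(consensus[[s]]))
    if (s <= length(sub_anchors)) parts <- c(parts, list(anchor_steps[[s]]))
  }
  cons_walk <- bind_rows(parts)
  part_seqs <- purrr::map_chr(parts, steps_seq, seqs = seqs)
  part_starts <- cumsum(c(0, head(nchar(part_seqs), -1)))  # 0-based offsets
  slot_offsets <- part_starts[seq(1, by = 2, length.out = n_slot)]
  deviations <- list()
  for (s in seq_len(n_slot)) {
    cons_key <- steps_key(consensus[[s]])
    sw <- purrr::map(slot_walks, s)
    k <- purrr::map_chr(sw, steps_key)
    dev_keys <- setdiff(unique(k), cons_key)
    for (dk in dev_keys) {
      carriers <- names(sw)[k == dk]
      deviations[[length(deviations) + 1]] <- list(
        offset0 = slot_offsets[[s]],
        ref = steps_seq(consensus[[s]], seqs),
        alt = steps_seq(sw[[match(dk, k)]], seqs),
        carriers = sort(carriers)
      )
    }
  }
  list(consensus_walk = cons_walk, deviations = deviations)
}

#' Call variants from the graph's haplotype paths
#'
#' Runs [detect_bubbles()] and converts each bubble into normalised
#' variant records against the reference coordinate system. Biallelic
#' bubbles become one record. Bubbles where carriers disagree internally
#' are decomposed into a parent record whose alternate allele is the
#' per-slot majority consensus among the carriers (ties broken by the
#' lexicographically smaller sequence) plus nested records carrying
#' `parent_id` and `sub_pos` (the 1-based offset of the deviation within
#' the parent alt allele); when no clean nesting structure exists the
#' bubble is reported as a single multi-allelic `COMPLEX`-style record
#' with comma-joined alternate alleles. The alternate-allele frequency is
#' carriers / called haplotypes, the reference path counting as one called
#' haplotype.
#'
#' @param g A [pangenome].
#' @param contig Restrict to one reference contig (default: all).
#' @return Variant record tibble with the same layout as the generator
#'   truth set (`variant_id`, `contig`, `pos`, `ref`, `alt`, `kind`,
#'   `event`, `carriers`, `n_carriers`, `n_called`, `af`, `parent_id`,
#'   `sub_pos`) plus a `genotypes` list column (named integer allele
#'   indices per haplotype path, `NA` for uncalled haplotypes).
#' @export
call_variants <- function(g, contig = NULL) {
  bubbles <- detect_bubbles(g, contig = contig)
  uncalled <- attr(bubbles, "uncalled")
  seqs <- segment_sequences(g)
  ref_paths <- filter(g$paths, .data$sample == g$reference_sample)
  ref_seqs <- setNames(purrr::map_chr(ref_paths$path_name, ~ path_sequence(g, .x)),
                       ref_paths$contig)
  # reference position of the last base of each reference segment, per contig
  end_pos <- list()
  for (i in seq_len(nrow(ref_paths))) {
    st <- ref_paths$steps[[i]]
    end_pos[[ref_paths$contig[[i]]]] <-
      setNames(cumsum(nchar(seqs[st$segment_id])), st$segment_id)
  }
  all_paths <- g$paths$path_name
  rows <- list(); vid <- 0L
  next_id <- function() { vid <<- vid + 1L; sprintf("c%04d", vid) }
  for (bi in seq_len(nrow(bubbles))) {
    ctg <- bubbles$contig[[bi]]
    ref_seq <- ref_seqs[[ctg]]
    pos0 <- end_pos[[ctg]][[bubbles$source[[bi]]]]
    ref_allele_raw <- steps_seq(bubbles$ref_walk[[bi]], seqs)
    walks <- bubbles$hap_walks[[bi]]
    keys <- purrr::map_chr(walks, steps_key)
    rkey <- steps_key(bubbles$ref_walk[[bi]])
    alt_haps <- names(keys)[keys != rkey]
    alt_keys <- unique(keys[alt_haps])
    called <- c(ref_paths$path_name[ref_paths$contig == ctg], names(keys))
    n_called <- length(called)
    mk_row <- function(pos, ref, alt, carriers, parent_id = NA_character_,
                       sub_pos = NA_integer_, genotypes = NULL) {
      gt <- setNames(rep(NA_integer_, length(all_paths)), all_paths)
      gt[called] <- 0L
      gt[carriers] <- 1L
      if (!is.null(genotypes)) gt <- genotypes
      n_car <- length(carriers)
      tibble(variant_id = next_id(), contig = ctg, pos = as.integer(pos),
             ref = ref, alt = alt, kind = classify_alleles(ref, alt),
             event = classify_alleles(ref, alt),
             carriers = list(sort(carriers)), n_carriers = n_car,
             n_called = n_called, af = n_car / n_called,
             parent_id = parent_id, sub_pos = sub_pos,
             genotypes = list(gt))
    }
    emit_multiallelic <- function() {
      alt_seqs <- sort(unique(purrr::map_chr(alt_keys, function(k) {
        steps_seq(walks[[match(k, keys)]], seqs)
      })))
      # anchor all alleles on the preceding reference base
      anchor <- substr(ref_seq, pos0, pos0)
      gt <- setNames(rep(NA_integer_, length(all_paths)), all_paths)
      gt[called] <- 0L
      for (h in alt_haps) {
        gt[[h]] <- match(steps_seq(walks[[h]], seqs), alt_seqs)
      }
      tibble(variant_id = next_id(), contig = ctg, pos = as.integer(pos0),
             ref = paste0(anchor, ref_allele_raw),
             alt = paste(paste0(anchor, alt_seqs), collapse = ","),
             kind = "COMPLEX", event = "COMPLEX",
             carriers = list(sort(alt_haps)), n_carriers = length(alt_haps),
             n_called = n_called, af = length(alt_haps) / n_called,
             parent_id = NA_character_, sub_pos = NA_integer_,
             genotypes = list(gt))
    }
    if (length(alt_keys) == 1) {
      alt_seq <- steps_seq(walks[[match(alt_keys, keys)]], seqs)
      nv <- normalize_variant(ref_seq, pos0 + 1L, ref_allele_raw, alt_seq)
      rows[[length(rows) + 1]] <- mk_row(nv$pos, nv$ref, nv$alt, sort(alt_haps))
    } else {
      dec <- nest_decompose(walks[alt_haps], seqs)
      emitted <- FALSE
      if (!is.null(dec)) {
        cons_seq <- steps_seq(dec$consensus_walk, seqs)
        nv <- normalize_variant(ref_seq, pos0 + 1L, ref_allele_raw, cons_seq)
        # nesting offsets are only valid if normalisation just prepended the
        # anchor base without shifting or trimming
        ok <- nv$pos == pos0 && nv$ref == substr(ref_seq, pos0, pos0) &&
          nv$alt == paste0(nv$ref, cons_seq) && nchar(ref_allele_raw) == 0
        if (ok) {
          parent <- mk_row(nv$pos, nv$ref, nv$alt, sort(alt_haps))
          rows[[length(rows) + 1]] <- parent
          for (d in dec$deviations) {
            rows[[length(rows) + 1]] <- mk_row(
              parent$pos, d$ref, d$alt, d$carriers,
              parent_id = parent$variant_id,
              sub_pos = 2L + d$offset0)
          }
          emitted <- TRUE
        }
      }
      if (!emitted) rows[[length(rows) + 1]] <- emit_multiallelic()
    }
  }
  res <- if (length(rows) > 0) {
    arrange(bind_rows(rows), .data$contig, .data$pos, .data$ref, .data$alt)
  } else {
    tibble(variant_id = character(), contig = character(), pos = integer(),
           ref = character(), alt = character(), kind = character(),
           event = character(), carriers = list(), n_carriers = integer(),
           n_called = integer(), af = numeric(), parent_id = character(),
           sub_pos = integer(), genotypes = list())
  }
  attr(res, "uncalled") <- uncalled
  res
}

#' Summarise a variant record set
#'
#' Counts and cumulative affected bp per variant kind (an SNV counts 1 bp;
#' insertions/deletions count their length change), plus a log-spaced
#' length histogram for length-changing variants.
#'
#' @param records Variant record tibble.
#' @return An object of class `variant_summary`: list with `by_kind`
#'   (tibble `kind`, `n`, `total_bp`) and `length_histogram` (tibble
#'   `bin_lo`, `bin_hi`, `n`), where bins are powers of two.
#' @export
summarize_variants <- function(records) {
  kinds <- c("SNV", "INS", "DEL", "COMPLEX")
  if (nrow(records) == 0) {
    by_kind <- tibble(kind = kinds, n = 0L, total_bp = 0)
    hist <- tibble(bin_lo = numeric(), bin_hi = numeric(), n = integer())
  } else {
    first_alt <- purrr::map_chr(strsplit(records$alt, ",", fixed = TRUE), 1)
    dlen <- abs(nchar(first_alt) - nchar(records$ref))
    bp <- ifelse(records$kind == "SNV", 1, dlen)
    by_kind <- tibble(kind = records$kind, bp = bp) |>
      group_by(.data$kind) |>
      summarise(n = dplyr::n(), total_bp = sum(.data$bp)) |>
      ungroup()
    by_kind <- left_join(tibble(kind = kinds), by_kind, by = "kind") |>
      mutate(n = ifelse(is.na(.data$n), 0L, .data$n),
             total_bp = ifelse(is.na(.data$total_bp), 0, .data$total_bp))
    ind <- dlen[records$kind %in% c("INS", "DEL", "COMPLEX") & dlen > 0]
    if (length(ind) > 0) {
      brk <- 2^(0:ceiling(log2(max(ind) + 1)))
      bin <- findInterval(ind, brk)
      hist <- tibble(bin = bin) |>
        group_by(.data$bin) |>
        summarise(n = dplyr::n()) |>
        ungroup() |>
        mutate(bin_lo = brk[.data$bin], bin_hi = brk[.data$bin + 1] - 1) |>
        select("bin_lo", "bin_hi", "n")
    } else {
      hist <- tibble(bin_lo = numeric(), bin_hi = numeric(), n = integer())
    }
  }
  structure(list(by_kind = by_kind, length_histogram = hist),
            class = "variant_summary")
}

#' @export
print.variant_summary <- function(x, ...) {
  cat("<variant_summary>\n")
  print(x$by_kind)
  invisible(x)
}

#' @rdname summarize_variants
#' @param x A `variant_summary`.
#' @param ... Unused.
#' @export
tidy.variant_summary <- function(x, ...) x$by_kind

#' @rdname summarize_variants
#' @export
glance.variant_summary <- function(x, ...) {
  tibble(n_variants = sum(x$by_kind$n),
         n_snv = x$by_kind$n[x$by_kind$kind == "SNV"],
         ins_bp = x$by_kind$total_bp[x$by_kind$kind == "INS"],
         del_bp = x$by_kind$total_bp[x$by_kind$kind == "DEL"])
}
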