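# Seeded synthetic pangenome generator with a known truth set. Emulates a
# multi-haplotype graph containing SNVs, small indels, large insertions
# with nested SNVs, deletions and tandem duplications, so the whole
# downstream pipeline can be exercised without external data.

#' Declare a structural (or explicitly-carried) event for simulation
#'
#' @param kind One of `"SNV"`, `"INS"`, `"DEL"`, `"DUP"`, `"ELEMENT_INS"`.
#'   `ELEMENT_INS` is an insertion of a fixed, labelled block standing in
#'   for a mobile-element / retroviral insertion (default length 7.5 kb,
#'   matching the scale of an endogenous avian leukosis provirus).
#' @param length Event length in bp (ignored for `SNV`).
#' @param carriers Integer indices of carrier haplotypes among the
#'   alternate haplotypes (1 .. n_haplotypes - 1), or `NULL` to draw a
#'   random carrier set.
#' @param nested_snv_count Number of SNVs to place inside the inserted
#'   sequence (`INS`/`ELEMENT_INS` only). Nested-SNV carriers are drawn as
#'   a strict minority of the insertion carriers, which requires at least
#'   3 carriers.
#' @return A `struct_event` list.
#' @export
struct_event <- function(kind = c("INS", "DEL", "DUP", "ELEMENT_INS", "SNV"),
                         length = 0L, carriers = NULL, nested_snv_count = 0L) {
  kind <- match.arg(kind)
  if (kind != "SNV" && length < 1) abort("event length must be >= 1")
  if (nested_snv_count > 0 && !kind %in% c("INS", "ELEMENT_INS")) {
    abort("nested SNVs are only supported inside insertions")
  }
  structure(list(kind = kind, length = as.integer(length), carriers = carriers,
                 nested_snv_count = as.integer(nested_snv_count)),
            class = "struct_event")
}

#' Simulation configuration for the synthetic pangenome
#'
#' @param seed Integer seed; the generator is byte-deterministic given the
#'   full configuration.
#' @param ref_length Reference contig length in bp.
#' @param n_haplotypes Total number of haplotype paths including the
#'   reference path.
#' @param snv_rate,small_indel_rate Per-bp probabilities of random SNVs
#'   and small indels.
#' @param indel_geom_p Geometric parameter for small-indel lengths
#'   (length = 1 + Geom(p)); insertions and deletions are equiprobable.
#' @param structural_events List of [struct_event()]s.
#' @param sample_names Sample names for the alternate haplotypes (two
#'   haplotypes per sample); autogenerated when `NULL`.
#' @param reference_sample Sample name of the reference path.
#' @param contig Contig name.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, ref_length = 100000L, n_haplotypes = 12L,
                       snv_rate = 1e-3, small_indel_rate = 1e-4,
                       indel_geom_p = 0.5, structural_events = list(),
                       sample_names = NULL, reference_sample = "ref",
                       contig = "chr1") {
  if (snv_rate < 0 || snv_rate > 1 || small_indel_rate < 0 || small_indel_rate > 1) {
    abort("rates must lie in [0, 1]")
  }
  if (n_haplotypes < 1) abort("need at least the reference haplotype")
  n_alt <- n_haplotypes - 1
  if (is.null(sample_names)) {
    sample_names <- sprintf("S%02d", seq_len(max(0, ceiling(n_alt / 2))))
  }
  for (ev in structural_events) {
    if (!inherits(ev, "struct_event")) abort("structural_events must be struct_event objects")
    if (!is.null(ev$carriers) && length(ev$carriers) > 0 &&
        (min(ev$carriers) < 1 || max(ev$carriers) > n_alt)) {
      abort("event carriers outside 1..(n_haplotypes - 1)")
    }
  }
  structure(list(seed = as.integer(seed), ref_length = as.integer(ref_length),
                 n_haplotypes = as.integer(n_haplotypes), snv_rate = snv_rate,
                 small_indel_rate = small_indel_rate, indel_geom_p = indel_geom_p,
                 structural_events = structural_events,
                 sample_names = sample_names,
                 reference_sample = reference_sample, contig = contig),
            class = "sim_config")
}

# path names of the alternate haplotypes, two per sample
alt_path_names <- function(config) {
  n_alt <- config$n_haplotypes - 1
  if (n_alt == 0) return(character())
  idx <- seq_len(n_alt)
  pansn_name(config$sample_names[ceiling(idx / 2)],
             as.character(1 + (idx - 1) %% 2), config$contig)
}

# place an interval of `span` bp avoiding `occupied` (a two-column matrix
# of start/end), with `gap` bp clearance; returns the start or NA
place_interval <- function(span, lo, hi, occupied, gap = 5L, tries = 200L) {
  for (t in seq_len(tries)) {
    s <- sample.int(hi - lo - span + 2L, 1L) + lo - 1L
    e <- s + span - 1L
    if (nrow(occupied) == 0 ||
        all(e + gap < occupied[, 1] | s - gap > occupied[, 2])) {
      return(s)
    }
  }
  NA_integer_
}

#' Generate a seeded synthetic pangenome with a known truth set
#'
#' Builds one reference path plus `n_haplotypes - 1` alternate haplotype
#' paths over a random reference sequence. Every variant is realised as a
#' bubble: SNVs as two single-base branches, deletions as bypass edges,
#' insertions as off-reference node chains (with sub-bubbles for nested
#' SNVs), and tandem duplications as a back edge traversed twice by
#' carriers. Shared flanks are merged maximally, so bubbles are minimal.
#' Event placement is rejection-sampled to keep variants non-overlapping
#' and separated by at least one invariant anchor base, and event edges
#' are resampled so that no variant can be left-shifted away from its
#' placement; the truth set is therefore unambiguous and already in
#' normalised VCF form.
#'
#' @param config A [sim_config()].
#' @return A list with elements `graph` (a [pangenome]), `truth` (variant
#'   record tibble: `variant_id`, `contig`, `pos`, `ref`, `alt`, `kind`,
#'   `event`, `carriers`, `n_carriers`, `n_called`, `af`, `parent_id`,
#'   `sub_pos`), `sequences` (named character: reference plus per-path
#'   haplotype sequences), and `config`.
#' @export
generate_pangenome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$ref_length
  ref_seq <- random_dna(L)
  base <- function(p) substr(ref_seq, p, p)
  sub_seq <- function(a, b) substr(ref_seq, a, b)
  alt_paths <- alt_path_names(config)
  n_alt <- length(alt_paths)
  ref_path <- pansn_name(config$reference_sample, "0", config$contig)

  draw_carriers <- function(spec) {
    if (!is.null(spec)) return(alt_paths[sort(unique(spec))])
    k <- sample.int(n_alt, 1L)
    sort(sample(alt_paths, k))
  }
  other_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)

  # --- event placement -------------------------------------------------------
  occupied <- matrix(integer(), ncol = 2)
  variants <- list()
  add_occ <- function(s, e) occupied <<- rbind(occupied, c(s, e))

  for (ev in config$structural_events) {
    if (ev$kind == "SNV") {
      p <- place_interval(1L, 10L, L - 10L, occupied)
      if (is.na(p)) abort("could not place SNV event without overlap")
      add_occ(p, p)
      variants[[length(variants) + 1]] <- list(
        kind = "SNV", event = "SNV", pos = p, alt_base = other_base(base(p)),
        carriers = draw_carriers(ev$carriers))
    } else if (ev$kind %in% c("INS", "ELEMENT_INS")) {
      p <- place_interval(2L, 10L, L - 10L, occupied)  # anchor p, next base p+1
      if (is.na(p)) abort("could not place insertion event without overlap")
      add_occ(p, p + 1L)
      ins <- random_dna(ev$length)
      # forbid left-shifting: last inserted base must differ from the anchor
      while (substr(ins, ev$length, ev$length) == base(p)) {
        ins <- paste0(substr(ins, 1, ev$length - 1),
                      other_base(substr(ins, ev$length, ev$length)))
      }
      carriers <- draw_carriers(ev$carriers)
      nested <- NULL
      if (ev$nested_snv_count > 0) {
        if (length(carriers) < 3) abort("nested SNVs need at least 3 insertion carriers")
        # keep nested sites >= 2 bp apart and off the insert edges so every
        # sub-bubble has non-empty anchors inside the insertion
        cand <- seq(3L, ev$length - 2L, by = 3L)
        qs <- sort(sample(cand, ev$nested_snv_count))
        max_k <- floor((length(carriers) - 1) / 2)
        nested <- purrr::map(qs, function(q) {
          k <- sample.int(max_k, 1L)
          list(offset = q,
               ref_base = substr(ins, q, q),
               alt_base = other_base(substr(ins, q, q)),
               carriers = sort(sample(carriers, k)))
        })
      }
      variants[[length(variants) + 1]] <- list(
        kind = "INS", event = ev$kind, pos = p, ins_seq = ins,
        nested = nested, carriers = carriers)
    } else if (ev$kind == "DEL") {
      repeat {
        p <- place_interval(ev$length + 1L, 10L, L - 10L, occupied)
        if (is.na(p)) abort("could not place deletion event without overlap")
        # anchor base must differ from the base after the deleted block,
        # otherwise the record could be left-shifted off its placement
        if (base(p) != base(p + ev$length)) break
      }
      add_occ(p, p + ev$length)
      variants[[length(variants) + 1]] <- list(
        kind = "DEL", event = "DEL", pos = p, del_len = ev$length,
        carriers = draw_carriers(ev$carriers))
    } else if (ev$kind == "DUP") {
      repeat {
        a <- place_interval(ev$length + 2L, 10L, L - 10L, occupied)
        if (is.na(a)) abort("could not place duplication event without overlap")
        a <- a + 1L
        b <- a + ev$length - 1L
        if (base(b) != base(a - 1L)) break
      }
      add_occ(a - 1L, b + 1L)
      variants[[length(variants) + 1]] <- list(
        kind = "DUP", event = "DUP", a = a, b = b,
        carriers = draw_carriers(ev$carriers))
    }
  }

  # random SNVs
  n_snv <- rbinom(1L, L, config$snv_rate)
  for (i in seq_len(n_snv)) {
    p <- place_interval(1L, 10L, L - 10L, occupied, gap = 2L)
    if (is.na(p)) next
    add_occ(p, p)
    variants[[length(variants) + 1]] <- list(
      kind = "SNV", event = "SNV", pos = p, alt_base = other_base(base(p)),
      carriers = draw_carriers(NULL))
  }
  # random small indels
  n_indel <- rbinom(1L, L, config$small_indel_rate)
  for (i in seq_len(n_indel)) {
    len <- 1L + rgeom(1L, config$indel_geom_p)
    if (runif(1) < 0.5) {  # insertion
      p <- place_interval(2L, 10L, L - 10L, occupied, gap = 2L)
      if (is.na(p)) next
      add_occ(p, p + 1L)
      ins <- random_dna(len)
      while (substr(ins, len, len) == base(p)) {
        ins <- paste0(substr(ins, 1, len - 1), other_base(substr(ins, len, len)))
      }
      variants[[length(variants) + 1]] <- list(
        kind = "INS", event = "INS", pos = p, ins_seq = ins, nested = NULL,
        carriers = draw_carriers(NULL))
    } else {  # deletion
      placed <- FALSE
      for (t in 1:50) {
        p <- place_interval(len + 1L, 10L, L - 10L, occupied, gap = 2L)
        if (is.na(p)) break
        if (base(p) != base(p + len)) { placed <- TRUE; break }
      }
      if (!placed) next
      add_occ(p, p + len)
      variants[[length(variants) + 1]] <- list(
        kind = "DEL", event = "DEL", pos = p, del_len = len,
        carriers = draw_carriers(NULL))
    }
  }

  # --- graph realisation -----------------------------------------------------
  cuts <- c(0L, L)
  for (v in variants) {
    cuts <- c(cuts, switch(v$kind,
      SNV = c(v$pos - 1L, v$pos),
      INS = v$pos,
      DEL = c(v$pos, v$pos + v$del_len),
      DUP = c(v$a - 1L, v$b)))
  }
  cuts <- sort(unique(cuts))
  node_start <- head(cuts, -1) + 1L
  node_end <- tail(cuts, -1)
  n_ref_nodes <- length(node_start)

  seg_seqs <- character(); n_seg <- 0L
  new_node <- function(seq) {
    n_seg <<- n_seg + 1L
    seg_seqs[[n_seg]] <<- seq
    sprintf("s%05d", n_seg)
  }
  ref_node_ids <- vapply(seq_len(n_ref_nodes),
                         function(i) new_node(sub_seq(node_start[[i]], node_end[[i]])),
                         character(1))
  node_at <- function(p) which(node_start == p)  # index of ref node starting at p

  # alternate structures per variant
  for (i in seq_along(variants)) {
    v <- variants[[i]]
    if (v$kind == "SNV") {
      variants[[i]]$ref_node <- ref_node_ids[[node_at(v$pos)]]
      variants[[i]]$alt_node <- new_node(v$alt_base)
    } else if (v$kind == "INS") {
      qs <- if (is.null(v$nested)) integer() else vapply(v$nested, `[[`, integer(1), "offset")
      bounds <- c(0L, qs, nchar(v$ins_seq) + 1L)
      walk_ref <- list(); walk_alt <- list()
      for (j in seq_len(length(bounds) - 1)) {
        a <- bounds[[j]] + 1L; b <- bounds[[j + 1L]] - 1L
        if (j > 1) {  # the nested site itself
          q <- bounds[[j]]
          rn <- new_node(substr(v$ins_seq, q, q))
          an <- new_node(v$nested[[j - 1]]$alt_base)
          variants[[i]]$nested[[j - 1]]$ref_node <- rn
          variants[[i]]$nested[[j - 1]]$alt_node <- an
          walk_ref <- c(walk_ref, rn); walk_alt <- c(walk_alt, an)
        }
        if (b >= a) {
          piece <- new_node(substr(v$ins_seq, a, b))
          walk_ref <- c(walk_ref, piece); walk_alt <- c(walk_alt, piece)
        }
      }
      variants[[i]]$walk_ref <- unlist(walk_ref)
      variants[[i]]$walk_alt_nodes <- walk_alt  # parallel to walk_ref
    } else if (v$kind == "DUP") {
      variants[[i]]$block_idx <- which(node_start >= v$a & node_end <= v$b)
    } else if (v$kind == "DEL") {
      variants[[i]]$del_idx <- which(node_start >= v$pos + 1L & node_end <= v$pos + v$del_len)
    }
  }
  segments <- tibble(segment_id = sprintf("s%05d", seq_len(n_seg)),
                     sequence = unlist(seg_seqs))

  # walk construction per haplotype
  snv_at <- list(); ins_after <- list(); dup_after <- list(); del_nodes <- list()
  for (v in variants) {
    if (v$kind == "SNV") snv_at[[v$ref_node]] <- v
    if (v$kind == "INS") ins_after[[ref_node_ids[[node_at(v$pos + 1L) - 1L]]]] <- v
    if (v$kind == "DUP") dup_after[[ref_node_ids[[max(v$block_idx)]]]] <- v
    if (v$kind == "DEL") for (ix in v$del_idx) del_nodes[[ref_node_ids[[ix]]]] <- v
  }
  build_walk <- function(hap) {
    ids <- character(0)
    for (i in seq_len(n_ref_nodes)) {
      nid <- ref_node_ids[[i]]
      dv <- del_nodes[[nid]]
      if (!is.null(dv) && hap %in% dv$carriers) next
      sv <- snv_at[[nid]]
      ids <- c(ids, if (!is.null(sv) && hap %in% sv$carriers) sv$alt_node else nid)
      iv <- ins_after[[nid]]
      if (!is.null(iv) && hap %in% iv$carriers) {
        w <- iv$walk_ref
        if (!is.null(iv$nested)) {
          for (nv in iv$nested) {
            if (hap %in% nv$carriers) w[w == nv$ref_node] <- nv$alt_node
          }
        }
        ids <- c(ids, w)
      }
      uv <- dup_after[[nid]]
      if (!is.null(uv) && hap %in% uv$carriers) {
        ids <- c(ids, ref_node_ids[uv$block_idx])
      }
    }
    ids
  }
  path_names <- c(ref_path, alt_paths)
  walks <- c(list(ref_node_ids), purrr::map(alt_paths, build_walk))
  paths <- tibble(path_name = path_names, steps = purrr::map(walks, steps_tbl))
  links <- purrr::map_dfr(walks, function(w) {
    k <- length(w)
    if (k < 2) return(NULL)
    tibble(from_id = w[-k], from_orient = "+", to_id = w[-1], to_orient = "+")
  })
  graph <- pangenome(segments, links, paths, config$reference_sample)

  # --- truth set -------------------------------------------------------------
  n_called <- length(path_names)
  rows <- list(); vid <- 0L
  next_id <- function() { vid <<- vid + 1L; sprintf("v%04d", vid) }
  rec <- function(pos, ref, alt, event, carriers, parent_id = NA_character_,
                  sub_pos = NA_integer_, normalize = TRUE) {
    if (normalize) {
      nv <- normalize_variant(ref_seq, pos, ref, alt)
      pos <- nv$pos; ref <- nv$ref; alt <- nv$alt
    }
    n_car <- length(carriers)
    tibble(variant_id = next_id(), contig = config$contig, pos = as.integer(pos),
           ref = ref, alt = alt, kind = classify_alleles(ref, alt), event = event,
           carriers = list(carriers), n_carriers = n_car,
           n_called = n_called, af = n_car / n_called,
           parent_id = parent_id, sub_pos = sub_pos)
  }
  for (v in variants) {
    if (v$kind == "SNV") {
      rows[[length(rows) + 1]] <- rec(v$pos, base(v$pos), v$alt_base, v$event, v$carriers)
    } else if (v$kind == "INS") {
      parent <- rec(v$pos, base(v$pos), paste0(base(v$pos), v$ins_seq), v$event, v$carriers)
      rows[[length(rows) + 1]] <- parent
      if (!is.null(v$nested)) {
        for (nv in v$nested) {
          rows[[length(rows) + 1]] <- rec(
            parent$pos, nv$ref_base, nv$alt_base, "SNV", nv$carriers,
            parent_id = parent$variant_id,
            sub_pos = 1L + nv$offset, normalize = FALSE)
        }
      }
    } else if (v$kind == "DEL") {
      rows[[length(rows) + 1]] <- rec(v$pos, sub_seq(v$pos, v$pos + v$del_len),
                                      base(v$pos), v$event, v$carriers)
    } else if (v$kind == "DUP") {
      rows[[length(rows) + 1]] <- rec(v$a, sub_seq(v$a, v$b),
                                      paste0(sub_seq(v$a, v$b), sub_seq(v$a, v$b)),
                                      v$event, v$carriers)
    }
  }
  truth <- if (length(rows) > 0) {
    arrange(bind_rows(rows), .data$pos, .data$ref, .data$alt)
  } else {
    tibble(variant_id = character(), contig = character(), pos = integer(),
           ref = character(), alt = character(), kind = character(),
           event = character(), carriers = list(), n_carriers = integer(),
           n_called = integer(), af = numeric(), parent_id = character(),
           sub_pos = integer())
  }

  sequences <- c(setNames(ref_seq, ref_path),
                 setNames(purrr::map_chr(alt_paths, ~ path_sequence(graph, .x)),
                          alt_paths))
  list(graph = graph, truth = truth, sequences = sequences, config = config)
}

#' Write sequences as FASTA
#'
#' @param sequences Named character vector of DNA sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Build the K-locus model fixture
#'
#' Constructs a small graph shaped like the feathering (K) locus on the Z
#' chromosome: a backbone with a tandem-duplicated block and, further
#' downstream, an optional mobile-element insertion standing in for the
#' ev21 provirus. Seven diagnostic links are labelled `e1`-`e7`:
#' every path enters the locus over `e1`; at the duplication fork a path
#' either leaves over `e2` (early feathering, EF) or loops back over
#' `e3` and `e4` to traverse the duplicated block a second time (late
#' feathering, LF); at the insertion site a path either skips the element
#' over `e5` (ev21-) or traverses `e6`, the element sequence, then `e7`
#' (ev21+). Each sample is hemizygous (one haplotype path), as for a
#' Z-linked locus in female birds.
#'
#' @param genotypes Named character vector: sample name ->
#'   `"EF/ev21-"`, `"EF/ev21+"`, `"LF/ev21-"` or `"LF/ev21+"`. The
#'   reference sample `ref` is always added as `EF/ev21-`.
#' @param seed Seed for the (fixed) segment sequences.
#' @param element_length Length of the element insertion in bp.
#' @return A list with `graph`, `edges` (tibble: `edge`, `from_id`,
#'   `from_orient`, `to_id`, `to_orient`), `duplicated_segments`,
#'   `element_segments`, and `genotypes` (tibble: `sample`, `path_name`,
#'   `genotype`, `lf`, `ev21`).
#' @export
k_locus_fixture <- function(genotypes = c(bird_ef = "EF/ev21-",
                                          bird_lf = "LF/ev21-",
                                          bird_ev = "EF/ev21+",
                                          bird_lf_ev = "LF/ev21+"),
                            seed = 1L, element_length = 7500L) {
  stopifnot(all(genotypes %in% c("EF/ev21-", "EF/ev21+", "LF/ev21-", "LF/ev21+")))
  set.seed(seed)
  seqs <- c(A = random_dna(2000), D1 = random_dna(800), D2 = random_dna(700),
            S = random_dna(50), B = random_dna(1500), C = random_dna(1200),
            V = random_dna(element_length), E = random_dna(1800))
  segments <- tibble(segment_id = names(seqs), sequence = unname(seqs))
  edges <- tibble(
    edge = c("e1", "e2", "e3", "e4", "e5", "e6", "e7", "d12", "bc"),
    from_id = c("A", "D2", "D2", "S", "C", "C", "V", "D1", "B"),
    from_orient = "+",
    to_id = c("D1", "B", "S", "D1", "E", "V", "E", "D2", "C"),
    to_orient = "+"
  )
  contig <- "K"
  walk_for <- function(gt) {
    lf <- startsWith(gt, "LF")
    ev <- endsWith(gt, "ev21+")
    ids <- c("A", "D1", "D2",
             if (lf) c("S", "D1", "D2"),
             "B", "C",
             if (ev) "V",
             "E")
    steps_tbl(ids)
  }
  samples <- c("ref", names(genotypes))
  gts <- c("EF/ev21-", unname(genotypes))
  path_names <- pansn_name(samples, "1", contig)
  paths <- tibble(path_name = path_names,
                  steps = purrr::map(gts, walk_for))
  links <- select(edges, -"edge")
  graph <- pangenome(segments, links, paths, "ref")
  list(
    graph = graph,
    edges = filter(edges, startsWith(.data$edge, "e")),
    duplicated_segments = c("D1", "D2"),
    element_segments = "V",
    genotypes = tibble(sample = samples, path_name = path_names, genotype = gts,
                       lf = startsWith(gts, "LF"), ev21 = endsWith(gts, "ev21+"))
  )
}
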