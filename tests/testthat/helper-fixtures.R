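# Shared fixtures and independent oracles used across the test files.

# three-segment chain with one reference path
toy_chain <- function(seqs = c(a = "ACGTACGTAC", b = "TTTTT", c = "GGGGGGG"),
                      path_name = "ref#0#chr1", reference_sample = "ref") {
  ids <- names(seqs)
  pangenome(
    tibble::tibble(segment_id = ids, sequence = unname(seqs)),
    tibble::tibble(from_id = head(ids, -1), from_orient = "+",
                   to_id = ids[-1], to_orient = "+"),
    tibble::tibble(path_name = path_name, steps = list(steps_tbl(ids))),
    reference_sample
  )
}

# random multi-path graph (random orientations) for round-trip and
# coverage properties; links are derived from the walks plus extras
random_graph <- function(seed, max_segments = 8, max_samples = 4) {
  set.seed(seed)
  n_seg <- sample(2:max_segments, 1)
  ids <- sprintf("n%02d", seq_len(n_seg))
  seqs <- vapply(ids, function(i) {
    paste(sample(c("A", "C", "G", "T"), sample(1:12, 1), replace = TRUE),
          collapse = "")
  }, character(1))
  n_samp <- sample(1:max_samples, 1)
  paths <- list()
  nm <- character()
  for (s in seq_len(n_samp)) {
    for (h in seq_len(sample(1:2, 1))) {
      k <- sample(1:(2 * n_seg), 1)
      paths[[length(paths) + 1]] <- steps_tbl(
        sample(ids, k, replace = TRUE),
        sample(c("+", "-"), k, replace = TRUE))
      nm <- c(nm, sprintf("P%02d#%d#c%d", s, h, s))
    }
  }
  links <- purrr::map_dfr(paths, function(st) {
    k <- nrow(st)
    if (k < 2) return(NULL)
    tibble::tibble(from_id = st$segment_id[-k], from_orient = st$orient[-k],
                   to_id = st$segment_id[-1], to_orient = st$orient[-1])
  })
  pangenome(tibble::tibble(segment_id = ids, sequence = unname(seqs)),
            links, tibble::tibble(path_name = nm, steps = paths),
            reference_sample = "P01")
}

# naive reimplementation of the greedy accessory-attribution rule
brute_force_attribution <- function(g, base_sample) {
  lens <- setNames(nchar(g$segments$sequence), g$segments$segment_id)
  per_sample <- list()
  for (i in seq_len(nrow(g$paths))) {
    s <- g$paths$sample[[i]]
    per_sample[[s]] <- union(per_sample[[s]], g$paths$steps[[i]]$segment_id)
  }
  left <- setdiff(names(lens), per_sample[[base_sample]])
  remaining <- sort(setdiff(names(per_sample), base_sample))
  out <- list()
  while (length(remaining) > 0) {
    best <- NULL; best_sum <- -1
    for (s in remaining) {  # 'remaining' is sorted, so ties pick the first
      v <- sum(lens[intersect(per_sample[[s]], left)])
      if (v > best_sum) { best <- s; best_sum <- v }
    }
    out[[length(out) + 1]] <- list(sample = best, bp = best_sum)
    left <- setdiff(left, per_sample[[best]])
    remaining <- setdiff(remaining, best)
  }
  list(order = vapply(out, `[[`, character(1), "sample"),
       bp = vapply(out, `[[`, numeric(1), "bp"),
       residual = sum(lens[left]))
}

# independent decision-rule oracle for the SV genotyper: exact two-sided
# binomial p by enumeration of point probabilities
enum_binom_p <- function(k, n, theta) {
  d <- dbinom(0:n, n, theta)
  sum(d[d <= d[[k + 1]] * (1 + 1e-7)])
}
oracle_sv_call <- function(k_p, k_a, theta_p, theta_a, alpha = 0.05,
                           min_reads = 4) {
  n <- k_p + k_a
  if (n < min_reads) return("no_data")
  pp <- enum_binom_p(k_p, n, theta_p)
  pa <- enum_binom_p(k_p, n, theta_a)
  if (pp > alpha && pa <= alpha) "present"
  else if (pa > alpha && pp <= alpha) "absent"
  else "inconclusive"
}

# per-cell brute-force genotype agreement between two genotype tables
brute_force_concordance <- function(a, b) {
  samples <- names(a$gt[[1]])
  per_sample <- numeric(length(samples)); names(per_sample) <- samples
  cell <- matrix(NA, nrow(a), length(samples))
  for (i in seq_len(nrow(a))) {
    for (s in seq_along(samples)) {
      ga <- a$gt[[i]][[samples[[s]]]]; gb <- b$gt[[i]][[samples[[s]]]]
      expand <- function(gt, ref, alt) {
        if (is.na(gt)) return(NULL)
        ix <- strsplit(gt, "[/|]")[[1]]
        if (any(ix == ".")) return(NULL)
        sort(c(ref, alt)[as.integer(ix) + 1])
      }
      ea <- expand(ga, a$ref[[i]], a$alt[[i]])
      eb <- expand(gb, b$ref[[i]], b$alt[[i]])
      cell[i, s] <- (is.null(ea) && is.null(eb)) ||
        (!is.null(ea) && !is.null(eb) && identical(ea, eb))
    }
  }
  list(per_sample = 100 * colMeans(cell),
       per_variant = 100 * rowMeans(cell))
}

ref_path_of <- function(sim) sim$graph$paths$path_name[
  sim$graph$paths$sample == sim$config$reference_sample][1]

variant_key <- function(x) {
  paste(x$contig, x$pos, x$ref, x$alt, x$kind,
        purrr::map_chr(x$carriers, paste, collapse = ","))
}
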