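make_ref <- function(len = 4000, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

test_that("pileups count aligned bases with mapq, flag and depth filters", {
  ref <- make_ref()
  # 12 reads at one site, 6 ref / 6 alt
  ha <- simulate_het_alignments(ref, positions = 500L, depth = 12,
                                alt_prob = 0.5, seed = 33)
  # force exactly 6 alt
  p <- 500L; start <- ha$records$pos[[1]]; off <- p - start + 1L
  base_at <- substr(ha$records$seq, off, off)
  ref_b <- substr(ref, p, p)
  want <- rep(c(ref_b, ha$sites$alt_base[[1]]), each = 6)
  substr(ha$records$seq, off, off) <- want
  sam <- tempfile(fileext = ".sam")
  write_sam(ha$records, ha$contigs, sam)
  pu <- pileup_sites(sam, setNames(ref, "chr1"))
  row <- pu[pu$pos == 500, ]
  expect_equal(row$depth, 12L)
  counts <- sort(as.integer(row[, c("A", "C", "G", "T")]), decreasing = TRUE)
  expect_equal(counts[1:2], c(6L, 6L))

  # a read with mapq 9 is excluded entirely
  recs <- ha$records
  recs$mapq[[1]] <- 9L
  write_sam(recs, ha$contigs, sam)
  pu2 <- pileup_sites(sam, setNames(ref, "chr1"), min_mapq = 10)
  expect_equal(pu2$depth[pu2$pos == 500], 11L)

  # 150 reads over one base with cap 100 -> depth exactly 100
  ha3 <- simulate_het_alignments(ref, positions = 1000L, depth = 150,
                                 alt_prob = 0.5, seed = 34)
  write_sam(ha3$records, ha3$contigs, sam)
  pu3 <- pileup_sites(sam, setNames(ref, "chr1"), depth_cap = 100)
  expect_equal(pu3$depth[pu3$pos == 1000], 100L)

  # secondary records are excluded when requested
  recs4 <- ha$records
  recs4$flag[1:3] <- 0x100
  write_sam(recs4, ha$contigs, sam)
  pu4 <- pileup_sites(sam, setNames(ref, "chr1"))
  expect_equal(pu4$depth[pu4$pos == 500], 9L)

  # unknown contig in the reference errors
  expect_error(pileup_sites(sam, setNames(ref, "other")), "absent")
})

test_that("deletions and insertions in CIGARs contribute no aligned base", {
  ref <- make_ref(200)
  recs <- tibble::tibble(
    qname = c("del_read", "ins_read"), flag = 0L, rname = "chr1",
    pos = c(10L, 50L), mapq = 60L,
    cigar = c("5M3D5M", "5M2I3M"),
    seq = c(paste0(substr(ref, 10, 14), substr(ref, 18, 22)),
            paste0(substr(ref, 50, 54), "GG", substr(ref, 55, 57))))
  sam <- tempfile(fileext = ".sam")
  write_sam(recs, c(chr1 = 200L), sam)
  pu <- pileup_sites(sam, setNames(ref, "chr1"))
  expect_false(any(pu$pos %in% 15:17))       # deleted positions uncovered
  expect_equal(sum(pu$pos %in% 50:57), 8L)   # insertion skipped, M bases only
  expect_true(all(pu$ref_base == purrr::map_chr(pu$pos,
                                                ~ substr(ref, .x, .x))))
})

test_that("the het-site filter implements depth >= 10 and minor >= 25%", {
  mk <- function(A, C, G = 0L, T = 0L, ref_base = "A") tibble::tibble(
    contig = "c", pos = 1L, ref_base = ref_base, A = A, C = C, G = G, T = T,
    depth = A + C + G + T)
  expect_equal(nrow(find_het_sites(mk(5L, 4L))), 0)        # depth 9
  expect_equal(nrow(find_het_sites(mk(16L, 4L))), 0)       # minor 20%
  hs <- find_het_sites(mk(6L, 6L))
  expect_equal(nrow(hs), 1)
  expect_equal(hs$alt_fraction, 0.5)
  expect_equal(hs$alt_base, "C")

  # exhaustive: membership is a pure function of depth and top-two counts
  for (depth in 1:30) {
    for (a in 0:depth) {
      site <- mk(as.integer(a), as.integer(depth - a))
      kept <- nrow(find_het_sites(site)) == 1
      minor <- min(a, depth - a)  # top-two counts are a and depth - a
      expect_equal(kept, depth >= 10 && minor / depth >= 0.25)
    }
  }
})

test_that("bias statistics follow the |mean - 0.5| definition", {
  sites <- tibble::tibble(alt_fraction = rep(0.5, 10))
  b <- alt_fraction_stats(sites)
  expect_equal(b$bias, 0)
  b2 <- alt_fraction_stats(tibble::tibble(alt_fraction = c(0.4, 0.5)))
  expect_equal(b2$bias, 0.05)
  expect_equal(b2$direction, -1)
  expect_equal(bias_reduction(0.05, 0.031), 38)
  expect_equal(bias_reduction(0.04, 0.04), 0)
  expect_error(bias_reduction(0, 0.01), "undefined")
  expect_error(alt_fraction_stats(sites[0, ]), "no heterozygous")
})

test_that("injected alt probabilities are recovered through the full pileup", {
  ref <- make_ref(30000, seed = 9)
  positions <- seq(100L, 29900L, by = 60L)  # ~500 isolated sites
  ha <- simulate_het_alignments(ref, positions, depth = 30, alt_prob = 0.4,
                                read_length = 40L, seed = 44)
  sam <- tempfile(fileext = ".sam")
  write_sam(ha$records, ha$contigs, sam)
  pu <- pileup_sites(sam, setNames(ref, "chr1"))
  at_sites <- pu[pu$pos %in% positions, ]
  expect_equal(nrow(at_sites), length(positions))
  expect_true(all(at_sites$depth == 30))
  hs <- find_het_sites(at_sites, min_depth = 0, min_minor_frac = 0)
  b <- alt_fraction_stats(hs)
  # binomial sampling oracle: the mean matches the empirical alt total
  expect_equal(b$mean_alt_fraction, mean(ha$sites$n_alt / 30))
  se <- sqrt(0.4 * 0.6 / 30 / length(positions))
  expect_lt(abs(b$mean_alt_fraction - 0.4), 3 * se + 0.005)
})
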