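test_that("a 25/5 SNV split yields one two-allele bubble at 17%", {
  sim <- generate_pangenome(sim_config(
    seed = 21, ref_length = 5000, n_haplotypes = 30, snv_rate = 0,
    small_indel_rate = 0,
    structural_events = list(struct_event("SNV", carriers = 1:5))))
  bub <- detect_bubbles(sim$graph)
  expect_equal(nrow(bub), 1)
  expect_equal(nrow(bub$ref_walk[[1]]), 1)
  walk_keys <- unique(purrr::map_chr(
    bub$hap_walks[[1]], ~ paste(.x$segment_id, collapse = ",")))
  expect_length(walk_keys, 2)  # reference node or single alt node
  rec <- call_variants(sim$graph)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$kind, "SNV")
  expect_equal(rec$af, 5 / 30)
  expect_equal(round(100 * rec$af), 17)
  expect_equal(nchar(rec$ref), 1)
  expect_equal(nchar(rec$alt), 1)
})

test_that("a single-haplotype deletion bubble has an empty allele walk", {
  sim <- generate_pangenome(sim_config(
    seed = 22, ref_length = 20000, n_haplotypes = 30, snv_rate = 0,
    small_indel_rate = 0,
    structural_events = list(struct_event("DEL", 5000, carriers = 1))))
  bub <- detect_bubbles(sim$graph)
  expect_equal(nrow(bub), 1)
  carrier <- sim$truth$carriers[[1]][[1]]
  expect_equal(nrow(bub$hap_walks[[1]][[carrier]]), 0)
  other <- setdiff(names(bub$hap_walks[[1]]), carrier)[[1]]
  expect_gt(nrow(bub$hap_walks[[1]][[other]]), 0)
  rec <- call_variants(sim$graph)
  expect_equal(rec$kind, "DEL")
  expect_equal(rec$af, 1 / 30)
  expect_equal(nchar(rec$ref) - nchar(rec$alt), 5000)
})

test_that("an insertion with an internal SNV yields a parent plus a nested record", {
  sim <- generate_pangenome(sim_config(
    seed = 23, ref_length = 10000, n_haplotypes = 24, snv_rate = 0,
    small_indel_rate = 0,
    structural_events = list(
      struct_event("INS", 300, carriers = 1:22, nested_snv_count = 1))))
  rec <- call_variants(sim$graph)
  expect_equal(nrow(rec), 2)
  parent <- rec[is.na(rec$parent_id), ]
  child <- rec[!is.na(rec$parent_id), ]
  expect_equal(parent$kind, "INS")
  expect_equal(child$kind, "SNV")
  expect_equal(child$parent_id, parent$variant_id)
  # the parent stays biallelic: insertion carriers all share allele 1
  gt <- parent$genotypes[[1]]
  expect_equal(sum(gt == 1, na.rm = TRUE), 22)
  expect_setequal(variant_key(rec), variant_key(sim$truth))
})

test_that("called records match generator truth exactly across mixed configs", {
  for (seed in c(31, 32, 33)) {
    sim <- generate_pangenome(sim_config(
      seed = seed, ref_length = 30000, n_haplotypes = 10, snv_rate = 1e-3,
      small_indel_rate = 2e-4,
      structural_events = list(
        struct_event("INS", 300, carriers = 1:4, nested_snv_count = 2),
        struct_event("DEL", 2000, carriers = 1:2),
        struct_event("DUP", 400, carriers = 3:4),
        struct_event("ELEMENT_INS", 2500, carriers = c(2, 5)))))
    called <- call_variants(sim$graph)
    expect_setequal(variant_key(called), variant_key(sim$truth))
    # editing oracle: called alleles rebuild every haplotype sequence
    ref_seq <- sim$sequences[[ref_path_of(sim)]]
    for (h in setdiff(names(sim$sequences), ref_path_of(sim))) {
      expect_identical(apply_variants(ref_seq, called, h), sim$sequences[[h]])
    }
    # per-site allele frequencies of ref + alt sum to 1 for biallelic sites
    bial <- called[!grepl(",", called$alt) & is.na(called$parent_id), ]
    gt_ref_frac <- purrr::map_dbl(bial$genotypes, ~ mean(.x == 0, na.rm = TRUE))
    expect_equal(gt_ref_frac + bial$af, rep(1, nrow(bial)))
  }
})

test_that("variant summaries add up", {
  expect_equal(summarize_variants(
    tibble::tibble(variant_id = character(), contig = character(),
                   pos = integer(), ref = character(), alt = character(),
                   kind = character(), carriers = list(),
                   parent_id = character(), sub_pos = integer())
  )$by_kind$n, rep(0L, 4))

  rec <- tibble::tibble(
    variant_id = c("v1", "v2"), contig = "c", pos = c(10L, 100L),
    ref = c("A", paste0("A", strrep("C", 5000))),
    alt = c(paste0("A", strrep("G", 300)), "A"),
    kind = c("INS", "DEL"), carriers = list("h1", "h2"),
    parent_id = NA_character_, sub_pos = NA_integer_)
  s <- summarize_variants(rec)
  expect_equal(s$by_kind$total_bp[s$by_kind$kind == "INS"], 300)
  expect_equal(s$by_kind$total_bp[s$by_kind$kind == "DEL"], 5000)
  expect_equal(sum(s$length_histogram$n), 2)

  sim <- generate_pangenome(sim_config(
    seed = 41, ref_length = 20000, n_haplotypes = 8, snv_rate = 1e-3,
    small_indel_rate = 2e-4))
  s2 <- summarize_variants(sim$truth)
  expect_equal(sum(s2$by_kind$n), nrow(sim$truth))
  # oracle: totals computed directly from the truth alleles
  dlen <- abs(nchar(sim$truth$alt) - nchar(sim$truth$ref))
  expect_equal(s2$by_kind$total_bp[s2$by_kind$kind == "SNV"],
               sum(sim$truth$kind == "SNV"))
  expect_equal(s2$by_kind$total_bp[s2$by_kind$kind == "INS"],
               sum(dlen[sim$truth$kind == "INS"]))
  expect_equal(s2$by_kind$total_bp[s2$by_kind$kind == "DEL"],
               sum(dlen[sim$truth$kind == "DEL"]))
})

test_that("normalisation left-aligns and anchors indels", {
  #         123456789
  ref <- "GGATATATCC"
  # deleting the 2nd AT (pos 5-6) left-aligns to pos 2 anchored on G
  nv <- normalize_variant(ref, 5, "AT", "")
  expect_equal(nv$pos, 2L)
  expect_equal(nv$ref, "GAT")
  expect_equal(nv$alt, "G")
  # SNVs pass through
  expect_equal(normalize_variant(ref, 4, "T", "C"),
               list(pos = 4L, ref = "T", alt = "C"))
  expect_equal(classify_alleles(c("A", "A", "ACC", "AC"),
                                c("G", "ACC", "A", "GG")),
               c("SNV", "INS", "DEL", "COMPLEX"))
})

test_that("VCF output round trips through a standard reader", {
  sim <- generate_pangenome(sim_config(
    seed = 51, ref_length = 15000, n_haplotypes = 8, snv_rate = 1e-3,
    small_indel_rate = 2e-4,
    structural_events = list(
      struct_event("INS", 200, carriers = 1:4, nested_snv_count = 1))))
  rec <- call_variants(sim$graph)
  f <- tempfile(fileext = ".vcf")
  write_vcf(rec, f, samples = sim$graph$paths$path_name,
            contig_lengths = c(chr1 = 15000))
  v <- read_vcf(f)
  expect_equal(nrow(v), nrow(rec))
  expect_equal(v$pos, rec$pos)
  expect_equal(v$ref, rec$ref)
  expect_equal(purrr::map_chr(v$alt, paste, collapse = ","), rec$alt)
  carr <- purrr::map(v$gt, ~ sort(names(.x)[.x == "1"]))
  expect_equal(carr, purrr::map(rec$carriers, sort))
  # an INS REF is the single anchor base
  ins <- v[grepl("KIND=INS", v$info), ]
  expect_true(all(nchar(ins$ref) == 1))
  # PARENT/SUBPOS survive in INFO
  expect_true(any(grepl("PARENT=", v$info)))
  # unsorted input is rejected
  expect_error(write_vcf(rec[c(2, 1), ], samples = "x"), "sorted")
})
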