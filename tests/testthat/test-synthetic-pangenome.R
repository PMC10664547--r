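test_that("zero rates and no events give identical paths on a single chain", {
  sim <- generate_pangenome(sim_config(seed = 3, ref_length = 2000,
                                       n_haplotypes = 5, snv_rate = 0,
                                       small_indel_rate = 0))
  expect_equal(nrow(sim$graph$segments), 1)
  expect_equal(nrow(sim$truth), 0)
  expect_true(all(sim$sequences == sim$sequences[[1]]))
})

test_that("explicit SNV carriers land in the truth set exactly", {
  # one SNV carried by 5 of 30 haplotypes
  sim <- generate_pangenome(sim_config(
    seed = 4, ref_length = 5000, n_haplotypes = 30, snv_rate = 0,
    small_indel_rate = 0,
    structural_events = list(struct_event("SNV", carriers = 1:5))))
  expect_equal(nrow(sim$truth), 1)
  expect_equal(sim$truth$n_carriers, 5L)
  expect_equal(sim$truth$n_called, 30L)
  expect_equal(sim$truth$kind, "SNV")
  expect_length(sim$truth$carriers[[1]], 5)
})

test_that("an insertion with nested SNVs is realised as nested bubbles", {
  sim <- generate_pangenome(sim_config(
    seed = 5, ref_length = 10000, n_haplotypes = 24, snv_rate = 0,
    small_indel_rate = 0,
    structural_events = list(
      struct_event("INS", length = 300, carriers = 1:22,
                   nested_snv_count = 2))))
  expect_equal(sum(is.na(sim$truth$parent_id)), 1)
  nested <- sim$truth[!is.na(sim$truth$parent_id), ]
  expect_equal(nrow(nested), 2)
  parent <- sim$truth[is.na(sim$truth$parent_id), ]
  expect_equal(parent$kind, "INS")
  expect_equal(nchar(parent$alt) - nchar(parent$ref), 300)
  expect_true(all(nested$parent_id == parent$variant_id))
  expect_true(all(nested$sub_pos > 1 & nested$sub_pos <= nchar(parent$alt)))
  # nested carriers are a subset of the insertion carriers
  for (cs in nested$carriers) {
    expect_true(all(cs %in% parent$carriers[[1]]))
  }
  # the insertion bubble's internal nodes host two sub-bubbles: the
  # carriers traverse off-reference nodes, some of which differ between
  # carriers with and without the nested alleles
  ref_nodes <- sim$graph$paths$steps[[
    match(ref_path_of(sim), sim$graph$paths$path_name)]]$segment_id
  carrier <- parent$carriers[[1]][[1]]
  cn <- sim$graph$paths$steps[[
    match(carrier, sim$graph$paths$path_name)]]$segment_id
  expect_gte(length(setdiff(cn, ref_nodes)), 3)  # pieces + site nodes
})

test_that("generation is byte-deterministic under the seed", {
  cfg <- sim_config(seed = 11, ref_length = 8000, n_haplotypes = 6,
                    snv_rate = 1e-3, small_indel_rate = 2e-4,
                    structural_events = list(
                      struct_event("DEL", 500, carriers = 1),
                      struct_event("DUP", 200, carriers = 2:3)))
  s1 <- generate_pangenome(cfg)
  s2 <- generate_pangenome(cfg)
  expect_identical(write_gfa(s1$graph, version = "1.1"),
                   write_gfa(s2$graph, version = "1.1"))
  expect_identical(s1$sequences, s2$sequences)
  expect_identical(write_vcf(s1$truth, samples = s1$graph$paths$path_name),
                   write_vcf(s2$truth, samples = s2$graph$paths$path_name))
})

test_that("each haplotype equals the reference edited by its truth variants", {
  for (seed in c(2, 9)) {
    sim <- generate_pangenome(sim_config(
      seed = seed, ref_length = 20000, n_haplotypes = 8, snv_rate = 1e-3,
      small_indel_rate = 2e-4,
      structural_events = list(
        struct_event("INS", 300, carriers = 1:4, nested_snv_count = 2),
        struct_event("DEL", 1000, carriers = 1),
        struct_event("DUP", 250, carriers = 2:3),
        struct_event("ELEMENT_INS", 1500, carriers = c(2, 5)))))
    ref_seq <- sim$sequences[[ref_path_of(sim)]]
    for (h in setdiff(names(sim$sequences), ref_path_of(sim))) {
      expect_identical(apply_variants(ref_seq, sim$truth, h),
                       sim$sequences[[h]])
    }
  }
})

test_that("every truth variant leaves a mark off the reference path", {
  sim <- generate_pangenome(sim_config(
    seed = 13, ref_length = 15000, n_haplotypes = 6, snv_rate = 5e-4,
    small_indel_rate = 1e-4,
    structural_events = list(struct_event("DUP", 300, carriers = 1))))
  ref_i <- match(ref_path_of(sim), sim$graph$paths$path_name)
  ref_steps <- sim$graph$paths$steps[[ref_i]]
  ref_nodes <- ref_steps$segment_id
  ref_edges <- pangraphr::canonical_links(tibble::tibble(
    from_id = head(ref_nodes, -1), from_orient = "+",
    to_id = ref_nodes[-1], to_orient = "+"))
  ref_keys <- with(ref_edges, paste(from_id, from_orient, to_id, to_orient))
  for (i in seq_len(nrow(sim$truth))) {
    marks <- purrr::map_lgl(sim$truth$carriers[[i]], function(h) {
      st <- sim$graph$paths$steps[[match(h, sim$graph$paths$path_name)]]
      extra_nodes <- length(setdiff(st$segment_id, ref_nodes)) > 0
      ek <- pangraphr::canonical_links(tibble::tibble(
        from_id = head(st$segment_id, -1), from_orient = head(st$orient, -1),
        to_id = st$segment_id[-1], to_orient = st$orient[-1]))
      extra_edges <- length(setdiff(
        with(ek, paste(from_id, from_orient, to_id, to_orient)), ref_keys)) > 0
      extra_nodes || extra_edges
    })
    expect_true(any(marks))
  }
})

test_that("the K-locus fixture has the documented walk structure", {
  kfix <- k_locus_fixture()
  g <- kfix$graph
  step_ids <- function(p) g$paths$steps[[match(p, g$paths$path_name)]]$segment_id
  # EF/ev21- covers every node exactly once and uses e1, e2, e5
  ef <- step_ids("bird_ef#1#K")
  expect_equal(ef, c("A", "D1", "D2", "B", "C", "E"))
  expect_false(anyDuplicated(ef) > 0)
  # LF traverses the duplicated block twice
  lf <- step_ids("bird_lf#1#K")
  expect_equal(sum(lf == "D1"), 2)
  expect_equal(sum(lf == "D2"), 2)
  # ev21+ includes the element between e6 and e7; ev21- does not
  expect_true("V" %in% step_ids("bird_ev#1#K"))
  expect_false("V" %in% ef)
  expect_equal(sort(kfix$edges$edge), paste0("e", 1:7))
  expect_identical(k_locus_fixture()$graph$segments, g$segments)
})
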