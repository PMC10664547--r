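test_that("path coverage counts traversals exactly", {
  g <- toy_chain()
  cov <- node_path_coverage(g)
  expect_true(all(cov$count == 1))
  # conservation: sum(count * length) equals the path length, and the
  # counts equal a brute-force step tally, on random graphs
  for (seed in 1:25) {
    rg <- random_graph(seed)
    cov <- node_path_coverage(rg)
    lens <- setNames(nchar(rg$segments$sequence), rg$segments$segment_id)
    st <- pangenome_stats(rg)
    for (pn in rg$paths$path_name) {
      cc <- cov[cov$path_name == pn, ]
      expect_equal(sum(cc$count * lens[cc$segment_id]),
                   st$path_lengths$path_length[
                     st$path_lengths$path_name == pn])
      steps <- rg$paths$steps[[match(pn, rg$paths$path_name)]]
      tally <- table(steps$segment_id)
      expect_equal(cc$count[match(names(tally), cc$segment_id)],
                   as.integer(tally), ignore_attr = TRUE)
    }
  }
})

test_that("duplication runs are maximal and not merged across gaps", {
  kfix <- k_locus_fixture()
  cov <- node_path_coverage(kfix$graph)
  dups <- detect_duplications(cov, kfix$graph)
  lf_paths <- kfix$genotypes$path_name[kfix$genotypes$lf]
  expect_setequal(unique(dups$path_name), lf_paths)
  for (p in lf_paths) {
    runs <- dups[dups$path_name == p, ]
    expect_equal(nrow(runs), 1)
    expect_setequal(runs$segments[[1]], kfix$duplicated_segments)
    expect_equal(runs$max_count, 2L)
  }
  # no duplication -> empty
  expect_equal(nrow(detect_duplications(node_path_coverage(toy_chain()),
                                        toy_chain())), 0)
  # two disjoint duplicated blocks stay two runs
  sim <- generate_pangenome(sim_config(
    seed = 71, ref_length = 20000, n_haplotypes = 4, snv_rate = 0,
    small_indel_rate = 0,
    structural_events = list(struct_event("DUP", 300, carriers = 1),
                             struct_event("DUP", 200, carriers = 1))))
  d2 <- detect_duplications(node_path_coverage(sim$graph), sim$graph)
  carrier <- sim$truth$carriers[[1]][[1]]
  expect_equal(nrow(d2[d2$path_name == carrier, ]), 2)
})

test_that("edge support requires the junction to be covered on both sides", {
  g <- toy_chain(c(a = strrep("A", 10), b = strrep("C", 10)))
  ev <- sv_event("e", presence_edges = "a+>b+", absence_edges = "a+>a+",
                 theta_present = 0.98)
  mk_gaf <- function(ps, pe) tibble::tibble(
    read_id = "r", read_length = pe - ps, read_start = 0L,
    read_end = pe - ps, strand = "+", walk = list(steps_tbl(c("a", "b"))),
    path_length = 20L, path_start = as.integer(ps), path_end = as.integer(pe),
    n_match = pe - ps, aln_length = pe - ps, mapq = 60L)
  count_of <- function(gaf) {
    s <- count_edge_support(gaf, g, ev)
    s$count[s$role == "presence"]
  }
  expect_equal(count_of(mk_gaf(5, 15)), 1L)   # spans the junction
  expect_equal(count_of(mk_gaf(5, 10)), 0L)   # ends exactly at the junction
  expect_equal(count_of(mk_gaf(10, 15)), 0L)  # starts exactly at the junction
  expect_equal(count_of(mk_gaf(9, 11)), 1L)   # one base on each side
  # unknown walk segments are skipped with a warning
  bad <- mk_gaf(5, 15); bad$walk <- list(steps_tbl(c("a", "zz")))
  expect_warning(s <- count_edge_support(bad, g, ev), "skipped")
  expect_equal(attr(s, "n_skipped"), 1L)
})

test_that("the genotyper reproduces the decision table", {
  ins <- sv_event("ins", "a+>b+", "a+>c+", theta_present = 0.98,
                  theta_absent = 0.02)
  expect_equal(genotype_sv(list(k_presence = 30, k_absence = 0), ins)$call,
               "present")
  expect_equal(genotype_sv(list(k_presence = 0, k_absence = 30), ins)$call,
               "absent")
  expect_equal(genotype_sv(list(k_presence = 1, k_absence = 1), ins)$call,
               "no_data")
  ins2 <- sv_event("ins", "a+>b+", "a+>c+", min_reads = 2)
  expect_equal(genotype_sv(list(k_presence = 1, k_absence = 1), ins2)$call,
               "inconclusive")
  expect_error(sv_event("x", "a+>b+", "a+>c+", theta_present = 0.5,
                        theta_absent = 0.5), "theta")

  # exhaustive agreement with an enumeration oracle for all n <= 6
  for (theta in list(c(0.98, 0.02), c(0.5, 0.02))) {
    for (n in 0:6) for (k in 0:n) {
      expect_equal(
        genotype_sv(list(k_presence = k, k_absence = n - k), ins_theta <-
                      sv_event("e", "a+>b+", "a+>c+",
                               theta_present = theta[[1]],
                               theta_absent = theta[[2]]))$call,
        oracle_sv_call(k, n - k, theta[[1]], theta[[2]]))
    }
  }
})

test_that("calls are monotone: more presence reads never flip present to absent", {
  ev <- sv_event("e", "a+>b+", "a+>c+", theta_present = 0.5,
                 theta_absent = 0.02)
  rank_of <- c(absent = 1, inconclusive = 2, no_data = 2, present = 3)
  for (k_a in c(0, 3, 10, 20)) {
    calls <- vapply(0:(40 - k_a), function(k_p) {
      genotype_sv(list(k_presence = k_p, k_absence = k_a), ev)$call
    }, character(1))
    seen_present <- FALSE
    for (cl in calls) {
      if (cl == "present") seen_present <- TRUE
      if (seen_present) expect_false(cl == "absent")
    }
  }
})

test_that("simulated event read counts recover the genotype almost always", {
  set.seed(401)
  n_events <- 500
  coverage <- 30
  ins <- sv_event("ins", "a+>b+", "a+>c+", theta_present = 0.98,
                  theta_absent = 0.02)
  dup <- sv_event("dup", "a+>b+", "a+>c+", theta_present = 0.5,
                  theta_absent = 0.02)
  models <- list(ins, dup)
  truth <- sample(c("present", "absent"), n_events, replace = TRUE)
  which_model <- sample(1:2, n_events, replace = TRUE)
  calls <- character(n_events)
  for (i in seq_len(n_events)) {
    m <- models[[which_model[[i]]]]
    theta <- if (truth[[i]] == "present") m$theta_present else m$theta_absent
    k_p <- rbinom(1, coverage, theta)
    calls[[i]] <- genotype_sv(list(k_presence = k_p,
                                   k_absence = coverage - k_p), m)$call
  }
  # no present <-> absent swaps at all, and conclusive calls are >= 99%
  # correct; a small fraction of true events is inconclusive by
  # construction of the decision rule (both hypotheses can be rejected at
  # borderline counts, e.g. 9/30 presence reads under theta 0.5)
  expect_equal(sum(calls == "present" & truth == "absent") +
                 sum(calls == "absent" & truth == "present"), 0)
  conclusive <- calls %in% c("present", "absent")
  expect_gte(mean(calls[conclusive] == truth[conclusive]), 0.99)
  expect_lte(mean(!conclusive), 0.05)
})

test_that("K-locus events genotype correctly and independently from reads", {
  kfix <- k_locus_fixture(seed = 8)
  events <- list(
    sv_event("ev21", presence_edges = c("C+>V+", "V+>E+"),
             absence_edges = "C+>E+", theta_present = 0.98),
    sv_event("dup", presence_edges = "D2+>S+", absence_edges = "D2+>B+",
             theta_present = 0.5))
  gt <- kfix$genotypes[kfix$genotypes$sample != "ref", ]
  lens <- nchar(kfix$graph$segments$sequence)
  names(lens) <- kfix$graph$segments$segment_id
  gafs <- list()
  for (i in seq_len(nrow(gt))) {
    st <- kfix$graph$paths$steps[[
      match(gt$path_name[[i]], kfix$graph$paths$path_name)]]
    plen <- sum(lens[st$segment_id])
    sim <- simulate_reads(kfix$graph, n_pairs = ceiling(30 * plen / 300),
                          path_names = gt$path_name[[i]],
                          model = error_model(0, 0), seed = 500 + i)
    gafs[[gt$sample[[i]]]] <- truth_gaf(sim, kfix$graph)
  }
  calls <- genotype_sv_samples(gafs, kfix$graph, events)
  merged <- dplyr::left_join(
    calls,
    dplyr::bind_rows(
      tibble::tibble(event = "ev21", sample = gt$sample,
                     truth = ifelse(gt$ev21, "present", "absent")),
      tibble::tibble(event = "dup", sample = gt$sample,
                     truth = ifelse(gt$lf, "present", "absent"))),
    by = c("event", "sample"))
  expect_equal(merged$call, merged$truth)
  # in particular the two events separate: LF without ev21 and ev21
  # without LF are both called correctly
  lf_only <- merged[merged$sample == "bird_lf", ]
  expect_equal(lf_only$call[lf_only$event == "dup"], "present")
  expect_equal(lf_only$call[lf_only$event == "ev21"], "absent")
  ev_only <- merged[merged$sample == "bird_ev", ]
  expect_equal(ev_only$call[ev_only$event == "dup"], "absent")
  expect_equal(ev_only$call[ev_only$event == "ev21"], "present")
})
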