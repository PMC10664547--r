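test_that("path sequences concatenate steps with reverse complements", {
  g <- toy_chain(c(A = "ACG", B = "T", C = "GG"))
  expect_equal(path_sequence(g, "ref#0#chr1"), "ACGTGG")

  # a '-' step contributes the reverse complement
  g2 <- pangenome(
    tibble::tibble(segment_id = c("A", "B"), sequence = c("ACG", "AAC")),
    tibble::tibble(from_id = "A", from_orient = "+", to_id = "B",
                   to_orient = "-"),
    tibble::tibble(path_name = "ref#0#c",
                   steps = list(steps_tbl(c("A", "B"), c("+", "-")))),
    "ref")
  expect_equal(path_sequence(g2, "ref#0#c"), "ACGGTT")
  expect_equal(reverse_complement("AAC"), "GTT")
})

test_that("a duplicated block gives path length A + 2B + C over A + B + C", {
  segs <- tibble::tibble(segment_id = c("A", "B", "C"),
                         sequence = c("ACGTACGTAC", "TTTTT", "GGGGGGG"))
  links <- tibble::tibble(from_id = c("A", "B", "B"), from_orient = "+",
                          to_id = c("B", "C", "B"), to_orient = "+")
  paths <- tibble::tibble(
    path_name = c("ref#0#c", "dup#1#c"),
    steps = list(steps_tbl(c("A", "B", "C")),
                 steps_tbl(c("A", "B", "B", "C"))))
  g <- pangenome(segs, links, paths, "ref")
  expect_equal(path_sequence(g, "dup#1#c"), "ACGTACGTACTTTTTTTTTTGGGGGGG")
  st <- pangenome_stats(g)
  expect_equal(st$total_length, 22)  # A + B + C
  pl <- st$path_lengths
  expect_equal(pl$path_length[pl$path_name == "dup#1#c"], 27)  # A + 2B + C
  expect_equal(st$sample_lengths$traversed_length[
    st$sample_lengths$sample == "dup"], 22)
  # path length of a sample with a duplication strictly exceeds its
  # traversed length
  expect_gt(pl$path_length[pl$path_name == "dup#1#c"],
            st$sample_lengths$traversed_length[
              st$sample_lengths$sample == "dup"])
})

test_that("mean degree uses the links-per-segment convention", {
  expect_equal(round(mean_degree(67e6, 49e6), 1), 1.4)
  expect_equal(round(mean_degree(45e6, 33e6), 1), 1.4)
  g <- toy_chain()
  st <- pangenome_stats(g)
  expect_equal(st$mean_degree, 2 / 3)
  expect_error(pangenome_stats(pangenome(
    tibble::tibble(segment_id = character(), sequence = character()),
    tibble::tibble(from_id = character(), from_orient = character(),
                   to_id = character(), to_orient = character()),
    tibble::tibble(path_name = character(), steps = list()),
    "ref", validate = FALSE)), "empty")
})

test_that("graph/path/sample lengths agree on a simple covered chain", {
  g <- toy_chain(c(a = strrep("A", 10), b = strrep("C", 5), c = strrep("G", 7)))
  st <- pangenome_stats(g)
  expect_equal(st$total_length, 22)
  expect_equal(st$path_lengths$path_length, 22)
  expect_equal(st$sample_lengths$traversed_length, 22)
  expect_equal(nchar(path_sequence(g, "ref#0#chr1")), 22)
})

test_that("coordinates project onto the reference path", {
  g <- toy_chain(c(A = strrep("A", 10), B = "CCCCC", C = "GGGGGGG"))
  expect_equal(project_to_reference(g, "B", 2L),
               tibble::tibble(contig = "chr1", position = 13L,
                              on_reference = TRUE))
  expect_equal(project_to_reference(g, "A", 0L)$position, 1L)
  expect_error(project_to_reference(g, "B", 5L), "offset")
  expect_error(project_to_reference(g, "nope", 0L), "unknown")
})

test_that("insertion-only nodes anchor to the last preceding reference base", {
  # ref: A(10) -> B(5); hap additionally traverses X between them
  segs <- tibble::tibble(segment_id = c("A", "B", "X"),
                         sequence = c(strrep("A", 10), "CCCCC", "TTT"))
  links <- tibble::tibble(from_id = c("A", "A", "X"), from_orient = "+",
                          to_id = c("B", "X", "B"), to_orient = "+")
  paths <- tibble::tibble(
    path_name = c("ref#0#c", "h#1#c"),
    steps = list(steps_tbl(c("A", "B")), steps_tbl(c("A", "X", "B"))))
  g <- pangenome(segs, links, paths, "ref")
  pr <- project_to_reference(g, "X", 1L)
  expect_equal(pr$position, 10L)
  expect_false(pr$on_reference)
  # a path offset inside the insertion projects the same way
  pp <- project_path_position(g, "h#1#c", 11L)  # second base of X
  expect_equal(pp$position, 10L)
  expect_false(pp$on_reference)
})

test_that("PanSN names parse with a plain-contig fallback", {
  p <- parse_pansn(c("s1#2#chr1", "chrZ"))
  expect_equal(p$sample, c("s1", "chrZ"))
  expect_equal(p$haplotype, c("2", "0"))
  expect_equal(p$contig, c("chr1", "chrZ"))
})

test_that("graph validation catches broken invariants", {
  segs <- tibble::tibble(segment_id = c("a", "b"), sequence = c("AC", "GT"))
  lk <- tibble::tibble(from_id = "a", from_orient = "+", to_id = "b",
                       to_orient = "+")
  mk <- function(paths, ...) pangenome(segs, lk, paths, "ref", ...)
  expect_error(mk(tibble::tibble(path_name = "ref#0#c",
                                 steps = list(steps_tbl(c("a", "zz"))))),
               "unknown segment")
  expect_error(mk(tibble::tibble(path_name = "ref#0#c",
                                 steps = list(steps_tbl(c("b", "a"))))),
               "without a link")
  expect_error(mk(tibble::tibble(path_name = "x#0#c",
                                 steps = list(steps_tbl(c("a", "b"))))),
               "reference sample")
  expect_error(pangenome(tibble::tibble(segment_id = c("a", "a"),
                                        sequence = c("A", "C")),
                         lk[0, ], tibble::tibble(path_name = character(),
                                                 steps = list()),
                         "ref"),
               "duplicate")
})

test_that("links are canonical with set semantics", {
  l <- tibble::tibble(from_id = c("b", "a", "a"), from_orient = c("-", "+", "+"),
                      to_id = c("a", "b", "b"), to_orient = c("-", "+", "+"))
  cl <- canonical_links(l)
  # a+ -> b+ duplicated, and b- -> a- is the same edge reversed
  expect_equal(nrow(cl), 1)
  expect_equal(cl$from_id, "a")
})
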