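test_that("two-column annotation tables parse, keeping unannotated genes", {
  p <- write_tmp(c("g1\tK00001", "g2\t"))
  ann <- read_ko_annotation(p, "org1")
  expect_equal(nrow(ann$records), 2L)
  expect_equal(sum(!is.na(ann$records$ko)), 1L)
  expect_equal(annotation_fraction(ann), 0.5)

  empty <- read_ko_annotation(write_tmp(character(0)), "org2")
  expect_equal(nrow(empty$records), 0L)
  expect_error(annotation_fraction(empty), "no records")

  comments <- read_ko_annotation(
    write_tmp(c("# a comment", "g1\tK00009")), "org3")
  expect_equal(nrow(comments$records), 1L)
})

test_that("malformed KO tokens and duplicate genes are rejected with line numbers", {
  p <- write_tmp(c("g1\tK00001", "g2\tK00002", "g3\tK1"))
  expect_error(read_ko_annotation(p, "o"), "line 3")
  expect_error(read_ko_annotation(write_tmp(c("g1\tK00001", "g1\tK00002")), "o"),
               "duplicate gene_id")
  expect_error(ko_annotation("o", gene_id = "g1", ko = "KO0001"),
               "malformed KO")
})

test_that("annotation fraction covers extremes and ignores record order", {
  full <- ko_annotation("u", gene_id = c("a", "b"), ko = c("K00001", "K00002"))
  none <- ko_annotation("u", gene_id = c("a", "b"))
  expect_equal(annotation_fraction(full), 1)
  expect_equal(annotation_fraction(none), 0)
  half <- ko_annotation("u", gene_id = letters[1:4],
                        ko = c("K00001", NA, "K00002", NA))
  perm <- ko_annotation("u", gene_id = letters[4:1],
                        ko = rev(c("K00001", NA, "K00002", NA)))
  expect_equal(annotation_fraction(half), annotation_fraction(perm))
})

test_that("pathway tables union duplicate lines and reject empty member lists", {
  p <- write_tmp(c("p1\tHistidine\tK00001,K00002"))
  ont <- read_pathway_table(p)
  expect_equal(pathway_members(ont, "p1"), c("K00001", "K00002"))

  dup <- read_pathway_table(write_tmp(c(
    "p1\tHistidine\tK00001,K00002", "p1\tHistidine\tK00002,K00003")))
  expect_equal(pathway_members(dup, "p1"), c("K00001", "K00002", "K00003"))

  expect_error(read_pathway_table(write_tmp("p2\tEmpty\t")), "empty KO list")
})

test_that("genus coverage tables populate genus/coverage with decided defaults", {
  p <- write_tmp(c("o1\tK00001\tLactobacillus\t12"))
  ann <- read_genus_coverage_table(p, "s1")
  expect_equal(ann$records$coverage, 12)
  expect_equal(ann$records$genus, "Lactobacillus")

  nog <- read_genus_coverage_table(write_tmp("o2\tK00002\t\t3"), "s1")
  expect_equal(nog$records$genus, "unclassified")

  expect_error(read_genus_coverage_table(
    write_tmp("o3\tK00003\tPantoea\t-1"), "s1"), "negative read count")

  unann <- read_genus_coverage_table(write_tmp("o4\t\tPantoea\t5"), "s1")
  expect_true(is.na(unann$records$ko))
})

test_that("matrix TSV round-trips losslessly with role and normalization", {
  vals <- matrix(c(1.5, 0, 2.25, 1e6 - 3.75), 2, 2,
                 dimnames = list(c("fa", "fb"), c("s1", "s2")))
  m <- feature_matrix(vals, role = "G")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(m, path)
  expect_length(readLines(path), 5L)  # 2 sidecar + header + 2 rows
  back <- read_matrix(path)
  expect_equal(back$values, m$values)
  expect_equal(back$role, "G")
  expect_equal(back$normalization, "raw")

  bad <- feature_matrix(matrix(1, 1, 1, dimnames = list("a\tb", "s")), "generic")
  expect_error(write_matrix(bad, path), "tab")
})

test_that("annotation writers round-trip through the matching readers", {
  ann <- ko_annotation("orgX", gene_id = c("g1", "g2", "g3"),
                       ko = c("K00001", NA, "K00010"))
  dir <- withr::local_tempdir()
  write_annotations(list(ann), dir)
  back <- read_ko_annotation(file.path(dir, "orgX.tsv"), "orgX")
  expect_equal(back$records$gene_id, ann$records$gene_id)
  expect_equal(back$records$ko, ann$records$ko)

  smp <- ko_annotation("sY", gene_id = c("o1", "o2"),
                       ko = c("K00001", NA),
                       genus = c("Pantoea", "Vitis"), coverage = c(4, 9))
  write_annotations(list(smp), dir)
  back2 <- read_genus_coverage_table(file.path(dir, "sY.tsv"), "sY")
  expect_equal(back2$records$coverage, smp$records$coverage)
  expect_equal(back2$records$genus, smp$records$genus)

  ont <- random_ontology(1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pathway_table(ont, path)
  back3 <- read_pathway_table(path)
  expect_equal(pathway_ids(back3), pathway_ids(ont))
  for (p in pathway_ids(ont)) {
    expect_equal(pathway_members(back3, p), pathway_members(ont, p))
  }
})
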