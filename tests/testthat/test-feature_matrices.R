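test_that("KO presence matrix is binary over the KO union", {
  a1 <- ko_annotation("org1", "g1", "K00001")
  a2 <- ko_annotation("org2", c("g1", "g2"), c("K00001", "K00002"))
  K <- build_ko_presence(list(a1, a2))
  expect_equal(K$values["K00001", ], c(org1 = 1, org2 = 1))
  expect_equal(K$values["K00002", ], c(org1 = 0, org2 = 1))

  # duplicate KO still scores presence 1
  a3 <- ko_annotation("org3", c("g1", "g2"), c("K00001", "K00001"))
  K3 <- build_ko_presence(list(a3, a2))
  expect_equal(max(K3$values), 1)

  # identical annotations give identical columns
  a4 <- ko_annotation("org4", c("x1", "x2"), c("K00001", "K00002"))
  K4 <- build_ko_presence(list(a2, a4))
  expect_equal(unname(K4$values[, "org2"]), unname(K4$values[, "org4"]))

  none <- ko_annotation("bare", "g1")
  expect_error(build_ko_presence(list(a1, none)), "bare")
})

test_that("pathway coverage is the member fraction, bounded and monotone", {
  ont <- pathway_ontology("p1", "Ten", list(rand_ko(1:10)))
  expect_equal(unname(pathway_coverage(rand_ko(1:5), ont)), 0.5)
  expect_equal(unname(pathway_coverage(rand_ko(1:10), ont)), 1.0)
  expect_equal(unname(pathway_coverage(rand_ko(11:12), ont)), 0.0)

  # growing the KO set never decreases coverage
  ont2 <- random_ontology(4)
  set.seed(4)
  kos <- rand_ko(sample(20, 6))
  extra <- union(kos, rand_ko(sample(20, 3)))
  expect_true(all(pathway_coverage(extra, ont2) >= pathway_coverage(kos, ont2)))
})

test_that("matrix builders match brute-force nested-loop tallies", {
  for (seed in 1:8) {
    anns <- random_annotations(seed)
    ont <- random_ontology(seed)
    expect_equal(build_ko_presence(anns)$values, oracle_K(anns))
    expect_equal(build_pathway_matrix(anns, ont)$values, oracle_P(anns, ont))

    m_anns <- random_annotations(seed + 50, metagenome = TRUE)
    expect_equal(build_genus_abundance(m_anns)$values, oracle_G(m_anns))
    expect_equal(build_ko_genus_matrix(m_anns)$values, oracle_A(m_anns))
    expect_equal(build_pathway_genus_matrix(m_anns, ont)$values,
                 oracle_PM(m_anns, ont))
  }
})

test_that("builders are invariant to record order", {
  anns <- random_annotations(99, metagenome = TRUE)
  shuffled <- lapply(anns, function(a) {
    set.seed(1); idx <- sample(nrow(a$records))
    ko_annotation(a$unit_id, a$records$gene_id[idx], a$records$ko[idx],
                  a$records$genus[idx], a$records$coverage[idx])
  })
  expect_equal(build_genus_abundance(anns)$values,
               build_genus_abundance(shuffled)$values)
  expect_equal(build_ko_genus_matrix(anns)$values,
               build_ko_genus_matrix(shuffled)$values)
})

test_that("summing KO-genus rows per genus reproduces the genus matrix exactly", {
  anns <- random_annotations(7, metagenome = TRUE)
  G <- build_genus_abundance(anns)
  A <- build_ko_genus_matrix(anns)
  marg <- rowsum(A$values, sub("^.*\\|", "", rownames(A$values)))
  expect_equal(marg[rownames(G$values), , drop = FALSE], G$values,
               ignore_attr = FALSE)
})

test_that("per-million normalization forces column sums to one million", {
  vals <- matrix(c(2, 3, 5, 1, 0, 1), 3, 2,
                 dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  pm <- normalize_per_million(feature_matrix(vals, role = "G"))
  expect_equal(unname(pm$values[, "s1"]), c(200000, 300000, 500000))
  expect_equal(unname(colSums(pm$values)), c(1e6, 1e6))

  # idempotent on already-normalized input
  again <- normalize_per_million(pm)
  expect_equal(again$values, pm$values)

  zero <- matrix(c(1, 2, 0, 0), 2, 2,
                 dimnames = list(c("a", "b"), c("ok", "empty")))
  expect_error(normalize_per_million(feature_matrix(zero, role = "G")),
               "empty")
})

test_that("complement adjustment rescales by 1 - focal fraction and restores sums", {
  vals <- matrix(c(200000, 400000, 400000,   # s1: focal 0.2
                   0,      600000, 400000),  # s2: focal 0
                 3, 2, dimnames = list(c("Lacto", "x", "y"), c("s1", "s2")))
  pm <- feature_matrix(vals, role = "G", normalization = "per_million")
  adj <- complement_adjust(pm, "Lacto")
  expect_false("Lacto" %in% rownames(adj$values))
  expect_equal(unname(adj$values[, "s1"]), c(400000, 400000) / 0.8)
  expect_equal(unname(adj$values[, "s2"]), c(600000, 400000))
  expect_equal(unname(colSums(adj$values)), c(1e6, 1e6))

  all_focal <- matrix(c(1e6, 0), 2, 1,
                      dimnames = list(c("Lacto", "x"), "s1"))
  expect_error(complement_adjust(
    feature_matrix(all_focal, "G", normalization = "per_million"), "Lacto"),
    "fraction is 1")
  expect_error(complement_adjust(pm, "Missing"), "not in matrix")
  expect_error(complement_adjust(feature_matrix(vals, role = "G"), "Lacto"),
               "per_million")
})

test_that("complement adjustment works on KO-genus rows too", {
  vals <- matrix(c(250000, 250000, 500000), 3, 1,
                 dimnames = list(c("K00001|Lacto", "K00002|Lacto", "K00001|Oeno"), "s1"))
  pm <- feature_matrix(vals, role = "A", normalization = "per_million")
  adj <- complement_adjust(pm, "Lacto")
  expect_equal(rownames(adj$values), "K00001|Oeno")
  expect_equal(unname(adj$values[1, 1]), 1e6)
})

test_that("SD row filter ranks by n-1 standard deviation with stable ties", {
  vals <- rbind(const = c(5, 5, 5), wide = c(0, 1e6, 0),
                mid = c(0, 100, 0))
  colnames(vals) <- paste0("s", 1:3)
  m <- feature_matrix(vals, role = "G")
  top1 <- filter_rows_by_sd(m, top_n = 1)
  expect_equal(rownames(top1$values), "wide")
  expect_equal(rownames(filter_rows_by_sd(m, sd_threshold = 0)$values),
               c("wide", "mid"))
  expect_equal(nrow(filter_rows_by_sd(m, top_n = 3)$values), 3L)
  expect_warning(all4 <- filter_rows_by_sd(m, top_n = 4), "exceeds row count")
  expect_equal(nrow(all4$values), 3L)

  tvals <- rbind(b = c(0, 1), a = c(1, 0), z = c(5, 5))
  colnames(tvals) <- c("s1", "s2")
  ties <- feature_matrix(tvals, role = "generic")
  expect_equal(rownames(filter_rows_by_sd(ties, top_n = 2)$values),
               c("a", "b"))
})

test_that("Shannon index matches closed forms", {
  expect_equal(shannon_index(rep(10, 4)), log(4))
  expect_equal(shannon_index(c(7, 0, 0)), 0)
  expect_equal(shannon_index(c(1, 1)), log(2))
  expect_error(shannon_index(c(0, 0)), "sums to zero")
  expect_error(shannon_index(c(-1, 2)), "non-negative")
})

test_that("feature matrix constructor enforces role invariants", {
  expect_error(feature_matrix(matrix(2, 1, 1, dimnames = list("a", "b")),
                              role = "K"), "binary")
  expect_error(feature_matrix(matrix(1.5, 1, 1, dimnames = list("a", "b")),
                              role = "P"), "\\[0, 1\\]")
  expect_error(feature_matrix(matrix(1, 1, 1), role = "K"), "labels")
})
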