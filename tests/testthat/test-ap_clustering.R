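test_that("similarity handles the standard cases for both measures", {
  vals <- cbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(3, 2, 1))
  rownames(vals) <- paste0("f", 1:3)
  s <- similarity(feature_matrix(vals, "generic"), "pearson")
  expect_equal(s$values["a", "b"], 1.0)
  expect_equal(s$values["a", "c"], -1.0)
  expect_equal(s$values, t(s$values))

  disj <- cbind(a = c(1, 0), b = c(0, 1))
  rownames(disj) <- c("f1", "f2")
  bc <- similarity(feature_matrix(disj, "generic"), "bray_curtis")
  expect_equal(bc$values["a", "b"], 0.0)
  expect_true(all(bc$values >= 0 & bc$values <= 1))

  const <- cbind(a = c(1, 1), b = c(0, 1))
  rownames(const) <- c("f1", "f2")
  expect_error(similarity(feature_matrix(const, "generic"), "pearson"), "'a'")
})

test_that("affinity propagation handles degenerate and tiny inputs", {
  one <- structure(list(values = matrix(0, 1, 1, dimnames = list("x", "x")),
                        labels = "x", measure = "pearson"),
                   class = "similarity_matrix")
  r1 <- affinity_propagation(one, preference = -1)
  expect_equal(r1$n_clusters, 1L)
  expect_equal(unname(r1$exemplar_of["x"]), "x")

  # two identical points, preference below mutual similarity -> one cluster
  vals <- cbind(a = c(1, 2, 3.0), b = c(1, 2, 3.0))
  rownames(vals) <- paste0("f", 1:3)
  vals[1, 2] <- 1 + 1e-9   # break exact constancy for pearson
  s <- similarity(feature_matrix(vals, "generic"), "pearson")
  r2 <- affinity_propagation(s, preference = 0.5)
  expect_equal(r2$n_clusters, 1L)
})

test_that("AP net similarity matches exhaustive exemplar search on blobs", {
  for (seed in c(11, 23, 37)) {
    vals <- blob_matrix(seed)
    s <- similarity(feature_matrix(vals, "generic"), "pearson")
    pref <- min(s$values[row(s$values) != col(s$values)])
    cl <- affinity_propagation(s, pref, seed = seed)
    expect_true(cl$converged)
    oracle <- exhaustive_net_similarity(s, pref, cl$n_clusters)
    expect_equal(cl$net_similarity, oracle, tolerance = 1e-9)
  }
})

test_that("preference extremes give all singletons and a single cluster", {
  vals <- blob_matrix(5)
  s <- similarity(feature_matrix(vals, "generic"), "pearson")
  od <- s$values[row(s$values) != col(s$values)]
  hi <- affinity_propagation(s, max(od) + 0.1, seed = 1)
  expect_equal(hi$n_clusters, ncol(vals))
  expect_true(all(names(hi$exemplar_of) == hi$exemplar_of))
  lo <- affinity_propagation(s, -1e6, seed = 1)
  expect_equal(lo$n_clusters, 1L)
})

test_that("AP is deterministic given the seed and equivariant to relabeling", {
  vals <- blob_matrix(13)
  s <- similarity(feature_matrix(vals, "generic"), "pearson")
  a <- affinity_propagation(s, -0.5, seed = 7)
  b <- affinity_propagation(s, -0.5, seed = 7)
  expect_identical(a, b)

  perm <- c(4:9, 1:3)
  vals_p <- vals[, perm]
  s_p <- similarity(feature_matrix(vals_p, "generic"), "pearson")
  c2 <- affinity_propagation(s_p, -0.5, seed = 7)
  la <- cluster_labels(a); lc <- cluster_labels(c2)
  expect_equal(adjusted_rand(la[colnames(vals_p)], lc), 1.0)
})

test_that("preference tuning hits exact targets on planted fixtures", {
  vals <- blob_matrix(11)
  s <- similarity(feature_matrix(vals, "generic"), "pearson")
  t3 <- tune_preference(s, 3, seed = 2)
  expect_true(attr(t3, "target_attained"))
  expect_equal(adjusted_rand(cluster_labels(t3), blob_truth()), 1.0)

  tn <- tune_preference(s, ncol(vals), seed = 2)
  expect_equal(tn$n_clusters, ncol(vals))

  # identical points: target 1 is exact
  ident <- cbind(a = c(1, 2, 3.0), b = c(1, 2, 3.0), c = c(1, 2, 3))
  ident[1, 2] <- 1 + 1e-9; ident[2, 3] <- 2 + 1e-9
  rownames(ident) <- paste0("f", 1:3)
  si <- similarity(feature_matrix(abs(ident), "generic"), "pearson")
  t1 <- tune_preference(si, 1, seed = 1)
  expect_equal(t1$n_clusters, 1L)
})

test_that("agglomeration produces a monotone merge tree with faithful cuts", {
  vals <- blob_matrix(11)
  s <- similarity(feature_matrix(vals, "generic"), "pearson")
  cl <- tune_preference(s, 3, seed = 2)
  d <- agglomerate_clusters(s, cl)
  expect_equal(nrow(d$merges), 2L)
  expect_true(all(diff(d$heights) >= 0))
  # cutting at k = n_clusters reproduces the AP labels
  expect_equal(adjusted_rand(cut_clusters(d, 3), cluster_labels(cl)), 1.0)
  expect_equal(length(unique(cut_clusters(d, 1))), 1L)
  expect_equal(length(unique(cut_clusters(d, 2))), 2L)
  expect_error(cut_clusters(d, 5), "between 1 and")

  lo <- affinity_propagation(s, -1e6, seed = 1)
  expect_error(agglomerate_clusters(s, lo), "at least two clusters")
})

test_that("leave-genus-out robustness is exact for uninformative drops", {
  anns <- random_annotations(21, metagenome = TRUE, n_units = 5)
  A <- build_ko_genus_matrix(anns)
  # add an all-zero genus row: dropping it removes no information
  vals <- rbind(A$values, "K00001|Ghost" = 0)
  A2 <- feature_matrix(vals, role = "A")
  r <- robustness_leave_genus_out(A2, "Ghost", target_k = 2, seed = 3)
  expect_equal(r$ari, 1.0)

  r0 <- robustness_leave_genus_out(A2, character(0), target_k = 2, seed = 3)
  expect_equal(r0$ari, 1.0)

  expect_error(robustness_leave_genus_out(A2, "NotThere", target_k = 2),
               "not present")
  all_gen <- unique(sub("^.*\\|", "", rownames(vals)))
  expect_error(robustness_leave_genus_out(A2, all_gen, target_k = 2),
               "every row")
})

test_that("clustering serializes to JSON with its diagnostics", {
  vals <- blob_matrix(3)
  s <- similarity(feature_matrix(vals, "generic"), "pearson")
  cl <- affinity_propagation(s, -0.5, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_clustering(cl, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$n_clusters, cl$n_clusters)
  expect_equal(back$preference, cl$preference)
  expect_equal(unlist(back$labels), cl$labels)
})
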