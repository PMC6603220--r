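# Clustering workflow: pairwise similarity (Pearson or Bray-Curtis),
# affinity propagation with damped responsibility/availability message
# passing, agglomerative merging of the resulting clusters, and bisection
# of the exemplar preference toward a desired cluster count.

#' Pairwise similarity between units of a feature matrix
#'
#' Pearson correlation, or Bray-Curtis similarity (1 minus the Bray-Curtis
#' dissimilarity, appropriate for non-negative abundances).
#'
#' @param m A [feature_matrix()] or a plain numeric matrix.
#' @param measure `"pearson"` or `"bray_curtis"`.
#' @param axis Compare `"columns"` (units, the default) or `"rows"`.
#' @return An object of class `similarity_matrix`: list with `values`
#'   (symmetric matrix), `labels` and `measure`.
#' @export
similarity <- function(m, measure = c("pearson", "bray_curtis"),
                       axis = c("columns", "rows")) {
  measure <- match.arg(measure)
  axis <- match.arg(axis)
  vals <- as_values(m)
  if (axis == "rows") vals <- t(vals)
  if (ncol(vals) < 2L) stop("need at least two units")
  labels <- colnames(vals)
  if (is.null(labels)) labels <- paste0("u", seq_len(ncol(vals)))
  if (measure == "pearson") {
    v <- apply(vals, 2L, sd)
    if (any(v == 0)) {
      stop("unit '", labels[which(v == 0)[1L]],
           "' is constant; Pearson correlation undefined")
    }
    s <- cor(vals)
  } else {
    if (any(vals < 0)) stop("Bray-Curtis requires non-negative values")
    d <- as.matrix(vegan::vegdist(t(vals), method = "bray"))
    s <- 1 - d
  }
  dimnames(s) <- list(labels, labels)
  s <- (s + t(s)) / 2
  structure(list(values = s, labels = labels, measure = measure),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("<similarity_matrix> ", x$measure, ", ", length(x$labels),
      " units\n", sep = "")
  invisible(x)
}

off_diagonal <- function(s) s[row(s) != col(s)]

#' Affinity propagation clustering
#'
#' Exemplar-based clustering by message passing: responsibilities and
#' availabilities are exchanged between all pairs of points, damped by
#' `damping`, until the exemplar set is stable for `convergence_window`
#' consecutive iterations.  The preference (diagonal similarity) controls
#' how many exemplars emerge: high preferences give many clusters, low
#' preferences few.  A tiny seeded symmetric noise (relative scale `1e-12`)
#' breaks degeneracies on tied similarities.
#'
#' @param s A [similarity()] result.
#' @param preference Diagonal value used for every point.
#' @param damping Message damping factor in `[0.5, 1)`.
#' @param max_iter Maximum number of iterations.
#' @param convergence_window Iterations of stable exemplar decisions
#'   required for convergence.
#' @param seed Integer seed for the degeneracy-breaking noise.
#' @return An object of class `clustering_result`: `labels`, `exemplar_of`
#'   (named character vector unit -> exemplar unit), `preference`,
#'   `n_clusters`, `net_similarity` (sum of similarities to exemplars plus
#'   exemplar preferences), `converged`, `iterations`.
#' @export
affinity_propagation <- function(s, preference, damping = 0.9,
                                 max_iter = 1000L,
                                 convergence_window = 100L, seed = 1L) {
  stopifnot(inherits(s, "similarity_matrix"),
            damping >= 0.5, damping < 1,
            max_iter >= convergence_window)
  S0 <- s$values
  n <- nrow(S0)
  labels <- s$labels
  if (n == 1L) {
    return(new_clustering_result(labels, setNames(labels, labels),
                                 preference, preference, TRUE, 0L))
  }
  S <- S0
  diag(S) <- preference
  # seeded symmetric tie-breaking noise
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  scale <- max(S) - min(S)
  if (scale <= 0) scale <- 1
  N <- matrix(rnorm(n * n), n, n)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  S <- S + 1e-12 * scale * (N + t(N)) / 2

  R <- A <- matrix(0, n, n)
  stable <- 0L
  prev_ex <- rep(NA, n)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # responsibilities: r(i,k) = s(i,k) - max_{k'!=k} [a(i,k') + s(i,k')]
    AS <- A + S
    max1_idx <- max.col(AS, ties.method = "first")
    max1 <- AS[cbind(seq_len(n), max1_idx)]
    AS2 <- AS
    AS2[cbind(seq_len(n), max1_idx)] <- -Inf
    max2 <- AS2[cbind(seq_len(n), max.col(AS2, ties.method = "first"))]
    Rnew <- S - max1
    Rnew[cbind(seq_len(n), max1_idx)] <- S[cbind(seq_len(n), max1_idx)] - max2
    R <- damping * R + (1 - damping) * Rnew
    # availabilities: a(i,k) = min(0, r(k,k) + sum_{i' not in {i,k}} max(0, r(i',k)))
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    colsum <- colSums(Rp)
    Anew <- matrix(colsum, n, n, byrow = TRUE) - Rp
    dAnew <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dAnew
    A <- damping * A + (1 - damping) * Anew
    ex <- diag(A) + diag(R) > 0
    if (identical(ex, prev_ex)) stable <- stable + 1L else stable <- 0L
    prev_ex <- ex
    if (stable >= convergence_window && any(ex)) {
      converged <- TRUE
      break
    }
  }
  exemplars <- which(prev_ex)
  if (length(exemplars) == 0L) {
    exemplars <- which.max(diag(A) + diag(R))
  }
  # assign points to their best exemplar, then refine each cluster's
  # exemplar to the member maximizing total within-cluster similarity
  assign_to <- function(exemplars) {
    idx <- apply(S[, exemplars, drop = FALSE], 1L, which.max)
    cl <- exemplars[idx]
    cl[exemplars] <- exemplars
    cl
  }
  cl <- assign_to(exemplars)
  for (rep in 1:2) {
    exemplars <- vapply(sort(unique(cl)), function(e) {
      members <- which(cl == e)
      members[which.max(colSums(S[members, members, drop = FALSE]))]
    }, integer(1))
    cl <- assign_to(exemplars)
  }
  Sclean <- S0
  diag(Sclean) <- preference
  net <- sum(Sclean[cbind(seq_len(n), cl)])
  new_clustering_result(labels, setNames(labels[cl], labels), preference,
                        net, converged, iter)
}

new_clustering_result <- function(labels, exemplar_of, preference, net,
                                  converged, iterations) {
  stopifnot(all(exemplar_of[unique(unname(exemplar_of))] ==
                  unique(unname(exemplar_of))))
  structure(list(
    labels = labels,
    exemplar_of = exemplar_of,
    preference = preference,
    n_clusters = length(unique(unname(exemplar_of))),
    net_similarity = net,
    converged = converged,
    iterations = iterations
  ), class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat("<clustering_result> ", x$n_clusters, " clusters over ",
      length(x$labels), " units (preference ", signif(x$preference, 4),
      ", net similarity ", signif(x$net_similarity, 6),
      if (x$converged) ", converged" else ", NOT converged",
      " in ", x$iterations, " iterations)\n", sep = "")
  invisible(x)
}

#' Cluster membership as an integer vector
#'
#' @param c A `clustering_result`.
#' @return Named integer vector of cluster indices (1-based, in order of
#'   first appearance of each exemplar).
#' @export
cluster_labels <- function(c) {
  stopifnot(inherits(c, "clustering_result"))
  ex <- unname(c$exemplar_of)
  setNames(match(ex, unique(ex)), c$labels)
}

#' Best achievable net similarity for k exemplars (exhaustive)
#'
#' Enumerates all exemplar subsets of size `k` and returns the maximum of
#' the affinity-propagation objective: each point's similarity to its
#' nearest exemplar, plus the exemplars' preferences.  Exponential in `k`;
#' intended as an exactness check on small inputs.
#'
#' @param s A [similarity()] result with few points.
#' @param preference Diagonal preference value.
#' @param k Number of exemplars.
#' @return The maximal net similarity.
#' @export
exhaustive_net_similarity <- function(s, preference, k) {
  S <- s$values
  diag(S) <- preference
  n <- nrow(S)
  stopifnot(k >= 1L, k <= n)
  best <- -Inf
  sets <- combn(n, k)
  for (j in seq_len(ncol(sets))) {
    e <- sets[, j]
    obj <- sum(apply(S[, e, drop = FALSE], 1L, max)[-e]) + sum(diag(S)[e])
    # points that are exemplars contribute their preference, others their
    # best similarity to an exemplar
    if (obj > best) best <- obj
  }
  best
}

#' Agglomerative merging of affinity-propagation clusters
#'
#' Starting from the AP partition, repeatedly merges the pair of clusters
#' whose joint best exemplar fits worst least — i.e. the pair maximizing the
#' mean similarity of the members of the union to the best joint exemplar.
#' The full merge tree allows any coarser partition to be cut out for
#' inspection, replacing manual dendrogram reading with an explicit `k`.
#'
#' @param s The [similarity()] used for clustering.
#' @param c A `clustering_result` with at least two clusters.
#' @return An object of class `cluster_dendrogram`: `merges` (two-column
#'   matrix of merged cluster indices per step, negative = initial AP
#'   cluster, positive = earlier merge), `heights` (non-decreasing),
#'   `base_clusters` (list of unit labels), `cut_table` (matrix of labels,
#'   one column per `k`).
#' @export
agglomerate_clusters <- function(s, c) {
  stopifnot(inherits(s, "similarity_matrix"), inherits(c, "clustering_result"))
  if (c$n_clusters < 2L) stop("need at least two clusters to agglomerate")
  S <- s$values
  lab <- cluster_labels(c)
  k0 <- c$n_clusters
  members <- lapply(seq_len(k0), function(i) which(lab == i))
  base_clusters <- lapply(members, function(m) c$labels[m])

  joint_fitness <- function(m) {
    # best joint exemplar: member maximizing mean similarity to the others
    if (length(m) == 1L) return(Inf)
    max(vapply(m, function(x) mean(S[setdiff(m, x), x]), numeric(1)))
  }
  active <- as.list(seq_len(k0))        # tree node id per active cluster
  node_of <- -seq_len(k0)               # hclust-style signed ids
  memb <- members
  merges <- matrix(0L, k0 - 1L, 2L)
  heights <- numeric(k0 - 1L)
  assign_steps <- matrix(NA_integer_, length(lab), k0)
  colnames(assign_steps) <- seq_len(k0)
  cur <- lab
  assign_steps[, k0] <- cur
  for (step in seq_len(k0 - 1L)) {
    nact <- length(memb)
    best <- c(-Inf, NA, NA)
    for (i in seq_len(nact - 1L)) for (j in (i + 1L):nact) {
      f <- joint_fitness(c(memb[[i]], memb[[j]]))
      if (f > best[1L]) best <- c(f, i, j)
    }
    i <- best[2L]; j <- best[3L]
    merges[step, ] <- c(node_of[i], node_of[j])
    h <- -best[1L]
    heights[step] <- if (step > 1L) max(h, heights[step - 1L]) else h
    memb[[i]] <- c(memb[[i]], memb[[j]])
    node_of[i] <- step
    memb[[j]] <- NULL
    node_of <- node_of[-j]
    cur <- integer(length(lab))
    for (q in seq_along(memb)) cur[memb[[q]]] <- q
    assign_steps[, k0 - step] <- cur
  }
  rownames(assign_steps) <- c$labels
  structure(list(merges = merges, heights = heights,
                 base_clusters = base_clusters, cut_table = assign_steps),
            class = "cluster_dendrogram")
}

#' @export
print.cluster_dendrogram <- function(x, ...) {
  cat("<cluster_dendrogram> over ", length(x$base_clusters),
      " base clusters (", nrow(x$cut_table), " units)\n", sep = "")
  invisible(x)
}

#' Cut a cluster dendrogram into k groups
#'
#' @param d A `cluster_dendrogram`.
#' @param k Number of groups (`1 <= k <=` number of base clusters).
#' @return Named integer vector of group labels per unit.
#' @export
cut_clusters <- function(d, k) {
  stopifnot(inherits(d, "cluster_dendrogram"))
  col <- as.character(k)
  if (!col %in% colnames(d$cut_table)) {
    stop("k must be between 1 and ", ncol(d$cut_table))
  }
  setNames(d$cut_table[, col], rownames(d$cut_table))
}

#' Tune the exemplar preference toward a target cluster count
#'
#' The number of affinity-propagation clusters grows with the preference;
#' this bisects the preference, starting from the bracket spanned by the
#' minimum and maximum off-diagonal similarity (extended downward when even
#' the minimum yields too many clusters), until the target count is reached
#' or the evaluation budget is exhausted.
#'
#' @param s A [similarity()] result.
#' @param target_k Desired number of clusters (1 to number of units).
#' @param damping,max_iter,convergence_window,seed Passed to
#'   [affinity_propagation()].
#' @param max_evals Maximum number of AP runs (default 50).
#' @return The best `clustering_result` found, with attribute
#'   `target_attained` (logical) and `evaluations` (count).
#' @export
tune_preference <- function(s, target_k, damping = 0.9, max_iter = 1000L,
                            convergence_window = 100L, seed = 1L,
                            max_evals = 50L) {
  stopifnot(inherits(s, "similarity_matrix"))
  n <- length(s$labels)
  stopifnot(target_k >= 1L, target_k <= n)
  od <- off_diagonal(s$values)
  lo <- min(od); hi <- max(od)
  if (lo == hi) { lo <- lo - 1; }
  evals <- 0L
  best <- NULL
  run <- function(pref) {
    evals <<- evals + 1L
    r <- affinity_propagation(s, pref, damping = damping,
                              max_iter = max_iter,
                              convergence_window = convergence_window,
                              seed = seed)
    if (is.null(best) ||
        abs(r$n_clusters - target_k) < abs(best$n_clusters - target_k)) {
      best <<- r
    }
    r
  }
  r_lo <- run(lo)
  # extend the bracket downward while even the low end gives too many
  span <- hi - lo
  while (r_lo$n_clusters > target_k && evals < max_evals / 2) {
    span <- span * 2
    lo <- lo - span
    r_lo <- run(lo)
  }
  if (r_lo$n_clusters == target_k) {
    attr(best, "target_attained") <- TRUE
    attr(best, "evaluations") <- evals
    return(best)
  }
  r_hi <- run(hi)
  # extend upward while even the high end gives too few clusters (e.g. an
  # all-singleton target on tightly similar units)
  span <- hi - lo
  while (r_hi$n_clusters < target_k && evals < 3 * max_evals / 4) {
    span <- span * 2
    hi <- hi + span
    r_hi <- run(hi)
  }
  while (evals < max_evals && best$n_clusters != target_k &&
         (hi - lo) > 1e-12 * max(1, abs(hi), abs(lo))) {
    mid <- (lo + hi) / 2
    r_mid <- run(mid)
    if (r_mid$n_clusters >= target_k) hi <- mid else lo <- mid
  }
  attained <- best$n_clusters == target_k
  if (!attained) {
    warning("target_k = ", target_k, " not attained; best has ",
            best$n_clusters, " clusters")
  }
  attr(best, "target_attained") <- attained
  attr(best, "evaluations") <- evals
  best
}

#' Adjusted Rand index between two clusterings
#'
#' @param a,b Cluster label vectors over the same units (order-aligned).
#' @return The chance-corrected Rand agreement (1 = identical partitions).
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}

#' Leave-genus-out robustness of sample clustering
#'
#' Removes all rows belonging to the named genera from a raw abundance
#' matrix (role `G` or `A`), re-normalizes per million, re-clusters with
#' the same parameters, and compares against the full-data clustering.  A
#' high adjusted Rand index means the grouping does not hinge on the
#' dropped genera.
#'
#' @param m A raw [feature_matrix()] of role `G` or `A`.
#' @param drop Character vector of genus names to remove (must be present).
#' @param measure Similarity measure, see [similarity()].
#' @param target_k Cluster count for [tune_preference()].
#' @param seed,damping Passed to the clustering.
#' @return List with `full` and `reduced` `clustering_result`s and `ari`.
#' @export
robustness_leave_genus_out <- function(m, drop, measure = "pearson",
                                       target_k, seed = 1L, damping = 0.9) {
  stopifnot(inherits(m, "feature_matrix"), m$role %in% c("G", "A"))
  gen <- row_genus(m)
  missing <- setdiff(drop, gen)
  if (length(missing)) {
    stop("genus '", missing[1L], "' not present in matrix rows")
  }
  keep <- !(gen %in% drop)
  if (!any(keep)) stop("dropping these genera removes every row")
  cluster_of <- function(vals) {
    fm <- normalize_per_million(feature_matrix(vals, role = m$role))
    s <- similarity(fm, measure = measure)
    tune_preference(s, target_k, seed = seed, damping = damping)
  }
  full <- cluster_of(m$values)
  reduced <- cluster_of(m$values[keep, , drop = FALSE])
  ari <- adjusted_rand(cluster_labels(full), cluster_labels(reduced))
  list(full = full, reduced = reduced, ari = ari)
}

#' Serialize a clustering result to JSON
#'
#' @param c A `clustering_result`.
#' @param path Output path.
#' @export
write_clustering <- function(c, path) {
  stopifnot(inherits(c, "clustering_result"))
  jsonlite::write_json(list(
    labels = c$labels,
    exemplar_of = as.list(c$exemplar_of),
    preference = c$preference,
    n_clusters = c$n_clusters,
    net_similarity = c$net_similarity,
    converged = c$converged,
    iterations = c$iterations
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}
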