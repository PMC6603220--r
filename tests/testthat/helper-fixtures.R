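# Fixture builders and independent brute-force oracles used across tests.
# Oracles deliberately use nested loops / exhaustive enumeration so they
# share no code with the implementation they check.

rand_ko <- function(i) sprintf("K%05d", i)

# random small annotation set: <= n_units units, KOs drawn from 1..n_kos,
# with genus and coverage populated when metagenome = TRUE
random_annotations <- function(seed, n_units = 5, n_kos = 20,
                               metagenome = FALSE, genera = c("Ga", "Gb", "Gc")) {
  set.seed(seed)
  m <- sample(2:n_units, 1)
  lapply(seq_len(m), function(j) {
    k <- sample(3:n_kos, 1)
    kos <- rand_ko(sample(n_kos, k))
    if (metagenome) {
      ko_annotation(sprintf("s%02d", j),
                    gene_id = sprintf("s%02d_o%03d", j, seq_along(kos)),
                    ko = kos,
                    genus = sample(genera, k, replace = TRUE),
                    coverage = sample(1:50, k, replace = TRUE))
    } else {
      ko_annotation(sprintf("u%02d", j),
                    gene_id = sprintf("u%02d_g%03d", j, seq_along(kos)),
                    ko = kos)
    }
  })
}

random_ontology <- function(seed, n_paths = 5, n_kos = 20) {
  set.seed(seed + 777)
  pathway_ontology(
    sprintf("pw%02d", seq_len(n_paths)),
    paste("Pathway", seq_len(n_paths)),
    lapply(seq_len(n_paths), function(i)
      rand_ko(sample(n_kos, sample(2:6, 1))))
  )
}

# --- brute-force matrix oracles (nested loops, no vectorization) --------

oracle_K <- function(anns) {
  ids <- sort(vapply(anns, `[[`, character(1), "unit_id"))
  kos <- sort(unique(unlist(lapply(anns, function(a)
    a$records$ko[!is.na(a$records$ko)]))))
  out <- matrix(0, length(kos), length(ids), dimnames = list(kos, ids))
  for (a in anns) for (ko in kos) {
    present <- FALSE
    for (i in seq_len(nrow(a$records))) {
      if (!is.na(a$records$ko[i]) && a$records$ko[i] == ko) present <- TRUE
    }
    out[ko, a$unit_id] <- as.numeric(present)
  }
  out
}

oracle_P <- function(anns, ont) {
  ids <- sort(vapply(anns, `[[`, character(1), "unit_id"))
  pids <- pathway_ids(ont)
  out <- matrix(0, length(pids), length(ids), dimnames = list(pids, ids))
  for (a in anns) {
    kos <- unique(a$records$ko[!is.na(a$records$ko)])
    for (p in pids) {
      mem <- pathway_members(ont, p)
      n_in <- 0
      for (m in mem) if (m %in% kos) n_in <- n_in + 1
      out[p, a$unit_id] <- n_in / length(mem)
    }
  }
  out
}

oracle_G <- function(anns) {
  ids <- sort(vapply(anns, `[[`, character(1), "unit_id"))
  genera <- sort(unique(unlist(lapply(anns, function(a)
    a$records$genus[!is.na(a$records$ko)]))))
  out <- matrix(0, length(genera), length(ids), dimnames = list(genera, ids))
  for (a in anns) for (i in seq_len(nrow(a$records))) {
    if (!is.na(a$records$ko[i])) {
      g <- a$records$genus[i]
      out[g, a$unit_id] <- out[g, a$unit_id] + a$records$coverage[i]
    }
  }
  out
}

oracle_A <- function(anns) {
  ids <- sort(vapply(anns, `[[`, character(1), "unit_id"))
  pairs <- sort(unique(unlist(lapply(anns, function(a) {
    r <- a$records[!is.na(a$records$ko), ]
    paste(r$ko, r$genus, sep = "|")
  }))))
  out <- matrix(0, length(pairs), length(ids), dimnames = list(pairs, ids))
  for (a in anns) for (i in seq_len(nrow(a$records))) {
    if (!is.na(a$records$ko[i])) {
      key <- paste(a$records$ko[i], a$records$genus[i], sep = "|")
      out[key, a$unit_id] <- out[key, a$unit_id] + a$records$coverage[i]
    }
  }
  out
}

oracle_PM <- function(anns, ont) {
  ids <- sort(vapply(anns, `[[`, character(1), "unit_id"))
  rows <- character(0)
  vals <- list()
  for (a in anns) {
    r <- a$records[!is.na(a$records$ko), ]
    for (g in unique(r$genus)) {
      kos <- unique(r$ko[r$genus == g])
      for (p in pathway_ids(ont)) {
        mem <- pathway_members(ont, p)
        n_in <- 0
        for (m in mem) if (m %in% kos) n_in <- n_in + 1
        if (n_in > 0) {
          key <- paste(p, g, sep = "|")
          rows <- union(rows, key)
          vals[[paste(key, a$unit_id)]] <- n_in / length(mem)
        }
      }
    }
  }
  rows <- sort(rows)
  out <- matrix(0, length(rows), length(ids), dimnames = list(rows, ids))
  for (key in names(vals)) {
    parts <- strsplit(key, " ", fixed = TRUE)[[1]]
    out[parts[1], parts[2]] <- vals[[key]]
  }
  out
}

# --- clustering fixtures ------------------------------------------------

# 9 points in 3 well-separated blobs (6-dim profiles), non-negative
blob_matrix <- function(seed, per_blob = 3, n_blob = 3, dim = 6,
                        spread = 0.2) {
  set.seed(seed)
  centers <- matrix(runif(dim * n_blob, 1, 10), dim, n_blob)
  vals <- do.call(cbind, lapply(seq_len(n_blob), function(b)
    abs(centers[, b] + matrix(rnorm(dim * per_blob, sd = spread),
                              dim, per_blob))))
  dimnames(vals) <- list(paste0("f", seq_len(dim)),
                         paste0("p", seq_len(n_blob * per_blob)))
  vals
}

blob_truth <- function(per_blob = 3, n_blob = 3) rep(seq_len(n_blob), each = per_blob)

# planted two-class feature-selection fixture (features x samples)
selection_fixture <- function(seed, n = 60, p_noise = 200, p_sig = 5,
                              delta = 2, null = FALSE) {
  set.seed(seed)
  y <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * p_noise), p_noise, n)
  rownames(X) <- paste0("noise", seq_len(p_noise))
  if (!null) {
    S <- matrix(rnorm(n * p_sig), p_sig, n)
    S[, y == "b"] <- S[, y == "b"] + delta
    rownames(S) <- paste0("sig", seq_len(p_sig))
    X <- rbind(S, X)
  }
  colnames(X) <- paste0("s", seq_len(n))
  list(x = X, y = y, signal = if (!null) paste0("sig", seq_len(p_sig)) else character(0))
}

write_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
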