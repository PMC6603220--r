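# The five feature matrices of the pipeline and their normalizations:
#   K  - KO presence/absence (KOs x organisms), binary
#   P  - pathway coverage (pathways x organisms), in [0,1]
#   G  - genus read abundance (genera x samples)
#   A  - KO-genus read abundance ((KO,genus) pairs x samples)
#   PM - pathway-genus coverage ((pathway,genus) pairs x samples), in [0,1]
# Row ids of A and PM are "<KO or pathway>|<genus>".

FM_ROLES <- c("K", "P", "G", "A", "PM", "generic")
FM_NORMS <- c("raw", "per_pathway", "per_million", "complement_adjusted")

#' Labeled feature matrix with a declared role and normalization state
#'
#' Rows are features, columns are units (organisms or samples).  The role
#' determines which invariants are enforced: `K` entries are binary, `P` and
#' `PM` entries lie in `[0, 1]`, `per_million` columns sum to one million.
#'
#' @param values Numeric matrix with row and column dimnames.
#' @param role One of `"K"`, `"P"`, `"G"`, `"A"`, `"PM"`, `"generic"`.
#' @param normalization One of `"raw"`, `"per_pathway"`, `"per_million"`,
#'   `"complement_adjusted"`.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, role = "generic", normalization = "raw") {
  role <- match.arg(role, FM_ROLES)
  normalization <- match.arg(normalization, FM_NORMS)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("feature matrix must have row and column labels")
  }
  if (any(values < 0)) stop("feature matrix entries must be non-negative")
  if (role == "K" && !all(values %in% c(0, 1))) {
    stop("role K requires binary entries")
  }
  if (role %in% c("P", "PM") && any(values > 1 + 1e-12)) {
    stop("role ", role, " requires entries in [0, 1]")
  }
  if (normalization == "per_million") {
    cs <- colSums(values)
    if (any(abs(cs - 1e6) > 1e-6 * 1e6)) {
      stop("per_million columns must sum to 1e6")
    }
  }
  structure(list(values = values, role = role, normalization = normalization),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> role ", x$role, " (", x$normalization, "): ",
      nrow(x$values), " features x ", ncol(x$values), " units\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

as_values <- function(m) if (inherits(m, "feature_matrix")) m$values else m

check_anns <- function(anns) {
  stopifnot(length(anns) >= 1L,
            all(vapply(anns, inherits, logical(1), "ko_annotation")))
  ids <- vapply(anns, `[[`, character(1), "unit_id")
  if (anyDuplicated(ids)) stop("duplicate unit ids among annotations")
  ids
}

#' KO presence/absence matrix (role K)
#'
#' Binary matrix over the union of observed KOs (rows) by units (columns);
#' entry 1 when the KO occurs at least once in the unit.  Row and column
#' order is lexicographic so output is bit-stable.
#'
#' @param anns List of [ko_annotation()] objects.
#' @return A [feature_matrix()] with role `K`.
#' @export
build_ko_presence <- function(anns) {
  ids <- check_anns(anns)
  sets <- lapply(anns, ko_set)
  empty <- vapply(sets, length, integer(1)) == 0L
  if (any(empty)) {
    stop("unit '", ids[which(empty)[1L]], "' has no KO-annotated genes")
  }
  kos <- sort(unique(unlist(sets)))
  ord <- order(ids)
  vals <- vapply(ord, function(i) as.numeric(kos %in% sets[[i]]),
                 numeric(length(kos)))
  vals <- matrix(vals, nrow = length(kos),
                 dimnames = list(kos, ids[ord]))
  feature_matrix(vals, role = "K")
}

#' Pathway coverage of a single unit
#'
#' For each pathway, the number of the unit's KOs that are members divided
#' by the pathway's total member count — the fraction of the pathway the
#' unit can cover.
#'
#' @param x A [ko_annotation()] or a character vector of KO identifiers.
#' @param ont A [pathway_ontology()].
#' @return Named numeric vector over pathways, values in `[0, 1]`.
#' @export
pathway_coverage <- function(x, ont) {
  stopifnot(inherits(ont, "pathway_ontology"))
  kos <- if (inherits(x, "ko_annotation")) ko_set(x) else unique(as.character(x))
  vapply(ont$pathways, function(p)
    sum(p$members %in% kos) / length(p$members), numeric(1))
}

#' Pathway coverage matrix (role P)
#'
#' Stacks [pathway_coverage()] columns for a set of organisms: rows are
#' pathways, columns are organisms, entries are coverage fractions
#' normalized by pathway size.
#'
#' @inheritParams build_ko_presence
#' @param ont A [pathway_ontology()].
#' @return A [feature_matrix()] with role `P`, normalization `per_pathway`.
#' @export
build_pathway_matrix <- function(anns, ont) {
  ids <- check_anns(anns)
  ord <- order(ids)
  cols <- lapply(ord, function(i) pathway_coverage(anns[[i]], ont))
  vals <- do.call(cbind, cols)
  dimnames(vals) <- list(pathway_ids(ont), ids[ord])
  feature_matrix(vals, role = "P", normalization = "per_pathway")
}

#' Genus read-abundance matrix (role G, raw counts)
#'
#' Sums per-ORF read counts by genus within each sample.  By default only
#' KO-annotated ORFs contribute, mirroring a KO-indexed analysis; set
#' `include_unannotated = TRUE` to conserve all reads in the totals.
#'
#' @param anns List of sample [ko_annotation()] objects with `genus` and
#'   `coverage` populated.
#' @param include_unannotated Include ORFs without a KO assignment?
#' @return A [feature_matrix()] with role `G`, raw counts.
#' @export
build_genus_abundance <- function(anns, include_unannotated = FALSE) {
  ids <- check_anns(anns)
  ord <- order(ids)
  tallies <- lapply(ord, function(i) {
    r <- anns[[i]]$records
    if (!include_unannotated) r <- r[!is.na(r$ko), , drop = FALSE]
    if (nrow(r) == 0L || sum(r$coverage, na.rm = TRUE) <= 0) {
      stop("sample '", ids[i], "' has zero total reads")
    }
    if (any(is.na(r$coverage))) {
      stop("sample '", ids[i], "' has records without coverage")
    }
    tapply(r$coverage, r$genus, sum)
  })
  genera <- sort(unique(unlist(lapply(tallies, names))))
  vals <- vapply(tallies, function(t) {
    v <- setNames(numeric(length(genera)), genera)
    v[names(t)] <- t
    v
  }, numeric(length(genera)))
  vals <- matrix(vals, nrow = length(genera),
                 dimnames = list(genera, ids[ord]))
  feature_matrix(vals, role = "G")
}

#' KO-genus read-abundance matrix (role A)
#'
#' Rows are `"<KO>|<genus>"` combinations observed in at least one sample;
#' entries are summed read counts.  Summing rows over KOs within each genus
#' reproduces the genus matrix G exactly (on KO-annotated reads).
#'
#' @inheritParams build_genus_abundance
#' @return A [feature_matrix()] with role `A`, raw counts.
#' @export
build_ko_genus_matrix <- function(anns) {
  ids <- check_anns(anns)
  ord <- order(ids)
  tallies <- lapply(ord, function(i) {
    r <- anns[[i]]$records
    r <- r[!is.na(r$ko), , drop = FALSE]
    if (nrow(r) == 0L || sum(r$coverage, na.rm = TRUE) <= 0) {
      stop("sample '", ids[i], "' has zero total reads")
    }
    if (any(is.na(r$coverage))) {
      stop("sample '", ids[i], "' has records without coverage")
    }
    tapply(r$coverage, paste(r$ko, r$genus, sep = "|"), sum)
  })
  feats <- sort(unique(unlist(lapply(tallies, names))))
  vals <- vapply(tallies, function(t) {
    v <- setNames(numeric(length(feats)), feats)
    v[names(t)] <- t
    v
  }, numeric(length(feats)))
  vals <- matrix(vals, nrow = length(feats),
                 dimnames = list(feats, ids[ord]))
  feature_matrix(vals, role = "A")
}

#' Pathway-genus coverage matrix (role PM)
#'
#' For each (pathway, genus) pair and sample: the number of distinct member
#' KOs of the pathway seen for that genus in the sample, divided by the
#' pathway's member count.  Only pairs with nonzero coverage in at least one
#' sample are kept as rows (`"<pathway>|<genus>"`).
#'
#' @inheritParams build_genus_abundance
#' @param ont A [pathway_ontology()].
#' @return A [feature_matrix()] with role `PM`, normalization `per_pathway`.
#' @export
build_pathway_genus_matrix <- function(anns, ont) {
  ids <- check_anns(anns)
  stopifnot(inherits(ont, "pathway_ontology"))
  ord <- order(ids)
  pids <- pathway_ids(ont)
  sizes <- vapply(ont$pathways, function(p) length(p$members), integer(1))
  cols <- lapply(ord, function(i) {
    r <- anns[[i]]$records
    r <- r[!is.na(r$ko), , drop = FALSE]
    kos_by_genus <- split(r$ko, r$genus)
    out <- list()
    for (g in names(kos_by_genus)) {
      kos <- unique(kos_by_genus[[g]])
      cov <- vapply(seq_along(pids), function(k)
        sum(ont$pathways[[k]]$members %in% kos) / sizes[k], numeric(1))
      nz <- cov > 0
      if (any(nz)) {
        out[[g]] <- setNames(cov[nz], paste(pids[nz], g, sep = "|"))
      }
    }
    unlist(unname(out)) %||% setNames(numeric(0), character(0))
  })
  feats <- sort(unique(unlist(lapply(cols, names))))
  if (length(feats) == 0L) stop("no (pathway, genus) pair has any coverage")
  vals <- vapply(cols, function(t) {
    v <- setNames(numeric(length(feats)), feats)
    v[names(t)] <- t
    v
  }, numeric(length(feats)))
  vals <- matrix(vals, nrow = length(feats),
                 dimnames = list(feats, ids[ord]))
  feature_matrix(vals, role = "PM", normalization = "per_pathway")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Per-million column normalization
#'
#' Divides every entry by its column total and multiplies by one million,
#' so samples with different sequencing depth become comparable.
#'
#' @param m A raw-count [feature_matrix()].
#' @return The matrix with normalization `per_million`; every column sums
#'   to 1,000,000.
#' @export
normalize_per_million <- function(m) {
  stopifnot(inherits(m, "feature_matrix"))
  cs <- colSums(m$values)
  if (any(cs <= 0)) {
    stop("sample '", colnames(m$values)[which(cs <= 0)[1L]],
         "' has zero column sum")
  }
  vals <- sweep(m$values, 2L, cs, "/") * 1e6
  feature_matrix(vals, role = m$role, normalization = "per_million")
}

# genus component of a row id: the row id itself for G, the part after the
# final '|' for A and PM
row_genus <- function(m) {
  if (m$role %in% c("A", "PM")) {
    sub("^.*\\|", "", rownames(m$values))
  } else {
    rownames(m$values)
  }
}

#' Complement normalization for an inoculated genus
#'
#' When one genus is inoculated its reads crowd out the rest of the
#' community; dividing every other entry by the complement `1 - f_j` of the
#' focal genus' relative abundance `f_j` in sample `j` makes the residual
#' community comparable across samples.  The focal rows are removed and
#' column sums return to one million.
#'
#' @param m A `per_million` [feature_matrix()] (role `G` or `A`).
#' @param focal_genus Genus whose abundance complement is used.
#' @return A [feature_matrix()] with normalization `complement_adjusted`.
#' @export
complement_adjust <- function(m, focal_genus) {
  stopifnot(inherits(m, "feature_matrix"))
  if (m$normalization != "per_million") {
    stop("complement_adjust expects a per_million matrix")
  }
  gen <- row_genus(m)
  focal <- gen == focal_genus
  if (!any(focal)) stop("focal genus '", focal_genus, "' not in matrix rows")
  f <- colSums(m$values[focal, , drop = FALSE]) / 1e6
  if (any(f >= 1 - 1e-12)) {
    stop("focal genus fraction is 1 in sample '",
         colnames(m$values)[which(f >= 1 - 1e-12)[1L]], "'")
  }
  vals <- sweep(m$values[!focal, , drop = FALSE], 2L, 1 - f, "/")
  feature_matrix(vals, role = m$role, normalization = "complement_adjusted")
}

row_sds <- function(vals) apply(vals, 1L, sd)

#' Keep the rows with the highest across-sample standard deviation
#'
#' Constant features carry no discriminative signal; this retains the rows
#' whose sample standard deviation (n-1 denominator) ranks highest, or
#' exceeds a threshold.  Rows are returned in descending SD order with ties
#' broken lexicographically by row id.
#'
#' @param m A [feature_matrix()] with at least two columns.
#' @param top_n Number of rows to keep (mutually exclusive with
#'   `sd_threshold`).
#' @param sd_threshold Keep rows with SD strictly above this value.
#' @return A [feature_matrix()] with the retained rows.
#' @export
filter_rows_by_sd <- function(m, top_n = NULL, sd_threshold = NULL) {
  stopifnot(inherits(m, "feature_matrix"), ncol(m$values) >= 2L)
  if (is.null(top_n) == is.null(sd_threshold)) {
    stop("give exactly one of top_n or sd_threshold")
  }
  sds <- row_sds(m$values)
  ord <- order(-sds, rownames(m$values))
  if (!is.null(top_n)) {
    if (top_n > nrow(m$values)) {
      warning("top_n (", top_n, ") exceeds row count (", nrow(m$values),
              "); returning all rows")
      top_n <- nrow(m$values)
    }
    keep <- ord[seq_len(top_n)]
  } else {
    keep <- ord[sds[ord] > sd_threshold]
  }
  # a row subset of a per-million matrix no longer sums to one million
  norm <- m$normalization
  if (norm == "per_million" && length(keep) < nrow(m$values)) norm <- "raw"
  feature_matrix(m$values[keep, , drop = FALSE], role = m$role,
                 normalization = norm)
}

#' Shannon diversity index of an abundance vector
#'
#' `-sum(q * log(q))` in nats over the relative abundances
#' `q = x / sum(x)`, with the convention `0 * log(0) = 0`.
#'
#' @param x Non-negative abundance vector with positive sum.
#' @return Shannon index in nats (`>= 0`).
#' @export
shannon_index <- function(x) {
  x <- as.numeric(x)
  if (any(x < 0)) stop("abundances must be non-negative")
  s <- sum(x)
  if (s <= 0) stop("abundance vector sums to zero")
  q <- x[x > 0] / s
  -sum(q * log(q)) + 0   # + 0 normalizes IEEE negative zero
}
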