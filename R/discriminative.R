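# What separates the groups: pathway ranking by the standard deviation of
# coverage across units, comparison tables for selected units/genera, and
# the response-vector helper for the wine classification tasks.

#' Rank pathways by the standard deviation of their coverage
#'
#' Pathways whose coverage varies most across the selected units are the
#' best candidates for discriminative biology (e.g. a biosynthesis pathway
#' absent from one organism but complete in its relatives).  SD uses the
#' n-1 denominator; ties are broken lexicographically by pathway id.
#'
#' @param p A [feature_matrix()] of role `P` or `PM`.
#' @param units Optional subset of column ids (default: all).
#' @param top_n Number of pathways to report (default: all).
#' @return An object of class `pathway_ranking`: a data frame with columns
#'   `pathway_id`, `sd`, and one coverage column per unit, ordered by
#'   descending SD.
#' @export
rank_pathways_by_sd <- function(p, units = NULL, top_n = Inf) {
  stopifnot(inherits(p, "feature_matrix"))
  vals <- p$values
  if (!is.null(units)) {
    missing <- setdiff(units, colnames(vals))
    if (length(missing)) stop("unknown unit '", missing[1L], "'")
    vals <- vals[, units, drop = FALSE]
  }
  if (ncol(vals) < 2L) stop("need at least two units to rank by SD")
  sds <- row_sds(vals)
  ord <- order(-sds, rownames(vals))
  n <- min(top_n, nrow(vals))
  keep <- ord[seq_len(n)]
  out <- data.frame(pathway_id = rownames(vals)[keep], sd = sds[keep],
                    vals[keep, , drop = FALSE],
                    row.names = NULL, check.names = FALSE)
  class(out) <- c("pathway_ranking", "data.frame")
  out
}

#' @export
print.pathway_ranking <- function(x, n = 10L, ...) {
  cat("<pathway_ranking> ", nrow(x), " pathways over ",
      ncol(x) - 2L, " units; top by SD:\n", sep = "")
  print.data.frame(head(as.data.frame(x), n), digits = 3)
  invisible(x)
}

#' Pathway comparison table for selected units
#'
#' Returns, for the chosen units, the pathways with nonzero coverage SD in
#' descending order, with coverage expressed as percentages — the numbers
#' behind a comparison heat map of e.g. candidate malolactic fermenters.
#'
#' @param p A [feature_matrix()] of role `P` or `PM`.
#' @param units Column ids to compare.
#' @param top_n Maximum number of pathways.
#' @return Data frame `pathway_id`, `sd`, then one percentage column
#'   (0-100) per unit.
#' @export
compare_units_pathways <- function(p, units, top_n = Inf) {
  r <- rank_pathways_by_sd(p, units = units, top_n = Inf)
  r <- r[r$sd > 0, , drop = FALSE]
  r <- head(r, min(top_n, nrow(r)))
  r[, -(1:2)] <- 100 * r[, -(1:2), drop = FALSE]
  as.data.frame(r)
}

#' Top genera by coverage of one pathway
#'
#' Ranks genera by their best coverage of the named pathway across samples,
#' dropping genera that never exceed `min_coverage` — e.g. the top-ten
#' genera for the phosphotransferase-system map, showing only those above
#' 5% coverage.
#'
#' @param pm A [feature_matrix()] of role `PM` (rows `"pathway|genus"`).
#' @param pathway_id Pathway to interrogate.
#' @param top_n Number of genera to return (default 10).
#' @param min_coverage Minimum max-coverage to qualify (default 0.05).
#' @return Data frame `genus`, `max_coverage`, `mean_coverage`, descending.
#' @export
top_units_for_pathway <- function(pm, pathway_id, top_n = 10L,
                                  min_coverage = 0.05) {
  stopifnot(inherits(pm, "feature_matrix"), pm$role == "PM")
  pid <- sub("\\|[^|]*$", "", rownames(pm$values))
  hit <- pid == pathway_id
  if (!any(hit)) stop("pathway '", pathway_id, "' not present in matrix")
  vals <- pm$values[hit, , drop = FALSE]
  genus <- sub("^.*\\|", "", rownames(vals))
  mx <- apply(vals, 1L, max)
  mn <- rowMeans(vals)
  keep <- mx >= min_coverage
  out <- data.frame(genus = genus[keep], max_coverage = mx[keep],
                    mean_coverage = mn[keep], row.names = NULL)
  out <- out[order(-out$max_coverage, out$genus), , drop = FALSE]
  head(out, min(top_n, nrow(out)))
}

#' Class labels for wine fermentation samples
#'
#' Maps grape varieties to response classes for supervised feature
#' selection: either the red/white dichotomy (Bobal and Tempranillo are
#' red, Airen is white) or the varieties themselves as three classes.
#'
#' @param sample_metadata Data frame with a `variety` column (and
#'   optionally row order matching the feature-matrix columns).
#' @param scheme `"red_white"` (two classes) or `"variety"` (one class per
#'   variety).
#' @return Factor of class labels, one per row of `sample_metadata`.
#' @export
build_response_vector <- function(sample_metadata,
                                  scheme = c("red_white", "variety")) {
  scheme <- match.arg(scheme)
  if (!"variety" %in% names(sample_metadata)) {
    stop("sample metadata needs a 'variety' column")
  }
  v <- as.character(sample_metadata$variety)
  known <- c(Airen = "white", Bobal = "red", Tempranillo = "red")
  if (scheme == "red_white") {
    unknown <- setdiff(unique(v), names(known))
    if (length(unknown)) stop("unknown variety '", unknown[1L], "'")
    factor(unname(known[v]), levels = c("red", "white"))
  } else {
    factor(v)
  }
}
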