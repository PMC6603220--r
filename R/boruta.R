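# All-relevant feature selection by the shadow-feature scheme: every
# feature competes against shuffled copies of the features (shadows) inside
# a random forest; features that beat the best shadow more often than
# chance are confirmed, those that lose persistently are rejected.  The
# forest itself is delegated to ranger.

#' Shadow-feature (Boruta-style) all-relevant feature selection
#'
#' Iterates: (1) append a freshly shuffled copy of every feature;
#' (2) fit a random-forest classifier and record importances; (3) a feature
#' scores a *hit* when its importance exceeds the maximum shadow importance
#' observed so far (the running maximum keeps the null hit probability at
#' or below one half even for the strongest chance-correlated feature);
#' (4) two-sided binomial tests on the hit counts at significance
#' `1 - confidence`, Bonferroni-corrected across the features under test,
#' confirm or reject features; (5) stop at `max_runs` or when no feature is
#' undecided.  Features still undecided at the end are reported as
#' tentative, never silently promoted.
#'
#' @param x A [feature_matrix()] (features x samples) or plain matrix with
#'   at least two rows; columns must align with `y`.
#' @param y Class labels (factor or character), one per sample; at least
#'   two classes with two samples each.
#' @param confidence Confidence of importance required (default 0.99).
#' @param max_runs Maximum number of importance-source runs (default 2000;
#'   raised to 5000 for hard problems).
#' @param seed Integer seed; the procedure is deterministic given it.
#' @param importance `"permutation"` (default) or `"impurity"`, passed to
#'   the forest.
#' @param num_trees Trees per forest (default 500).
#' @return An object of class `selection_result`: `decision` (named factor
#'   confirmed/tentative/rejected), `hit_count`, `runs_used` (runs each
#'   feature was tested in before its decision), `importance_history`
#'   (runs x features), `confidence`, `response_classes`, `seed`, `params`.
#' @export
boruta_select <- function(x, y, confidence = 0.99, max_runs = 2000L,
                          seed = 1L,
                          importance = c("permutation", "impurity"),
                          num_trees = 500L) {
  importance <- match.arg(importance)
  vals <- as_values(x)
  if (nrow(vals) < 2L) stop("need at least two features")
  if (ncol(vals) != length(y)) {
    stop("length of y (", length(y), ") must match number of samples (",
         ncol(vals), ")")
  }
  y <- factor(y)
  if (nlevels(y) < 2L) stop("response is constant")
  if (any(table(y) < 2L)) stop("every class needs at least two samples")
  feats <- rownames(vals)
  if (is.null(feats)) feats <- paste0("f", seq_len(nrow(vals)))
  p <- length(feats)
  X <- t(vals)                     # samples x features
  colnames(X) <- feats

  decision <- setNames(rep("tentative", p), feats)
  hits <- setNames(integer(p), feats)
  runs_used <- setNames(integer(p), feats)
  imp_hist <- matrix(NA_real_, 0L, p, dimnames = list(NULL, feats))
  alpha <- 1 - confidence
  cw <- 1 / table(y)
  case_weights <- as.numeric(cw[y])   # class-balanced sampling

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  # all features stay in the design matrix for every run (decided ones are
  # merely no longer tested): this keeps the importance competition and the
  # max-shadow null stationary across runs — with a shrinking model the
  # shadow threshold weakens and chance correlations get spuriously
  # confirmed late in the run
  run <- 0L
  sh_max_ever <- -Inf
  while (run < max_runs && any(decision == "tentative")) {
    run <- run + 1L
    n_sh <- max(5L, p)
    src <- rep_len(seq_len(p), n_sh)
    Sh <- apply(X[, src, drop = FALSE], 2L, sample)
    colnames(Sh) <- paste0(".shadow", seq_len(n_sh))
    dat <- data.frame(X, Sh, check.names = FALSE)
    dat$.response <- y
    fit <- ranger::ranger(
      dependent.variable.name = ".response", data = dat,
      num.trees = num_trees, importance = importance,
      scale.permutation.importance = importance == "permutation",
      case.weights = case_weights,
      seed = seed + run, num.threads = 1L,
      respect.unordered.factors = "order")
    imp <- fit$variable.importance
    sh_max_ever <- max(sh_max_ever,
                       imp[paste0(".shadow", seq_len(n_sh))])
    real_imp <- imp[feats]
    imp_hist <- rbind(imp_hist, real_imp)
    und <- which(decision == "tentative")
    # hits are scored against the running maximum shadow importance: the
    # per-run maximum gives the strongest chance-correlated feature a hit
    # probability above 1/2 (winner's curse), which breaks the binomial
    # null; the best shadow seen so far keeps null hit probabilities at or
    # below 1/2
    hit <- real_imp[feats[und]] > sh_max_ever
    hits[und] <- hits[und] + as.integer(hit)
    runs_used[und] <- runs_used[und] + 1L
    # two-sided binomial decisions with Bonferroni over features under test
    thr <- alpha / length(und)
    p_conf <- pbinom(hits[und] - 1L, runs_used[und], 0.5,
                     lower.tail = FALSE)
    p_rej <- pbinom(hits[und], runs_used[und], 0.5)
    newly_conf <- und[p_conf < thr]
    newly_rej <- und[p_rej < thr]
    decision[newly_conf] <- "confirmed"
    decision[newly_rej] <- "rejected"
  }
  structure(list(
    decision = factor(decision,
                      levels = c("confirmed", "tentative", "rejected")),
    hit_count = hits,
    runs_used = runs_used,
    importance_history = imp_hist,
    confidence = confidence,
    response_classes = levels(y),
    seed = seed,
    params = list(max_runs = max_runs, importance = importance,
                  num_trees = num_trees, total_runs = run)
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  tb <- table(x$decision)
  cat("<selection_result> ", length(x$decision), " features after ",
      x$params$total_runs, " runs: ", tb[["confirmed"]], " confirmed, ",
      tb[["tentative"]], " tentative, ", tb[["rejected"]],
      " rejected (confidence ", x$confidence, ")\n", sep = "")
  invisible(x)
}

#' Features confirmed by a selection run
#' @param sel A `selection_result`.
#' @return Character vector of confirmed feature ids.
#' @export
confirmed_features <- function(sel) {
  stopifnot(inherits(sel, "selection_result"))
  names(sel$decision)[sel$decision == "confirmed"]
}

#' Export a selection result as TSV plus a JSON run log
#'
#' Writes `<path>` with one row per feature (decision, hit count, runs,
#' median importance) and `<path>.log.json` with the seed and parameters.
#'
#' @param sel A `selection_result`.
#' @param path Output TSV path.
#' @export
write_selection <- function(sel, path) {
  stopifnot(inherits(sel, "selection_result"))
  med <- apply(sel$importance_history, 2L, function(v)
    if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE))
  out <- data.frame(feature = names(sel$decision),
                    decision = as.character(sel$decision),
                    hit_count = sel$hit_count,
                    runs_used = sel$runs_used,
                    median_importance = med[names(sel$decision)],
                    row.names = NULL)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    seed = sel$seed, confidence = sel$confidence,
    response_classes = sel$response_classes, params = sel$params,
    n_confirmed = sum(sel$decision == "confirmed"),
    n_tentative = sum(sel$decision == "tentative"),
    n_rejected = sum(sel$decision == "rejected")
  ), paste0(path, ".log.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}
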