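# Orchestration of the two end-to-end workflows, each writing a
# deterministic report bundle (TSV matrices, clustering JSON, ranking
# tables, run log).  Stage failures abort with the stage name so partial
# bundles are never mistaken for complete ones.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

run_log <- function(out_dir, config, extra = list()) {
  log <- c(list(
    package = "funcdiff",
    version = as.character(packageVersion("funcdiff")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = config[!vapply(config, is.function, logical(1))]
  ), extra)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
}

#' Run the isolate-genome comparison workflow
#'
#' Reads (or accepts) per-organism KO annotations and a pathway ontology,
#' builds the KO presence matrix K and pathway coverage matrix P, clusters
#' the organisms at the requested cluster count, merges the clusters
#' agglomeratively for inspection, and ranks pathways by coverage SD across
#' the cluster exemplars.  All outputs land in `config$out_dir`.
#'
#' @param config List with elements:
#'   `annotations` (list of [ko_annotation()]) or `annotation_paths`
#'   (named character vector path -> unit id);
#'   `ontology` (a [pathway_ontology()]) or `ontology_path`;
#'   `target_k` (desired cluster count); `measure` (default `"pearson"`);
#'   `cluster_on` (`"K"` or `"P"`, default `"K"`); `top_n` pathways
#'   (default 20); `seed` (default 1); `out_dir` (default `NULL`: nothing
#'   written).
#' @return List with `K`, `P`, `clustering`, `dendrogram`, `ranking`,
#'   `annotation_fractions`.
#' @export
run_isolate_workflow <- function(config) {
  cfg <- utils::modifyList(list(measure = "pearson", cluster_on = "K",
                                top_n = 20L, seed = 1L, out_dir = NULL),
                           config)
  ont <- stage("read_ontology", {
    if (!is.null(cfg[["ontology"]])) cfg[["ontology"]]
    else read_pathway_table(cfg$ontology_path)
  })
  anns <- stage("read_annotations", {
    if (!is.null(cfg[["annotations"]])) cfg[["annotations"]]
    else Map(read_ko_annotation, names(cfg$annotation_paths),
             unname(cfg$annotation_paths))
  })
  K <- stage("build_ko_presence", build_ko_presence(anns))
  P <- stage("build_pathway_matrix", build_pathway_matrix(anns, ont))
  frac <- stage("annotation_fraction",
                vapply(anns, annotation_fraction, numeric(1)))
  names(frac) <- vapply(anns, `[[`, character(1), "unit_id")
  s <- stage("similarity",
             similarity(if (cfg$cluster_on == "K") K else P,
                        measure = cfg$measure))
  cl <- stage("cluster", tune_preference(s, cfg$target_k, seed = cfg$seed))
  dend <- stage("agglomerate",
                if (cl$n_clusters >= 2L) agglomerate_clusters(s, cl) else NULL)
  exemplars <- unique(unname(cl$exemplar_of))
  ranking <- stage("rank_pathways",
                   rank_pathways_by_sd(P, units = exemplars,
                                       top_n = cfg$top_n))
  if (!is.null(cfg$out_dir)) {
    stage("write_bundle", {
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_matrix(K, file.path(cfg$out_dir, "K.tsv"))
      write_matrix(P, file.path(cfg$out_dir, "P.tsv"))
      write_clustering(cl, file.path(cfg$out_dir, "clustering.json"))
      if (!is.null(dend)) {
        write.table(dend$cut_table,
                    file.path(cfg$out_dir, "cluster_cuts.tsv"),
                    sep = "\t", quote = FALSE, col.names = NA)
      }
      write.table(as.data.frame(ranking),
                  file.path(cfg$out_dir, "pathway_ranking.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      run_log(cfg$out_dir, cfg,
              list(n_clusters = cl$n_clusters,
                   annotation_fractions = as.list(frac)))
    })
  }
  invisible(list(K = K, P = P, clustering = cl, dendrogram = dend,
                 ranking = ranking, annotation_fractions = frac))
}

#' Run the metagenome community workflow
#'
#' From per-sample ORF coverage tables: builds the genus abundance matrix G
#' (per-million normalized, optionally complement-adjusted for an
#' inoculated genus), the KO-genus matrix A and pathway-genus matrix PM;
#' keeps the most variable genera as a dynamics table; clusters the samples
#' on the per-million A matrix; computes Shannon diversity per sample; and,
#' when class labels are supplied, runs shadow-feature selection and the
#' leave-genus-out robustness check.
#'
#' @param config List with elements:
#'   `annotations` (list of sample [ko_annotation()]) or
#'   `annotation_paths` (named character vector path -> sample id);
#'   `ontology` / `ontology_path`; `target_k`; `measure` (default
#'   `"pearson"`); `focal_genus` (optional, complement adjustment);
#'   `dynamics_top_n` (default 10); `labels` (optional class labels, in
#'   column order of the matrices); `select_max_runs` (default 100);
#'   `robustness_drop` (optional genera to drop); `seed`; `out_dir`.
#' @return List with `G_raw`, `G`, `G_adjusted` (or NULL), `A`, `PM`,
#'   `dynamics`, `clustering`, `shannon`, `selection` (or NULL),
#'   `robustness` (or NULL).
#' @export
run_metagenome_workflow <- function(config) {
  cfg <- utils::modifyList(list(measure = "pearson", dynamics_top_n = 10L,
                                select_max_runs = 100L, seed = 1L,
                                out_dir = NULL, focal_genus = NULL,
                                labels = NULL, robustness_drop = NULL),
                           config)
  ont <- stage("read_ontology", {
    if (!is.null(cfg[["ontology"]])) cfg[["ontology"]]
    else read_pathway_table(cfg$ontology_path)
  })
  anns <- stage("read_annotations", {
    if (!is.null(cfg[["annotations"]])) cfg[["annotations"]]
    else Map(read_genus_coverage_table, names(cfg$annotation_paths),
             unname(cfg$annotation_paths))
  })
  G_raw <- stage("build_genus_abundance", build_genus_abundance(anns))
  G <- stage("normalize_per_million", normalize_per_million(G_raw))
  G_adj <- if (!is.null(cfg$focal_genus)) {
    stage("complement_adjust", complement_adjust(G, cfg$focal_genus))
  }
  A <- stage("build_ko_genus_matrix", build_ko_genus_matrix(anns))
  PM <- stage("build_pathway_genus_matrix",
              build_pathway_genus_matrix(anns, ont))
  dynamics <- stage("filter_dynamics",
                    filter_rows_by_sd(if (is.null(G_adj)) G else G_adj,
                                      top_n = min(cfg$dynamics_top_n,
                                                  nrow((if (is.null(G_adj)) G else G_adj)$values))))
  A_pm <- stage("normalize_A", normalize_per_million(A))
  s <- stage("similarity", similarity(A_pm, measure = cfg$measure))
  cl <- stage("cluster", tune_preference(s, cfg$target_k, seed = cfg$seed))
  shannon <- stage("shannon",
                   apply(G_raw$values, 2L, shannon_index))
  selection <- if (!is.null(cfg$labels)) {
    stage("feature_selection",
          boruta_select(A_pm, cfg$labels, seed = cfg$seed,
                        max_runs = cfg$select_max_runs))
  }
  robustness <- if (!is.null(cfg$robustness_drop)) {
    stage("robustness",
          robustness_leave_genus_out(A, cfg$robustness_drop,
                                     measure = cfg$measure,
                                     target_k = cfg$target_k,
                                     seed = cfg$seed))
  }
  if (!is.null(cfg$out_dir)) {
    stage("write_bundle", {
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_matrix(G_raw, file.path(cfg$out_dir, "G_raw.tsv"))
      write_matrix(G, file.path(cfg$out_dir, "G_per_million.tsv"))
      if (!is.null(G_adj)) {
        write_matrix(G_adj, file.path(cfg$out_dir, "G_complement.tsv"))
      }
      write_matrix(A, file.path(cfg$out_dir, "A_raw.tsv"))
      write_matrix(PM, file.path(cfg$out_dir, "PM.tsv"))
      write_matrix(dynamics, file.path(cfg$out_dir, "genus_dynamics.tsv"))
      write_clustering(cl, file.path(cfg$out_dir, "clustering.json"))
      write.table(data.frame(sample = names(shannon),
                             shannon = unname(shannon)),
                  file.path(cfg$out_dir, "shannon.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(selection)) {
        write_selection(selection, file.path(cfg$out_dir, "selection.tsv"))
      }
      run_log(cfg$out_dir, cfg[setdiff(names(cfg), c("annotations", "ontology", "labels"))],
              list(n_clusters = cl$n_clusters,
                   robustness_ari = if (!is.null(robustness)) robustness$ari))
    })
  }
  invisible(list(G_raw = G_raw, G = G, G_adjusted = G_adj, A = A, PM = PM,
                 dynamics = dynamics, clustering = cl, shannon = shannon,
                 selection = selection, robustness = robustness))
}
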