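# Synthetic communities with the statistical structure the pipeline
# assumes: a pathway ontology of disjoint KO blocks, isolate genomes with
# planted pathway absences (auxotrophies), and metagenome read series with
# planted genus dynamics, an inoculated genus and red/white class structure.
# Everything is deterministic given the spec seed.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  force(code)
}

default_organisms <- function() {
  groups <- list(
    list(genus = "Lactobacillus_kefir", n = 2, absences = paste0("path", sprintf("%02d", 1:4))),
    list(genus = "Lactobacillus",       n = 4, absences = "path05"),
    list(genus = "Lactococcus",         n = 5, absences = paste0("path", sprintf("%02d", 6:7))),
    list(genus = "Leuconostoc",         n = 4, absences = paste0("path", sprintf("%02d", 8:9))),
    list(genus = "Acetobacter",         n = 4, absences = paste0("path", sprintf("%02d", 10:11))),
    list(genus = "Rothia",              n = 3, absences = paste0("path", sprintf("%02d", 12:13))),
    list(genus = "Staphylococcus",      n = 4, absences = paste0("path", sprintf("%02d", 14:15))),
    list(genus = "Micrococcus",         n = 4, absences = paste0("path", sprintf("%02d", 16:17)))
  )
  do.call(rbind, lapply(groups, function(g) {
    data.frame(name = paste0(g$genus, "_", seq_len(g$n)), genus = g$genus,
               absences = I(rep(list(g$absences), g$n)),
               stringsAsFactors = FALSE)
  }))
}

default_samples <- function() {
  varieties <- c(Bobal = "red", Tempranillo = "red", Airen = "white")
  timepoints <- c(0, 1, 2, 3, 4, 7, 14, 21)
  out <- do.call(rbind, lapply(names(varieties), function(v) {
    do.call(rbind, lapply(c("inoc", "ctrl1", "ctrl2"), function(f) {
      data.frame(
        name = paste(v, f, paste0("d", timepoints), sep = "_"),
        variety = v, class_label = varieties[[v]],
        treatment = if (f == "inoc") "inoculated" else "control",
        timepoint = timepoints, stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

default_genus_dynamics <- function() {
  # baseline genus weight per timepoint (columns d0..d21); weights are
  # relative and renormalized per sample after class/variety effects
  m <- rbind(
    Saccharomyces = c(0.10, 0.25, 0.45, 0.60, 0.70, 0.75, 0.70, 0.60),
    Vitis         = c(0.35, 0.25, 0.15, 0.08, 0.05, 0.03, 0.02, 0.02),
    Pseudomonas   = c(0.20, 0.15, 0.10, 0.08, 0.06, 0.05, 0.05, 0.05),
    Lactobacillus = c(0.01, 0.01, 0.02, 0.02, 0.02, 0.03, 0.03, 0.03),
    Oenococcus    = c(0.01, 0.02, 0.03, 0.05, 0.08, 0.10, 0.15, 0.20),
    Pediococcus   = c(0.02, 0.02, 0.03, 0.03, 0.03, 0.03, 0.03, 0.03),
    Pantoea       = c(0.10, 0.10, 0.08, 0.06, 0.04, 0.03, 0.02, 0.02),
    Gluconobacter = c(0.08, 0.08, 0.06, 0.04, 0.03, 0.02, 0.02, 0.02),
    Dyella        = c(0.05, 0.04, 0.03, 0.02, 0.02, 0.02, 0.01, 0.01),
    Acetobacter   = c(0.04, 0.04, 0.03, 0.03, 0.02, 0.02, 0.02, 0.02),
    Aspergillus   = c(0.06, 0.04, 0.03, 0.02, 0.02, 0.01, 0.01, 0.01),
    Sclerotinia   = c(0.04, 0.03, 0.02, 0.02, 0.01, 0.01, 0.01, 0.01)
  )
  colnames(m) <- paste0("d", c(0, 1, 2, 3, 4, 7, 14, 21))
  m
}

default_class_effects <- function() {
  # multiplicative genus weight per class; 0 = genus absent from the class
  list(
    Pantoea       = c(red = 0, white = 1),
    Gluconobacter = c(red = 0, white = 1),
    Dyella        = c(red = 1, white = 0),
    Acetobacter   = c(red = 1, white = 0),
    Vitis         = c(red = 1, white = 0.15),
    Aspergillus   = c(red = 0.3, white = 1),
    Sclerotinia   = c(red = 0.3, white = 1)
  )
}

#' Specification of a synthetic community experiment
#'
#' Bundles the generator parameters for both branches of the pipeline: the
#' pathway ontology, the isolate genomes with planted pathway absences, and
#' the metagenome time series with planted genus dynamics, class structure
#' (red vs. white) and an inoculated genus.  The defaults emulate a
#' milk-kefir isolate panel (30 organisms in 8 functional groups over a
#' 20-pathway ontology) and a wine-fermentation series (3 varieties x 3
#' fermentations x 8 timepoints = 72 samples, *Lactobacillus* inoculated in
#' one fermentation per variety).
#'
#' @param n_pathways Number of pathways in the ontology.
#' @param kos_per_pathway Integer range `c(lo, hi)` of member KOs drawn
#'   uniformly per pathway.
#' @param organisms Data frame `name`, `genus`, `absences` (list column of
#'   pathway ids absent from the organism).
#' @param extra_ko_rate Probability that a KO from an absent pathway leaks
#'   into an organism anyway (annotation noise).
#' @param unannotated_rate Fraction of genes/ORFs with no KO assignment
#'   (default 0.5, the typical annotatable fraction of bacterial genomes).
#' @param samples Data frame `name`, `variety`, `class_label`, `treatment`,
#'   `timepoint`.
#' @param genus_dynamics Matrix genus x timepoint of baseline relative
#'   weights (renormalized per sample).
#' @param class_effects Named list genus -> named multiplier per class.
#' @param inoculated_genus List `name`, `boost` (weight multiplier applied
#'   in samples with `treatment == "inoculated"`).
#' @param genus_ko_rate Probability a genus carries any given KO.
#' @param reads_per_sample Reads drawn per metagenome sample.
#' @param overdispersion `NULL` for multinomial reads, or a Dirichlet
#'   concentration (smaller = more overdispersed) for
#'   Dirichlet-multinomial reads.
#' @param seed Integer seed; all generators are deterministic given it.
#' @return An object of class `community_spec`.
#' @export
community_spec <- function(n_pathways = 20L,
                           kos_per_pathway = c(4L, 12L),
                           organisms = default_organisms(),
                           extra_ko_rate = 0.02,
                           unannotated_rate = 0.5,
                           samples = default_samples(),
                           genus_dynamics = default_genus_dynamics(),
                           class_effects = default_class_effects(),
                           inoculated_genus = list(name = "Lactobacillus",
                                                   boost = 30),
                           genus_ko_rate = 0.4,
                           reads_per_sample = 100000L,
                           overdispersion = NULL,
                           seed = 1L) {
  stopifnot(n_pathways >= 1L, length(kos_per_pathway) == 2L,
            reads_per_sample >= 1L,
            extra_ko_rate >= 0, extra_ko_rate <= 1,
            unannotated_rate >= 0, unannotated_rate < 1)
  if (kos_per_pathway[1L] > kos_per_pathway[2L] || kos_per_pathway[1L] < 1L) {
    stop("kos_per_pathway must be a non-empty positive range")
  }
  all_paths <- paste0("path", sprintf("%02d", seq_len(n_pathways)))
  bad <- setdiff(unlist(organisms$absences), all_paths)
  if (length(bad)) {
    stop("pathway_absences reference unknown pathway '", bad[1L], "'")
  }
  structure(list(
    n_pathways = as.integer(n_pathways),
    kos_per_pathway = as.integer(kos_per_pathway),
    organisms = organisms, extra_ko_rate = extra_ko_rate,
    unannotated_rate = unannotated_rate,
    samples = samples, genus_dynamics = genus_dynamics,
    class_effects = class_effects, inoculated_genus = inoculated_genus,
    genus_ko_rate = genus_ko_rate,
    reads_per_sample = as.integer(reads_per_sample),
    overdispersion = overdispersion,
    seed = as.integer(seed)
  ), class = "community_spec")
}

#' @export
print.community_spec <- function(x, ...) {
  cat("<community_spec> ", x$n_pathways, " pathways, ",
      nrow(x$organisms), " organisms, ", nrow(x$samples),
      " samples, ", x$reads_per_sample, " reads/sample (seed ",
      x$seed, ")\n", sep = "")
  invisible(x)
}

#' Generate a synthetic pathway ontology
#'
#' Pathways receive pairwise-disjoint blocks of consecutive KO identifiers,
#' with sizes drawn uniformly from `kos_per_pathway`.  Disjoint blocks keep
#' brute-force coverage oracles exact; the real KEGG ontology overlaps, so
#' treat these fixtures as idealized.
#'
#' @param spec A [community_spec()].
#' @return A [pathway_ontology()].
#' @export
make_ontology <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  with_seed(spec$seed, {
    rng <- seq(spec$kos_per_pathway[1L], spec$kos_per_pathway[2L])
    sizes <- rng[sample.int(length(rng), spec$n_pathways, replace = TRUE)]
    ids <- paste0("path", sprintf("%02d", seq_len(spec$n_pathways)))
    stops <- cumsum(sizes)
    starts <- c(1L, head(stops, -1L) + 1L)
    members <- Map(function(a, b) sprintf("K%05d", a:b), starts, stops)
    pathway_ontology(ids, paste("Pathway", seq_along(ids)), members)
  })
}

#' Generate isolate genome annotations with planted pathway absences
#'
#' Each organism carries every KO of the pathways *not* in its absence set;
#' KOs of absent pathways leak in independently at `extra_ko_rate`
#' (annotation noise).  Unannotated genes are appended so the KO-annotated
#' fraction matches `1 - unannotated_rate`.  Before noise, a planted
#' absence yields pathway coverage exactly 0 and all other pathways
#' coverage exactly 1.
#'
#' @param spec A [community_spec()].
#' @param ont The ontology from [make_ontology()] (or compatible).
#' @return List of [ko_annotation()] objects, one per organism.
#' @export
make_isolates <- function(spec, ont) {
  stopifnot(inherits(spec, "community_spec"),
            inherits(ont, "pathway_ontology"))
  orgs <- spec$organisms
  if (nrow(orgs) == 0L) stop("spec has no organisms")
  lapply(seq_len(nrow(orgs)), function(i) {
    with_seed(spec$seed + 1000L + i, {
      absent <- unlist(orgs$absences[[i]])
      kos <- unlist(lapply(pathway_ids(ont), function(p) {
        m <- pathway_members(ont, p)
        if (p %in% absent) m[runif(length(m)) < spec$extra_ko_rate] else m
      }), use.names = FALSE)
      kos <- sort(unique(kos))
      n_ann <- length(kos)
      n_un <- round(n_ann * spec$unannotated_rate / (1 - spec$unannotated_rate))
      ko_annotation(
        orgs$name[i],
        gene_id = sprintf("%s_g%04d", orgs$name[i], seq_len(n_ann + n_un)),
        ko = c(kos, rep(NA_character_, n_un)),
        genus = orgs$genus[i])
    })
  })
}

# deterministic KO repertoire per genus (which KOs a genus can express)
genus_repertoires <- function(spec, ont) {
  kos <- sort(unique(unlist(lapply(pathway_ids(ont),
                                   pathway_members, ont = ont))))
  genera <- rownames(spec$genus_dynamics)
  reps <- lapply(seq_along(genera), function(i) {
    with_seed(spec$seed + 5000L + i, {
      r <- kos[runif(length(kos)) < spec$genus_ko_rate]
      if (length(r) == 0L) r <- kos[1L + (i %% length(kos))]
      r
    })
  })
  names(reps) <- genera
  reps
}

#' Expected genus relative abundances per sample
#'
#' The planted truth behind [make_metagenome_series()]: baseline dynamics
#' at the sample's timepoint, multiplied by the class effect and the
#' inoculation boost, renormalized to sum to 1.
#'
#' @param spec A [community_spec()].
#' @return Matrix genera x samples of relative abundances (columns sum
#'   to 1).
#' @export
expected_genus_shares <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  dyn <- spec$genus_dynamics
  genera <- rownames(dyn)
  smp <- spec$samples
  shares <- vapply(seq_len(nrow(smp)), function(j) {
    tp <- paste0("d", smp$timepoint[j])
    if (!tp %in% colnames(dyn)) {
      stop("no dynamics column for timepoint '", tp, "'")
    }
    w <- dyn[, tp]
    for (g in names(spec$class_effects)) {
      eff <- spec$class_effects[[g]]
      if (g %in% genera && smp$class_label[j] %in% names(eff)) {
        w[g] <- w[g] * eff[[smp$class_label[j]]]
      }
    }
    ig <- spec$inoculated_genus
    if (!is.null(ig) && smp$treatment[j] == "inoculated" &&
        ig$name %in% genera) {
      w[ig$name] <- w[ig$name] * ig$boost
    }
    s <- sum(w)
    if (s <= 0) stop("sample '", smp$name[j], "' has zero total weight")
    w / s
  }, numeric(length(genera)))
  dimnames(shares) <- list(genera, smp$name)
  stopifnot(all(abs(colSums(shares) - 1) < 1e-9))
  shares
}

#' Generate a metagenome read-coverage time series
#'
#' Reads are drawn multinomially (or Dirichlet-multinomially when
#' `overdispersion` is set) over (genus, KO) cells: each genus receives its
#' planted relative abundance, split uniformly over its KO repertoire, with
#' a fraction `unannotated_rate` of each genus' reads assigned to
#' unannotated ORFs.  The expected KO-annotated genus share therefore
#' equals [expected_genus_shares()].
#'
#' @param spec A [community_spec()].
#' @param ont The ontology from [make_ontology()].
#' @return List of sample [ko_annotation()] objects with `genus` and
#'   `coverage` populated.
#' @export
make_metagenome_series <- function(spec, ont) {
  stopifnot(inherits(spec, "community_spec"),
            inherits(ont, "pathway_ontology"))
  reps <- genus_repertoires(spec, ont)
  shares <- expected_genus_shares(spec)
  genera <- rownames(shares)
  smp <- spec$samples
  lapply(seq_len(nrow(smp)), function(j) {
    with_seed(spec$seed + 20000L + j, {
      cells <- do.call(rbind, lapply(genera, function(g) {
        kos <- reps[[g]]
        ann <- shares[g, j] * (1 - spec$unannotated_rate) / length(kos)
        rbind(data.frame(ko = kos, genus = g, p = ann),
              data.frame(ko = NA_character_, genus = g,
                         p = shares[g, j] * spec$unannotated_rate))
      }))
      pr <- cells$p
      if (!is.null(spec$overdispersion)) {
        a <- rgamma(length(pr), shape = spec$overdispersion * pr, rate = 1)
        if (sum(a) > 0) pr <- a / sum(a)
      }
      counts <- as.vector(rmultinom(1L, spec$reads_per_sample, pr))
      keep <- counts > 0
      n <- sum(keep)
      ko_annotation(
        smp$name[j],
        gene_id = sprintf("%s_orf%05d", smp$name[j], seq_len(n)),
        ko = cells$ko[keep], genus = cells$genus[keep],
        coverage = counts[keep])
    })
  })
}

#' Write synthetic annotations in the pipeline's TSV dialects
#'
#' Isolate annotations are written as two-column gene/KO tables, sample
#' annotations as four-column ORF coverage tables, into `dir` as
#' `<unit>.tsv`.
#'
#' @param anns List of [ko_annotation()] objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_annotations <- function(anns, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(anns, function(a) {
    path <- file.path(dir, paste0(a$unit_id, ".tsv"))
    r <- a$records
    if (all(is.na(r$coverage))) {
      lines <- paste(r$gene_id, ifelse(is.na(r$ko), "", r$ko), sep = "\t")
    } else {
      lines <- paste(r$gene_id, ifelse(is.na(r$ko), "", r$ko),
                     ifelse(is.na(r$genus), "", r$genus),
                     format(r$coverage, trim = TRUE, scientific = FALSE),
                     sep = "\t")
    }
    writeLines(lines, path)
    path
  }, character(1))
  invisible(paths)
}

#' Write a pathway ontology as a membership table
#'
#' @param ont A [pathway_ontology()].
#' @param path Output TSV path.
#' @export
write_pathway_table <- function(ont, path) {
  stopifnot(inherits(ont, "pathway_ontology"))
  lines <- vapply(pathway_ids(ont), function(p)
    paste(p, ont$pathways[[p]]$name,
          paste(ont$pathways[[p]]$members, collapse = ","), sep = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(NULL)
}
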