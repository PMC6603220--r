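# I/O for the tab-separated dialects the pipeline consumes:
#   gene_id <TAB> KO                          (KOALA-style annotator output)
#   pathway_id <TAB> name <TAB> KO,KO,...     (pathway membership)
#   orf_id <TAB> KO <TAB> genus <TAB> reads   (metagenome ORF coverage)
# All files are UTF-8, '#'-prefixed lines are comments.

KO_PATTERN <- "^K[0-9]{5}$"

#' KO annotation of one unit (organism or metagenome sample)
#'
#' Container for the gene (or ORF) to KO ortholog mapping of a single unit.
#' For metagenome samples each record may additionally carry the genus the
#' ORF was taxonomically assigned to and the number of reads mapped to it.
#'
#' @param unit_id Single string naming the organism or sample.
#' @param gene_id Character vector of gene/ORF identifiers, unique within the
#'   unit.
#' @param ko Character vector of KO identifiers (`K` followed by five digits)
#'   or `NA` for unannotated genes.
#' @param genus Optional character vector of genus labels (`NA` if unknown).
#' @param coverage Optional non-negative numeric read counts (`NA` if absent).
#'
#' @return An object of class `ko_annotation`: a list with elements `unit_id`
#'   and `records` (a data frame with columns `gene_id`, `ko`, `genus`,
#'   `coverage`).
#' @export
ko_annotation <- function(unit_id, gene_id = character(), ko = NA,
                          genus = NA, coverage = NA) {
  stopifnot(is.character(unit_id), length(unit_id) == 1L, nzchar(unit_id))
  n <- length(gene_id)
  rec <- data.frame(
    gene_id  = as.character(gene_id),
    ko       = rep_len(as.character(ko), n),
    genus    = rep_len(as.character(genus), n),
    coverage = rep_len(as.numeric(coverage), n),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(rec$gene_id)) {
    dup <- rec$gene_id[duplicated(rec$gene_id)][1L]
    stop("duplicate gene_id '", dup, "' in unit '", unit_id, "'")
  }
  bad <- !is.na(rec$ko) & !grepl(KO_PATTERN, rec$ko)
  if (any(bad)) {
    stop("malformed KO identifier '", rec$ko[which(bad)[1L]],
         "' in unit '", unit_id, "' (expected K followed by five digits)")
  }
  if (any(!is.na(rec$coverage) & rec$coverage < 0)) {
    stop("negative coverage in unit '", unit_id, "'")
  }
  structure(list(unit_id = unit_id, records = rec), class = "ko_annotation")
}

#' @export
print.ko_annotation <- function(x, ...) {
  n <- nrow(x$records)
  cat("<ko_annotation> unit '", x$unit_id, "': ", n, " records, ",
      sum(!is.na(x$records$ko)), " KO-annotated\n", sep = "")
  invisible(x)
}

#' KOs present in a unit
#'
#' @param ann A [ko_annotation()].
#' @return Sorted character vector of distinct KO identifiers.
#' @export
ko_set <- function(ann) {
  stopifnot(inherits(ann, "ko_annotation"))
  sort(unique(ann$records$ko[!is.na(ann$records$ko)]))
}

#' Pathway ontology: pathway id -> member KO set
#'
#' The universe against which pathway coverage is computed.  A KO may belong
#' to several pathways; every member set must be non-empty because it is the
#' coverage denominator.
#'
#' @param pathway_id Character vector of pathway identifiers.
#' @param name Character vector of human-readable pathway names.
#' @param members List of character vectors of member KO identifiers,
#'   parallel to `pathway_id`.
#'
#' @return An object of class `pathway_ontology`: a named list of
#'   `list(name, members)` entries keyed by pathway id, ordered
#'   lexicographically.
#' @export
pathway_ontology <- function(pathway_id, name, members) {
  stopifnot(length(pathway_id) == length(name),
            length(pathway_id) == length(members))
  if (anyDuplicated(pathway_id)) stop("duplicate pathway ids")
  ok <- vapply(members, function(m) length(m) > 0L, logical(1))
  if (!all(ok)) {
    stop("pathway '", pathway_id[which(!ok)[1L]], "' has an empty KO set")
  }
  for (i in seq_along(members)) {
    m <- members[[i]]
    if (any(!grepl(KO_PATTERN, m))) {
      stop("pathway '", pathway_id[i], "' has a malformed KO identifier")
    }
    members[[i]] <- sort(unique(m))
  }
  ord <- order(pathway_id)
  pw <- Map(function(nm, mem) list(name = nm, members = mem),
            name[ord], members[ord])
  names(pw) <- pathway_id[ord]
  structure(list(pathways = pw), class = "pathway_ontology")
}

#' @export
print.pathway_ontology <- function(x, ...) {
  sizes <- vapply(x$pathways, function(p) length(p$members), integer(1))
  cat("<pathway_ontology> ", length(x$pathways), " pathways, ",
      length(unique(unlist(lapply(x$pathways, `[[`, "members")))),
      " distinct KOs (pathway sizes ", min(sizes), "-", max(sizes), ")\n",
      sep = "")
  invisible(x)
}

#' Pathway ids of an ontology
#' @param ont A [pathway_ontology()].
#' @return Character vector of pathway identifiers (lexicographic order).
#' @export
pathway_ids <- function(ont) names(ont$pathways)

#' Member KOs of one pathway
#' @param ont A [pathway_ontology()].
#' @param pathway_id Single pathway identifier.
#' @return Character vector of member KOs.
#' @export
pathway_members <- function(ont, pathway_id) {
  p <- ont$pathways[[pathway_id]]
  if (is.null(p)) stop("unknown pathway '", pathway_id, "'")
  p$members
}

# read non-comment, non-blank lines with their original line numbers
read_data_lines <- function(path) {
  if (!file.exists(path)) stop("cannot open file '", path, "'")
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(text = lines[keep], lineno = which(keep))
}

#' Read a two-column gene-to-KO annotation table
#'
#' Parses the output dialect of KOALA-style annotators: one gene per line,
#' `gene_id<TAB>KO`, with an empty second column for genes that received no
#' ortholog assignment.  Unannotated genes are retained (with `ko = NA`) so
#' that the annotation fraction can be reported.
#'
#' @param path Path to a tab-separated file.
#' @param unit_id Name of the organism or sample the file describes.
#' @return A [ko_annotation()].
#' @export
read_ko_annotation <- function(path, unit_id) {
  dl <- read_data_lines(path)
  if (length(dl$text) == 0L) return(ko_annotation(unit_id))
  parts <- strsplit(dl$text, "\t", fixed = TRUE)
  gene <- vapply(parts, `[`, character(1), 1L)
  ko <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else "",
               character(1))
  ko <- trimws(ko)
  bad <- nzchar(ko) & !grepl(KO_PATTERN, ko)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("malformed KO token '", ko[i], "' at line ", dl$lineno[i],
         " of '", path, "'")
  }
  ko[!nzchar(ko)] <- NA_character_
  if (anyDuplicated(gene)) {
    i <- which(duplicated(gene))[1L]
    stop("duplicate gene_id '", gene[i], "' at line ", dl$lineno[i],
         " of '", path, "'")
  }
  ko_annotation(unit_id, gene_id = gene, ko = ko)
}

#' Read a pathway-membership table
#'
#' Format: `pathway_id<TAB>pathway_name<TAB>comma-separated KO list`.
#' Multiple lines for the same pathway are unioned; duplicate
#' (pathway, KO) pairs are deduplicated.
#'
#' @param path Path to a tab-separated file.
#' @return A [pathway_ontology()].
#' @export
read_pathway_table <- function(path) {
  dl <- read_data_lines(path)
  if (length(dl$text) == 0L) stop("empty pathway table '", path, "'")
  parts <- strsplit(dl$text, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1L)
  nms <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else "",
                character(1))
  kos <- lapply(parts, function(p) {
    raw <- if (length(p) >= 3L) p[[3L]] else ""
    toks <- trimws(strsplit(raw, ",", fixed = TRUE)[[1L]])
    toks[nzchar(toks)]
  })
  empty <- vapply(kos, length, integer(1)) == 0L
  if (any(empty)) {
    i <- which(empty)[1L]
    stop("pathway '", ids[i], "' at line ", dl$lineno[i],
         " has an empty KO list")
  }
  uid <- sort(unique(ids))
  members <- lapply(uid, function(id) sort(unique(unlist(kos[ids == id]))))
  name <- vapply(uid, function(id) nms[ids == id][1L], character(1))
  pathway_ontology(uid, name, members)
}

#' Read a per-ORF genus/coverage table for one metagenome sample
#'
#' Format: `orf_id<TAB>KO<TAB>genus<TAB>read_count`.  An empty KO field
#' marks an unannotated ORF (kept, `ko = NA`); an empty genus field is
#' mapped to the reserved genus `"unclassified"` so that per-sample read
#' totals are conserved.
#'
#' @param path Path to a tab-separated file.
#' @param sample_id Name of the sample.
#' @return A [ko_annotation()] with `genus` and `coverage` populated.
#' @export
read_genus_coverage_table <- function(path, sample_id) {
  dl <- read_data_lines(path)
  if (length(dl$text) == 0L) return(ko_annotation(sample_id))
  parts <- strsplit(dl$text, "\t", fixed = TRUE)
  field <- function(k) vapply(parts, function(p)
    if (length(p) >= k) trimws(p[[k]]) else "", character(1))
  orf <- field(1L); ko <- field(2L); genus <- field(3L); cnt <- field(4L)
  bad <- nzchar(ko) & !grepl(KO_PATTERN, ko)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("malformed KO token '", ko[i], "' at line ", dl$lineno[i],
         " of '", path, "'")
  }
  ko[!nzchar(ko)] <- NA_character_
  genus[!nzchar(genus)] <- "unclassified"
  cov <- suppressWarnings(as.numeric(cnt))
  if (any(is.na(cov))) {
    i <- which(is.na(cov))[1L]
    stop("missing or non-numeric read count at line ", dl$lineno[i],
         " of '", path, "'")
  }
  if (any(cov < 0)) {
    i <- which(cov < 0)[1L]
    stop("negative read count at line ", dl$lineno[i], " of '", path, "'")
  }
  ko_annotation(sample_id, gene_id = orf, ko = ko, genus = genus,
                coverage = cov)
}

#' Fraction of genes with a KO assignment
#'
#' In typical bacterial genomes only around half of the coding sequences can
#' be mapped to a KO ortholog group; this reports that fraction for a unit.
#'
#' @param ann A [ko_annotation()] with at least one record.
#' @return A number in `[0, 1]`.
#' @export
annotation_fraction <- function(ann) {
  stopifnot(inherits(ann, "ko_annotation"))
  n <- nrow(ann$records)
  if (n == 0L) stop("annotation of unit '", ann$unit_id, "' has no records")
  sum(!is.na(ann$records$ko)) / n
}

#' Write a feature matrix as labeled TSV
#'
#' Header row of unit ids, first column of feature ids; the role and
#' normalization state are recorded in `#`-prefixed sidecar lines so the
#' file round-trips losslessly through [read_matrix()].
#'
#' @param m A [feature_matrix()].
#' @param path Output path.
#' @export
write_matrix <- function(m, path) {
  stopifnot(inherits(m, "feature_matrix"))
  labs <- c(rownames(m$values), colnames(m$values))
  if (any(grepl("\t", labs, fixed = TRUE))) {
    stop("matrix labels must not contain tab characters")
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(paste0("# role: ", m$role),
               paste0("# normalization: ", m$normalization)), con)
  writeLines(paste(c("feature", colnames(m$values)), collapse = "\t"), con)
  body <- apply(m$values, 1L, function(r)
    paste(format(r, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(paste(rownames(m$values), body, sep = "\t"), con)
  invisible(NULL)
}

#' Read a labeled TSV feature matrix written by [write_matrix()]
#'
#' @param path Path to the file.
#' @return A [feature_matrix()] with role and normalization restored from
#'   the sidecar comment lines (`generic`/`raw` when absent).
#' @export
read_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  meta <- lines[grepl("^#", lines)]
  get_meta <- function(key, default) {
    hit <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
    if (length(hit) == 0L) return(default)
    trimws(sub(paste0("^#\\s*", key, ":"), "", hit[1L]))
  }
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) < 1L) stop("no header row in '", path, "'")
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  cols <- header[-1L]
  rows <- body[-1L]
  parts <- strsplit(rows, "\t", fixed = TRUE)
  rid <- vapply(parts, `[`, character(1), 1L)
  vals <- t(vapply(parts, function(p) as.numeric(p[-1L]),
                   numeric(length(cols))))
  if (length(cols) == 1L) vals <- matrix(vals, ncol = 1L)
  dimnames(vals) <- list(rid, cols)
  feature_matrix(vals, role = get_meta("role", "generic"),
                 normalization = get_meta("normalization", "raw"))
}
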