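#' Pathway collections
#'
#' A `pathway_collection` holds named gene sets ("pathways", e.g. GO terms)
#' together with an ontology namespace label.  Gene identifiers are stored in
#' canonical form (see [normalize_gene_ids()]) and deduplicated within each
#' set; empty gene sets are rejected.
#'
#' @param id Character vector of unique pathway identifiers.
#' @param name Character vector of human-readable pathway names.
#' @param namespace Character vector (recycled) with values among
#'   `"biological_process"`, `"cellular_component"`, `"molecular_function"`,
#'   `"unassigned"`.
#' @param genes List of character vectors, one gene set per pathway.
#' @return An object of class `pathway_collection`.
#' @export
pathway_collection <- function(id, name = id, namespace = "unassigned",
                               genes) {
  id <- as.character(id)
  name <- as.character(name)
  if (anyDuplicated(id)) {
    stop("pathway ids must be unique; duplicated: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (length(genes) != length(id)) {
    stop("`genes` must have one entry per pathway id")
  }
  ns_levels <- c("biological_process", "cellular_component",
                 "molecular_function", "unassigned")
  namespace <- rep_len(as.character(namespace), length(id))
  if (!all(namespace %in% ns_levels)) {
    stop("unknown namespace label(s): ",
         paste(setdiff(unique(namespace), ns_levels), collapse = ", "))
  }
  genes <- lapply(genes, function(g) unique(normalize_gene_ids(g)))
  sizes <- lengths(genes)
  if (any(sizes == 0)) {
    stop("every pathway must have a non-empty gene set; empty: ",
         paste(id[sizes == 0], collapse = ", "))
  }
  structure(
    list(id = id, name = rep_len(name, length(id)),
         namespace = namespace, genes = genes),
    class = "pathway_collection"
  )
}

#' @export
length.pathway_collection <- function(x) length(x$id)

#' @export
`[.pathway_collection` <- function(x, i) {
  structure(
    list(id = x$id[i], name = x$name[i], namespace = x$namespace[i],
         genes = x$genes[i]),
    class = "pathway_collection"
  )
}

#' @export
print.pathway_collection <- function(x, ...) {
  n <- length(x)
  cat("<pathway_collection> ", n, " pathway(s)\n", sep = "")
  if (n > 0) {
    sz <- pathway_sizes(x)
    cat("  sizes: ", min(sz), "-", max(sz),
        " | distinct genes: ", length(unique(unlist(x$genes))), "\n", sep = "")
    ns <- table(x$namespace)
    cat("  namespaces: ",
        paste(names(ns), ns, sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Pathway set sizes
#'
#' @param collection A [pathway_collection()].
#' @return Named integer vector of gene-set sizes.
#' @export
pathway_sizes <- function(collection) {
  stopifnot(inherits(collection, "pathway_collection"))
  stats::setNames(lengths(collection$genes), collection$id)
}

#' Read gene-set annotations from GMT or GAF files
#'
#' GMT rows are `set-id <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#' GAF 2.x rows are inverted into term -> gene sets using the DB Object ID
#' (column 2), GO ID (column 5) and aspect (column 9, mapped to the GO
#' namespace).  Comment lines (leading `!` in GAF) and empty lines are
#' skipped; duplicate memberships within a set are collapsed.
#'
#' @param path Path to the annotation file.
#' @param format Either `"gmt"` or `"gaf"`.
#' @return A [pathway_collection()].
#' @export
read_gene_sets <- function(path, format = c("gmt", "gaf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "gmt") {
    keep <- nzchar(trimws(lines))
    idx <- which(keep)
    if (length(idx) == 0) stop("zero parsed sets in ", path)
    ids <- nms <- character(length(idx))
    genes <- vector("list", length(idx))
    for (k in seq_along(idx)) {
      fields <- strsplit(lines[idx[k]], "\t", fixed = TRUE)[[1]]
      if (length(fields) < 3) {
        stop("malformed GMT row at line ", idx[k],
             ": expected >= 3 tab-separated fields")
      }
      ids[k] <- fields[1]
      nms[k] <- fields[2]
      genes[[k]] <- fields[-(1:2)][nzchar(fields[-(1:2)])]
      if (length(genes[[k]]) == 0) {
        stop("malformed GMT row at line ", idx[k], ": no genes listed")
      }
    }
    return(pathway_collection(ids, nms, "unassigned", genes))
  }
  ## GAF 2.x
  idx <- which(nzchar(trimws(lines)) & !startsWith(lines, "!"))
  if (length(idx) == 0) stop("zero parsed sets in ", path)
  gene <- term <- aspect <- character(length(idx))
  for (k in seq_along(idx)) {
    fields <- strsplit(lines[idx[k]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 15) {
      stop("malformed GAF row at line ", idx[k],
           ": expected >= 15 tab-separated columns, got ", length(fields))
    }
    gene[k] <- fields[2]
    term[k] <- fields[5]
    aspect[k] <- fields[9]
  }
  ns_map <- c(P = "biological_process", C = "cellular_component",
              F = "molecular_function")
  sets <- split(gene, term)
  ns <- vapply(split(aspect, term), function(a) {
    m <- ns_map[a[1]]
    if (is.na(m)) "unassigned" else unname(m)
  }, character(1))
  pathway_collection(names(sets), names(sets), ns, sets)
}

#' Write a pathway collection as a GMT file
#'
#' @param collection A [pathway_collection()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "pathway_collection"))
  rows <- vapply(seq_along(collection$id), function(i) {
    paste(c(collection$id[i], collection$name[i], collection$genes[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Filter pathways by gene-set size
#'
#' Retains pathways whose size lies in the closed interval
#' `[min_size, max_size]`; removing under-informative (size < 6) and very
#' large (size > 1500) sets is the conventional preprocessing step, so those
#' are the defaults.  Order is preserved and the operation is idempotent.
#'
#' @param collection A [pathway_collection()].
#' @param min_size,max_size Inclusive size bounds (`1 <= min_size <= max_size`).
#' @return The filtered [pathway_collection()] (possibly empty).
#' @export
filter_by_size <- function(collection, min_size = 6, max_size = 1500) {
  stopifnot(inherits(collection, "pathway_collection"))
  if (!(min_size >= 1 && min_size <= max_size)) {
    stop("need 1 <= min_size <= max_size")
  }
  sz <- lengths(collection$genes)
  out <- collection[sz >= min_size & sz <= max_size]
  if (length(out) == 0) {
    message("filter_by_size: no pathways in [", min_size, ", ",
            max_size, "]")
  }
  out
}

candidate_id_set <- function(candidates) {
  if (inherits(candidates, "candidate_genes")) {
    normalize_gene_ids(candidates$gene_id)
  } else {
    unique(normalize_gene_ids(candidates))
  }
}

#' Keep only pathways containing at least one candidate gene
#'
#' @param collection A [pathway_collection()].
#' @param candidates A [candidate_genes()] table or character vector of ids.
#' @return The restricted [pathway_collection()].
#' @export
restrict_to_candidates <- function(collection, candidates) {
  stopifnot(inherits(collection, "pathway_collection"))
  cand <- candidate_id_set(candidates)
  hit <- vapply(collection$genes, function(g) any(g %in% cand), logical(1))
  collection[hit]
}

#' Intersect every pathway with a gene universe
#'
#' Each pathway's gene set is intersected with `universe` (the measured
#' genes of a condition); pathways emptied by the intersection are dropped.
#' This makes pathway sizes, candidate counts and the enrichment background
#' mutually consistent.
#'
#' @param collection A [pathway_collection()].
#' @param universe Non-empty character vector of gene ids.
#' @return The restricted [pathway_collection()].
#' @export
restrict_to_universe <- function(collection, universe) {
  stopifnot(inherits(collection, "pathway_collection"))
  universe <- unique(normalize_gene_ids(universe))
  if (length(universe) == 0) stop("universe must be non-empty")
  genes <- lapply(collection$genes, function(g) g[g %in% universe])
  keep <- lengths(genes) > 0
  out <- collection[keep]
  out$genes <- genes[keep]
  out
}

#' Candidate gene lists
#'
#' A prioritized candidate-gene list (e.g. the flooding-tolerance genes of a
#' soybean submergence study): unique gene ids with a dimensionless priority
#' score.  If `cutoff` is given, entries below it are dropped.
#'
#' @param gene_id Character vector of gene ids (unique after normalization).
#' @param priority_score Numeric prioritization scores.
#' @param cutoff Optional score cutoff; retained entries satisfy
#'   `priority_score >= cutoff`.
#' @return A `data.frame` of class `candidate_genes` with columns `gene_id`
#'   and `priority_score`.
#' @export
candidate_genes <- function(gene_id, priority_score = NA_real_,
                            cutoff = NULL) {
  gene_id <- normalize_gene_ids(gene_id)
  priority_score <- rep_len(as.numeric(priority_score), length(gene_id))
  if (anyDuplicated(gene_id)) {
    stop("candidate gene ids must be unique; duplicated: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  }
  df <- data.frame(gene_id = gene_id, priority_score = priority_score,
                   stringsAsFactors = FALSE)
  if (!is.null(cutoff)) df <- df[!is.na(df$priority_score) &
                                   df$priority_score >= cutoff, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("candidate_genes", "data.frame")
  df
}

#' Read a candidate-gene table
#'
#' Expects a TSV with header columns `gene_id` and (optionally)
#' `priority_score`; extra columns are ignored.
#'
#' @param path Path to the TSV file.
#' @param cutoff Optional priority-score cutoff (e.g. 42).
#' @return A [candidate_genes()] table.
#' @export
read_candidates <- function(path, cutoff = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(df)) {
    stop("candidate file must have a 'gene_id' column: ", path)
  }
  score <- if ("priority_score" %in% names(df)) df$priority_score else NA_real_
  candidate_genes(df$gene_id, score, cutoff = cutoff)
}
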