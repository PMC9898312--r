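#' Pipeline configuration
#'
#' Collects every input path and analysis threshold of the workflow.  All
#' defaults are ordinary configuration keys, none is hard-coded elsewhere:
#' pathway-size bounds 6/1500, raw significance threshold 1e-4, FDR level
#' 0.05, 10,000 permutations, degree band 20-30, low-degree collapse at 2,
#' intermediate recruitment at 2 seed links, single-gene score threshold 3.
#'
#' @param annotations Path to the GMT (or GAF) annotation file.
#' @param scores Named character vector of per-condition score-table TSV
#'   paths; names are the condition labels.
#' @param candidates Path to the candidate-gene TSV.
#' @param edges Path to the weighted edge-list TSV.
#' @param outdir Optional output directory; when `NULL` nothing is written.
#' @param annotation_format `"gmt"` or `"gaf"`.
#' @param min_size,max_size Pathway-size filter bounds.
#' @param significance_threshold Raw-p threshold for enrichment calls.
#' @param fdr_level Benjamini-Hochberg level reported alongside.
#' @param B Permutation count for the self-contained tests.
#' @param seed Top-level seed for all randomness.
#' @param degree_band Length-2 integer vector, inclusive degree band of
#'   the dense-core subnetwork.
#' @param low_degree_collapse Degree at or below which nodes are collapsed
#'   into a meta-node in the exported networks.
#' @param min_seed_links Seed-adjacency threshold for intermediate
#'   recruitment.
#' @param single_gene_threshold Score threshold for single-gene flags.
#' @param candidate_cutoff Optional priority-score cutoff applied when
#'   reading the candidate list.
#' @param group_resamples Resamples for the group-mean permutation tests.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(annotations, scores, candidates, edges,
                            outdir = NULL, annotation_format = "gmt",
                            min_size = 6, max_size = 1500,
                            significance_threshold = 1e-4,
                            fdr_level = 0.05, B = 10000, seed = 1,
                            degree_band = c(20, 30),
                            low_degree_collapse = 2, min_seed_links = 2,
                            single_gene_threshold = 3,
                            candidate_cutoff = NULL,
                            group_resamples = 2000) {
  stopifnot(min_size <= max_size, significance_threshold > 0,
            fdr_level > 0, degree_band[1] <= degree_band[2],
            min_seed_links >= 1, single_gene_threshold >= 0)
  if (is.null(names(scores)) || any(!nzchar(names(scores)))) {
    stop("`scores` must be a named vector: names are condition labels")
  }
  structure(
    list(annotations = annotations, scores = scores,
         candidates = candidates, edges = edges, outdir = outdir,
         annotation_format = annotation_format,
         min_size = min_size, max_size = max_size,
         significance_threshold = significance_threshold,
         fdr_level = fdr_level, B = as.integer(B), seed = as.integer(seed),
         degree_band = as.integer(degree_band),
         low_degree_collapse = as.integer(low_degree_collapse),
         min_seed_links = as.integer(min_seed_links),
         single_gene_threshold = single_gene_threshold,
         candidate_cutoff = candidate_cutoff,
         group_resamples = as.integer(group_resamples)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' The file holds the same keys as [pipeline_config()]; `scores` is a
#' mapping of condition label to path.  `overrides` (a named list, e.g.
#' from command-line flags) replaces keys after the file is read.
#'
#' @param path Path to the YAML configuration.
#' @param overrides Named list of overriding values.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  for (k in names(overrides)) raw[[k]] <- overrides[[k]]
  if (!is.null(raw$scores)) raw$scores <- unlist(raw$scores)
  do.call(pipeline_config, raw)
}

#' Run the full pathway / network / key-gene workflow
#'
#' Executes, in order: annotation filtering and candidate restriction;
#' score-table loading; competitive (hypergeometric) and self-contained
#' (SUMSTAT, SUMSQ) enrichment per condition; multiple-testing adjustment
#' and cross-condition consensus per method plus method intersections;
#' candidate-seeded network construction for the hypergeometric consensus
#' genes, the SUMSTAT consensus genes and their intersection; degree-band
#' core extraction and key-gene selection; and group-mean score
#' comparisons (key vs candidate vs intermediate vs remaining genes) per
#' condition.  When `config$outdir` is set, every stage's tables and
#' networks plus a run manifest are written there; reruns with an
#' identical configuration and seed produce byte-identical files.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `pathkey_run`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## Step 1: annotations
  collection <- stage("annotations", {
    coll <- read_gene_sets(config$annotations,
                           format = config$annotation_format)
    filter_by_size(coll, config$min_size, config$max_size)
  })
  candidates <- stage("candidates",
                      read_candidates(config$candidates,
                                      cutoff = config$candidate_cutoff))
  collection <- restrict_to_candidates(collection, candidates)

  ## Step 2: gene-wise statistic scores
  tables <- stage("scores", {
    tl <- lapply(names(config$scores), function(cond) {
      read_score_table(config$scores[[cond]], condition = cond)
    })
    stats::setNames(tl, names(config$scores))
  })

  ## Step 3: enrichment per condition and method
  pcfg <- perm_config(B = config$B, seed = config$seed)
  background <- list()
  results <- stage("enrichment", {
    out <- list()
    for (cond in names(tables)) {
      tab <- tables[[cond]]
      coll_u <- restrict_to_universe(collection, tab$gene_id)
      hyp <- test_competitive(tab, coll_u, candidates,
                              threshold = config$significance_threshold,
                              fdr_level = config$fdr_level)
      background[[cond]] <- list(L = attr(hyp, "L"), M = attr(hyp, "M"))
      sums <- lapply(c("sumstat", "sumsq"), function(st) {
        test_selfcontained(tab, coll_u, statistic = st, config = pcfg,
                           candidates = candidates,
                           threshold = config$significance_threshold,
                           fdr_level = config$fdr_level)
      })
      out[[cond]] <- do.call(rbind, c(list(hyp), sums))
    }
    do.call(rbind, out)
  })
  rownames(results) <- NULL
  consensus <- consensus_pathways(results, config$significance_threshold,
                                  require_all_conditions = TRUE)

  ## Steps 4-5: networks, degree bands, key genes
  reference <- stage("network", read_edge_list(config$edges))
  gene_subsets <- list(
    hypergeometric = consensus$per_method[["hypergeometric"]] %||%
      character(0),
    sumstat = consensus$per_method[["sumstat"]] %||% character(0),
    intersection = consensus$intersections[["hypergeometric.sumstat"]] %||%
      character(0)
  )
  networks <- list(); selections <- list()
  for (nm in names(gene_subsets)) {
    pids <- gene_subsets[[nm]]
    seeds <- if (length(pids) > 0) {
      intersect(unique(unlist(collection$genes[collection$id %in% pids])),
                candidate_id_set(candidates))
    } else character(0)
    if (length(seeds) == 0) {
      networks[[nm]] <- NULL
      next
    }
    net <- build_seeded_network(reference, seeds, config$min_seed_links)
    networks[[nm]] <- net
    selections[[nm]] <- extract_degree_band(net, config$degree_band[1],
                                            config$degree_band[2])
  }
  key_genes <- if (length(selections) > 0) {
    select_key_genes(selections, candidates)
  } else character(0)

  ## Step 5b: group comparisons
  intermediates <- unique(unlist(lapply(networks, function(n) {
    igraph::V(n)$name[igraph::V(n)$role == "intermediate"]
  })))
  comparisons <- stage("group_compare", {
    rows <- list()
    for (cond in names(tables)) {
      tab <- tables[[cond]]
      groups <- stratify_genes(tab, key_genes, candidates, intermediates)
      groups <- Filter(function(g) length(g) >= 2, groups)
      sc <- stats::setNames(tab$score, tab$gene_id)
      pairs <- list(c("key", "candidate"), c("key", "intermediate"),
                    c("key", "remaining"), c("candidate", "remaining"),
                    c("intermediate", "remaining"))
      for (pr in pairs) {
        if (!all(pr %in% names(groups))) next
        cmp <- compare_group_means(
          sc[groups[[pr[1]]]], sc[groups[[pr[2]]]],
          method = "permutation_mean_diff",
          n_resamples = config$group_resamples,
          seed = derive_seed(config$seed, "groups", cond, pr[1], pr[2]),
          group_a = pr[1], group_b = pr[2]
        )
        rows[[length(rows) + 1]] <- data.frame(
          condition = cond, group_a = pr[1], group_b = pr[2],
          n_a = length(groups[[pr[1]]]), n_b = length(groups[[pr[2]]]),
          mean_a = cmp$mean_a, mean_b = cmp$mean_b,
          statistic = cmp$statistic, p_value = cmp$p_value,
          method = cmp$method, exact = cmp$exact,
          stringsAsFactors = FALSE
        )
      }
    }
    if (length(rows) > 0) do.call(rbind, rows) else NULL
  })

  manifest <- list(
    config = unclass(config),
    background = background,
    n_pathways_analysed = length(collection),
    n_candidates = nrow(candidates),
    n_conditions = length(tables),
    consensus_sizes = lapply(consensus$per_method, length),
    key_genes = key_genes,
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )

  run <- structure(
    list(config = config, collection = collection,
         candidates = candidates, tables = tables, results = results,
         consensus = consensus, networks = networks,
         selections = selections, key_genes = key_genes,
         intermediates = intermediates, comparisons = comparisons,
         manifest = manifest),
    class = "pathkey_run"
  )
  if (!is.null(config$outdir)) write_run_outputs(run, config$outdir)
  run
}

## Serialize every stage's outputs; deterministic (no timestamps).
write_run_outputs <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- run$config
  write_gmt(run$collection, file.path(outdir, "pathways_filtered.gmt"))
  for (cond in names(run$tables)) {
    write_score_table(run$tables[[cond]],
                      file.path(outdir, paste0("scores_", cond, ".tsv")),
                      threshold = cfg$single_gene_threshold)
  }
  res <- run$results
  for (m in unique(res$method)) {
    for (cond in unique(res$condition)) {
      sub <- res[res$method == m & res$condition == cond, , drop = FALSE]
      write.table(sub,
                  file.path(outdir,
                            paste0("enrichment_", m, "_", cond, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  cons <- run$consensus
  cons_rows <- do.call(rbind, c(
    lapply(names(cons$per_method), function(m) {
      if (length(cons$per_method[[m]]) == 0) return(NULL)
      data.frame(set = m, kind = "method",
                 pathway_id = cons$per_method[[m]],
                 stringsAsFactors = FALSE)
    }),
    lapply(names(cons$intersections), function(m) {
      if (length(cons$intersections[[m]]) == 0) return(NULL)
      data.frame(set = m, kind = "intersection",
                 pathway_id = cons$intersections[[m]],
                 stringsAsFactors = FALSE)
    })
  ))
  if (is.null(cons_rows)) {
    cons_rows <- data.frame(set = character(0), kind = character(0),
                            pathway_id = character(0))
  }
  write.table(cons_rows, file.path(outdir, "consensus.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (nm in names(run$networks)) {
    net <- run$networks[[nm]]
    export_network(net, file.path(outdir, paste0("network_", nm, ".sif")),
                   "sif")
    export_network(net,
                   file.path(outdir, paste0("network_", nm, ".graphml")),
                   "graphml")
    collapsed <- collapse_low_degree(net, cfg$low_degree_collapse)
    export_network(collapsed,
                   file.path(outdir,
                             paste0("network_", nm, "_collapsed.graphml")),
                   "graphml")
    ## selection report: gene, role, degree, selection membership, is_key
    deg <- node_degrees(net)
    sel <- run$selections[[nm]]
    rep <- data.frame(
      gene_id = names(deg),
      role = igraph::V(net)$role,
      degree = as.integer(deg),
      in_band = names(deg) %in% sel$member_genes,
      is_key = names(deg) %in% run$key_genes,
      stringsAsFactors = FALSE
    )
    rep <- rep[order(rep$gene_id), , drop = FALSE]
    write.table(rep,
                file.path(outdir, paste0("selection_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(run$key_genes, file.path(outdir, "key_genes.txt"))
  if (!is.null(run$comparisons)) {
    write.table(run$comparisons,
                file.path(outdir, "group_comparisons.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  yaml::write_yaml(run$manifest, file.path(outdir, "run_manifest.yml"))
  invisible(outdir)
}

#' @export
print.pathkey_run <- function(x, ...) {
  cat("<pathkey_run> ", length(x$tables), " condition(s), ",
      length(x$collection), " pathway(s) analysed, ",
      nrow(x$candidates), " candidate gene(s)\n", sep = "")
  for (m in names(x$consensus$per_method)) {
    cat("  consensus [", m, "]: ", length(x$consensus$per_method[[m]]),
        " pathway(s)\n", sep = "")
  }
  cat("  key genes: ", if (length(x$key_genes) > 0)
    paste(x$key_genes, collapse = ", ") else "(none)", "\n", sep = "")
  invisible(x)
}

#' @export
summary.pathkey_run <- function(object, ...) {
  res <- object$results
  tab <- stats::aggregate(significant ~ method + condition, data = res,
                          FUN = sum)
  names(tab)[3] <- "n_significant"
  out <- list(
    n_pathways = length(object$collection),
    n_candidates = nrow(object$candidates),
    significant_by_method = tab,
    consensus = object$consensus,
    key_genes = object$key_genes,
    background = object$manifest$background
  )
  class(out) <- "summary.pathkey_run"
  out
}

#' @export
print.summary.pathkey_run <- function(x, ...) {
  cat("Pathway enrichment summary\n")
  cat("  pathways analysed: ", x$n_pathways, "; candidates: ",
      x$n_candidates, "\n", sep = "")
  print(x$significant_by_method, row.names = FALSE)
  for (cond in names(x$background)) {
    cat("  background ", cond, ": L = ", x$background[[cond]][["L"]],
        ", M = ", x$background[[cond]][["M"]], "\n", sep = "")
  }
  cat("  key genes (", length(x$key_genes), "): ",
      paste(x$key_genes, collapse = ", "), "\n", sep = "")
  invisible(x)
}
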