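#' Synthetic ground truth for a simulated study
#'
#' Fixes every random choice of a simulated dataset -- which pathways are
#' enriched, which genes are candidates, which candidates are planted
#' network hubs -- as a pure function of the seed and the parameters, so
#' that the generators ([simulate_annotations()], [simulate_scores()],
#' [simulate_candidates()], [simulate_network()]) reproduce the same
#' dataset bitwise on every call.
#'
#' The defaults emulate the statistical structure of a submergence
#' RNA-seq / GO / candidate-list study at desk scale: a universe of 5,000
#' genes; 200 pathways with sizes log-uniform over 6-300 (so large sets do
#' not dominate); 10 enriched pathways whose member p-values follow
#' Beta(a, 1) with `a = 0.1` (stochastically much smaller than uniform) in
#' all four conditions `3h/6h/12h/24h`; 144 candidate genes (echoing a
#' 144-gene prioritized list) of which 30% of each enriched pathway's
#' members (at least 6) are candidates; and 5 planted hub candidates wired to
#' 20-28 neighbours over a preferential-attachment background with mean
#' degree near 7.
#'
#' @param seed Integer seed; everything else is derived from it.
#' @param universe_size Number of genes in the expression universe.
#' @param n_pathways Number of simulated pathways.
#' @param size_range Inclusive pathway-size range (within `[6, 1500]`).
#' @param n_enriched Number of planted enriched pathways.
#' @param enrichment_effect Beta shape `a` in (0, 1] for member p-values
#'   (`a = 1` is the uniform null; smaller `a` is stronger enrichment).
#' @param eligible_enriched_size Size range from which enriched pathways
#'   are drawn (moderate sizes keep the candidate budget feasible).
#' @param n_candidates Number of candidate genes.
#' @param candidate_overlap Fraction of each enriched pathway's members
#'   made candidates (at least `min_candidate_overlap` genes).
#' @param min_candidate_overlap Minimum planted overlap per enriched
#'   pathway.
#' @param n_hubs Number of planted hub candidates.
#' @param hub_degree_range Target degree range for planted hubs
#'   (inclusive).
#' @param n_background Background (non-candidate) nodes of the simulated
#'   interactome.
#' @param pa_edges Edges attached per node in the preferential-attachment
#'   background (mean background degree is about `2 * pa_edges`).
#' @param condition_labels Condition labels of the simulated score tables.
#' @return An object of class `synthetic_truth` listing all parameters
#'   plus `enriched_pathway_ids`, `candidate_ids`, `planted_hub_ids`.
#' @export
synthetic_truth <- function(seed,
                            universe_size = 5000,
                            n_pathways = 200,
                            size_range = c(6, 300),
                            n_enriched = 10,
                            enrichment_effect = 0.1,
                            eligible_enriched_size = c(20, 50),
                            n_candidates = 144,
                            candidate_overlap = 0.3,
                            min_candidate_overlap = 6,
                            n_hubs = 5,
                            hub_degree_range = c(20, 28),
                            n_background = 300,
                            pa_edges = 3,
                            condition_labels = c("3h", "6h", "12h", "24h")) {
  stopifnot(length(size_range) == 2, size_range[1] >= 6,
            size_range[2] <= 1500, size_range[1] <= size_range[2],
            n_pathways >= 1, universe_size >= size_range[2],
            enrichment_effect > 0, enrichment_effect <= 1,
            n_enriched >= 0, n_hubs >= 0)
  truth <- structure(
    list(seed = as.integer(seed), universe_size = as.integer(universe_size),
         n_pathways = as.integer(n_pathways),
         size_range = as.integer(size_range),
         n_enriched = as.integer(n_enriched),
         enrichment_effect = enrichment_effect,
         eligible_enriched_size = as.integer(eligible_enriched_size),
         n_candidates = as.integer(n_candidates),
         candidate_overlap = candidate_overlap,
         min_candidate_overlap = as.integer(min_candidate_overlap),
         n_hubs = as.integer(n_hubs),
         hub_degree_range = as.integer(hub_degree_range),
         n_background = as.integer(n_background),
         pa_edges = as.integer(pa_edges),
         condition_labels = as.character(condition_labels)),
    class = "synthetic_truth"
  )
  ## Planted identities are derived once, deterministically, from the seed.
  coll <- simulate_annotations(truth)
  sizes <- pathway_sizes(coll)
  eligible <- names(sizes)[sizes >= eligible_enriched_size[1] &
                             sizes <= eligible_enriched_size[2]]
  if (length(eligible) < n_enriched) {
    stop("not enough pathways in eligible_enriched_size range (",
         length(eligible), " < ", n_enriched, ")")
  }
  truth$enriched_pathway_ids <- with_seed(
    derive_seed(seed, "enriched"),
    sort(sample(eligible, n_enriched))
  )
  ## Candidates: a planted overlap inside each enriched pathway plus a
  ## uniform background fill.
  cand <- with_seed(derive_seed(seed, "candidates"), {
    planted <- character(0)
    for (pid in truth$enriched_pathway_ids) {
      g <- coll$genes[[match(pid, coll$id)]]
      k <- min(length(g),
               max(min_candidate_overlap,
                   ceiling(candidate_overlap * length(g))))
      planted <- union(planted, sample(g, k))
    }
    if (length(planted) > n_candidates) {
      warning("planted candidate overlap (", length(planted),
              ") exceeds n_candidates; truncating")
      planted <- planted[seq_len(n_candidates)]
    }
    pool <- setdiff(universe_genes(truth), planted)
    fill <- sample(pool, n_candidates - length(planted))
    list(planted = planted, all = sort(c(planted, fill)))
  })
  truth$candidate_ids <- cand$all
  planted <- cand$planted
  truth$planted_candidate_ids <- sort(planted)
  hub_pool <- if (length(planted) >= n_hubs) truth$planted_candidate_ids
              else truth$candidate_ids
  truth$planted_hub_ids <- with_seed(
    derive_seed(seed, "hubs"),
    sort(sample(hub_pool, n_hubs))
  )
  truth
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> seed ", x$seed, "\n", sep = "")
  cat("  universe ", x$universe_size, " genes | ", x$n_pathways,
      " pathways (sizes ", x$size_range[1], "-", x$size_range[2], ")\n",
      sep = "")
  cat("  planted: ", x$n_enriched, " enriched pathway(s) (Beta a = ",
      x$enrichment_effect, "), ", length(x$candidate_ids),
      " candidates, ", x$n_hubs, " hub(s)\n", sep = "")
  cat("  conditions: ", paste(x$condition_labels, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

universe_genes <- function(truth) {
  sprintf("gene%05d", seq_len(truth$universe_size))
}

#' Simulate a pathway collection
#'
#' Pathway sizes are drawn log-uniformly over `size_range`; memberships
#' are sampled without replacement per pathway from the gene universe, so
#' overlap between pathways arises naturally.  Deterministic given the
#' truth's seed.
#'
#' @param truth A [synthetic_truth()].
#' @return A [pathway_collection()] with ids `PW001`, `PW002`, ...
#' @export
simulate_annotations <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  genes <- universe_genes(truth)
  with_seed(derive_seed(truth$seed, "annotations"), {
    sizes <- round(exp(runif(truth$n_pathways,
                             log(truth$size_range[1]),
                             log(truth$size_range[2] + 0.999))))
    sizes <- pmin(pmax(sizes, truth$size_range[1]), truth$size_range[2])
    sets <- lapply(sizes, function(k) sample(genes, k))
    pathway_collection(
      sprintf("PW%03d", seq_len(truth$n_pathways)),
      sprintf("simulated pathway %d", seq_len(truth$n_pathways)),
      "unassigned", sets
    )
  })
}

#' Simulate per-condition gene score tables
#'
#' Non-member p-values are Uniform(0, 1); every member of a planted
#' enriched pathway has p ~ Beta(a, 1) with `a = enrichment_effect` in
#' every condition (the same pathways are enriched at all conditions, as a
#' multi-condition consensus step requires).  The resulting `-log10` score
#' distribution is right-skewed even under the null and its skewness grows
#' as `a` shrinks.
#'
#' @param truth A [synthetic_truth()].
#' @param collection The [simulate_annotations()] collection of the same
#'   truth.
#' @param condition_labels Condition labels (defaults to the truth's).
#' @return Named list of [gene_score_table()]s, one per condition.
#' @export
simulate_scores <- function(truth, collection,
                            condition_labels = truth$condition_labels) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(collection, "pathway_collection"))
  if (!all(truth$enriched_pathway_ids %in% collection$id)) {
    stop("enriched pathways missing from the collection")
  }
  genes <- universe_genes(truth)
  enriched_members <- unique(unlist(
    collection$genes[match(truth$enriched_pathway_ids, collection$id)]
  ))
  idx <- match(enriched_members, genes)
  tables <- lapply(condition_labels, function(cond) {
    with_seed(derive_seed(truth$seed, "scores", cond), {
      p <- runif(truth$universe_size)
      if (length(idx) > 0 && truth$enrichment_effect < 1) {
        p[idx] <- rbeta(length(idx), truth$enrichment_effect, 1)
      }
      gene_score_table(genes, p, condition = cond)
    })
  })
  stats::setNames(tables, condition_labels)
}

#' Simulate the prioritized candidate list
#'
#' Priority scores start at the conventional cutoff of 42 and decay
#' exponentially above it; planted hub candidates receive no special
#' score (prioritization and network centrality are separate axes).
#'
#' @param truth A [synthetic_truth()].
#' @return A [candidate_genes()] table.
#' @export
simulate_candidates <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  ids <- truth$candidate_ids
  scores <- with_seed(derive_seed(truth$seed, "candscore"),
                      round(42 + rexp(length(ids), rate = 1 / 15), 2))
  candidate_genes(ids, scores)
}

#' Simulate a hub-structured functional interactome
#'
#' The background is a preferential-attachment graph over
#' `n_background` non-candidate genes (`pa_edges` edges per node, so mean
#' background degree is about `2 * pa_edges`, with the heavy right tail
#' typical of interactomes).  Every non-hub candidate is attached to two
#' random background nodes (so background nodes touching two or more
#' candidates later become recruited intermediates).  Every planted hub is
#' wired to a target number of neighbours drawn from `hub_degree_range`,
#' chosen among the planted (enriched-pathway) candidates when enough
#' exist, excluding other hubs -- hubs therefore hit their target degree
#' exactly, inside the band, while non-hub candidates stay at low degree
#' (at most `n_hubs + 2` by construction).  Edge weights are positive
#' log-likelihood-scale draws.  Deterministic given the seed.
#'
#' @param truth A [synthetic_truth()].
#' @return A [gene_network()] reference interactome.
#' @export
simulate_network <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (truth$hub_degree_range[2] >
        truth$n_background + truth$n_candidates) {
    stop("hub_degree_range exceeds available node count")
  }
  genes <- universe_genes(truth)
  cand <- truth$candidate_ids
  hubs <- truth$planted_hub_ids
  with_seed(derive_seed(truth$seed, "network"), {
    bg_ids <- sample(setdiff(genes, cand), truth$n_background)
    bg <- igraph::sample_pa(truth$n_background, power = 1,
                            m = truth$pa_edges, directed = FALSE)
    el <- igraph::as_edgelist(bg)
    edges <- data.frame(gene_a = bg_ids[el[, 1]], gene_b = bg_ids[el[, 2]],
                        weight = NA_real_, stringsAsFactors = FALSE)
    ## low-degree attachment of ordinary candidates
    for (g in setdiff(cand, hubs)) {
      nb <- sample(bg_ids, 2)
      edges <- rbind(edges, data.frame(gene_a = g, gene_b = nb,
                                       weight = NA_real_))
    }
    ## planted hubs: exact target degree, neighbours among planted
    ## candidates (falling back to all non-hub candidates)
    pool0 <- setdiff(truth$planted_candidate_ids %||% character(0), hubs)
    if (length(pool0) < truth$hub_degree_range[2]) {
      pool0 <- setdiff(cand, hubs)
    }
    for (h in hubs) {
      d <- sample(seq(truth$hub_degree_range[1],
                      truth$hub_degree_range[2]), 1)
      nb <- sample(pool0, d)
      edges <- rbind(edges, data.frame(gene_a = h, gene_b = nb,
                                       weight = NA_real_))
    }
    edges$weight <- round(runif(nrow(edges), 0.5, 5), 3)
    net <- gene_network(edges, nodes = c(bg_ids, cand))
    igraph::V(net)$role <- ifelse(igraph::V(net)$name %in% cand,
                                  "candidate", NA_character_)
    net
  })
}

#' Write a complete fixture bundle to disk
#'
#' Writes the GMT annotation file, one score TSV per condition, the
#' candidate TSV, the edge-list TSV and a flat machine-readable truth
#' manifest, in exactly the formats the readers consume, so the full
#' pipeline can run from disk as it would on real inputs.
#'
#' @param truth A [synthetic_truth()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
write_fixture_bundle <- function(truth, outdir) {
  stopifnot(inherits(truth, "synthetic_truth"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  coll <- simulate_annotations(truth)
  tables <- simulate_scores(truth, coll)
  cand <- simulate_candidates(truth)
  net <- simulate_network(truth)

  paths <- list(annotations = file.path(outdir, "annotations.gmt"))
  write_gmt(coll, paths$annotations)
  paths$scores <- stats::setNames(
    file.path(outdir, paste0("scores_", names(tables), ".tsv")),
    names(tables)
  )
  for (cond in names(tables)) {
    write.table(as.data.frame(tables[[cond]])[, c("gene_id", "p_value")],
                paths$scores[[cond]], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  paths$candidates <- file.path(outdir, "candidates.tsv")
  write.table(as.data.frame(cand), paths$candidates, sep = "\t",
              quote = FALSE, row.names = FALSE)
  paths$edges <- file.path(outdir, "edges.tsv")
  el <- igraph::as_edgelist(net)
  write.table(
    data.frame(gene_a = el[, 1], gene_b = el[, 2],
               weight = igraph::E(net)$weight),
    paths$edges, sep = "\t", quote = FALSE, row.names = FALSE
  )
  paths$truth <- file.path(outdir, "truth.tsv")
  flat <- vapply(names(unclass(truth)), function(k) {
    paste(truth[[k]], collapse = ",")
  }, character(1))
  writeLines(paste(names(flat), flat, sep = "\t"), paths$truth)
  invisible(paths)
}

#' Read a truth manifest written by [write_fixture_bundle()]
#'
#' @param path Path to the `truth.tsv` manifest.
#' @return A named list of character vectors (values split on commas).
#' @export
read_truth_manifest <- function(path) {
  lines <- readLines(path, warn = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  vals <- lapply(parts, function(p) {
    strsplit(if (length(p) > 1) p[2] else "", ",", fixed = TRUE)[[1]]
  })
  stats::setNames(vals, vapply(parts, `[`, character(1), 1))
}
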