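#' Gene networks
#'
#' Networks are undirected, simple (no self-loops, no duplicate edges)
#' [igraph][igraph::igraph-package] graphs whose vertices carry a `role`
#' attribute (`"candidate"`, `"intermediate"` or `NA` for an unclassified
#' reference node) and whose edges carry a numeric `weight`
#' (log-likelihood-scale functional-interaction score).  Vertex names are
#' canonical gene ids.
#'
#' @param edges A data frame with columns `gene_a`, `gene_b`, `weight`.
#' @param nodes Optional character vector of additional (isolated) nodes.
#' @return An igraph object of class `gene_network`/`igraph`.
#' @export
gene_network <- function(edges, nodes = character(0)) {
  stopifnot(is.data.frame(edges),
            all(c("gene_a", "gene_b", "weight") %in% names(edges)))
  a <- normalize_gene_ids(edges$gene_a)
  b <- normalize_gene_ids(edges$gene_b)
  w <- as.numeric(edges$weight)
  if (anyNA(w)) stop("non-numeric edge weight(s)")
  loop <- a == b
  if (any(loop)) {
    warning(sum(loop), " self-loop edge(s) skipped")
    a <- a[!loop]; b <- b[!loop]; w <- w[!loop]
  }
  ## unordered dedup: keep maximum weight among conflicting duplicates
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  if (anyDuplicated(key)) {
    message(sum(duplicated(key)),
            " duplicate edge(s) collapsed (max weight kept)")
    w <- vapply(split(w, key), max, numeric(1))[unique(key)]
    lo <- lo[!duplicated(key)]; hi <- hi[!duplicated(key)]
  }
  verts <- unique(c(lo, hi, normalize_gene_ids(nodes)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = lo, to = hi, weight = w, stringsAsFactors = FALSE),
    directed = FALSE, vertices = verts
  )
  igraph::V(g)$role <- NA_character_
  class(g) <- c("gene_network", class(g))
  g
}

#' Read a weighted edge list
#'
#' Expects a TSV with rows `gene_a <TAB> gene_b <TAB> weight` (a header
#' naming those columns is detected and skipped).  Self-loops are skipped
#' with a warning; duplicate unordered edges keep the maximum weight.
#'
#' @param path Path to the edge-list file.
#' @return A [gene_network()].
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("edge list not found: ", path)
  first <- readLines(path, n = 1)
  f3 <- strsplit(first, "\t", fixed = TRUE)[[1]]
  if (length(f3) < 3) stop("malformed edge list: expected 3 tab-separated columns")
  header <- is.na(suppressWarnings(as.numeric(f3[3])))
  df <- read.delim(path, header = header, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("malformed edge list: expected 3 columns")
  names(df)[1:3] <- c("gene_a", "gene_b", "weight")
  w <- suppressWarnings(as.numeric(df$weight))
  if (anyNA(w)) {
    stop("malformed edge list row(s): non-numeric weight at ",
         paste(which(is.na(w)), collapse = ", "))
  }
  df$weight <- w
  gene_network(df)
}

#' Build a candidate-seeded network from a reference interactome
#'
#' Retains (i) the seed (candidate) genes present in the reference network
#' and (ii) every non-seed reference gene adjacent to at least
#' `min_seed_links` seeds -- the recruited "intermediate" genes that
#' connect multiple candidates -- together with all reference edges among
#' the retained genes.  Seeds absent from the reference are reported in
#' the `missing_seeds` graph attribute.
#'
#' @param reference A [gene_network()] reference interactome.
#' @param seeds Character vector of seed (candidate) gene ids.
#' @param min_seed_links Minimum number of distinct seed neighbours needed
#'   to recruit a non-seed gene (default 2).
#' @return A [gene_network()] whose vertices carry `role`
#'   (`"candidate"`/`"intermediate"`); a subgraph of `reference`.
#' @export
build_seeded_network <- function(reference, seeds, min_seed_links = 2) {
  stopifnot(inherits(reference, "igraph"), min_seed_links >= 1)
  seeds <- unique(normalize_gene_ids(seeds))
  vn <- igraph::V(reference)$name
  present <- intersect(seeds, vn)
  missing <- setdiff(seeds, vn)
  ## count seed neighbours of every vertex
  el <- igraph::as_edgelist(reference, names = TRUE)
  a_seed <- el[, 1] %in% present
  b_seed <- el[, 2] %in% present
  cnt <- table(c(el[b_seed, 1], el[a_seed, 2]))
  recruited <- setdiff(names(cnt)[cnt >= min_seed_links], present)
  keep <- c(present, recruited)
  g <- igraph::induced_subgraph(reference, keep)
  igraph::V(g)$role <- ifelse(igraph::V(g)$name %in% present,
                              "candidate", "intermediate")
  g <- igraph::set_graph_attr(g, "missing_seeds", missing)
  if (length(missing) > 0) {
    message(length(missing), " seed(s) not found in the reference network")
  }
  class(g) <- c("gene_network", class(g))
  g
}

#' Node degrees (unweighted incident-edge counts)
#'
#' @param network A [gene_network()].
#' @return Named integer vector of degrees.
#' @export
node_degrees <- function(network) {
  stopifnot(inherits(network, "igraph"))
  igraph::degree(network, loops = FALSE)
}

#' Extract the subnetwork of nodes in a degree band
#'
#' Members are the nodes whose degree in the *parent* network lies in
#' `[low, high]` (degrees are not recomputed on the induced subgraph);
#' a band of 20-30 conventionally captures the dense, highly central core.
#'
#' @param network A [gene_network()].
#' @param low,high Inclusive degree bounds (`low <= high`).
#' @return An object of class `subnetwork_selection`: list with
#'   `member_genes`, `degree_band`, `degrees` (named, parent degrees of
#'   members) and `mean_degree` (`NA` when the band is empty).
#' @export
extract_degree_band <- function(network, low = 20, high = 30) {
  stopifnot(low <= high)
  deg <- node_degrees(network)
  members <- names(deg)[deg >= low & deg <= high]
  structure(
    list(member_genes = members,
         degree_band = c(low = low, high = high),
         degrees = deg[members],
         mean_degree = if (length(members) > 0) mean(deg[members]) else
           NA_real_),
    class = "subnetwork_selection"
  )
}

#' @export
print.subnetwork_selection <- function(x, ...) {
  cat("<subnetwork_selection> band [", x$degree_band[["low"]], ", ",
      x$degree_band[["high"]], "]: ", length(x$member_genes),
      " gene(s)", sep = "")
  if (length(x$member_genes) > 0) {
    cat(", mean degree ", format(x$mean_degree, digits = 4), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Collapse low-degree nodes into a single meta-node
#'
#' All nodes with degree at most `max_degree` are replaced by one
#' meta-node (e.g. `"Group0_2"` for degrees 0-2) carrying the member list
#' in the `group_members` graph attribute.  Edges from members to retained
#' nodes are merged per retained neighbour, keeping the maximum weight and
#' recording the multiplicity; member-member edges are dropped.  The
#' meta-node carries role `"group"` and must not enter key-gene selection.
#'
#' @param network A [gene_network()].
#' @param max_degree Collapse nodes with degree `<= max_degree`
#'   (nonnegative; use 0 to collapse only isolates).
#' @param group_label Name of the meta-node.
#' @return A [gene_network()] with the meta-node (unchanged if no node
#'   qualifies).
#' @export
collapse_low_degree <- function(network, max_degree = 2,
                                group_label = "Group0_2") {
  stopifnot(inherits(network, "igraph"), max_degree >= 0)
  deg <- node_degrees(network)
  members <- names(deg)[deg <= max_degree]
  if (length(members) == 0) return(network)
  retained <- setdiff(names(deg), members)
  el <- igraph::as_edgelist(network, names = TRUE)
  w <- igraph::E(network)$weight
  keep_e <- el[, 1] %in% retained & el[, 2] %in% retained
  cross <- xor(el[, 1] %in% members, el[, 2] %in% members)
  edges <- data.frame(gene_a = el[keep_e, 1], gene_b = el[keep_e, 2],
                      weight = w[keep_e], stringsAsFactors = FALSE)
  mult <- integer(0)
  if (any(cross)) {
    other <- ifelse(el[cross, 1] %in% members, el[cross, 2], el[cross, 1])
    merged_w <- vapply(split(w[cross], other), max, numeric(1))
    mult <- vapply(split(w[cross], other), length, integer(1))
    edges <- rbind(edges, data.frame(
      gene_a = group_label, gene_b = names(merged_w),
      weight = unname(merged_w), stringsAsFactors = FALSE
    ))
  }
  roles <- stats::setNames(igraph::V(network)$role,
                           igraph::V(network)$name)
  g <- gene_network(edges, nodes = c(retained, group_label))
  vn <- igraph::V(g)$name
  igraph::V(g)$role <- ifelse(vn == normalize_gene_ids(group_label),
                              "group", unname(roles[vn]))
  g <- igraph::set_graph_attr(g, "group_members", members)
  g <- igraph::set_graph_attr(g, "group_label", group_label)
  g <- igraph::set_graph_attr(
    g, "group_multiplicity",
    stats::setNames(as.integer(mult), names(mult))
  )
  g
}

#' Select key genes from degree-band subnetworks
#'
#' The key genes are the union, over one or more subnetwork selections, of
#' the member genes that are also candidate genes.  Intermediate
#' (recruited) genes are never key genes.  Provenance -- which
#' selection(s) contributed each gene -- is attached as the `provenance`
#' attribute.
#'
#' @param selections A single `subnetwork_selection` or a (preferably
#'   named) list of them.
#' @param candidates A [candidate_genes()] table or character vector.
#' @return Sorted character vector of key gene ids with a `provenance`
#'   attribute (named list: gene -> contributing selection labels).
#' @export
select_key_genes <- function(selections, candidates) {
  if (inherits(selections, "subnetwork_selection")) {
    selections <- list(selections)
  }
  stopifnot(length(selections) >= 1,
            all(vapply(selections, inherits, logical(1),
                       "subnetwork_selection")))
  labels <- names(selections) %||% as.character(seq_along(selections))
  labels[!nzchar(labels)] <- as.character(which(!nzchar(labels)))
  cand <- candidate_id_set(candidates)
  prov <- list()
  for (i in seq_along(selections)) {
    hit <- intersect(selections[[i]]$member_genes, cand)
    for (gid in hit) prov[[gid]] <- c(prov[[gid]], labels[i])
  }
  keys <- sort(as.character(names(prov)))
  structure(keys, provenance = prov[keys])
}

#' Export a network to SIF or GraphML
#'
#' SIF lines are `a interacts b`; isolated nodes are written as single-name
#' lines so the node set round-trips.  GraphML (via igraph) carries the
#' `role`, `weight` and name attributes.
#'
#' @param network A [gene_network()].
#' @param path Output file path.
#' @param format `"sif"` or `"graphml"`.
#' @return Invisibly, `path`.
#' @export
export_network <- function(network, path, format = c("sif", "graphml")) {
  stopifnot(inherits(network, "igraph"))
  format <- match.arg(format)
  if (format == "sif") {
    el <- igraph::as_edgelist(network, names = TRUE)
    lines <- if (nrow(el) > 0) paste(el[, 1], "interacts", el[, 2]) else
      character(0)
    iso <- names(which(igraph::degree(network) == 0))
    writeLines(c(lines, iso), path)
  } else {
    g <- network
    class(g) <- "igraph"
    if (is.null(igraph::V(g)$role)) igraph::V(g)$role <- NA_character_
    igraph::V(g)$role[is.na(igraph::V(g)$role)] <- ""
    ## GraphML graph attributes must be scalars
    for (at in igraph::graph_attr_names(g)) {
      v <- igraph::graph_attr(g, at)
      if (length(v) != 1 || !is.atomic(v)) {
        g <- igraph::set_graph_attr(
          g, at, paste(c(names(v), as.character(v)), collapse = ","))
      }
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network written by [export_network()]
#'
#' @param path Path to the SIF or GraphML file.
#' @param format `"sif"` or `"graphml"`.
#' @return A [gene_network()].  SIF carries no weights; they are set to 1.
#' @export
read_network <- function(path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "sif") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "[ \t]+")
    nfield <- lengths(parts)
    if (any(!nfield %in% c(1, 3))) {
      stop("malformed SIF line(s): ",
           paste(which(!nfield %in% c(1, 3)), collapse = ", "))
    }
    edges <- do.call(rbind, lapply(parts[nfield == 3], function(p) {
      data.frame(gene_a = p[1], gene_b = p[3], weight = 1,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(edges)) {
      edges <- data.frame(gene_a = character(0), gene_b = character(0),
                          weight = numeric(0))
    }
    iso <- vapply(parts[nfield == 1], `[`, character(1), 1)
    return(gene_network(edges, nodes = iso))
  }
  g <- igraph::read_graph(path, format = "graphml")
  g <- igraph::as_undirected(g, mode = "collapse")
  if (is.null(igraph::E(g)$weight)) igraph::E(g)$weight <- 1
  if (!is.null(igraph::V(g)$role)) {
    igraph::V(g)$role[igraph::V(g)$role == ""] <- NA_character_
  }
  class(g) <- c("gene_network", class(g))
  g
}
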