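edge_df <- function(a, b, w = 1) {
  data.frame(gene_a = a, gene_b = b, weight = w, stringsAsFactors = FALSE)
}

test_that("edge lists deduplicate, drop self-loops and keep max weight", {
  path <- write_lines_tmp(c("gene_a\tgene_b\tweight",
                            "a\tb\t1.0", "b\ta\t2.0", "c\tc\t1.0",
                            "b\tc\t0.5", "c\ta\t0.7"), ".tsv")
  expect_warning(net <- read_edge_list(path), "self-loop")
  expect_equal(igraph::vcount(net), 3)
  expect_equal(igraph::ecount(net), 3)  # triangle
  eid <- igraph::get_edge_ids(net, c("a", "b"))
  expect_equal(igraph::E(net)$weight[eid], 2.0)  # max of duplicate

  headerless <- write_lines_tmp(c("x\ty\t1", "y\tz\t2"), ".tsv")
  expect_equal(igraph::ecount(read_edge_list(headerless)), 2)
  expect_error(
    read_edge_list(write_lines_tmp(c("gene_a\tgene_b\tweight",
                                     "a\tb\t1", "c\td\tnope"))),
    "non-numeric"
  )
  expect_error(read_edge_list(write_lines_tmp("a\tb")), "3 tab-separated")
})

test_that("seeded networks recruit connectors of multiple seeds", {
  ## star: hub h adjacent to seeds s1..s4 plus a one-seed hanger-on
  ref <- gene_network(edge_df(
    c("h", "h", "h", "h", "x"),
    c("s1", "s2", "s3", "s4", "s1")
  ))
  net <- build_seeded_network(ref, c("s1", "s2", "s3", "s4"),
                              min_seed_links = 2)
  expect_setequal(igraph::V(net)$name, c("s1", "s2", "s3", "s4", "h"))
  roles <- setNames(igraph::V(net)$role, igraph::V(net)$name)
  expect_equal(unname(roles["h"]), "intermediate")
  expect_true(all(roles[c("s1", "s2")] == "candidate"))
  ## x has only one seed link -> excluded
  expect_false("x" %in% igraph::V(net)$name)

  ## seeds absent from the reference are reported
  expect_message(
    net2 <- build_seeded_network(ref, c("s1", "s2", "nope"), 2),
    "not found"
  )
  expect_equal(igraph::graph_attr(net2, "missing_seeds"), "nope")

  ## subgraph property: nodes and edges are subsets of the reference
  expect_true(all(igraph::V(net)$name %in% igraph::V(ref)$name))
  el <- apply(igraph::as_edgelist(net), 1, function(e)
    paste(sort(e), collapse = "|"))
  el_ref <- apply(igraph::as_edgelist(ref), 1, function(e)
    paste(sort(e), collapse = "|"))
  expect_true(all(el %in% el_ref))
})

test_that("degrees obey the handshake lemma and hand counts", {
  tri <- gene_network(edge_df(c("a", "b", "c"), c("b", "c", "a")))
  expect_equal(unname(node_degrees(tri)), c(2L, 2L, 2L))
  path3 <- gene_network(edge_df(c("a", "b"), c("b", "c")))
  expect_equal(node_degrees(path3)[c("a", "b", "c")],
               c(a = 1, b = 2, c = 1))
  lonely <- gene_network(edge_df("a", "b"), nodes = "z")
  expect_equal(node_degrees(lonely)[["z"]], 0)

  set.seed(5)
  for (i in 1:5) {
    g <- igraph::sample_gnp(30, 0.2)
    el <- igraph::as_edgelist(g)
    net <- gene_network(edge_df(sprintf("v%02d", el[, 1]),
                                sprintf("v%02d", el[, 2])))
    expect_equal(sum(node_degrees(net)), 2 * igraph::ecount(net))
  }
})

test_that("degree-band extraction uses parent degrees inclusively", {
  ## build a graph with degrees {0, 5, 21, 25, 30, 31} via a hub-and-stub
  ## construction, then check band membership and mean
  degs <- c(0, 5, 21, 25, 30, 31)
  hubs <- paste0("h", seq_along(degs))
  edges <- do.call(rbind, lapply(seq_along(degs), function(i) {
    if (degs[i] == 0) return(NULL)
    edge_df(hubs[i], sprintf("stub_%d_%03d", i, seq_len(degs[i])))
  }))
  net <- gene_network(edges, nodes = hubs[degs == 0])
  expect_equal(unname(node_degrees(net)[hubs]), degs)

  sel <- extract_degree_band(net, 20, 30)
  expect_setequal(sel$member_genes, hubs[degs >= 20 & degs <= 30])
  expect_equal(sel$mean_degree, mean(c(21, 25, 30)), tolerance = 1e-12)
  expect_equal(sel$mean_degree, 25.333, tolerance = 1e-3)

  all_sel <- extract_degree_band(net, 0, 10^6)
  expect_equal(sort(all_sel$member_genes),
               sort(igraph::V(net)$name))
  none <- extract_degree_band(net, 100, 200)
  expect_length(none$member_genes, 0)
  expect_true(is.na(none$mean_degree))
  expect_error(extract_degree_band(net, 5, 2))
})

test_that("low-degree collapsing merges members into one meta-node", {
  ## 6-node toy: core triangle a-b-c, leaves l1 (on a), l2 (on b), and an
  ## isolate l3; degrees: a=3 b=3 c=2 l1=1 l2=1 l3=0
  net <- gene_network(
    edge_df(c("a", "b", "c", "a", "b"), c("b", "c", "a", "l1", "l2")),
    nodes = "l3"
  )
  col <- collapse_low_degree(net, max_degree = 2, group_label = "Group0_2")
  vn <- igraph::V(col)$name
  expect_setequal(vn, c("a", "b", "group0_2"))
  expect_setequal(igraph::graph_attr(col, "group_members"),
                  c("c", "l1", "l2", "l3"))
  ## meta-node degree = distinct retained neighbours of members (a and b)
  expect_equal(node_degrees(col)[["group0_2"]], 2)
  roles <- setNames(igraph::V(col)$role, vn)
  expect_equal(unname(roles["group0_2"]), "group")
  ## collapsing when nothing qualifies is the identity
  tri <- gene_network(edge_df(c("a", "b", "c"), c("b", "c", "a")))
  expect_identical(collapse_low_degree(tri, 0), tri)
})

test_that("key genes are the candidate-restricted union with provenance", {
  mk_sel <- function(members) {
    structure(list(member_genes = members, degree_band = c(low = 20, high = 30),
                   degrees = setNames(rep(25, length(members)), members),
                   mean_degree = 25),
              class = "subnetwork_selection")
  }
  sels <- list(net1 = mk_sel(c("a", "b", "c")), net2 = mk_sel(c("b", "d")))
  keys <- select_key_genes(sels, candidates = c("a", "b", "d"))
  expect_equal(as.character(keys), c("a", "b", "d"))
  prov <- attr(keys, "provenance")
  expect_equal(prov$b, c("net1", "net2"))
  expect_equal(prov$a, "net1")

  ## intermediates only -> empty
  expect_length(select_key_genes(mk_sel(c("x", "y")), c("a", "b")), 0)

  ## monotone: adding a selection never removes a key gene
  more <- select_key_genes(c(sels, list(net3 = mk_sel("zz"))),
                           c("a", "b", "d"))
  expect_true(all(as.character(keys) %in% as.character(more)))
})

test_that("networks round-trip through SIF and GraphML", {
  tri <- gene_network(edge_df(c("a", "b", "c"), c("b", "c", "a"),
                              w = c(1, 2, 3)), nodes = "iso")
  sif <- tempfile(fileext = ".sif")
  export_network(tri, sif, "sif")
  lines <- readLines(sif)
  expect_length(grep(" interacts ", lines), 3)
  expect_true("iso" %in% lines)
  back <- read_network(sif, "sif")
  expect_setequal(igraph::V(back)$name, igraph::V(tri)$name)
  expect_equal(igraph::ecount(back), 3)

  set.seed(8)
  g <- igraph::sample_gnp(50, 0.08)
  net <- gene_network(edge_df(
    sprintf("n%02d", igraph::as_edgelist(g)[, 1]),
    sprintf("n%02d", igraph::as_edgelist(g)[, 2]),
    w = round(runif(igraph::ecount(g)), 3)
  ), nodes = sprintf("n%02d", 1:50))
  igraph::V(net)$role <- sample(c("candidate", "intermediate"), 50, TRUE)
  gml <- tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  back <- read_network(gml, "graphml")
  expect_setequal(igraph::V(back)$name, igraph::V(net)$name)
  key <- function(n) sort(apply(igraph::as_edgelist(n), 1, function(e)
    paste(sort(e), collapse = "|")))
  expect_equal(key(back), key(net))
  expect_error(export_network(net, tempfile(), "dot"))

  empty <- gene_network(edge_df(character(0), character(0), numeric(0)))
  p <- tempfile(fileext = ".sif")
  export_network(empty, p, "sif")
  expect_length(readLines(p), 0)
})
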