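test_that("GMT parsing yields one pathway per row with deduplicated genes", {
  path <- write_lines_tmp(c("GO:1\tdesc one\tg1\tg2",
                            "GO:2\tdesc two\tg3"), ".gmt")
  coll <- read_gene_sets(path, "gmt")
  expect_s3_class(coll, "pathway_collection")
  expect_length(coll, 2)
  expect_equal(unname(pathway_sizes(coll)), c(2L, 1L))
  expect_equal(coll$genes[[1]], c("g1", "g2"))

  dup <- read_gene_sets(
    write_lines_tmp("GO:9\td\tg1\tG1\tg2", ".gmt"), "gmt")
  expect_equal(dup$genes[[1]], c("g1", "g2"))
})

test_that("malformed or empty GMT input fails with row context", {
  bad <- write_lines_tmp(c("GO:1\tdesc\tg1", "GO:2\tonly-two-fields"))
  expect_error(read_gene_sets(bad, "gmt"), "line 2")
  empty <- write_lines_tmp(character(0))
  expect_error(read_gene_sets(empty, "gmt"), "zero parsed sets")
  expect_error(read_gene_sets(tempfile(), "gmt"), "not found")
})

test_that("GAF input is inverted into term -> gene sets", {
  path <- write_lines_tmp(c(
    "!gaf-version: 2.1",
    gaf_row("g1", "GO:1", "P"),
    gaf_row("g2", "GO:1", "P"),
    gaf_row("g1", "GO:1", "P"),   # duplicate membership
    gaf_row("g9", "GO:2", "F")
  ), ".gaf")
  coll <- read_gene_sets(path, "gaf")
  expect_length(coll, 2)
  i <- match("GO:1", coll$id)
  expect_setequal(coll$genes[[i]], c("g1", "g2"))
  expect_equal(coll$namespace[i], "biological_process")
  expect_equal(coll$namespace[match("GO:2", coll$id)],
               "molecular_function")
  only_comments <- write_lines_tmp("!gaf-version: 2.1", ".gaf")
  expect_error(read_gene_sets(only_comments, "gaf"), "zero parsed sets")
})

test_that("GMT round-trips through write_gmt", {
  coll <- tiny_collection()
  path <- tempfile(fileext = ".gmt")
  write_gmt(coll, path)
  back <- read_gene_sets(path, "gmt")
  expect_equal(back$id, coll$id)
  expect_equal(back$genes, coll$genes)
})

test_that("size filter bounds are inclusive and the filter is idempotent", {
  sizes <- c(5, 6, 1500, 1501)
  coll <- pathway_collection(
    paste0("P", sizes), genes = lapply(sizes, function(k) {
      sprintf("x%04d", seq_len(k))
    })
  )
  kept <- filter_by_size(coll, 6, 1500)
  expect_equal(unname(pathway_sizes(kept)), c(6L, 1500L))
  expect_equal(filter_by_size(kept, 6, 1500), kept)
  expect_equal(filter_by_size(coll, 1, 10^6), coll)
  expect_message(
    empty <- filter_by_size(tiny_collection(), 6, 1500),
    "no pathways"
  )
  expect_length(empty, 0)
  expect_error(filter_by_size(coll, 0, 5), "min_size")
  expect_error(filter_by_size(coll, 7, 6), "min_size")
})

test_that("candidate restriction keeps exactly the intersecting pathways", {
  coll <- pathway_collection(c("A", "B"),
                             genes = list(c("g1", "g2"), "g3"))
  expect_equal(restrict_to_candidates(coll, "g1")$id, "A")
  expect_length(restrict_to_candidates(coll, "zz"), 0)
  expect_equal(restrict_to_candidates(coll, c("g1", "g2", "g3", "g9"))$id,
               c("A", "B"))
  expect_lte(length(restrict_to_candidates(coll, "g3")), length(coll))
})

test_that("universe restriction intersects sets and drops emptied pathways", {
  coll <- pathway_collection("A", genes = list(c("g1", "g2", "g3")))
  r <- restrict_to_universe(coll, c("g1", "g2"))
  expect_equal(r$genes[[1]], c("g1", "g2"))
  expect_length(restrict_to_universe(coll, "zz"), 0)
  expect_equal(restrict_to_universe(coll, paste0("g", 1:9)), coll)
  expect_error(restrict_to_universe(coll, character(0)), "non-empty")

  ## never increases any pathway's size
  set.seed(42)
  big <- pathway_collection(
    paste0("P", 1:20),
    genes = lapply(1:20, function(i) sample(sprintf("u%03d", 1:80), 10))
  )
  univ <- sample(sprintf("u%03d", 1:80), 40)
  shrunk <- restrict_to_universe(big, univ)
  expect_true(all(pathway_sizes(shrunk) <=
                    pathway_sizes(big)[names(pathway_sizes(shrunk))]))
})

test_that("gene ids are case-normalized before intersection", {
  coll <- pathway_collection("A", genes = list(c("Glyma.02G222400")))
  r <- restrict_to_candidates(coll, "glyma.02g222400")
  expect_length(r, 1)
  expect_equal(restrict_to_universe(coll, " GLYMA.02g222400 ")$genes[[1]],
               "glyma.02g222400")
})

test_that("candidate lists enforce uniqueness and the score cutoff", {
  expect_error(candidate_genes(c("a", "A")), "unique")
  cand <- candidate_genes(c("a", "b", "c"), c(50, 41.9, 42), cutoff = 42)
  expect_equal(cand$gene_id, c("a", "c"))
  path <- write_lines_tmp(
    c("gene_id\tpriority_score\textra", "gA\t55\tx", "gB\t10\ty"), ".tsv")
  expect_equal(read_candidates(path, cutoff = 42)$gene_id, "ga")
  expect_error(read_candidates(write_lines_tmp("foo\tbar", ".tsv")),
               "gene_id")
})
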