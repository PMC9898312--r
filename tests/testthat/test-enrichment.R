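test_that("hypergeometric tail matches subset enumeration and phyper", {
  expect_identical(hypergeometric_pvalue(20, 5, 4, 0), 1)

  ## literal enumeration of all C(20,5) draws from a 20-gene universe with
  ## a 4-gene pathway
  draws <- combn(20, 5)
  overlap <- colSums(draws <= 4)  # genes 1..4 are the pathway
  expect_equal(hypergeometric_pvalue(20, 5, 4, 2), mean(overlap >= 2),
               tolerance = 1e-12)
  expect_equal(hypergeometric_pvalue(20, 5, 4, 2), 0.2487, tolerance = 1e-4)

  ## strictly decreasing in g over the feasible range
  p <- vapply(0:4, function(g) hypergeometric_pvalue(20, 5, 4, g),
              numeric(1))
  expect_true(all(diff(p) < 0))

  ## independent distributional cross-check on random instances
  set.seed(3)
  for (i in 1:25) {
    L <- sample(30:2000, 1); M <- sample.int(L, 1); S <- sample.int(L, 1)
    g <- sample.int(min(S, M), 1)
    expect_equal(hypergeometric_pvalue(L, M, S, g),
                 phyper(g - 1, S, L - S, M, lower.tail = FALSE),
                 tolerance = 1e-10)
  }

  expect_error(hypergeometric_pvalue(10, 5, 11, 1), "infeasible")
  expect_error(hypergeometric_pvalue(10, 11, 5, 1), "infeasible")
  expect_error(hypergeometric_pvalue(10, 5, 5, 6), "infeasible")
})

test_that("enrichment scores are plain sums / sums of squares", {
  expect_equal(enrichment_score(c(1, 2, 3), "sumstat"), 6)
  expect_equal(enrichment_score(c(1, 2, 3), "sumsq"), 14)
  expect_equal(enrichment_score(rep(0, 5), "sumstat"), 0)
  expect_equal(enrichment_score(rep(0, 5), "sumsq"), 0)
  expect_error(enrichment_score(numeric(0), "sumstat"), "empty")
})

test_that("permutation nulls are deterministic and size-exact", {
  tab <- gene_score_table(paste0("g", 1:40), rep(0.1, 40))
  cfg <- perm_config(B = 200, seed = 5)
  null1 <- permutation_null(tab, 7, "sumstat", cfg)
  expect_length(null1, 200)
  expect_true(all(null1 == 7 * 1))  # constant universe: ES = k * c
  expect_identical(null1, permutation_null(tab, 7, "sumstat", cfg))

  set.seed(2)
  tab2 <- gene_score_table(paste0("g", 1:40), runif(40))
  n1 <- permutation_null(tab2, 5, "sumstat", cfg)
  n2 <- permutation_null(tab2, 6, "sumstat", cfg)
  expect_false(identical(n1[1], n2[1]))  # distinct per-size streams
  expect_error(permutation_null(tab2, 41, "sumstat", cfg), "exceeds")
  expect_error(perm_config(B = 50), ">= 100")
})

test_that("empirical p-values use the add-one upper-tail estimator", {
  expect_equal(empirical_pvalue(6, 1:10), 6 / 11)
  expect_equal(empirical_pvalue(100, 1:10), 1 / 11)
  expect_equal(empirical_pvalue(0, 1:10), 1)
  expect_error(empirical_pvalue(1, numeric(0)), "non-empty")
  ## order invariance of the null vector
  set.seed(1)
  nul <- rnorm(500)
  expect_equal(empirical_pvalue(0.3, nul), empirical_pvalue(0.3, sort(nul)))
})

test_that("ES normalization is a z-score with a normal upper tail", {
  nul <- 1:10
  z <- normalize_es(6, nul)
  expect_equal(normalize_es(mean(nul), nul)$z, 0)
  expect_equal(z$z, (6 - 5.5) / sd(1:10), tolerance = 1e-12)
  expect_equal(z$z, 0.16514, tolerance = 1e-4)
  expect_equal(z$p_asymptotic, pnorm(z$z, lower.tail = FALSE))
  shifted <- normalize_es(6 + 100, nul + 100)
  expect_equal(shifted$z, z$z, tolerance = 1e-12)
  expect_error(normalize_es(1, rep(2, 10)), "zero null variance")
})

test_that("BH and Bonferroni match their direct formulas", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.3), 0.3)
  expect_equal(adjust_bh(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(adjust_bonferroni(c(0.3, 0.4, 0.5)), c(0.9, 1, 1))
  expect_equal(adjust_bonferroni(0.01), 0.01)

  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(2:60, 1))
    bh <- adjust_bh(p)
    expect_equal(bh, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(bh >= p))
    expect_true(all(adjust_bonferroni(p) >= p))
    expect_false(is.unsorted(bh[order(p)]))  # monotone transform
  }
  expect_error(adjust_bh(c(0.5, 1.2)), "0, 1")
  expect_error(adjust_bonferroni(c(-0.1)), "0, 1")
})

test_that("competitive test recovers a planted over-represented pathway", {
  ## pathway disjoint from candidates, and pathway = whole universe
  tab <- gene_score_table(paste0("g", 1:30), rep(0.5, 30))
  coll <- pathway_collection(
    c("disjoint", "whole"),
    genes = list(paste0("g", 1:6), paste0("g", 1:30))
  )
  res <- test_competitive(tab, coll, candidates = paste0("g", 25:30))
  expect_equal(res$N_FT, c(0L, 6L))
  expect_equal(res$p_raw[res$pathway_id == "disjoint"], 1)
  expect_equal(res$p_raw[res$pathway_id == "whole"], 1)
  expect_equal(attr(res, "L"), 30)
  expect_equal(attr(res, "M"), 6)

  ## planted: universe 1000, 50 candidates, pathway of 40 with overlap 20
  set.seed(11)
  genes <- sprintf("u%04d", 1:1000)
  tab <- gene_score_table(genes, runif(1000))
  planted <- sample(genes, 40)
  cand <- c(sample(planted, 20), sample(setdiff(genes, planted), 30))
  sets <- c(list(planted = planted),
            lapply(1:100, function(i) sample(genes, 40)))
  names(sets) <- c("planted", paste0("null", 1:100))
  coll <- pathway_collection(names(sets), genes = sets)
  res <- test_competitive(tab, coll, cand)
  expect_lt(res$p_raw[res$pathway_id == "planted"], 1e-4)
  expect_equal(res$pathway_id[which.min(res$p_raw)], "planted")
})

test_that("self-contained test flags a planted pathway and is reproducible", {
  set.seed(21)
  genes <- sprintf("u%04d", 1:600)
  sets <- lapply(1:20, function(i) sample(genes, 25))
  names(sets) <- sprintf("PW%02d", 1:20)
  coll <- pathway_collection(names(sets), genes = sets)
  p <- runif(600)
  planted <- match(sets[["PW07"]], genes)
  p[planted] <- rbeta(25, 0.1, 1)
  tab <- gene_score_table(genes, p, condition = "t1")
  cfg <- perm_config(B = 500, seed = 3)

  for (st in c("sumstat", "sumsq")) {
    res <- test_selfcontained(tab, coll, st, cfg,
                              candidates = sets[["PW07"]][1:5])
    expect_equal(res$pathway_id[which.min(res$p_asymptotic)], "PW07")
    expect_equal(res$p_empirical[res$pathway_id == "PW07"], 1 / 501)
    expect_true(all(res$p_empirical >= 1 / 501))
    expect_equal(res$N_FT[res$pathway_id == "PW07"], 5L)
    ## observed ES equals the direct member sum
    sc <- setNames(tab$score, tab$gene_id)
    i <- match("PW03", res$pathway_id)
    expect_equal(res$ES[i],
                 enrichment_score(sc[coll$genes[[match("PW03", coll$id)]]],
                                  st))
    res2 <- test_selfcontained(tab, coll, st, cfg,
                               candidates = sets[["PW07"]][1:5])
    expect_identical(res, res2)
  }
})

test_that("consensus collects per-method persistent pathways and intersections", {
  mk <- function(method, condition, p) {
    data.frame(pathway_id = paste0("P", seq_along(p)), condition = condition,
               method = method, p_raw = p, stringsAsFactors = FALSE)
  }
  ## P1 significant in all 4 conditions, P2 in 3 of 4 (hypergeometric);
  ## sumstat: only P1 persists
  res <- rbind(
    mk("hypergeometric", "c1", c(1e-6, 1e-6, 0.5)),
    mk("hypergeometric", "c2", c(1e-6, 1e-6, 0.5)),
    mk("hypergeometric", "c3", c(1e-6, 1e-6, 0.5)),
    mk("hypergeometric", "c4", c(1e-6, 0.2, 0.5)),
    mk("sumstat", "c1", c(1e-5, 0.9, 0.9)),
    mk("sumstat", "c2", c(1e-5, 0.9, 0.9)),
    mk("sumstat", "c3", c(1e-5, 0.9, 0.9)),
    mk("sumstat", "c4", c(1e-5, 0.9, 0.9))
  )
  cons <- consensus_pathways(res, threshold = 1e-4,
                             require_all_conditions = TRUE)
  expect_equal(cons$per_method$hypergeometric, "P1")
  expect_equal(cons$per_method$sumstat, "P1")
  expect_equal(cons$intersections[["hypergeometric.sumstat"]], "P1")
  expect_equal(cons$intersections[["all"]], "P1")

  any_cond <- consensus_pathways(res, threshold = 1e-4,
                                 require_all_conditions = FALSE)
  expect_setequal(any_cond$per_method$hypergeometric, c("P1", "P2"))
})
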