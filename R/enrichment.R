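#' Permutation configuration
#'
#' @param B Number of permutations (at least 100; 10,000 by default).
#' @param seed Top-level RNG seed.  Per-statistic / per-size streams are
#'   derived deterministically from it, so results do not depend on pathway
#'   iteration order.
#' @param scheme Resampling scheme.  Only `"gene_label_shuffle"` is
#'   implemented: size-matched random gene sets are drawn without
#'   replacement from the score universe.  Phenotype permutation is not
#'   possible when only gene-level summary statistics are available.
#' @return An object of class `perm_config`.
#' @export
perm_config <- function(B = 10000, seed = 1, scheme = "gene_label_shuffle") {
  B <- as.integer(B)
  if (is.na(B) || B < 100) stop("B must be an integer >= 100")
  scheme <- match.arg(scheme, "gene_label_shuffle")
  structure(list(B = B, seed = as.integer(seed), scheme = scheme),
            class = "perm_config")
}

#' Upper-tail hypergeometric p-value
#'
#' Probability of observing `g` or more pathway genes among `M` genes drawn
#' without replacement from a universe of `L` genes of which `S` belong to
#' the pathway:
#' \deqn{p = \sum_{x=g}^{\min(S,M)} \binom{S}{x}\binom{L-S}{M-x} / \binom{L}{M}.}
#' The sum is accumulated from log-binomial coefficients for numerical
#' stability; `g = 0` returns exactly 1.
#'
#' @param L Universe size.
#' @param M Number of candidate (important) genes in the universe.
#' @param S Pathway size in the universe.
#' @param g Observed overlap between candidates and the pathway.
#' @return The p-value in (0, 1].
#' @export
hypergeometric_pvalue <- function(L, M, S, g) {
  L <- as.integer(L); M <- as.integer(M); S <- as.integer(S); g <- as.integer(g)
  if (S > L || M > L) stop("infeasible counts: need S <= L and M <= L")
  if (g < 0 || g > min(S, M)) {
    stop("infeasible overlap: need 0 <= g <= min(S, M)")
  }
  if (g == 0) return(1)
  x <- g:min(S, M)
  terms <- lchoose(S, x) + lchoose(L - S, M - x) - lchoose(L, M)
  mx <- max(terms)
  p <- exp(mx) * sum(exp(terms - mx))
  min(p, 1)
}

#' Competitive (over-representation) pathway test
#'
#' For each pathway, tests whether candidate genes are over-represented
#' among its members via the upper-tail hypergeometric probability.  The
#' background is `L` = genes in the score table, `M` = candidate genes
#' within that universe, `S` = pathway size within the universe and
#' `g` = candidate/pathway overlap.  Both `L` and `M` are recorded as
#' attributes of the result.
#'
#' @param table A [gene_score_table()] defining the universe.
#' @param collection A [pathway_collection()].
#' @param candidates A [candidate_genes()] table or character vector.
#' @param threshold Raw-p significance threshold (default 1e-4).
#' @param fdr_level Benjamini-Hochberg level reported alongside.
#' @return A `data.frame` of class `enrichment_result` with one row per
#'   pathway: `pathway_id`, `name`, `condition`, `method`, `N_G`, `N_FT`,
#'   `ES`, `normalized_ES`, `p_empirical`, `p_asymptotic`, `p_raw`, `p_bh`,
#'   `p_bonferroni`, `significant`.  For the hypergeometric method the ES
#'   fields and `p_empirical` are `NA` and `p_raw = p_asymptotic` is the
#'   exact tail probability.
#' @export
test_competitive <- function(table, collection, candidates,
                             threshold = 1e-4, fdr_level = 0.05) {
  stopifnot(inherits(table, "gene_score_table"),
            inherits(collection, "pathway_collection"))
  universe <- table$gene_id
  collection <- restrict_to_universe(collection, universe)
  cand <- intersect(candidate_id_set(candidates), universe)
  L <- length(universe)
  M <- length(cand)
  n <- length(collection)
  N_G <- lengths(collection$genes)
  N_FT <- vapply(collection$genes, function(g) sum(g %in% cand), integer(1))
  p <- vapply(seq_len(n), function(i) {
    hypergeometric_pvalue(L, M, N_G[i], N_FT[i])
  }, numeric(1))
  res <- enrichment_result_frame(
    collection, condition = attr(table, "condition"),
    method = "hypergeometric", N_G = N_G, N_FT = N_FT,
    ES = NA_real_, normalized_ES = NA_real_,
    p_empirical = NA_real_, p_asymptotic = p, p_raw = p,
    threshold = threshold, fdr_level = fdr_level
  )
  attr(res, "L") <- L
  attr(res, "M") <- M
  res
}

#' Enrichment score of a gene set
#'
#' `sumstat` is the sum of member gene-wise statistics, `sumsq` the sum of
#' their squares.
#'
#' @param member_scores Numeric vector of member gene-wise statistics
#'   (at least one).
#' @param statistic `"sumstat"` or `"sumsq"`.
#' @return The enrichment score.
#' @export
enrichment_score <- function(member_scores, statistic = c("sumstat", "sumsq")) {
  statistic <- match.arg(statistic)
  if (length(member_scores) == 0) stop("empty gene-set membership")
  if (statistic == "sumstat") sum(member_scores) else sum(member_scores^2)
}

#' Permutation null distribution for one set size
#'
#' Draws `B` uniformly random gene subsets of `set_size` without
#' replacement from the score universe and returns their enrichment
#' scores.  Reproducible given the configuration seed; the stream is
#' derived from `(seed, statistic, set_size)` so every size has its own
#' deterministic stream.
#'
#' @param table A [gene_score_table()].
#' @param set_size Subset size (at most the universe size).
#' @param statistic `"sumstat"` or `"sumsq"`.
#' @param config A [perm_config()].
#' @return Numeric vector of `B` permuted enrichment scores.
#' @export
permutation_null <- function(table, set_size,
                             statistic = c("sumstat", "sumsq"),
                             config = perm_config()) {
  stopifnot(inherits(table, "gene_score_table"),
            inherits(config, "perm_config"))
  statistic <- match.arg(statistic)
  n <- nrow(table)
  if (set_size > n) stop("set_size exceeds universe size")
  if (set_size < 1) stop("set_size must be positive")
  vals <- if (statistic == "sumstat") table$score else table$score^2
  with_seed(derive_seed(config$seed, statistic, set_size), {
    vapply(seq_len(config$B),
           function(b) sum(vals[sample.int(n, set_size)]), numeric(1))
  })
}

#' Add-one empirical p-value
#'
#' `p = (1 + #\{null >= observed\}) / (B + 1)`: one-sided upper tail with
#' the add-one correction, so 0 is never reported and the smallest
#' attainable value is `1/(B+1)`.
#'
#' @param observed_ES Observed enrichment score.
#' @param null_ES Non-empty numeric vector of permuted scores.
#' @return The empirical p-value in `[1/(B+1), 1]`.
#' @export
empirical_pvalue <- function(observed_ES, null_ES) {
  if (length(null_ES) == 0) stop("null_ES must be non-empty")
  (1 + sum(null_ES >= observed_ES)) / (length(null_ES) + 1)
}

#' Normalize an enrichment score against its permutation null
#'
#' Subtracts the mean of the permuted scores and divides by their standard
#' deviation.  The upper-tail standard-normal probability of the resulting
#' z is exposed as the asymptotic p-value, which resolves p-values below
#' the empirical floor `1/(B+1)`.
#'
#' @param observed_ES Observed enrichment score.
#' @param null_ES Numeric vector of permuted scores with positive sd.
#' @return A list with elements `z` and `p_asymptotic`.
#' @export
normalize_es <- function(observed_ES, null_ES) {
  if (length(null_ES) < 2) stop("need at least 2 permuted scores")
  s <- sd(null_ES)
  if (s == 0) stop("zero null variance: cannot normalize ES")
  z <- (observed_ES - mean(null_ES)) / s
  list(z = z, p_asymptotic = pnorm(z, lower.tail = FALSE))
}

#' Self-contained pathway test (SUMSTAT / SUMSQ)
#'
#' For each pathway, computes the enrichment score over member gene-wise
#' statistics and compares it with scores of size-matched random gene sets
#' drawn from the score universe.  Reports the add-one empirical p-value,
#' the normalized ES (z-scale) and its asymptotic normal upper-tail
#' p-value.  Genes outside a pathway never enter its observed score.
#'
#' Null generation is shared across pathways: each permutation draws one
#' random gene sequence without replacement and the null score of a
#' size-`k` set is the statistic of its first `k` genes, so all pathway
#' sizes are served by one pass and equal sizes share one null
#' distribution.  The marginal null per size is exactly the uniform
#' random-subset null.
#'
#' @param table A [gene_score_table()].
#' @param collection A [pathway_collection()]; pathways are intersected
#'   with the table's universe and emptied pathways dropped.
#' @param statistic `"sumstat"` or `"sumsq"`.
#' @param config A [perm_config()].
#' @param candidates Optional [candidate_genes()] used only to report the
#'   candidate overlap `N_FT`.
#' @param threshold Raw-p significance threshold applied to the empirical
#'   p-value (default 1e-4).
#' @param fdr_level Benjamini-Hochberg level reported alongside.
#' @return An `enrichment_result` data frame (see [test_competitive()]).
#' @export
test_selfcontained <- function(table, collection,
                               statistic = c("sumstat", "sumsq"),
                               config = perm_config(), candidates = NULL,
                               threshold = 1e-4, fdr_level = 0.05) {
  stopifnot(inherits(table, "gene_score_table"),
            inherits(collection, "pathway_collection"),
            inherits(config, "perm_config"))
  statistic <- match.arg(statistic)
  collection <- restrict_to_universe(collection, table$gene_id)
  if (length(collection) == 0) {
    return(enrichment_result_frame(
      collection, condition = attr(table, "condition"), method = statistic,
      N_G = integer(0), N_FT = integer(0), ES = numeric(0),
      normalized_ES = numeric(0), p_empirical = numeric(0),
      p_asymptotic = numeric(0), p_raw = numeric(0),
      threshold = threshold, fdr_level = fdr_level
    ))
  }
  n_univ <- nrow(table)
  scores <- stats::setNames(table$score, table$gene_id)
  vals <- if (statistic == "sumstat") table$score else table$score^2
  sizes <- lengths(collection$genes)
  usize <- sort(unique(sizes))
  maxS <- max(usize)

  ## One prefix draw per permutation serves every pathway size.
  B <- config$B
  nullmat <- matrix(0, nrow = length(usize), ncol = B)
  with_seed(derive_seed(config$seed, statistic,
                        attr(table, "condition") %||% ""), {
    for (b in seq_len(B)) {
      cs <- cumsum(vals[sample.int(n_univ, maxS)])
      nullmat[, b] <- cs[usize]
    }
  })
  null_mean <- rowMeans(nullmat)
  null_sd <- apply(nullmat, 1, sd)

  cand <- if (is.null(candidates)) character(0) else
    intersect(candidate_id_set(candidates), table$gene_id)
  n <- length(collection)
  ES <- numeric(n); p_emp <- numeric(n); z <- numeric(n); p_asy <- numeric(n)
  N_FT <- integer(n)
  for (i in seq_len(n)) {
    g <- collection$genes[[i]]
    member <- scores[g]
    ES[i] <- enrichment_score(member, statistic)
    k <- match(length(g), usize)
    nulls <- nullmat[k, ]
    p_emp[i] <- (1 + sum(nulls >= ES[i])) / (B + 1)
    if (null_sd[k] == 0) {
      stop("zero null variance for set size ", usize[k],
           ": constant score universe")
    }
    z[i] <- (ES[i] - null_mean[k]) / null_sd[k]
    p_asy[i] <- pnorm(z[i], lower.tail = FALSE)
    N_FT[i] <- sum(g %in% cand)
  }
  res <- enrichment_result_frame(
    collection, condition = attr(table, "condition"), method = statistic,
    N_G = sizes, N_FT = N_FT, ES = ES, normalized_ES = z,
    p_empirical = p_emp, p_asymptotic = p_asy, p_raw = p_emp,
    threshold = threshold, fdr_level = fdr_level
  )
  attr(res, "B") <- B
  res
}

## Assemble the common per-pathway result frame, applying multiple-testing
## adjustment within this one method x condition family.
enrichment_result_frame <- function(collection, condition, method,
                                    N_G, N_FT, ES, normalized_ES,
                                    p_empirical, p_asymptotic, p_raw,
                                    threshold, fdr_level) {
  res <- data.frame(
    pathway_id = collection$id,
    name = collection$name,
    condition = condition %||% NA_character_,
    method = method,
    N_G = as.integer(N_G),
    N_FT = as.integer(N_FT),
    ES = ES,
    normalized_ES = normalized_ES,
    p_empirical = p_empirical,
    p_asymptotic = p_asymptotic,
    p_raw = p_raw,
    stringsAsFactors = FALSE
  )
  res$p_bh <- adjust_bh(res$p_raw)
  res$p_bonferroni <- adjust_bonferroni(res$p_raw)
  res$significant <- res$p_raw < threshold
  attr(res, "threshold") <- threshold
  attr(res, "fdr_level") <- fdr_level
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; a monotone transform that
#' preserves the raw p-value ordering.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
adjust_bh <- function(p_values) {
  check_pvec(p_values)
  p.adjust(p_values, method = "BH")
}

#' Bonferroni adjusted p-values
#'
#' `min(1, p * m)` for a family of `m` tests.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
adjust_bonferroni <- function(p_values) {
  check_pvec(p_values)
  p.adjust(p_values, method = "bonferroni")
}

check_pvec <- function(p) {
  if (length(p) == 0) return(invisible(p))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  invisible(p)
}

#' Cross-condition and cross-method consensus pathways
#'
#' Per method, collects the pathways whose raw p-value beats `threshold`
#' in every condition (or in at least one, when
#' `require_all_conditions = FALSE`), then forms all pairwise method
#' intersections and the intersection over all methods.
#'
#' @param results One or more `enrichment_result` frames row-bound
#'   together (several methods and conditions).
#' @param threshold Raw-p significance threshold (default 1e-4).
#' @param require_all_conditions Require significance at every condition
#'   present for that method.
#' @return A list with `per_method` (named list of pathway-id vectors),
#'   `intersections` (named list; pairs named `"a.b"` plus `"all"`),
#'   `combined` (the union over methods -- the overall consensus, since
#'   competitive and self-contained tests answer different null
#'   hypotheses and their joint report is the union of their calls), and
#'   `threshold`.
#' @export
consensus_pathways <- function(results, threshold = 1e-4,
                               require_all_conditions = TRUE) {
  stopifnot(is.data.frame(results),
            all(c("pathway_id", "condition", "method", "p_raw") %in%
                  names(results)))
  methods <- unique(results$method)
  per_method <- lapply(methods, function(m) {
    sub <- results[results$method == m, , drop = FALSE]
    conds <- unique(sub$condition)
    sig <- sub[sub$p_raw < threshold, , drop = FALSE]
    counts <- table(sig$pathway_id)
    need <- if (require_all_conditions) length(conds) else 1L
    sort(names(counts[counts >= need]))
  })
  names(per_method) <- methods
  intersections <- list()
  if (length(methods) > 1) {
    prs <- combn(methods, 2, simplify = FALSE)
    for (pr in prs) {
      intersections[[paste(pr, collapse = ".")]] <-
        intersect(per_method[[pr[1]]], per_method[[pr[2]]])
    }
    intersections[["all"]] <- Reduce(intersect, per_method)
  }
  list(per_method = per_method, intersections = intersections,
       combined = sort(Reduce(union, per_method, character(0))),
       threshold = threshold)
}
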