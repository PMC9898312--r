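#' Compare mean gene-wise scores of two gene groups
#'
#' One-sided test of `mean(a) > mean(b)`.  The default is a label
#' permutation test on the mean difference: when the number of label
#' splits `choose(n_a + n_b, n_a)` is at most `n_resamples` the splits are
#' enumerated exhaustively (exact p, no add-one); otherwise
#' `n_resamples` random shuffles are drawn and the add-one estimator
#' `(1 + exceedances) / (n_resamples + 1)` is used.  Welch's t test is the
#' asymptotic alternative; score distributions are heavily right-skewed,
#' which is why the permutation test is the default.
#'
#' @param scores_a,scores_b Numeric score vectors (each of length >= 2;
#'   the caller must ensure the gene groups are disjoint).
#' @param method `"permutation_mean_diff"` or `"welch_t"`.
#' @param n_resamples Number of random shuffles (and the enumeration
#'   budget) for the permutation method.
#' @param seed RNG seed for the shuffles.
#' @param group_a,group_b Optional group labels carried into the result.
#' @return A list of class `group_comparison` with `group_a`, `group_b`,
#'   `mean_a`, `mean_b`, `statistic` (mean difference, or Welch t),
#'   `p_value`, `method` and `exact` (logical).
#' @export
compare_group_means <- function(scores_a, scores_b,
                                method = c("permutation_mean_diff",
                                           "welch_t"),
                                n_resamples = 10000, seed = 1,
                                group_a = "a", group_b = "b") {
  method <- match.arg(method)
  scores_a <- as.numeric(scores_a); scores_b <- as.numeric(scores_b)
  na <- length(scores_a); nb <- length(scores_b)
  if (na < 2 || nb < 2) stop("both groups need at least 2 values")
  obs <- mean(scores_a) - mean(scores_b)
  exact <- FALSE
  if (method == "welch_t") {
    if (sd(scores_a) == 0 && sd(scores_b) == 0) {
      ## t.test cannot handle constant data; the decision is deterministic
      statistic <- if (obs == 0) 0 else sign(obs) * Inf
      p <- if (obs > 0) .Machine$double.xmin else 1
    } else {
      tt <- t.test(scores_a, scores_b, alternative = "greater")
      statistic <- unname(tt$statistic)
      p <- tt$p.value
    }
  } else {
    pooled <- c(scores_a, scores_b)
    n <- na + nb
    total <- choose(n, na)
    statistic <- obs
    if (total <= n_resamples) {
      exact <- TRUE
      splits <- combn(n, na)
      tot <- sum(pooled)
      stats <- apply(splits, 2, function(ix) {
        sa <- sum(pooled[ix])
        sa / na - (tot - sa) / nb
      })
      p <- sum(stats >= obs - 1e-12) / total
    } else {
      exceed <- with_seed(seed, {
        sum(vapply(seq_len(n_resamples), function(b) {
          ix <- sample.int(n, na)
          sa <- sum(pooled[ix])
          (sa / na - (sum(pooled) - sa) / nb) >= obs - 1e-12
        }, logical(1)))
      })
      p <- (1 + exceed) / (n_resamples + 1)
    }
  }
  structure(
    list(group_a = group_a, group_b = group_b,
         mean_a = mean(scores_a), mean_b = mean(scores_b),
         statistic = statistic, p_value = p, method = method,
         exact = exact),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> ", x$group_a, " vs ", x$group_b, " (",
      x$method, if (x$exact) ", exact" else "", ")\n", sep = "")
  cat("  mean_a = ", format(x$mean_a, digits = 5),
      ", mean_b = ", format(x$mean_b, digits = 5),
      ", statistic = ", format(x$statistic, digits = 5),
      ", p = ", format(x$p_value, digits = 5), "\n", sep = "")
  invisible(x)
}

#' Pooled two-proportion z statistic
#'
#' \deqn{z = (\hat p_1 - \hat p_2) /
#'   \sqrt{\hat p (1-\hat p) (1/n_1 + 1/n_2)}}
#' with the pooled proportion \eqn{\hat p = (x_1+x_2)/(n_1+n_2)}.  When the
#' pooled proportion is 0 or 1 the statistic is degenerate and 0 is
#' returned with attribute `degenerate = TRUE`.
#'
#' @param x1,n1 Successes and trials in sample 1 (`0 <= x1 <= n1`,
#'   `n1 >= 1`).
#' @param x2,n2 Successes and trials in sample 2.
#' @return The z statistic (numeric scalar, possibly with a `degenerate`
#'   attribute).
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  if (n1 < 1 || n2 < 1 || x1 < 0 || x2 < 0 || x1 > n1 || x2 > n2) {
    stop("need 0 <= x <= n and n >= 1 for both samples")
  }
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  if (pp == 0 || pp == 1) {
    return(structure(0, degenerate = TRUE))
  }
  (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
}

#' Partition the score universe into analysis gene groups
#'
#' Splits the genes of a score table into four disjoint groups: key genes,
#' other candidates, intermediate (network-recruited) genes and the
#' remaining genes.  Key genes must be a subset of the candidates; a gene
#' listed as both candidate and intermediate is kept as a candidate with a
#' warning (candidacy is the analysis-defining label).
#'
#' @param table A [gene_score_table()].
#' @param key_genes Character vector (subset of `candidates`).
#' @param candidates Character vector or [candidate_genes()] table.
#' @param intermediates Character vector of recruited genes.
#' @return Named list of four character vectors: `key`, `candidate`,
#'   `intermediate`, `remaining` -- a partition of the universe.
#' @export
stratify_genes <- function(table, key_genes, candidates, intermediates) {
  stopifnot(inherits(table, "gene_score_table"))
  universe <- table$gene_id
  key <- unique(normalize_gene_ids(key_genes))
  cand <- candidate_id_set(candidates)
  inter <- unique(normalize_gene_ids(intermediates))
  if (!all(key %in% cand)) {
    stop("key genes must be a subset of the candidate list; offending: ",
         paste(setdiff(key, cand), collapse = ", "))
  }
  both <- intersect(cand, inter)
  if (length(both) > 0) {
    warning(length(both), " gene(s) listed as both candidate and ",
            "intermediate; kept as candidate")
    inter <- setdiff(inter, cand)
  }
  key <- intersect(universe, key)
  cand_only <- setdiff(intersect(universe, cand), key)
  inter <- intersect(universe, inter)
  remaining <- setdiff(universe, c(key, cand_only, inter))
  list(key = key, candidate = cand_only, intermediate = inter,
       remaining = remaining)
}
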