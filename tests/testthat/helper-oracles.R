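# Independent oracles used across the suite.  These deliberately take the
# most direct route (explicit enumeration, naive formulas) and share no
# code with the package internals they check.

# Upper-tail hypergeometric probability via the naive binomial-coefficient
# ratio, no log-space.
oracle_hyper <- function(L, M, S, g) {
  if (g == 0) return(1)
  x <- g:min(S, M)
  sum(choose(S, x) * choose(L - S, M - x)) / choose(L, M)
}

# Three-pass central-moment skewness.
oracle_skewness <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  d <- x - m
  m2 <- sum(d^2) / n
  m3 <- sum(d^3) / n
  m3 / m2^(3 / 2)
}

# Benjamini-Hochberg by the literal step-up definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  run <- Inf
  for (i in m:1) {
    run <- min(run, sorted[i] * m / i)
    adj[i] <- min(run, 1)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exhaustive one-sided label-permutation p for the mean difference.
oracle_perm_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  splits <- utils::combn(length(pooled), na)
  obs <- mean(a) - mean(b)
  stats <- apply(splits, 2, function(ix) {
    mean(pooled[ix]) - mean(pooled[-ix])
  })
  mean(stats >= obs - 1e-12)
}

# A reduced-scale synthetic truth used across the generator and pipeline
# tests.
small_truth <- function(seed = 1, ...) {
  synthetic_truth(seed, universe_size = 2000, n_pathways = 80,
                  size_range = c(6, 100), n_enriched = 5,
                  eligible_enriched_size = c(20, 40),
                  candidate_overlap = 0.4, min_candidate_overlap = 7,
                  n_candidates = 80, n_background = 200,
                  condition_labels = c("3h", "6h"), ...)
}

# A tiny hand-built pathway collection for parser-free tests.
tiny_collection <- function() {
  pathway_collection(
    id = c("PA", "PB", "PC"),
    name = c("alpha", "beta", "gamma"),
    namespace = c("biological_process", "molecular_function", "unassigned"),
    genes = list(c("g1", "g2", "g3"), c("g3", "g4"), c("g5"))
  )
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# A GAF 2.x row with the given gene, term and aspect in the right columns.
gaf_row <- function(gene, term, aspect) {
  fields <- rep("", 17)
  fields[1] <- "DB"
  fields[2] <- gene
  fields[3] <- toupper(gene)
  fields[5] <- term
  fields[7] <- "IEA"
  fields[9] <- aspect
  fields[12] <- "protein"
  fields[13] <- "taxon:3847"
  paste(fields, collapse = "\t")
}
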