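#' Canonicalize gene identifiers
#'
#' Gene identifiers are compared after whitespace stripping and lower-casing,
#' because Glyma-style identifiers (and many other nomenclatures) are
#' case-inconsistent across annotation sources (e.g. `Glyma.02g222400` vs
#' `Glyma.14G127800`).  All set operations in the package go through this
#' canonical form.
#'
#' @param x Character vector of gene identifiers.
#' @return Character vector of canonical identifiers.
#' @export
normalize_gene_ids <- function(x) {
  tolower(trimws(as.character(x)))
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Deterministically derive a child seed from a top-level seed and a small
# set of integer/character tags.  Keeps results independent of iteration
# order (each consumer gets its own stream) and the result below 2^31.
derive_seed <- function(seed, ...) {
  tags <- list(...)
  h <- as.double(seed) %% 2147483647
  for (tag in tags) {
    if (is.character(tag)) {
      tag <- sum(as.integer(charToRaw(paste(tag, collapse = ""))) *
                   seq_along(charToRaw(paste(tag, collapse = ""))))
    }
    h <- (h * 48271 + as.double(tag) + 1) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
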