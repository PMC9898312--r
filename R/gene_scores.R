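#' Gene score tables
#'
#' Per-gene differential-expression p-values for one condition (e.g. one
#' submergence time point), together with the derived gene-wise statistic
#' score `-log10(p)`.  Larger scores mean stronger expression change.
#' p-values of exactly zero are clamped to `p_floor` with a warning so the
#' transform stays finite.
#'
#' @param gene_id Character vector of gene ids (unique after normalization).
#' @param p_value Numeric p-values in (0, 1].
#' @param condition Condition label (e.g. `"3h"`).
#' @param p_floor Positive floor applied to p-values of exactly 0.
#' @return A `data.frame` of class `gene_score_table` with columns
#'   `gene_id`, `p_value`, `score` and attribute `condition`.
#' @export
gene_score_table <- function(gene_id, p_value, condition = "cond",
                             p_floor = 1e-300) {
  gene_id <- normalize_gene_ids(gene_id)
  p_value <- as.numeric(p_value)
  if (length(gene_id) != length(p_value)) {
    stop("gene_id and p_value must have equal length")
  }
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene id(s) in score table: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  }
  if (anyNA(p_value)) stop("non-numeric or missing p-value(s)")
  if (any(p_value < 0 | p_value > 1)) {
    stop("p-values must lie in (0, 1]; offending rows: ",
         paste(which(p_value < 0 | p_value > 1), collapse = ", "))
  }
  nzero <- sum(p_value == 0)
  if (nzero > 0) {
    warning(nzero, " p-value(s) of exactly 0 clamped to ", p_floor)
    p_value[p_value == 0] <- p_floor
  }
  df <- data.frame(gene_id = gene_id, p_value = p_value,
                   score = -log10(p_value), stringsAsFactors = FALSE)
  attr(df, "condition") <- as.character(condition)
  class(df) <- c("gene_score_table", "data.frame")
  df
}

#' Read a per-gene p-value table
#'
#' Expects a TSV with header columns `gene_id` and `p_value` (extra columns
#' ignored).  Duplicate gene ids and unparseable p-values are errors.
#'
#' @param path Path to the TSV file.
#' @param condition Condition label; defaults to the file name without
#'   extension.
#' @param p_floor Floor applied to p-values of exactly 0.
#' @return A [gene_score_table()].
#' @export
read_score_table <- function(path, condition = NULL, p_floor = 1e-300) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(c("gene_id", "p_value"), names(df))
  if (length(miss) > 0) {
    stop("score table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  p <- suppressWarnings(as.numeric(df$p_value))
  if (anyNA(p)) {
    stop("non-numeric p-value(s) in ", path, " at row(s): ",
         paste(which(is.na(p)), collapse = ", "))
  }
  condition <- condition %||% sub("\\.[^.]*$", "", basename(path))
  gene_score_table(df$gene_id, p, condition = condition, p_floor = p_floor)
}

#' Recompute gene-wise statistic scores from p-values
#'
#' Applies the 10-based logarithm transform `score = -log10(p)` to every
#' row, refreshing the `score` column.  Strictly decreasing in p.
#'
#' @param table A [gene_score_table()].
#' @return The table with the `score` column recomputed.
#' @export
transform_pvalues <- function(table) {
  stopifnot(inherits(table, "gene_score_table"))
  table$score <- -log10(table$p_value)
  table
}

#' Moment-coefficient sample skewness
#'
#' Computes `g1 = m3 / m2^(3/2)` with central moments over the full vector
#' (population-moment form, no small-sample bias correction).  Right-skewed
#' `-log10(p)` score distributions typically have skewness well above 1.
#'
#' @param values Numeric vector with at least 3 values and nonzero variance.
#' @return The skewness coefficient.
#' @export
sample_skewness <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3) stop("need at least 3 values")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) stop("undefined skewness: constant vector")
  m3 <- mean((values - m)^3)
  m3 / m2^1.5
}

#' Flag single-gene significance
#'
#' A gene is flagged when its score strictly exceeds `threshold`
#' (conventionally `-log10(p) = 3`); genes exactly on the threshold are not
#' flagged.
#'
#' @param table A [gene_score_table()].
#' @param threshold Nonnegative score threshold.
#' @return Named logical vector, one entry per gene.
#' @export
flag_single_gene_significance <- function(table, threshold = 3) {
  stopifnot(inherits(table, "gene_score_table"), threshold >= 0)
  stats::setNames(table$score > threshold, table$gene_id)
}

#' Write a score table with flags
#'
#' @param table A [gene_score_table()].
#' @param path Output TSV path.
#' @param threshold Single-gene significance threshold.
#' @return Invisibly, `path`.
#' @export
write_score_table <- function(table, path, threshold = 3) {
  out <- as.data.frame(table)
  out$significant <- flag_single_gene_significance(table, threshold)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
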