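# Per-gene transforms: relative expression, binary transform, entropy.

check_expression_matrix <- function(mat, arg = deparse(substitute(mat))) {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop("`", arg, "` must be a numeric matrix", call. = FALSE)
  if (anyNA(mat))
    stop("`", arg, "` contains missing values", call. = FALSE)
  if (any(mat < 0))
    stop("`", arg, "` contains negative intensities", call. = FALSE)
  if (is.null(rownames(mat)))
    rownames(mat) <- sprintf("gene%05d", seq_len(nrow(mat)))
  if (anyDuplicated(rownames(mat)))
    stop("duplicate gene ids in `", arg, "`", call. = FALSE)
  invisible(mat)
}

#' Relative expression transform
#'
#' Divides each gene's intensity in each tissue by the gene's total across
#' all tissues, so every row sums to 1. This removes gene-level (and any
#' species-wide multiplicative) intensity scale and leaves only the shape
#' of the expression profile, which is what makes cross-species
#' comparisons of linear-scale intensities meaningful.
#'
#' @param mat gene x tissue matrix of non-negative linear-scale
#'   intensities; every row must have a strictly positive sum.
#' @return matrix of the same shape with rows summing to 1.
#' @export
#' @examples
#' to_relative(matrix(c(1, 3), 1, 2, dimnames = list("g1", c("a", "b"))))
to_relative <- function(mat) {
  mat <- check_expression_matrix(mat)
  rs <- rowSums(mat)
  if (any(rs <= 0)) {
    bad <- rownames(mat)[which(rs <= 0)]
    stop("gene(s) with zero total expression: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  mat / rs
}

#' Binary (presence/absence) transform
#'
#' Thresholds each gene at its own mean across tissues: an entry becomes 1
#' when the intensity is greater than or equal to the gene's row mean, 0
#' otherwise. Tissue-specific genes give sparse vectors (few ones);
#' housekeeping genes give dense ones. Ties at the mean map to 1, so a
#' perfectly constant gene is all ones (never all zeros: the row maximum
#' is always >= the row mean).
#'
#' @param mat gene x tissue matrix of non-negative intensities.
#' @return 0/1 integer matrix of the same shape.
#' @export
to_binary <- function(mat) {
  mat <- check_expression_matrix(mat)
  out <- (mat >= rowMeans(mat)) + 0L
  storage.mode(out) <- "integer"
  out
}

#' Shannon entropy of expression profiles
#'
#' Per-gene entropy (base 2) of the relative-expression row:
#' `H = -sum_j p_j log2 p_j` with `p` the gene's relative expression and
#' `0 * log2(0) = 0`. Ranges from 0 for a gene expressed in a single
#' tissue to `log2(n_tissues)` for perfectly uniform expression, and is
#' the standard operationalization of "uniformly expressed".
#'
#' @param mat gene x tissue matrix of non-negative intensities (every row
#'   sum strictly positive).
#' @return named numeric vector of per-gene entropies in bits.
#' @export
gene_entropy <- function(mat) {
  p <- to_relative(mat)
  terms <- ifelse(p > 0, p * log2(p), 0)
  -rowSums(terms)
}
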