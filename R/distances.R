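# Distance measures between paired expression profiles: Euclidean,
# correlation-based, and the generalized-average (GA) family on binary
# vectors. Undefined distances are returned as NA and excluded (with a
# count) by pairwise_distances(); they are never imputed, since an imputed
# value would distort the moment statistics used for distance selection.

GA_PLAIN_LAMBDA_MAX <- 100  # |lambda| above which the factored form is used

#' Euclidean distance between two profiles
#'
#' Root-sum-of-squared differences. Applied to relative-expression rows it
#' measures uniform divergence of profile shape: the larger the
#' coordinate-wise differences, the larger the distance, regardless of
#' whether the changes are concerted.
#'
#' @param u,v numeric vectors of equal length >= 2.
#' @return a non-negative scalar; 0 iff `u == v`.
#' @export
euclidean_distance <- function(u, v) {
  if (length(u) != length(v)) stop("length mismatch", call. = FALSE)
  if (length(u) < 2) stop("vectors must have length >= 2", call. = FALSE)
  sqrt(sum((u - v)^2))
}

#' Correlation-based distance between two profiles
#'
#' `1 - r` with `r` the Pearson correlation, in \[0, 2\]. Sensitive to
#' concerted (shape) changes and invariant to separate positive affine
#' rescaling of either profile; negative correlations are kept (values
#' above 1), not truncated.
#'
#' @param u,v numeric vectors of equal length >= 2.
#' @return scalar in \[0, 2\], or `NA` when either vector has zero
#'   variance (the correlation is undefined there; callers exclude and
#'   count such pairs).
#' @export
correlation_distance <- function(u, v) {
  if (length(u) != length(v)) stop("length mismatch", call. = FALSE)
  if (length(u) < 2) stop("vectors must have length >= 2", call. = FALSE)
  if (stats::sd(u) == 0 || stats::sd(v) == 0) return(NA_real_)
  1 - stats::cor(u, v)
}

# Vectorized GA distance from pair summaries: x = scalar product,
# m, n = one-counts of the two binary vectors; lambda a scalar exponent
# (finite, -Inf or +Inf). Returns NA where m == 0 or n == 0.
ga_from_counts <- function(x, m, n, lambda) {
  lo <- pmin(m, n)
  hi <- pmax(m, n)
  B <- if (identical(lambda, Inf)) {
    hi
  } else if (identical(lambda, -Inf)) {
    lo
  } else if (lambda == 0) {
    sqrt(m * n)  # geometric-mean limit of the power mean
  } else if (abs(lambda) <= GA_PLAIN_LAMBDA_MAX) {
    ((m^lambda + n^lambda) / 2)^(1 / lambda)
  } else if (lambda > 0) {
    # factor out the max so the power never overflows
    hi * ((1 + (lo / hi)^lambda) / 2)^(1 / lambda)
  } else {
    lo * (((hi / lo)^lambda + 1) / 2)^(1 / lambda)
  }
  out <- 1 - x / B
  out[m == 0 | n == 0] <- NA_real_
  out
}

#' Generalized-average (GA) distance between binary profiles
#'
#' For binary vectors with one-counts `m` and `n` and scalar product `X`,
#' the GA similarity is `X / B_lambda` where `B_lambda` is the power mean
#' `((m^lambda + n^lambda) / 2)^(1/lambda)` of the two one-counts; the
#' distance is one minus the similarity. The exponent selects a member of
#' a large family of binary dissimilarities:
#' `lambda -> -Inf` gives `B = min(m, n)` (Simpson), `lambda = 0` the
#' geometric mean (Ochiai/cosine), `lambda = 1` the arithmetic mean
#' (Dice), and `lambda -> +Inf` `B = max(m, n)` (max-overlap). Because
#' `X <= min(m, n) <= B_lambda`, the distance always lies in \[0, 1\].
#'
#' Large finite exponents are evaluated with the maximum (or minimum)
#' factored out of the power mean so that `m^lambda` never overflows.
#'
#' @param u,v binary (0/1) vectors of equal length.
#' @param lambda the exponent: a finite real, `-Inf` or `Inf`.
#' @return scalar in \[0, 1\], or `NA` when either vector is all zeros
#'   (the similarity is undefined there).
#' @export
#' @examples
#' u <- c(1, 1, 1, 0, 0, 0, 0, 0)
#' v <- c(1, 1, 0, 0, 0, 0, 0, 0)
#' ga_distance(u, v, -Inf)  # Simpson: 1 - 2/2 = 0
#' ga_distance(u, v, 1)     # Dice:    1 - 2/2.5 = 0.2
#' ga_distance(u, v, Inf)   # max:     1 - 2/3
ga_distance <- function(u, v, lambda) {
  if (length(u) != length(v)) stop("length mismatch", call. = FALSE)
  if (!all(u %in% c(0, 1)) || !all(v %in% c(0, 1)))
    stop("ga_distance requires binary (0/1) vectors", call. = FALSE)
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda))
    stop("`lambda` must be a single real (possibly infinite)", call. = FALSE)
  ga_from_counts(sum(u * v), sum(u), sum(v), lambda)
}

# Row-wise vectorized kernels over aligned matrices (one row per pair).
rowwise_euclidean <- function(A, B) sqrt(rowSums((A - B)^2))

rowwise_correlation_distance <- function(A, B) {
  Ac <- A - rowMeans(A)
  Bc <- B - rowMeans(B)
  va <- rowSums(Ac^2)
  vb <- rowSums(Bc^2)
  r <- rowSums(Ac * Bc) / sqrt(va * vb)
  r[va == 0 | vb == 0] <- NA_real_
  1 - r
}

rowwise_ga <- function(A, B, lambda)
  ga_from_counts(rowSums(A * B), rowSums(A), rowSums(B), lambda)

DISTANCE_MEASURES <- c("euclidean", "correlation", "binary_correlation", "ga")

#' Distances between paired genes of two species
#'
#' Computes one distance per gene pair between two already-transformed
#' matrices: pass relative-expression matrices for `euclidean` and
#' `correlation`, binary matrices for `binary_correlation` and `ga`.
#' Pairs whose distance is undefined (zero-variance profile for
#' correlation measures, empty binary profile for GA) are excluded and
#' counted, never imputed.
#'
#' @param matA,matB transformed gene x tissue matrices for species 1 and
#'   2, with gene ids as rownames.
#' @param pairs data.frame with columns `species1`, `species2` naming rows
#'   of `matA` and `matB` respectively.
#' @param measure one of `"euclidean"`, `"correlation"`,
#'   `"binary_correlation"`, `"ga"`.
#' @param lambda GA exponent, required when `measure = "ga"`.
#' @return an object of class `pair_distances`: a list with `measure`,
#'   `lambda`, `pairs` (the defined pairs, input order, with a `distance`
#'   column), `excluded` (pairs dropped as undefined) and `n_input`.
#' @export
pairwise_distances <- function(matA, matB, pairs,
                               measure = DISTANCE_MEASURES, lambda = NULL) {
  measure <- match.arg(measure)
  stopifnot(is.data.frame(pairs),
            all(c("species1", "species2") %in% names(pairs)))
  miss_a <- setdiff(pairs$species1, rownames(matA))
  miss_b <- setdiff(pairs$species2, rownames(matB))
  if (length(miss_a) || length(miss_b))
    stop("unknown gene id(s): ",
         paste(utils::head(c(miss_a, miss_b), 5), collapse = ", "),
         call. = FALSE)
  A <- matA[pairs$species1, , drop = FALSE]
  B <- matB[pairs$species2, , drop = FALSE]
  if (ncol(A) != ncol(B)) stop("tissue count mismatch", call. = FALSE)

  if (measure == "ga") {
    if (is.null(lambda)) stop("`lambda` is required for measure \"ga\"",
                              call. = FALSE)
    d <- rowwise_ga(A, B, lambda)
  } else if (measure == "euclidean") {
    d <- rowwise_euclidean(A, B)
  } else {  # correlation and binary_correlation share the kernel
    d <- rowwise_correlation_distance(A, B)
  }

  ok <- !is.na(d)
  res <- pairs[ok, c("species1", "species2"), drop = FALSE]
  res$distance <- d[ok]
  rownames(res) <- NULL
  structure(list(
    measure = measure,
    lambda = if (measure == "ga") lambda else NULL,
    pairs = res,
    excluded = pairs[!ok, c("species1", "species2"), drop = FALSE],
    n_input = nrow(pairs)
  ), class = "pair_distances")
}

#' @export
print.pair_distances <- function(x, ...) {
  lab <- if (x$measure == "ga")
    sprintf("ga (lambda = %g)", x$lambda) else x$measure
  cat(sprintf("pair_distances: %s, %d pairs (%d excluded as undefined)\n",
              lab, nrow(x$pairs), nrow(x$excluded)))
  if (nrow(x$pairs)) {
    q <- stats::quantile(x$pairs$distance, c(0, 0.25, 0.5, 0.75, 1))
    cat(sprintf("  distance range [%.4g, %.4g], median %.4g\n",
                q[1], q[5], q[3]))
  }
  invisible(x)
}
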