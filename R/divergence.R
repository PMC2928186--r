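# Conserved-pair calling against an empirical random-pair null, and the
# characterization of what each distance measure calls conserved.

#' Empirical null model from random-pair distances
#'
#' A conserved ortholog pair is one whose distance is unusually *small*
#' compared to distances between random cross-species gene pairs, so the
#' significance threshold is the lower-tail nearest-rank quantile of the
#' random-pair distance distribution: the `ceiling(alpha * N)`-th
#' smallest of the N defined random-pair distances. Nearest-rank avoids
#' any interpolation ambiguity.
#'
#' @param random_distances a `pair_distances` object computed on randomly
#'   re-paired genes (see [generate_random_pairs()]).
#' @param alpha significance level in (0, 1); requires at least
#'   `1/alpha` defined distances.
#' @return object of class `null_model`: list with `measure`, `lambda`,
#'   `alpha`, `n`, `threshold` and the sorted null `values`.
#' @export
build_null <- function(random_distances, alpha) {
  stopifnot(inherits(random_distances, "pair_distances"))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  values <- sort(random_distances$pairs$distance)
  n <- length(values)
  if (n < 1 / alpha)
    stop("need at least ", ceiling(1 / alpha),
         " defined random-pair distances for alpha = ", alpha,
         "; got ", n, call. = FALSE)
  k <- ceiling(alpha * n)
  structure(list(
    measure = random_distances$measure,
    lambda = random_distances$lambda,
    alpha = alpha,
    n = n,
    threshold = values[k],
    values = values
  ), class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  lab <- if (identical(x$measure, "ga"))
    sprintf("ga (lambda = %g)", x$lambda) else x$measure
  cat(sprintf(
    "null_model: %s, N = %d random pairs, alpha = %g, threshold = %.6g\n",
    lab, x$n, x$alpha, x$threshold))
  invisible(x)
}

#' Call ortholog pairs with conserved expression
#'
#' An ortholog pair is called conserved when its distance is less than or
#' equal to the null model's lower-tail threshold. For each called pair
#' the report records the mean absolute (untransformed) expression in
#' each species — the relative transform erases expression level, so
#' characterizing *which* genes a measure calls conserved has to go back
#' to the raw intensities.
#'
#' @param ortholog_distances a `pair_distances` object for the true
#'   ortholog pairs, computed with the same measure/parameters as the
#'   null.
#' @param null a [build_null()] model.
#' @param exprA,exprB the untransformed linear-scale expression matrices
#'   (used for the mean-expression characterization).
#' @param upper_quartile_genes optional character vector of species-1
#'   gene ids (e.g. from [upper_quartile_entropy_genes()]); when given,
#'   the report counts how many called pairs fall in that set.
#' @return object of class `conserved_report`: list with `measure`,
#'   `lambda`, `alpha`, `threshold`, `n_tested`, `n_called`, `called`
#'   (data.frame of called pairs with distances and per-species mean
#'   expression) and `n_in_entropy_quartile` (NA when no gene set given).
#' @export
call_conserved <- function(ortholog_distances, null, exprA, exprB,
                           upper_quartile_genes = NULL) {
  stopifnot(inherits(ortholog_distances, "pair_distances"),
            inherits(null, "null_model"))
  if (!identical(ortholog_distances$measure, null$measure) ||
      !identical(ortholog_distances$lambda, null$lambda))
    stop("measure/parameters of distances and null model differ",
         call. = FALSE)
  tested <- ortholog_distances$pairs
  called <- tested[tested$distance <= null$threshold, , drop = FALSE]
  rownames(called) <- NULL
  if (nrow(called)) {
    called$mean_expr1 <- rowMeans(exprA[called$species1, , drop = FALSE])
    called$mean_expr2 <- rowMeans(exprB[called$species2, , drop = FALSE])
  } else {
    called$mean_expr1 <- called$mean_expr2 <- numeric(0)
  }
  n_uq <- if (is.null(upper_quartile_genes)) NA_integer_
          else sum(called$species1 %in% upper_quartile_genes)
  structure(list(
    measure = ortholog_distances$measure,
    lambda = ortholog_distances$lambda,
    alpha = null$alpha,
    threshold = null$threshold,
    n_tested = nrow(tested),
    n_called = nrow(called),
    called = called,
    n_in_entropy_quartile = n_uq
  ), class = "conserved_report")
}

#' @export
print.conserved_report <- function(x, ...) {
  lab <- if (identical(x$measure, "ga"))
    sprintf("ga (lambda = %g)", x$lambda) else x$measure
  cat(sprintf(
    "conserved_report: %s, alpha = %g -> %d / %d pairs called conserved\n",
    lab, x$alpha, x$n_called, x$n_tested))
  invisible(x)
}

#' Genes in the upper quartile of the entropy distribution
#'
#' Returns the `ceiling(N/4)` gene ids with the largest expression
#' entropy ("uniformly expressed" genes under the entropy definition).
#' Ties at the cut are resolved by stable input (gene-id) order, so the
#' result always has exactly `ceiling(N/4)` genes.
#'
#' @param entropy named numeric vector of per-gene entropies (see
#'   [gene_entropy()]); needs at least 4 genes.
#' @return character vector of gene ids, in decreasing-entropy order.
#' @export
upper_quartile_entropy_genes <- function(entropy) {
  n <- length(entropy)
  if (n < 4) stop("need at least 4 genes, got ", n, call. = FALSE)
  if (is.null(names(entropy)))
    names(entropy) <- sprintf("gene%05d", seq_len(n))
  k <- ceiling(n / 4)
  names(entropy)[order(-entropy, seq_len(n))][seq_len(k)]
}

#' Contrast the gene sets called conserved by two measures
#'
#' Compares what two distance measures consider "conserved expression":
#' per called set it summarizes the distribution of mean absolute
#' expression (averaged over the two species) and the across-tissue
#' coefficient of variation, and reports the difference in median mean
#' expression between the sets (A minus B) together with a two-sided
#' Wilcoxon rank-sum statistic as a purely descriptive quantity — no
#' inferential thresholding is performed.
#'
#' @param reportA,reportB two [call_conserved()] reports on the same
#'   dataset.
#' @param exprA,exprB the untransformed linear-scale matrices.
#' @return list with per-set summaries (`set_a`, `set_b`: n, median mean
#'   expression, median CV), `median_diff` (A - B), `wilcoxon_W` and
#'   `wilcoxon_p` (descriptive; NA when either set is empty), and
#'   `empty_sets` flagging empty called sets.
#' @export
contrast_called_sets <- function(reportA, reportB, exprA, exprB) {
  stopifnot(inherits(reportA, "conserved_report"),
            inherits(reportB, "conserved_report"))
  set_stats <- function(rep) {
    if (rep$n_called == 0)
      return(list(n = 0L, median_mean_expr = NA_real_,
                  median_cv = NA_real_, mean_expr = numeric(0)))
    prof1 <- exprA[rep$called$species1, , drop = FALSE]
    prof2 <- exprB[rep$called$species2, , drop = FALSE]
    me <- (rowMeans(prof1) + rowMeans(prof2)) / 2
    cv <- (apply(prof1, 1, stats::sd) / rowMeans(prof1) +
           apply(prof2, 1, stats::sd) / rowMeans(prof2)) / 2
    list(n = rep$n_called, median_mean_expr = stats::median(me),
         median_cv = stats::median(cv), mean_expr = me)
  }
  a <- set_stats(reportA)
  b <- set_stats(reportB)
  empty <- a$n == 0 || b$n == 0
  if (!empty) {
    wt <- stats::wilcox.test(a$mean_expr, b$mean_expr, exact = FALSE)
    W <- unname(wt$statistic); p <- wt$p.value
    md <- a$median_mean_expr - b$median_mean_expr
  } else {
    W <- p <- md <- NA_real_
  }
  list(set_a = a[c("n", "median_mean_expr", "median_cv")],
       set_b = b[c("n", "median_mean_expr", "median_cv")],
       median_diff = md, wilcoxon_W = W, wilcoxon_p = p,
       empty_sets = empty)
}
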