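# Moment-based selection of GA exponents: the empirically best-performing
# member of a distance family tends to have extreme third and fourth
# moments of its pair-distance distribution, so we scan a lambda grid and
# flag the extremes.

#' Moment summary of a pair-distance distribution
#'
#' Computes mean, standard deviation, skewness and excess kurtosis of the
#' defined distances in a [pairwise_distances()] result, using the biased
#' (divide-by-N) central-moment convention: `g1 = m3 / m2^(3/2)`,
#' `g2 = m4 / m2^2 - 3`. The convention is irrelevant to ranking
#' distributions of equal N but is fixed here for reproducibility.
#'
#' @param d a `pair_distances` object (or a bare numeric vector of
#'   distances).
#' @return one-row data.frame with `measure`, `lambda`, `n`, `mean`, `sd`,
#'   `skewness`, `kurtosis` (excess). Moments are `NA` when the variance
#'   is zero.
#' @export
distance_moments <- function(d) {
  if (inherits(d, "pair_distances")) {
    values <- d$pairs$distance
    measure <- d$measure
    lambda <- if (is.null(d$lambda)) NA_real_ else d$lambda
  } else {
    values <- as.numeric(d)
    measure <- NA_character_
    lambda <- NA_real_
  }
  n <- length(values)
  if (n < 4)
    stop("need at least 4 defined distances, got ", n, call. = FALSE)
  m <- mean(values)
  cm <- values - m
  m2 <- mean(cm^2)
  if (m2 == 0) {
    g1 <- g2 <- NA_real_
  } else {
    g1 <- mean(cm^3) / m2^1.5
    g2 <- mean(cm^4) / m2^2 - 3
  }
  data.frame(measure = measure, lambda = lambda, n = n, mean = m,
             sd = sqrt(m2), skewness = g1, kurtosis = g2,
             stringsAsFactors = FALSE)
}

#' Default exponent grid for the GA scan
#' @export
default_lambda_grid <- function()
  c(-Inf, -10, -5, -2, -1, 0, 1, 2, 5, 10, Inf)

#' Scan GA exponents by distribution moments
#'
#' Computes the pair-distance distribution for each exponent in
#' `lambda_grid` (plus the binary correlation distance as a comparator
#' row) between binary-transformed matrices, summarizes each by its third
#' and fourth moments, and flags the extreme entries: the minimum
#' skewness and both the minimum and maximum excess kurtosis. The
#' extreme-moment rule is a heuristic, so ties are listed, never silently
#' broken, and all extremes are reported rather than committing to one.
#'
#' @param matA,matB binary gene x tissue matrices (see [to_binary()]).
#' @param pairs ortholog (or random) pair table.
#' @param lambda_grid numeric vector of exponents (may include `-Inf`,
#'   `Inf`); defaults to [default_lambda_grid()].
#' @param include_binary_correlation append the binary correlation
#'   distance as a comparator row (default TRUE), so the selection can
#'   fall on it as well as on a GA family member.
#' @return list with `table` (one moment-summary row per grid entry plus a
#'   `binary_correlation` row) and `selection`, itself a list of character
#'   vectors `min_skewness`, `min_kurtosis`, `max_kurtosis` naming the
#'   selected rows (ties all listed).
#' @export
scan_ga_exponents <- function(matA, matB, pairs,
                              lambda_grid = default_lambda_grid(),
                              include_binary_correlation = TRUE) {
  if (length(lambda_grid) == 0) stop("empty lambda grid", call. = FALSE)
  rows <- lapply(lambda_grid, function(lam)
    distance_moments(pairwise_distances(matA, matB, pairs, "ga", lam)))
  if (include_binary_correlation) rows <- c(rows, list(
    distance_moments(pairwise_distances(matA, matB, pairs,
                                        "binary_correlation"))))
  tab <- do.call(rbind, rows)
  tab$label <- ifelse(tab$measure == "ga",
                      paste0("ga(", tab$lambda, ")"), tab$measure)
  rownames(tab) <- NULL

  pick <- function(stat, extreme) {
    v <- tab[[stat]]
    if (all(is.na(v))) return(character())
    x <- extreme(v, na.rm = TRUE)
    tab$label[!is.na(v) & v == x]
  }
  list(table = tab,
       selection = list(min_skewness = pick("skewness", min),
                        min_kurtosis = pick("kurtosis", min),
                        max_kurtosis = pick("kurtosis", max)))
}
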