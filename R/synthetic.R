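# Synthetic paired two-species expression data with known ground truth.

GENE_CLASSES <- c("tissue_specific", "housekeeping", "background")

# Eight tissues shared by the classic human/rat cross-tissue compendia;
# used as default labels when n_tissues == 8.
DEFAULT_TISSUES <- c("bone_marrow", "heart", "kidney", "pituitary",
                     "skeletal_muscle", "small_intestine", "spleen", "thymus")

#' Configuration for the synthetic two-species expression generator
#'
#' Builds and validates the parameter set of the generative model used by
#' [generate_paired_expression()]. Genes fall into three classes:
#' tissue-specific (a strong expression bump in one target tissue),
#' housekeeping (uniform, moderately high) and background (uniform, low,
#' near the noise floor). All location/scale parameters are on the log2
#' scale; generated intensities are returned on the linear scale.
#'
#' @param n_genes number of genes (= ortholog pairs) to simulate.
#' @param n_tissues number of tissues (homologous between species); >= 2.
#' @param frac_tissue_specific,frac_housekeeping,frac_background class
#'   proportions; must sum to 1. Class counts are `floor(n_genes * frac)`
#'   for the first two classes, remainder background, then shuffled.
#' @param baseline_mean_by_class named numeric vector of per-class mean
#'   baseline log2 intensities (names `tissue_specific`, `housekeeping`,
#'   `background`).
#' @param baseline_sd standard deviation of the per-gene baseline draw
#'   around its class mean (log2 units).
#' @param tissue_effect_size amplitude of the tissue-specific expression
#'   bump (log2 units).
#' @param conservation either a single value in \[0, 1\] applied to every
#'   gene or a named per-class vector. 1 means the tissue-effect profile is
#'   fully shared between the species' orthologs, 0 means each species
#'   draws an independent profile of the same magnitude.
#' @param species_shift constant added to all log2 intensities of species 2
#'   (a species-wide intensity shift, as seen between array platforms).
#' @param noise_sd standard deviation of per-measurement Gaussian noise
#'   (log2 units), independent between species.
#' @param seed integer seed; the generator is deterministic given the
#'   config.
#'
#' @return an object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_genes = 3152,
                             n_tissues = 8,
                             frac_tissue_specific = 0.4,
                             frac_housekeeping = 0.2,
                             frac_background = 0.4,
                             baseline_mean_by_class = c(tissue_specific = 8,
                                                        housekeeping = 8,
                                                        background = 4),
                             baseline_sd = 1,
                             tissue_effect_size = 4,
                             conservation = c(tissue_specific = 0.8,
                                              housekeeping = 1,
                                              background = 0),
                             species_shift = 1,
                             noise_sd = 0.25,
                             seed = 1L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1 || n_genes < 1 ||
      n_genes != round(n_genes))
    stop("`n_genes` must be a positive integer", call. = FALSE)
  if (!is.numeric(n_tissues) || length(n_tissues) != 1 || n_tissues < 2 ||
      n_tissues != round(n_tissues))
    stop("`n_tissues` must be an integer >= 2", call. = FALSE)
  fr <- c(frac_tissue_specific, frac_housekeeping, frac_background)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1))
    stop("class fractions must lie in [0, 1]", call. = FALSE)
  if (abs(sum(fr) - 1) > 1e-8)
    stop("class fractions must sum to 1 (got ", sum(fr), ")", call. = FALSE)
  if (!all(GENE_CLASSES %in% names(baseline_mean_by_class)))
    stop("`baseline_mean_by_class` must be named for all three classes",
         call. = FALSE)
  if (length(conservation) == 1 && is.null(names(conservation)))
    conservation <- stats::setNames(rep(conservation, 3), GENE_CLASSES)
  if (!all(GENE_CLASSES %in% names(conservation)))
    stop("`conservation` must be a single value or named per class",
         call. = FALSE)
  if (any(conservation < 0 | conservation > 1))
    stop("`conservation` must lie in [0, 1]", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (baseline_sd < 0) stop("`baseline_sd` must be >= 0", call. = FALSE)

  structure(list(
    n_genes = as.integer(n_genes),
    n_tissues = as.integer(n_tissues),
    frac_tissue_specific = frac_tissue_specific,
    frac_housekeeping = frac_housekeeping,
    frac_background = frac_background,
    baseline_mean_by_class = baseline_mean_by_class[GENE_CLASSES],
    baseline_sd = baseline_sd,
    tissue_effect_size = tissue_effect_size,
    conservation = conservation[GENE_CLASSES],
    species_shift = species_shift,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so the generator has no global side effects.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

tissue_labels_for <- function(n_tissues) {
  if (n_tissues == 8) DEFAULT_TISSUES
  else sprintf("tissue%02d", seq_len(n_tissues))
}

#' Generate paired two-species expression matrices
#'
#' Simulates log2 expression `y[s, i, t] = b_i + delta * 1\{s = 2\} +
#' c_i * e[i, t] + (1 - c_i) * e2[s, i, t] + eps[s, i, t]` for gene `i`,
#' tissue `t`, species `s`, where `b_i` is the per-gene baseline drawn
#' around its class mean, `delta` the species-wide shift, `e` the shared
#' tissue-effect profile (a bump of `tissue_effect_size` at the target
#' tissue for tissue-specific genes, zero for the uniform classes), `e2`
#' an independently drawn per-species profile of the same construction,
#' `c_i` the per-gene conservation weight and `eps` Gaussian noise,
#' independent between species. Returned intensities are `2^y`, i.e. on a
#' strictly positive linear scale.
#'
#' @param config a [synthetic_config()].
#' @return a list with components:
#'   \item{expr1, expr2}{gene x tissue linear-scale intensity matrices,
#'     one per species, with gene ids as rownames and tissue labels as
#'     colnames; the species tag is stored in `attr(, "species")`.}
#'   \item{pairs}{data.frame with columns `species1`, `species2`: the
#'     one-to-one ortholog map (row i of `expr1` pairs with row i of
#'     `expr2`).}
#'   \item{truth}{data.frame with per-gene `class`, `target_tissue`
#'     (NA unless tissue-specific) and `conservation`.}
#' @export
#' @examples
#' sim <- generate_paired_expression(synthetic_config(n_genes = 50, seed = 7))
#' dim(sim$expr1)
#' table(sim$truth$class)
generate_paired_expression <- function(config) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, as.list(config))
  n <- config$n_genes
  nt <- config$n_tissues

  with_seed(config$seed, {
    # deterministic block class assignment, then a seeded shuffle
    n_ts <- floor(n * config$frac_tissue_specific)
    n_hk <- floor(n * config$frac_housekeeping)
    n_bg <- n - n_ts - n_hk
    classes <- rep(GENE_CLASSES, c(n_ts, n_hk, n_bg))[sample.int(n)]

    b <- stats::rnorm(n, config$baseline_mean_by_class[classes],
                      config$baseline_sd)
    cons <- unname(config$conservation[classes])
    is_ts <- classes == "tissue_specific"
    target <- ifelse(is_ts, sample.int(nt, n, replace = TRUE), NA_integer_)

    # shared tissue-effect profile e[i, t]
    e <- matrix(0, n, nt)
    e[cbind(which(is_ts), target[is_ts])] <- config$tissue_effect_size

    make_species <- function(shift) {
      # independent per-species profile e2 of the same construction
      e2 <- matrix(0, n, nt)
      own_target <- sample.int(nt, n, replace = TRUE)
      e2[cbind(which(is_ts), own_target[is_ts])] <- config$tissue_effect_size
      eps <- matrix(stats::rnorm(n * nt, 0, config$noise_sd), n, nt)
      b + shift + cons * e + (1 - cons) * e2 + eps
    }
    y1 <- make_species(0)
    y2 <- make_species(config$species_shift)

    g1 <- sprintf("s1_g%05d", seq_len(n))
    g2 <- sprintf("s2_g%05d", seq_len(n))
    tl <- tissue_labels_for(nt)
    expr1 <- 2^y1; dimnames(expr1) <- list(g1, tl)
    expr2 <- 2^y2; dimnames(expr2) <- list(g2, tl)
    attr(expr1, "species") <- "species1"
    attr(expr2, "species") <- "species2"

    list(
      expr1 = expr1,
      expr2 = expr2,
      pairs = data.frame(species1 = g1, species2 = g2,
                         stringsAsFactors = FALSE),
      truth = data.frame(gene = g1, class = classes,
                         target_tissue = ifelse(is_ts, tl[target], NA),
                         conservation = cons, stringsAsFactors = FALSE)
    )
  })
}

#' Randomly re-pair genes across species (derangement)
#'
#' Builds a null set of gene pairs by re-pairing each species-1 gene with a
#' species-2 gene drawn from a uniform random permutation, rejecting and
#' re-drawing any permutation that re-creates a true ortholog pair
#' (a fixed point). The result therefore has the same cardinality as the
#' input and shares no pair with it, giving a clean random-pair null for
#' distance distributions.
#'
#' @param pairs data.frame with columns `species1`, `species2` (the true
#'   ortholog map).
#' @param seed integer seed; deterministic given `seed`.
#' @return a data.frame of the same shape: same `species1` column, permuted
#'   `species2` column with no fixed points.
#' @export
generate_random_pairs <- function(pairs, seed) {
  stopifnot(is.data.frame(pairs),
            all(c("species1", "species2") %in% names(pairs)))
  n <- nrow(pairs)
  if (n < 2)
    stop("need at least 2 pairs to build a fixed-point-free re-pairing",
         call. = FALSE)
  with_seed(seed, {
    repeat {
      perm <- sample.int(n)
      if (!any(perm == seq_len(n))) break
    }
    data.frame(species1 = pairs$species1,
               species2 = pairs$species2[perm],
               stringsAsFactors = FALSE)
  })
}
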