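# Plain-text I/O: tab-separated, UTF-8, '.' decimal, header row, no
# quoting. Expression tables carry the gene id in the first column and
# tissue labels in the header.

#' Read / write an expression matrix as TSV
#'
#' The on-disk dialect is a header row of tissue labels preceded by a
#' `gene_id` column; values are linear-scale intensities. Reading
#' validates uniqueness of gene ids and rectangular shape, and reports
#' the offending line on failure.
#'
#' @param path file path.
#' @param species optional species tag stored in `attr(, "species")`.
#' @return `read_expression_tsv()`: a numeric gene x tissue matrix.
#' @export
read_expression_tsv <- function(path, species = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("expected a gene id column plus at least one tissue column in ",
         path, call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop("duplicate gene id '", dup, "' (first duplicate at line ",
         which(ids == dup)[2] + 1L, ") in ", path, call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!stats::complete.cases(suppressWarnings(
      apply(m, 2, as.numeric))))[1]
    stop("non-numeric expression value at line ", bad + 1L, " of ", path,
         call. = FALSE)
  }
  rownames(m) <- ids
  if (!is.null(species)) attr(m, "species") <- species
  m
}

#' @rdname read_expression_tsv
#' @param mat gene x tissue matrix with dimnames.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write an ortholog pair table as two-column TSV
#' @param path file path.
#' @return `read_ortholog_tsv()`: data.frame with `species1`, `species2`.
#' @export
read_ortholog_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("species1", "species2") %in% names(df)))
    stop("ortholog table must have columns species1, species2: ", path,
         call. = FALSE)
  if (anyDuplicated(df$species1) || anyDuplicated(df$species2))
    stop("ortholog map is not one-to-one in ", path, call. = FALSE)
  df[c("species1", "species2")]
}

#' @rdname read_ortholog_tsv
#' @param pairs data.frame with `species1`, `species2`.
#' @export
write_ortholog_tsv <- function(pairs, path) {
  utils::write.table(pairs[c("species1", "species2")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a pair-distance table as TSV
#'
#' Columns: pair ids, distance, measure and (for GA) lambda; pairs
#' excluded as undefined are listed in a side-car file
#' `<path>.excluded.tsv` when any exist.
#'
#' @param d a `pair_distances` object.
#' @param path output file path.
#' @export
write_pair_distances_tsv <- function(d, path) {
  stopifnot(inherits(d, "pair_distances"))
  out <- d$pairs
  out$measure <- d$measure
  out$lambda <- if (is.null(d$lambda)) NA else d$lambda
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(d$excluded))
    utils::write.table(d$excluded, paste0(path, ".excluded.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  invisible(path)
}
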