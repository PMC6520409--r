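#' Read a gene x sample expression matrix from TSV
#'
#' The dialect is a tab-separated table with a header row whose first column
#' is `gene_id` and whose remaining columns are sample identifiers.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix with gene ids as rownames and sample ids as colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop("first column must be `gene_id`", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "double"
  stop_if_not_matrix(m)
  m
}

#' Write an expression matrix as TSV
#'
#' @param expr Gene x sample numeric matrix.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  stop_if_not_matrix(expr)
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table from TSV
#'
#' @param path Path to a TSV with at least a `sample_id` column; the usual
#'   columns are `sample_id, sex, stratum, age, batch, bmi` plus optional
#'   numeric traits.
#' @return A data.frame.
#' @export
read_sample_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("missing `sample_id` column", call. = FALSE)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids", call. = FALSE)
  df
}

#' Write a sample metadata table as TSV
#'
#' @param samples Sample data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_sample_tsv <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' Standard GMT: one set per line, `set_name<TAB>description<TAB>gene1<TAB>...`.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lapply(sets, unique)
}

#' Write a gene-set collection in GMT format
#'
#' @param collection Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions
#'   (defaults to the set names).
#' @return The path, invisibly.
#' @export
write_gmt <- function(collection, path, descriptions = names(collection)) {
  if (is.null(names(collection)) || any(names(collection) == "")) {
    stop("every gene set must be named", call. = FALSE)
  }
  if (any(lengths(collection) == 0)) stop("empty gene sets are not allowed", call. = FALSE)
  lines <- vapply(seq_along(collection), function(i) {
    paste(c(names(collection)[i], descriptions[i], collection[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
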