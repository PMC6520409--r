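#' Hypergeometric over-representation test
#'
#' Upper-tail probability `P(X >= overlap)` for the overlap between a query
#' gene list and a gene set drawn from a common background.
#'
#' @param overlap Observed overlap count.
#' @param query_size Size of the query list.
#' @param set_size Size of the gene set within the background.
#' @param background_size Size of the background universe.
#' @return The p-value.
#' @export
hypergeom_test <- function(overlap, query_size, set_size, background_size) {
  if (overlap > min(query_size, set_size) ||
      set_size > background_size || query_size > background_size ||
      any(c(overlap, query_size, set_size, background_size) < 0)) {
    stop("inconsistent counts", call. = FALSE)
  }
  stats::phyper(overlap - 1, set_size, background_size - set_size, query_size,
                lower.tail = FALSE)
}

#' Over-representation of a query list against a gene-set collection
#'
#' Each set is intersected with the background before testing (so the
#' background defines the effective set sizes); query genes absent from the
#' background are dropped with a warning. One hypergeometric test per
#' surviving set, BH adjustment across sets, sorted by p-value.
#'
#' @param query Character vector of query gene ids.
#' @param collection Named list of character vectors (e.g. from [read_gmt()]).
#' @param background Character vector of background gene ids.
#' @return data.frame `set, overlap, set_size, query_size, background_size,
#'   p, p_adj`.
#' @export
enrich_collection <- function(query, collection, background) {
  background <- unique(background)
  query <- unique(query)
  outside <- setdiff(query, background)
  if (length(outside)) {
    warning(length(outside), " query gene(s) absent from background dropped")
    query <- setdiff(query, outside)
  }
  sets <- lapply(collection, function(s) intersect(unique(s), background))
  sets <- sets[lengths(sets) > 0]
  if (length(sets) == 0) {
    return(data.frame(set = character(0), overlap = integer(0),
                      set_size = integer(0), query_size = integer(0),
                      background_size = integer(0), p = numeric(0),
                      p_adj = numeric(0), stringsAsFactors = FALSE))
  }
  res <- data.frame(
    set = names(sets),
    overlap = vapply(sets, function(s) length(intersect(s, query)), integer(1)),
    set_size = lengths(sets),
    query_size = length(query),
    background_size = length(background),
    stringsAsFactors = FALSE, row.names = NULL)
  res$p <- mapply(hypergeom_test, res$overlap, res$query_size, res$set_size,
                  res$background_size)
  res$p_adj <- bh_adjust(res$p)
  res <- res[order(res$p, res$set), , drop = FALSE]
  rownames(res) <- NULL
  res
}
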