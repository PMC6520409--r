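#' Percentile cutoff over the off-diagonal TOM values
#'
#' @param tom TOM matrix (at least 2 genes).
#' @param percentile Percentile in (0, 1), default 0.99; linear interpolation.
#' @return The cutoff value.
#' @export
percentile_cutoff <- function(tom, percentile = 0.99) {
  stopifnot(is.matrix(tom), nrow(tom) >= 2)
  if (percentile <= 0 || percentile >= 1) {
    stop("`percentile` must be in (0, 1)", call. = FALSE)
  }
  unname(stats::quantile(tom[upper.tri(tom)], probs = percentile))
}

#' Edge set above a TOM cutoff
#'
#' A pair of distinct genes is an edge iff its TOM value strictly exceeds the
#' cutoff.
#'
#' @param tom TOM matrix.
#' @param cutoff Cutoff in \[0, 1\].
#' @return data.frame `gene_a, gene_b, tom` (gene_a < gene_b).
#' @export
edge_set <- function(tom, cutoff) {
  stopifnot(is.matrix(tom), cutoff >= 0, cutoff <= 1)
  ut <- upper.tri(tom)
  hit <- which(ut & tom > cutoff, arr.ind = TRUE)
  ids <- rownames(tom)
  data.frame(gene_a = ids[hit[, 1]], gene_b = ids[hit[, 2]],
             tom = tom[hit], stringsAsFactors = FALSE)
}

#' Whole-network connectivity from an edge set
#'
#' Number of edge partners per gene, self excluded. Genes of `universe` with
#' no edges get 0.
#'
#' @param edges Edge data.frame from [edge_set()].
#' @param universe Character vector of all gene ids in the network.
#' @return Named integer vector.
#' @export
edge_connectivity <- function(edges, universe) {
  counts <- table(factor(c(edges$gene_a, edges$gene_b), levels = universe))
  stats::setNames(as.integer(counts), universe)
}

#' Within-module connectivity
#'
#' Per gene, the number of edge partners sharing its module label.
#' Unassigned genes are reported NA.
#'
#' @param edges Edge data.frame.
#' @param assignment Named module vector covering every gene in the edges.
#' @return Named numeric vector (NA for unassigned genes).
#' @export
within_module_connectivity <- function(edges, assignment) {
  missing <- setdiff(c(edges$gene_a, edges$gene_b), names(assignment))
  if (length(missing)) {
    stop("genes missing from assignment: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  same <- assignment[edges$gene_a] == assignment[edges$gene_b] &
    assignment[edges$gene_a] != "unassigned"
  counts <- table(factor(c(edges$gene_a[same], edges$gene_b[same]),
                         levels = names(assignment)))
  out <- stats::setNames(as.numeric(counts), names(assignment))
  out[assignment == "unassigned"] <- NA_real_
  out
}

#' Group-specific networks and connectivities
#'
#' For each weight group separately: soft adjacency, TOM, the group's own
#' percentile cutoff, edge set, and whole-network connectivity over the
#' identical gene universe.
#'
#' @param expr Gene x sample numeric matrix.
#' @param samples Sample data.frame with a `group` column
#'   ("normal"/"overweight") aligned with `colnames(expr)`.
#' @param power Soft-thresholding power.
#' @param percentile Edge percentile (default 0.99).
#' @return List with `edges` (named list of edge data.frames), `connectivity`
#'   (data.frame `gene_id, c_normal, c_overweight`), and `cutoffs`.
#' @export
group_networks <- function(expr, samples, power = 6, percentile = 0.99) {
  stop_if_not_matrix(expr)
  if (!"group" %in% names(samples)) stop("samples need a `group` column", call. = FALSE)
  groups <- c("normal", "overweight")
  n_by_group <- table(factor(samples$group, levels = groups))
  if (any(n_by_group < 10)) {
    stop("each weight group needs at least 10 samples", call. = FALSE)
  }
  edges <- list(); cutoffs <- c(); conn <- list()
  for (g in groups) {
    j <- samples$group == g
    tom <- tom_similarity(soft_adjacency(expr[, j, drop = FALSE], power))
    cut <- percentile_cutoff(tom, percentile)
    e <- edge_set(tom, cut)
    edges[[g]] <- e
    cutoffs[g] <- cut
    conn[[g]] <- edge_connectivity(e, rownames(expr))
  }
  list(edges = edges,
       connectivity = data.frame(gene_id = rownames(expr),
                                 c_normal = conn$normal,
                                 c_overweight = conn$overweight,
                                 stringsAsFactors = FALSE, row.names = NULL),
       cutoffs = cutoffs)
}

#' Differential connectivity statistic
#'
#' `delta_C = (C2 - C1) / (C2 + C1 + s)` where `s > 0` is a pseudo-count of
#' gene connectivity damping small-degree noise. Bounded in (-1, 1) and
#' antisymmetric in its first two arguments.
#'
#' @param c1 Connectivity in network 1 (normal), non-negative.
#' @param c2 Connectivity in network 2 (overweight), non-negative.
#' @param s Pseudo-count, strictly positive.
#' @return Numeric vector of delta-C values.
#' @export
delta_connectivity <- function(c1, c2, s) {
  if (length(s) != 1 || is.na(s) || s <= 0) stop("`s` must be > 0", call. = FALSE)
  stopifnot(all(c1 >= 0), all(c2 >= 0))
  (c2 - c1) / (c2 + c1 + s)
}

#' Classify hub conversions from delta-C
#'
#' Strictly above `threshold`: a non-hub gene converted to a hub in the
#' overweight network; strictly below `-threshold`: a hub converted to a
#' non-hub; values at the boundary are stable.
#'
#' @param delta_c Numeric vector of delta-C values.
#' @param threshold Positive conversion threshold (default 0.5).
#' @return Character vector: "nonhub_to_hub", "hub_to_nonhub" or "stable".
#' @export
classify_hub_conversion <- function(delta_c, threshold = 0.5) {
  stopifnot(threshold > 0)
  ifelse(delta_c > threshold, "nonhub_to_hub",
         ifelse(delta_c < -threshold, "hub_to_nonhub", "stable"))
}

#' Mean gene connectivity
#'
#' The arithmetic mean of per-gene connectivities; the default pseudo-count
#' for [delta_connectivity()].
#'
#' @param connectivities Numeric vector of per-gene connectivities.
#' @return A single number.
#' @export
mean_connectivity <- function(connectivities) {
  stopifnot(length(connectivities) > 0)
  mean(connectivities)
}

#' Differential-connectivity table between weight groups
#'
#' Builds the two group networks, computes delta-C per gene with the
#' pseudo-count defaulting to the mean connectivity of the combined
#' (all-sample) network, and classifies hub conversions.
#'
#' @param expr Gene x sample numeric matrix.
#' @param samples Sample data.frame with a `group` column.
#' @param power Soft power (default 6).
#' @param percentile Edge percentile (default 0.99).
#' @param s Pseudo-count; NULL (default) uses the combined-network mean
#'   connectivity.
#' @param threshold Hub-conversion threshold (default 0.5).
#' @return data.frame `gene_id, c_normal, c_overweight, delta_c, conversion`
#'   with attributes `s` and `cutoffs`.
#' @export
differential_connectivity <- function(expr, samples, power = 6,
                                      percentile = 0.99, s = NULL,
                                      threshold = 0.5) {
  nets <- group_networks(expr, samples, power = power, percentile = percentile)
  rec <- nets$connectivity
  if (is.null(s)) {
    tom_all <- tom_similarity(soft_adjacency(expr, power))
    cut_all <- percentile_cutoff(tom_all, percentile)
    c_all <- edge_connectivity(edge_set(tom_all, cut_all), rownames(expr))
    s <- mean_connectivity(c_all)
    if (s <= 0) stop("combined network has no edges; supply `s` explicitly",
                     call. = FALSE)
  }
  rec$delta_c <- delta_connectivity(rec$c_normal, rec$c_overweight, s)
  rec$conversion <- classify_hub_conversion(rec$delta_c, threshold)
  attr(rec, "s") <- s
  attr(rec, "cutoffs") <- nets$cutoffs
  rec
}
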