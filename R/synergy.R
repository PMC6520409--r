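#' Parameters for three-way interaction detection
#'
#' @param tree_height Relative dendrogram cut height in (0, 1\] (merge heights
#'   are rescaled by their maximum before cutting), default 0.02.
#' @param top_n Number of entropy-ranked genes searched for pairs, default 100.
#' @param synergy_threshold Minimum synergy for a pair to proceed to control
#'   gene attribution, default 0.9.
#' @param purity_threshold Minimum cluster purity for a successful control
#'   gene attribution, default 0.5.
#' @param min_cluster_size Clusters with fewer samples are pooled into a
#'   background pool before any information statistic is computed, default 5.
#'   This guards the plug-in estimators against the near-singleton clusters
#'   that a fine cut produces on unstructured data.
#' @param entropy_sort `"desc"` (default) ranks genes by decreasing
#'   conditional entropy of weight status given the gene's high/low state, so
#'   genes carrying no single-gene information come first; `"asc"` reverses
#'   the ranking.
#' @return A validated list of class `synergy_params`.
#' @export
synergy_params <- function(tree_height = 0.02, top_n = 100,
                           synergy_threshold = 0.9, purity_threshold = 0.5,
                           min_cluster_size = 5,
                           entropy_sort = c("desc", "asc")) {
  entropy_sort <- match.arg(entropy_sort)
  stopifnot(tree_height > 0, tree_height <= 1,
            top_n >= 2, synergy_threshold > 0, synergy_threshold <= 1.5,
            purity_threshold >= 0, purity_threshold <= 1,
            min_cluster_size >= 1)
  structure(list(tree_height = tree_height, top_n = as.integer(top_n),
                 synergy_threshold = synergy_threshold,
                 purity_threshold = purity_threshold,
                 min_cluster_size = as.integer(min_cluster_size),
                 entropy_sort = entropy_sort),
            class = "synergy_params")
}

#' Conditional entropy of status given a gene's high/low state
#'
#' The gene is dichotomized at its median (strictly above = high) and the
#' plug-in conditional entropy `H(status | bin)` in bits is returned. A
#' constant gene carries no information and returns `H(status)` with a
#' warning.
#'
#' @param x Numeric expression vector (at least 4 samples).
#' @param status Binary status labels aligned with `x`.
#' @return Conditional entropy in bits.
#' @export
conditional_entropy <- function(x, status) {
  if (length(x) < 4) stop("need at least 4 samples", call. = FALSE)
  if (length(unique(status)) != 2) stop("`status` must be binary", call. = FALSE)
  if (stats::sd(x) == 0) {
    warning("constant gene; returning H(status)")
    return(plugin_entropy(status))
  }
  b <- median_high(x)
  plugin_entropy(status) - plugin_mi(b, status)
}

#' Rank genes by conditional entropy with weight status
#'
#' Genes are sorted by the conditional entropy of status given their
#' median-dichotomized state — by default in descending order, so that genes
#' whose individual state says nothing about status (the candidates for
#' purely synergistic effects) come first. Ties in the discrete statistic
#' (common, since a balanced 2x2 table gives exactly zero information) are
#' broken by the absolute Pearson correlation of the gene with status, in
#' the direction consistent with the sort, then by gene id.
#'
#' @param expr Gene x sample numeric matrix.
#' @param status Binary status per sample.
#' @param top_n How many gene ids to return (default all).
#' @param sort `"desc"` or `"asc"`.
#' @return Character vector of gene ids.
#' @export
rank_genes_by_entropy <- function(expr, status, top_n = nrow(expr),
                                  sort = c("desc", "asc")) {
  sort <- match.arg(sort)
  stop_if_not_matrix(expr)
  stopifnot(top_n <= nrow(expr))
  hs <- plugin_entropy(status)
  ce <- apply(expr, 1, function(x) {
    if (stats::sd(x) == 0) return(hs)
    hs - plugin_mi(median_high(x), status)
  })
  y <- as.numeric(factor(status))
  sds <- apply(expr, 1, stats::sd)
  abs_r <- rep(0, nrow(expr))
  abs_r[sds > 0] <- abs(as.numeric(stats::cor(t(expr[sds > 0, , drop = FALSE]), y)))
  o <- if (sort == "desc") order(-ce, abs_r, rownames(expr))
       else order(ce, -abs_r, rownames(expr))
  rownames(expr)[o][seq_len(top_n)]
}

#' Cluster samples in the 2-D expression space of a gene pair
#'
#' Samples are embedded as points `(scale(a), scale(b))`, clustered by
#' average-linkage on Euclidean distance, and the tree is cut at
#' `tree_height` times the maximum merge height. Singletons are allowed.
#'
#' @param a,b Numeric expression vectors of the two genes.
#' @param tree_height Relative cut height in (0, 1\].
#' @return Integer cluster labels per sample.
#' @export
pair_cluster <- function(a, b, tree_height = 0.02) {
  stopifnot(length(a) == length(b), length(a) >= 4,
            tree_height > 0, tree_height <= 1)
  pts <- cbind(as.numeric(scale(a)), as.numeric(scale(b)))
  hc <- stats::hclust(stats::dist(pts), method = "average")
  stats::cutree(hc, h = tree_height * max(hc$height))
}

# pool clusters below the minimum size into label 0
pool_small_clusters <- function(cl, min_size) {
  tab <- table(cl)
  cl[cl %in% as.integer(names(tab)[tab < min_size])] <- 0L
  cl
}

#' Synergy of a gene pair with respect to status
#'
#' `syn = [I(cluster; status) - I(a_bin; status) - I(b_bin; status)] /
#' H(status)` with plug-in mutual information, gene states dichotomized at
#' their medians, and clusters smaller than `min_cluster_size` pooled into a
#' background pool. The score is at most 1 and reaches 1 for the exact
#' balanced XOR configuration.
#'
#' @param cl Cluster labels from [pair_cluster()].
#' @param a,b The two genes' expression vectors.
#' @param status Binary status per sample.
#' @param min_cluster_size Pooling threshold (default 5).
#' @return The synergy score.
#' @export
synergy_score <- function(cl, a, b, status, min_cluster_size = 5) {
  hs <- plugin_entropy(status)
  if (hs == 0) stop("status has a single class", call. = FALSE)
  cl <- pool_small_clusters(cl, min_cluster_size)
  (plugin_mi(cl, status) - plugin_mi(median_high(a), status) -
     plugin_mi(median_high(b), status)) / hs
}

#' Attribute a cluster structure to a control gene
#'
#' Each candidate is dichotomized at its median; its purity is
#' `I(cluster; candidate bin) / H(candidate bin)` — 1 when every cluster is
#' filled with a single up/down state of the candidate. The best candidate
#' is the purity argmax; attribution succeeds iff its purity reaches
#' `purity_threshold`.
#'
#' @param cl Cluster labels.
#' @param candidates Gene x sample numeric matrix of candidate control genes.
#' @param purity_threshold Minimum purity (default 0.5).
#' @param min_cluster_size Pooling threshold applied to `cl` (default 5).
#' @return List `gene`, `purity`, `attributed`.
#' @export
attribute_control_gene <- function(cl, candidates, purity_threshold = 0.5,
                                   min_cluster_size = 5) {
  stopifnot(is.matrix(candidates), nrow(candidates) >= 1)
  cl <- pool_small_clusters(cl, min_cluster_size)
  purity <- apply(candidates, 1, function(x) {
    if (stats::sd(x) == 0) return(0)
    b <- median_high(x)
    hb <- plugin_entropy(b)
    if (hb == 0) return(0)
    plugin_mi(cl, b) / hb
  })
  best <- which.max(purity)
  list(gene = rownames(candidates)[best], purity = unname(purity[best]),
       attributed = unname(purity[best]) >= purity_threshold)
}

#' Detect three-way gene interactions
#'
#' Ranks genes by conditional entropy with weight status, clusters every
#' pair among the top-ranked genes in its 2-D expression space, scores the
#' pair's synergy, and for pairs exceeding the synergy threshold attempts to
#' attribute the cluster structure to a third control gene among the
#' remaining top-ranked genes. Triples with a successful attribution are
#' returned sorted by synergy (descending).
#'
#' @param expr Gene x sample numeric matrix.
#' @param status Binary status per sample (e.g. the weight group).
#' @param params A [synergy_params()] object.
#' @return data.frame `gene_a, gene_b, control_gene, synergy, purity`; the
#'   per-triple cluster labels are attached as the `clusters` attribute
#'   (a list of integer vectors).
#' @export
find_three_way_interactions <- function(expr, status, params = synergy_params()) {
  stopifnot(inherits(params, "synergy_params"))
  top <- rank_genes_by_entropy(expr, status,
                               top_n = min(params$top_n, nrow(expr)),
                               sort = params$entropy_sort)
  sub <- expr[top, , drop = FALSE]
  bins <- t(apply(sub, 1, median_high))
  mi_single <- apply(bins, 1, function(b) plugin_mi(b, status))
  hs <- plugin_entropy(status)
  if (hs == 0) stop("status has a single class", call. = FALSE)

  res <- list(); clusters <- list()
  n_top <- length(top)
  for (i in seq_len(n_top - 1)) {
    for (j in (i + 1):n_top) {
      cl <- pair_cluster(sub[i, ], sub[j, ], params$tree_height)
      pooled <- pool_small_clusters(cl, params$min_cluster_size)
      syn <- (plugin_mi(pooled, status) - mi_single[i] - mi_single[j]) / hs
      if (syn <= params$synergy_threshold) next
      cand <- sub[setdiff(seq_len(n_top), c(i, j)), , drop = FALSE]
      att <- attribute_control_gene(cl, cand,
                                    purity_threshold = params$purity_threshold,
                                    min_cluster_size = params$min_cluster_size)
      if (!att$attributed) next
      res[[length(res) + 1]] <- data.frame(
        gene_a = top[i], gene_b = top[j], control_gene = att$gene,
        synergy = syn, purity = att$purity, stringsAsFactors = FALSE)
      clusters[[length(clusters) + 1]] <- cl
    }
  }
  if (length(res) == 0) {
    out <- data.frame(gene_a = character(0), gene_b = character(0),
                      control_gene = character(0), synergy = numeric(0),
                      purity = numeric(0), stringsAsFactors = FALSE)
    attr(out, "clusters") <- list()
    return(out)
  }
  out <- do.call(rbind, res)
  o <- order(-out$synergy, out$gene_a, out$gene_b)
  clusters <- clusters[o]
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "clusters") <- clusters
  out
}
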