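#' Unsigned soft-thresholded adjacency
#'
#' `a_ij = |cor(gene_i, gene_j)|^power` with unit diagonal (unsigned network).
#'
#' @param expr Gene x sample numeric matrix.
#' @param power Soft-thresholding power (integer >= 1).
#' @return Symmetric adjacency matrix in \[0, 1\].
#' @export
soft_adjacency <- function(expr, power = 6) {
  stop_if_not_matrix(expr)
  stopifnot(power >= 1)
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(expr)[sds == 0], 5), collapse = ", "),
         call. = FALSE)
  }
  a <- abs(stats::cor(t(expr)))^power
  diag(a) <- 1
  a
}

#' Signed scale-free topology fit index
#'
#' Bins the connectivity distribution into equal-width bins and regresses
#' `log10(p(k))` on `log10(mean k)`; the fit index is `-sign(slope) * R^2`,
#' so positive values indicate the inverse power-law decay expected of a
#' scale-free degree distribution. Degenerate input (all connectivities
#' equal) yields 0 with a warning.
#'
#' @param adjacency Symmetric adjacency matrix (used to compute `k_i =
#'   sum_{j != i} a_ij`), or NULL if `k` is given directly.
#' @param k Optional pre-computed connectivity vector.
#' @param n_bins Number of equal-width bins (default 10).
#' @return List with `sft_r2`, `slope` and `mean_connectivity`.
#' @export
scale_free_fit <- function(adjacency = NULL, k = NULL, n_bins = 10) {
  if (is.null(k)) {
    stopifnot(is.matrix(adjacency))
    if (nrow(adjacency) < 30) stop("need at least 30 genes", call. = FALSE)
    k <- colSums(adjacency) - diag(adjacency)
  }
  if (stats::sd(k) == 0) {
    warning("all connectivities equal; fit index set to 0")
    return(list(sft_r2 = 0, slope = NA_real_, mean_connectivity = mean(k)))
  }
  bins <- cut(k, breaks = n_bins, include.lowest = TRUE)
  k_mean <- as.numeric(tapply(k, bins, mean))
  p_k <- as.numeric(table(bins)) / length(k)
  ok <- !is.na(k_mean) & p_k > 0 & k_mean > 0
  if (sum(ok) < 3) {
    warning("degenerate binning; fit index set to 0")
    return(list(sft_r2 = 0, slope = NA_real_, mean_connectivity = mean(k)))
  }
  fit <- stats::lm(log10(p_k[ok]) ~ log10(k_mean[ok]))
  slope <- stats::coef(fit)[2]
  r2 <- summary(fit)$r.squared
  list(sft_r2 = unname(-sign(slope) * r2), slope = unname(slope),
       mean_connectivity = mean(k))
}

#' Scale-free fit profile over candidate soft powers
#'
#' @param expr Gene x sample numeric matrix.
#' @param powers Strictly increasing candidate powers.
#' @param n_bins Bins for [scale_free_fit()].
#' @return data.frame `power, sft_r2, slope, mean_connectivity`.
#' @export
soft_threshold_profile <- function(expr, powers = c(1:10, 12, 14, 16, 18, 20),
                                   n_bins = 10) {
  stopifnot(all(diff(powers) > 0))
  cc <- abs(stats::cor(t(expr)))
  rows <- lapply(powers, function(b) {
    a <- cc^b
    diag(a) <- 1
    sf <- scale_free_fit(a, n_bins = n_bins)
    data.frame(power = b, sft_r2 = sf$sft_r2, slope = sf$slope,
               mean_connectivity = sf$mean_connectivity)
  })
  do.call(rbind, rows)
}

#' Pick the soft power from a scale-free fit profile
#'
#' Returns the smallest power whose fit index reaches `r2_floor`; if none
#' does, the power with the maximal fit index is returned with a warning.
#'
#' @param profile data.frame from [soft_threshold_profile()].
#' @param r2_floor Fit-index floor (default 0.8).
#' @return A single power.
#' @export
pick_soft_power <- function(profile, r2_floor = 0.8) {
  stopifnot(nrow(profile) > 0)
  hit <- which(profile$sft_r2 >= r2_floor)
  if (length(hit) == 0) {
    warning("no power reaches the fit-index floor; returning the argmax")
    return(profile$power[which.max(profile$sft_r2)])
  }
  profile$power[hit[1]]
}

#' Topological overlap matrix (unsigned)
#'
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `L_ij = sum_{u != i,j} a_iu a_uj` and `k_i = sum_{u != i} a_iu`;
#' the diagonal is 1.
#'
#' @param adjacency Symmetric adjacency matrix with unit diagonal.
#' @return TOM matrix of the same dimensions.
#' @export
tom_similarity <- function(adjacency) {
  stopifnot(is.matrix(adjacency))
  if (!isSymmetric(unname(adjacency), tol = 1e-10)) {
    stop("adjacency must be symmetric", call. = FALSE)
  }
  a <- adjacency
  diag(a) <- 0
  L <- a %*% a                 # L_ij = sum_u a_iu a_uj (u != i,j since diag 0)
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (L + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect modules by hierarchical clustering of the TOM dissimilarity
#'
#' Average-linkage clustering on `1 - TOM`, cut by a simplified tree cut.
#' By default the tree is cut at the fixed dissimilarity 0.96: TOM
#' dissimilarities of unrelated genes concentrate just below 1, so branches
#' completing below the cut correspond to genuinely overlapping
#' neighbourhoods while unrelated genes stay out.
#' Clusters smaller than `min_size` are labelled `"unassigned"`; surviving
#' modules are named `"M1", "M2", ...` in decreasing size order.
#'
#' @param tom TOM matrix from [tom_similarity()].
#' @param min_size Minimum module size (default 10).
#' @param cut_method `"height"` (default, fixed absolute cut), `"gap"` (cut
#'   in the middle of the largest jump of the sorted merge heights, ignoring
#'   the lowest 5% of merges) or `"quantile"` (cut at a quantile of the merge
#'   heights).
#' @param cut_height Absolute dissimilarity cut for `cut_method = "height"`.
#' @param cut_quantile Height quantile for `cut_method = "quantile"`.
#' @return Named character vector: gene id -> module label.
#' @export
cluster_modules <- function(tom, min_size = 10,
                            cut_method = c("height", "gap", "quantile"),
                            cut_height = 0.96,
                            cut_quantile = 0.99) {
  cut_method <- match.arg(cut_method)
  stopifnot(is.matrix(tom), min_size >= 2)
  gene_ids <- rownames(tom)
  if (nrow(tom) < min_size) {
    return(stats::setNames(rep("unassigned", nrow(tom)), gene_ids))
  }
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  hc$height <- cummax(hc$height)  # guard against float-level inversions
  h <- sort(hc$height)
  m <- length(h)
  if (cut_method == "height") {
    cut_h <- cut_height
  } else if (cut_method == "gap") {
    lo <- max(1L, ceiling(0.05 * m))
    elig <- lo:max(lo, m - 1L)
    gaps <- h[elig + 1L] - h[elig]
    j <- elig[which.max(gaps)]
    cut_h <- (h[j] + h[j + 1L]) / 2
  } else {
    cut_h <- stats::quantile(h, cut_quantile)
  }
  cl <- stats::cutree(hc, h = cut_h)
  tab <- table(cl)
  cl[cl %in% as.integer(names(tab)[tab < min_size])] <- 0L
  keep <- sort(table(cl[cl != 0L]), decreasing = TRUE)
  labels <- stats::setNames(rep("unassigned", length(cl)), gene_ids)
  for (i in seq_along(keep)) {
    labels[cl == as.integer(names(keep)[i])] <- sprintf("M%d", i)
  }
  labels
}

#' Module eigengene
#'
#' First principal component of the standardized module submatrix across
#' samples, oriented so its correlation with the module's mean expression
#' profile is positive, and scaled to unit variance.
#'
#' @param expr Gene x sample numeric matrix.
#' @param genes Gene ids of the module (at least 2).
#' @return Named numeric vector of per-sample scores (variance 1).
#' @export
eigengene <- function(expr, genes) {
  stop_if_not_matrix(expr)
  genes <- intersect(genes, rownames(expr))
  if (length(genes) < 2) stop("module needs at least 2 genes", call. = FALSE)
  Z <- t(scale(t(expr[genes, , drop = FALSE])))
  sv <- svd(Z, nu = 0, nv = 1)
  e <- sv$v[, 1]
  if (stats::cor(e, colMeans(Z)) < 0) e <- -e
  e <- e / stats::sd(e)
  stats::setNames(e, colnames(expr))
}

#' Eigengenes for every module of an assignment
#'
#' @param expr Gene x sample numeric matrix.
#' @param assignment Named vector from [cluster_modules()].
#' @return Matrix modules x samples ("unassigned" is skipped).
#' @export
module_eigengenes <- function(expr, assignment) {
  mods <- setdiff(sort(unique(assignment)), "unassigned")
  if (length(mods) == 0) stop("no assigned modules", call. = FALSE)
  out <- t(vapply(mods, function(m) eigengene(expr, names(assignment)[assignment == m]),
                  numeric(ncol(expr))))
  rownames(out) <- mods
  out
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the closest pair of modules whose eigengene
#' dissimilarity `1 - r` falls below `cut_height`, recomputing eigengenes
#' after each merge, until no pair qualifies.
#'
#' @param expr Gene x sample numeric matrix.
#' @param assignment Named module vector.
#' @param cut_height Eigengene dissimilarity threshold in (0, 1), default 0.25.
#' @return Updated assignment (merged modules renamed `"M1", ...` by size).
#' @export
merge_modules <- function(expr, assignment, cut_height = 0.25) {
  stopifnot(cut_height > 0, cut_height < 1)
  repeat {
    mods <- setdiff(unique(assignment), "unassigned")
    if (length(mods) < 2) break
    me <- module_eigengenes(expr, assignment)
    cc <- stats::cor(t(me))
    diag(cc) <- -Inf
    best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (1 - max(cc) >= cut_height) break
    from <- rownames(me)[best[2]]; to <- rownames(me)[best[1]]
    assignment[assignment == from] <- to
  }
  # normalize labels by decreasing size
  mods <- setdiff(unique(assignment), "unassigned")
  sizes <- sort(table(assignment[assignment != "unassigned"]), decreasing = TRUE)
  relab <- stats::setNames(sprintf("M%d", seq_along(sizes)), names(sizes))
  out <- assignment
  out[assignment != "unassigned"] <- relab[assignment[assignment != "unassigned"]]
  out
}

#' Module-trait correlation matrix
#'
#' Pearson correlation and two-sided t-test p-value between each module
#' eigengene and each numeric trait; NA trait values are excluded pairwise.
#' Cells with fewer than 3 complete pairs are NA.
#'
#' @param eigengenes Modules x samples matrix from [module_eigengenes()].
#' @param samples Sample data.frame aligned with the eigengene columns.
#' @param traits Character vector of numeric trait columns (default: all
#'   numeric columns except identifiers).
#' @return List with matrices `r` and `p` (modules x traits).
#' @export
module_trait_cor <- function(eigengenes, samples,
                             traits = setdiff(names(samples)[vapply(samples, is.numeric, logical(1))],
                                              c("batch", "stratum"))) {
  stopifnot(is.matrix(eigengenes))
  r <- p <- matrix(NA_real_, nrow(eigengenes), length(traits),
                   dimnames = list(rownames(eigengenes), traits))
  for (m in seq_len(nrow(eigengenes))) {
    for (tr in seq_along(traits)) {
      x <- eigengenes[m, ]; y <- samples[[traits[tr]]]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 3 || stats::sd(y[ok]) == 0) next
      ct <- stats::cor.test(x[ok], y[ok])
      r[m, tr] <- unname(ct$estimate)
      p[m, tr] <- ct$p.value
    }
  }
  list(r = r, p = p)
}

#' Module membership and gene significance
#'
#' Module membership (MM) is the correlation of each gene's profile with each
#' module eigengene; gene significance (GS) is the absolute correlation of
#' the gene's profile with the trait.
#'
#' @param expr Gene x sample numeric matrix.
#' @param eigengenes Modules x samples matrix.
#' @param trait Numeric per-sample trait vector (NA excluded pairwise).
#' @return List with `mm` (genes x modules matrix) and `gs` (named vector).
#' @export
membership_and_significance <- function(expr, eigengenes, trait) {
  stop_if_not_matrix(expr)
  ok <- !is.na(trait)
  mm <- stats::cor(t(expr), t(eigengenes))
  gs <- abs(as.numeric(stats::cor(t(expr[, ok, drop = FALSE]), trait[ok])))
  list(mm = mm, gs = stats::setNames(gs, rownames(expr)))
}
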