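#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the common reference distribution given
#' by the row-wise mean of the column-sorted data. Ties within a column
#' receive the mean of the reference quantiles of their tied ranks, so the
#' operation is idempotent.
#'
#' @param expr Gene x sample numeric matrix with no missing values.
#' @return Matrix of the same dimensions, gene and sample order preserved.
#' @export
quantile_normalize <- function(expr) {
  stop_if_not_matrix(expr)
  if (ncol(expr) < 2) stop("need at least 2 samples", call. = FALSE)
  if (anyNA(expr)) {
    bad <- which(is.na(expr), arr.ind = TRUE)[1, ]
    stop(sprintf("NA value at gene %s, sample %s",
                 rownames(expr)[bad[1]], colnames(expr)[bad[2]]), call. = FALSE)
  }
  ref <- rowMeans(apply(expr, 2, sort))
  out <- expr
  for (j in seq_len(ncol(expr))) {
    o <- order(expr[, j])
    xs <- expr[o, j]
    tie_grp <- cumsum(c(TRUE, diff(xs) != 0))
    out[o, j] <- stats::ave(ref, tie_grp)
  }
  out
}

#' Empirical-Bayes batch adjustment (parametric location/scale)
#'
#' Removes additive and multiplicative batch effects by the parametric
#' empirical-Bayes procedure: genes are standardized against the batch-free
#' model, per-batch gene-wise means and variances are estimated, shrunk
#' toward a normal and an inverse-gamma prior respectively (hyperparameters
#' by method of moments, batch effects solved by the standard fixed-point
#' iteration), and the data are adjusted and de-standardized.
#'
#' With a single gene the moment estimators are undefined and the batch
#' effects are removed without shrinkage (direct per-batch standardization).
#'
#' @param expr Gene x sample numeric matrix.
#' @param batch Batch label per sample (coerced to factor).
#' @return Adjusted matrix, same dimensions and dimnames.
#' @export
adjust_batch <- function(expr, batch) {
  stop_if_not_matrix(expr)
  batch <- as.factor(batch)
  if (length(batch) != ncol(expr)) stop("one batch label per sample", call. = FALSE)
  if (nlevels(batch) < 2) stop("need at least 2 batches", call. = FALSE)
  nb <- table(batch)
  if (any(nb < 2)) {
    stop("batch with fewer than 2 samples: ",
         paste(names(nb)[nb < 2], collapse = ", "), call. = FALSE)
  }
  ng <- nrow(expr); ns <- ncol(expr)
  levs <- levels(batch)
  design <- stats::model.matrix(~ -1 + batch)

  # gene-wise batch-mean model; grand mean weights batches by size
  beta_hat <- t(solve(crossprod(design), crossprod(design, t(expr))))
  grand <- as.numeric(beta_hat %*% (nb / ns))
  resid <- expr - beta_hat %*% t(design)
  var_pooled <- rowSums(resid^2) / ns
  var_pooled <- pmax(var_pooled, .Machine$double.eps)
  Z <- (expr - grand) / sqrt(var_pooled)

  gamma_star <- delta2_star <- matrix(0, ng, length(levs))
  for (b in seq_along(levs)) {
    j <- batch == levs[b]
    gh <- rowMeans(Z[, j, drop = FALSE])
    d2 <- apply(Z[, j, drop = FALSE], 1, stats::var)
    d2 <- pmax(d2, .Machine$double.eps)
    if (ng == 1) {
      gamma_star[, b] <- gh
      delta2_star[, b] <- d2
      next
    }
    g_bar <- mean(gh); t2 <- stats::var(gh)
    m <- mean(d2); s2 <- stats::var(d2)
    a_prior <- (2 * s2 + m^2) / s2
    b_prior <- (m * s2 + m^3) / s2
    nj <- sum(j)
    ssq <- rowSums((Z[, j, drop = FALSE] - gh)^2)
    g_new <- gh; d_new <- d2
    for (it in 1:200) {
      g_old <- g_new; d_old <- d_new
      g_new <- (t2 * nj * gh + d_new * g_bar) / (t2 * nj + d_new)
      sum2 <- ssq + nj * (gh - g_new)^2
      d_new <- (0.5 * sum2 + b_prior) / (nj / 2 + a_prior - 1)
      change <- max(abs(g_new - g_old) / abs(g_old + 1e-12),
                    abs(d_new - d_old) / abs(d_old + 1e-12))
      if (change < 1e-8) break
    }
    gamma_star[, b] <- g_new
    delta2_star[, b] <- d_new
  }

  out <- Z
  for (b in seq_along(levs)) {
    j <- batch == levs[b]
    out[, j] <- (Z[, j, drop = FALSE] - gamma_star[, b]) / sqrt(delta2_star[, b])
  }
  out <- out * sqrt(var_pooled) + grand
  dimnames(out) <- dimnames(expr)
  out
}

#' Flag outlier samples by standardized sample connectivity
#'
#' Scores each sample by its summed correlation with all other samples,
#' z-scores the result, and flags samples scoring below `-z_cut`.
#'
#' @param expr Gene x sample numeric matrix (at least 4 samples).
#' @param z_cut Positive threshold on the standardized connectivity score.
#' @return Character vector of flagged sample ids (possibly empty).
#' @export
detect_outlier_samples <- function(expr, z_cut = 2.5) {
  stop_if_not_matrix(expr)
  if (ncol(expr) < 4) stop("need at least 4 samples", call. = FALSE)
  cc <- stats::cor(expr)
  score <- rowSums(cc) - 1   # drop self-correlation
  z <- (score - mean(score)) / stats::sd(score)
  colnames(expr)[z < -z_cut]
}

#' Keep the top fraction of genes by mean expression
#'
#' Genes are ranked by mean expression (descending, ties broken by gene id)
#' and the top `round(fraction * n_genes)` are kept, rounding half away from
#' zero. The returned matrix preserves the original gene order.
#'
#' @param expr Gene x sample numeric matrix.
#' @param fraction Fraction of genes to keep, in (0, 1].
#' @return Sub-matrix with the selected genes.
#' @export
select_expressed <- function(expr, fraction = 0.35) {
  stop_if_not_matrix(expr)
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1) {
    stop("`fraction` must be a single value in (0, 1]", call. = FALSE)
  }
  n_keep <- round_half_up(fraction * nrow(expr))
  means <- rowMeans(expr)
  ord <- order(-means, rownames(expr))
  keep <- sort(ord[seq_len(n_keep)])
  expr[keep, , drop = FALSE]
}

#' Assign weight groups by the stratum-median BMI rule
#'
#' Within each stratum the median BMI is the cutoff: samples strictly above
#' it are "overweight", all others (including samples exactly at the median)
#' are "normal". Samples with missing BMI are labelled "unset" with a
#' warning.
#'
#' @param samples Sample data.frame with `bmi` and `stratum` columns.
#' @return The data.frame with a `group` column added (or replaced).
#' @export
assign_weight_groups <- function(samples) {
  if (!all(c("bmi", "stratum") %in% names(samples))) {
    stop("`samples` must have `bmi` and `stratum` columns", call. = FALSE)
  }
  group <- rep("unset", nrow(samples))
  if (anyNA(samples$bmi)) {
    warning(sum(is.na(samples$bmi)), " sample(s) with missing BMI left unset")
  }
  for (s in unique(samples$stratum)) {
    i <- which(samples$stratum == s & !is.na(samples$bmi))
    med <- stats::median(samples$bmi[i])
    group[i] <- ifelse(samples$bmi[i] > med, "overweight", "normal")
  }
  samples$group <- group
  samples
}

#' Principal-component vs covariate association diagnostics
#'
#' Computes a PCA over samples (genes standardized) and, for each of the
#' leading components, the F-test p-value of a linear model of the component
#' scores on each covariate (categorical covariates as factors). Constant
#' covariates get p = 1 with a warning.
#'
#' @param expr Gene x sample numeric matrix.
#' @param samples Sample data.frame aligned with `colnames(expr)`.
#' @param n_pcs Number of leading components to report.
#' @param covariates Character vector of column names of `samples` to test.
#' @return data.frame with columns `pc`, `var_frac`, `covariate`, `p`.
#' @export
pc_covariate_association <- function(expr, samples,
                                     n_pcs = 3,
                                     covariates = intersect(
                                       c("sex", "stratum", "age", "batch", "group"),
                                       names(samples))) {
  stop_if_not_matrix(expr)
  if (n_pcs >= ncol(expr)) stop("`n_pcs` must be below the sample count", call. = FALSE)
  keep <- apply(expr, 1, stats::sd) > 0
  Z <- t(scale(t(expr[keep, , drop = FALSE])))
  sv <- svd(Z, nu = 0, nv = n_pcs)
  var_frac <- sv$d^2 / sum(sv$d^2)
  scores <- sv$v %*% diag(sv$d[seq_len(n_pcs)], n_pcs)

  res <- list()
  for (i in seq_len(n_pcs)) {
    for (cv in covariates) {
      v <- samples[[cv]]
      x <- if (is.numeric(v)) v else factor(v)
      ok <- !is.na(x)
      if (length(unique(x[ok])) < 2) {
        warning("covariate `", cv, "` is constant; p set to 1")
        p <- 1
      } else {
        fit <- stats::lm(scores[ok, i] ~ x[ok])
        an <- stats::anova(fit)
        p <- an$`Pr(>F)`[1]
      }
      res[[length(res) + 1]] <- data.frame(pc = i, var_frac = var_frac[i],
                                           covariate = cv, p = p,
                                           stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}
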