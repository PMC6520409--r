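#' Moderated two-group t-test with empirical-Bayes variance shrinkage
#'
#' Per gene, the difference of group means (second factor level minus first)
#' is tested with a t-statistic whose residual variance is shrunk toward a
#' common prior. The prior degrees of freedom `d0` and prior variance `s0^2`
#' are fitted by matching moments of the log sample variances: with
#' `e_g = log(s_g^2) - digamma(d/2) + log(d/2)`, the excess spread
#' `var(e) - trigamma(d/2)` identifies `trigamma(d0/2)` and the mean of `e`
#' identifies `log(s0^2)`. The posterior variance is
#' `(d0 s0^2 + d s_g^2) / (d0 + d)` and p-values use `d0 + d` degrees of
#' freedom.
#'
#' @param expr Gene x sample numeric matrix.
#' @param groups Two-level grouping (coerced to factor), one label per sample.
#' @param prior_df Optional fixed prior degrees of freedom `d0`. `NULL`
#'   (default) estimates it from the data; `0` gives the ordinary pooled
#'   two-sample t-test; `Inf` fixes every gene's variance at `s0^2`.
#' @return data.frame with columns `gene_id`, `log_fold_change`, `avg_expr`,
#'   `t`, `p`, plus attributes `d0`, `s0_sq` and `df_total`.
#' @export
moderated_t_test <- function(expr, groups, prior_df = NULL) {
  stop_if_not_matrix(expr)
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("`groups` must have exactly two levels", call. = FALSE)
  n1 <- sum(groups == levels(groups)[1]); n2 <- sum(groups == levels(groups)[2])
  if (min(n1, n2) < 2) stop("each group needs at least 2 samples", call. = FALSE)

  i1 <- groups == levels(groups)[1]; i2 <- groups == levels(groups)[2]
  m1 <- rowMeans(expr[, i1, drop = FALSE]); m2 <- rowMeans(expr[, i2, drop = FALSE])
  lfc <- m2 - m1
  d <- n1 + n2 - 2
  ss <- rowSums((expr[, i1, drop = FALSE] - m1)^2) +
    rowSums((expr[, i2, drop = FALSE] - m2)^2)
  s2 <- ss / d
  if (any(s2 < .Machine$double.eps)) {
    warning(sum(s2 < .Machine$double.eps), " zero-variance gene(s); variance floored")
    s2 <- pmax(s2, .Machine$double.eps)
  }

  if (is.null(prior_df)) {
    e <- log(s2) - digamma(d / 2) + log(d / 2)
    excess <- mean(e^2) * length(e) / (length(e) - 1) -
      mean(e)^2 * length(e) / (length(e) - 1)  # var(e)
    excess <- excess - trigamma(d / 2)
    if (is.na(excess) || excess <= 0) {
      d0 <- Inf
      s0_sq <- exp(mean(e))
    } else {
      d0 <- 2 * trigamma_inverse(excess)
      s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    }
  } else {
    stopifnot(prior_df >= 0)
    d0 <- prior_df
    e <- log(s2) - digamma(d / 2) + log(d / 2)
    s0_sq <- exp(mean(e))
  }

  if (is.infinite(d0)) {
    s2_post <- rep(s0_sq, length(s2))
    df_total <- Inf
  } else if (d0 == 0) {
    s2_post <- s2
    df_total <- d
  } else {
    s2_post <- (d0 * s0_sq + d * s2) / (d0 + d)
    df_total <- d0 + d
  }

  tstat <- lfc / sqrt(s2_post * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tstat), df = df_total)

  out <- data.frame(gene_id = rownames(expr), log_fold_change = lfc,
                    avg_expr = rowMeans(expr), t = tstat, p = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  attr(out, "df_total") <- df_total
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values (monotone in rank, capped at 1).
#' @export
bh_adjust <- function(p) {
  check_probability(p)
  stats::p.adjust(p, method = "BH")
}

#' Estimate the proportion of true nulls (pi0)
#'
#' Fixed-lambda estimator `pi0(lambda) = #{p > lambda} / (m (1 - lambda))`,
#' capped at 1. With a grid of lambdas a cubic smoothing spline is fitted to
#' `pi0(lambda)` and evaluated at the largest lambda (the q-value software's
#' smoother method).
#'
#' @param p Numeric vector of p-values.
#' @param lambda Single tuning value in (0, 1), or a grid of at least 4
#'   values. Default is the grid 0.05, 0.10, ..., 0.95.
#' @return List of class `pi0_estimate` with elements `pi0`, `lambda`,
#'   `pi0_lambda` (the raw per-lambda estimates) and `method`.
#' @export
estimate_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  check_probability(p)
  if (any(lambda <= 0) || any(lambda >= 1)) {
    stop("`lambda` must lie in (0, 1)", call. = FALSE)
  }
  m <- length(p)
  pi0_lambda <- vapply(lambda, function(l) sum(p > l) / (m * (1 - l)), numeric(1))
  if (length(lambda) == 1) {
    pi0 <- min(pi0_lambda, 1)
    method <- "fixed-lambda"
  } else {
    if (length(lambda) < 4) stop("grid mode needs at least 4 lambdas", call. = FALSE)
    fit <- stats::smooth.spline(lambda, pi0_lambda, df = 3)
    pi0 <- min(max(stats::predict(fit, x = max(lambda))$y, 0), 1)
    method <- "smoother"
  }
  structure(list(pi0 = pi0, lambda = lambda, pi0_lambda = pi0_lambda,
                 method = method), class = "pi0_estimate")
}

#' Estimated number of non-null genes
#'
#' `floor(m * (1 - pi0))`: the expected count of genes violating the null
#' given the estimated true-null proportion.
#'
#' @param m Total number of tests.
#' @param pi0 Estimated proportion of true nulls, in \[0, 1\].
#' @return Integer count.
#' @export
estimate_nonnull_count <- function(m, pi0) {
  stopifnot(m > 0, pi0 >= 0, pi0 <= 1)
  as.integer(floor(m * (1 - pi0)))
}

#' q-values from p-values and pi0
#'
#' `q_i = min over p_j >= p_i of (pi0 * m * p_j / rank_j)`, capped at 1.
#' With `pi0 = 1` this reduces to the Benjamini-Hochberg adjusted values.
#'
#' @param p Numeric vector of p-values.
#' @param pi0 True-null proportion used to scale the estimate.
#' @return q-values in the original order.
#' @export
q_values <- function(p, pi0 = 1) {
  check_probability(p)
  stopifnot(pi0 >= 0, pi0 <= 1)
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(pi0 * m * p[o] / rank(p, ties.method = "max")[o]))
  q[order(o)]
}

#' Full differential-expression table
#'
#' Runs [moderated_t_test()], then adds BH-adjusted p-values, the smoother
#' pi0 estimate, q-values, and a significance flag at the given FDR cutoff.
#' Rows are sorted by p-value.
#'
#' @param expr Gene x sample numeric matrix.
#' @param groups Two-level grouping per sample.
#' @param fdr FDR cutoff for the `significant` flag (default 0.1).
#' @return data.frame `gene_id, log_fold_change, avg_expr, t, p, p_adj_bh, q,
#'   significant` with attributes `pi0` and `estimated_nonnull`.
#' @export
differential_expression <- function(expr, groups, fdr = 0.1) {
  de <- moderated_t_test(expr, groups)
  de$p_adj_bh <- bh_adjust(de$p)
  pi0 <- estimate_pi0(de$p)
  de$q <- q_values(de$p, pi0 = pi0$pi0)
  de$significant <- de$p_adj_bh < fdr
  de <- de[order(de$p, de$gene_id), , drop = FALSE]
  rownames(de) <- NULL
  attr(de, "pi0") <- pi0$pi0
  attr(de, "estimated_nonnull") <- estimate_nonnull_count(nrow(de), pi0$pi0)
  de
}
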