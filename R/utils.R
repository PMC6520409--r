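# Shared input checks and small numeric helpers.

# round-half-away-from-zero; base round() uses banker's rounding
round_half_up <- function(x) {
  trunc(x + sign(x) * 0.5)
}

stop_if_not_matrix <- function(expr, arg = "expr") {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop(sprintf("`%s` must be a numeric genes x samples matrix", arg), call. = FALSE)
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop(sprintf("`%s` must carry gene ids (rownames) and sample ids (colnames)", arg),
         call. = FALSE)
  }
  if (anyDuplicated(rownames(expr))) stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(colnames(expr))) stop("duplicate sample ids", call. = FALSE)
  invisible(expr)
}

check_probability <- function(p, arg = "p") {
  if (length(p) == 0) stop(sprintf("`%s` is empty", arg), call. = FALSE)
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop(sprintf("`%s` must lie in [0, 1]", arg), call. = FALSE)
  }
  invisible(p)
}

# Shannon entropy (bits) of a label vector, plug-in estimate
plugin_entropy <- function(x) {
  p <- tabulate(as.integer(factor(x)))
  p <- p[p > 0] / length(x)
  -sum(p * log2(p))
}

# plug-in mutual information (bits) between two label vectors
plugin_mi <- function(x, y) {
  plugin_entropy(x) + plugin_entropy(y) - plugin_entropy(paste(x, y, sep = "\r"))
}

# dichotomize a numeric vector at its median: TRUE = above
median_high <- function(v) v > stats::median(v)

# Newton solve of trigamma(y) = x, following the standard variance-shrinkage
# recursion; x > 0
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}
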