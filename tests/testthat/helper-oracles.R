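# Independent brute-force oracles used to validate the fast implementations.

# TOM by explicit triple loop
brute_tom <- function(a) {
  n <- nrow(a)
  out <- matrix(1, n, n, dimnames = dimnames(a))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    out[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  out
}

# BH rejection set straight from the step-up definition:
# reject the genes with the k smallest p-values, k = max{k : p_(k) <= k*alpha/m}
brute_bh_reject <- function(p, alpha) {
  m <- length(p)
  ps <- sort(p)
  ks <- which(ps <= seq_len(m) * alpha / m)
  if (length(ks) == 0) return(rep(FALSE, m))
  p <= ps[max(ks)]
}

# hypergeometric upper tail by exhaustive enumeration of all draws
brute_hyper <- function(overlap, query_size, set_size, background_size) {
  draws <- utils::combn(background_size, query_size)
  hits <- colSums(draws <= set_size)  # the first set_size elements are "the set"
  mean(hits >= overlap)
}

# entropies straight from the joint probability table
brute_entropy <- function(x) {
  p <- as.numeric(table(x)) / length(x)
  -sum(p * log2(p))
}
brute_mi <- function(x, y) {
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  }
  unname(s)
}

# random named expression matrix
rmat <- function(ng, ns, seed = 1, sd = 1) {
  withr::with_seed(seed, {
    matrix(stats::rnorm(ng * ns, sd = sd), ng, ns,
           dimnames = list(sprintf("g%04d", seq_len(ng)),
                           sprintf("s%03d", seq_len(ns))))
  })
}
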