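# The standard validation cohort is expensive enough to build once per run.
.fixture_cache <- new.env(parent = emptyenv())

standard_cohort <- function() {
  if (is.null(.fixture_cache$cohort)) {
    .fixture_cache$cohort <- generate_cohort(sim_config())
  }
  .fixture_cache$cohort
}

standard_expressed <- function() {
  if (is.null(.fixture_cache$expressed)) {
    .fixture_cache$expressed <- select_expressed(standard_cohort()$expr, 0.35)
  }
  .fixture_cache$expressed
}

standard_tom <- function() {
  if (is.null(.fixture_cache$tom)) {
    .fixture_cache$tom <- tom_similarity(soft_adjacency(standard_expressed(), 6))
  }
  .fixture_cache$tom
}

standard_samples <- function() {
  ch <- standard_cohort()
  data.frame(sample_id = colnames(ch$expr),
             group = unname(ch$truth$group[colnames(ch$expr)]),
             bmi = unname(ch$truth$bmi[colnames(ch$expr)]),
             stringsAsFactors = FALSE)
}

# adjusted Rand index between two label vectors (closed form on the
# contingency table); avoids an extra test dependency
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}
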