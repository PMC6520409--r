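test_that("quantile normalization forces the reference distribution", {
  m <- matrix(c(2, 4, 6, 5, 1, 3), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  out <- quantile_normalize(m)
  # sort-and-average by hand: ref = (1.5, 3.5, 5.5), applied in rank order
  expect_equal(unname(out[, 1]), c(1.5, 3.5, 5.5))
  expect_equal(unname(out[, 2]), c(5.5, 1.5, 3.5))
  expect_equal(unname(diff(colMeans(out))), 0)

  # identical columns are a fixed point
  m2 <- cbind(s1 = c(1, 5, 2), s2 = c(1, 5, 2))
  rownames(m2) <- paste0("g", 1:3)
  expect_equal(quantile_normalize(m2), m2)

  # idempotence on tie-free data
  m3 <- rmat(50, 6, seed = 2)
  q1 <- quantile_normalize(m3)
  expect_equal(quantile_normalize(q1), q1, tolerance = 1e-10)
  expect_true(all(abs(colMeans(q1) - mean(q1)) < 1e-12))

  # ties within a column share the mean of their reference quantiles
  m4 <- cbind(s1 = c(1, 1, 5), s2 = c(2, 4, 6))
  rownames(m4) <- paste0("g", 1:3)
  q4 <- quantile_normalize(m4)
  ref <- rowMeans(apply(m4, 2, sort))   # (1.5, 2.5, 5.5)
  expect_equal(unname(q4[, 1]),
               unname(c(mean(ref[1:2]), mean(ref[1:2]), ref[3])))
})

test_that("quantile normalization rejects missing values by location", {
  m <- rmat(5, 3)
  m[2, 3] <- NA
  expect_error(quantile_normalize(m), "g0002.*s003")
})

test_that("batch adjustment removes location/scale batch effects", {
  # single gene, two batches shifted apart: means must realign
  withr::with_seed(10, {
    x <- matrix(c(rnorm(100, 5), rnorm(100, -5)), 1, 200,
                dimnames = list("g1", sprintf("s%03d", 1:200)))
  })
  batch <- rep(c("A", "B"), each = 100)
  adj <- adjust_batch(x, batch)
  expect_lt(abs(mean(adj[1, batch == "A"]) - mean(adj[1, batch == "B"])), 0.2)
  expect_identical(dim(adj), dim(x))
  expect_identical(dimnames(adj), dimnames(x))

  # statistically identical batches: output stays close to input
  m <- rmat(100, 40, seed = 3)
  adj2 <- adjust_batch(m, rep(1:2, each = 20))
  expect_lt(max(abs(adj2 - m)), 0.5 * stats::sd(m))

  # batch F-statistic decreases for >= 95% of genes on a shifted simulation
  m3 <- rmat(200, 60, seed = 7)
  b <- rep(1:2, each = 30)
  withr::with_seed(8, m3 <- m3 + outer(rnorm(200, 0, 1), ifelse(b == 2, 1, -1)))
  adj3 <- adjust_batch(m3, b)
  fstat <- function(mm) apply(mm, 1, function(v) summary(lm(v ~ factor(b)))$fstatistic[1])
  expect_gte(mean(fstat(adj3) < fstat(m3)), 0.95)

  expect_error(adjust_batch(rmat(5, 5), c(1, 1, 1, 1, 2)), "fewer than 2")
})

test_that("batch adjustment matches the reference empirical-Bayes implementation", {
  skip_if_not_installed("sva")
  m <- rmat(250, 30, seed = 12)
  b <- rep(1:3, each = 10)
  m[, b == 2] <- m[, b == 2] * 1.4 + 0.8
  mine <- adjust_batch(m, b)
  ref <- suppressMessages(sva::ComBat(m, batch = b))
  expect_equal(mine, ref, tolerance = 1e-4)
})

test_that("outlier samples are flagged by standardized connectivity", {
  # 50 samples sharing a common signal, one replaced by independent noise
  withr::with_seed(5, {
    sig <- rnorm(400)
    m <- sapply(1:50, function(i) sig + rnorm(400, 0, 0.6))
    m[, 50] <- rnorm(400)
  })
  dimnames(m) <- list(sprintf("g%03d", 1:400), sprintf("s%02d", 1:50))
  expect_identical(detect_outlier_samples(m), "s50")
  expect_length(detect_outlier_samples(m, z_cut = Inf), 0)

  # homogeneous cohorts usually flag nothing
  flags <- withr::with_seed(6, vapply(1:20, function(s) {
    base <- rnorm(300)
    mm <- sapply(1:16, function(i) base + rnorm(300, 0, 0.6))
    dimnames(mm) <- list(sprintf("g%03d", 1:300), sprintf("s%02d", 1:16))
    length(detect_outlier_samples(mm))
  }, integer(1)))
  expect_gte(mean(flags == 0), 0.9)
})

test_that("expressed-gene selection keeps round(fraction * n) top-mean genes", {
  big <- matrix(0, 13276, 2, dimnames = list(sprintf("g%05d", 1:13276), c("a", "b")))
  expect_equal(nrow(select_expressed(big + rnorm(2 * 13276), 0.35)), 4647)

  m <- matrix(rep(1:10, 2), 10, 2, dimnames = list(sprintf("g%02d", 1:10), c("a", "b")))
  kept <- select_expressed(m, 0.3)
  expect_setequal(rownames(kept), c("g08", "g09", "g10"))
  expect_identical(select_expressed(m, 1), m)
  # round-half-away-from-zero: 10 * 0.25 = 2.5 -> 3 genes
  expect_equal(nrow(select_expressed(m, 0.25)), 3)
  expect_error(select_expressed(m, 0), "fraction")
  expect_error(select_expressed(m, 1.2), "fraction")

  # exact size for random fractions
  for (f in c(0.1, 0.33, 0.5, 0.77)) {
    expect_equal(nrow(select_expressed(rmat(57, 4, seed = 1), f)),
                 floor(f * 57 + 0.5))
  }
})

test_that("weight groups follow the strict stratum-median rule", {
  s1 <- data.frame(sample_id = 1:3, stratum = 1, bmi = c(20, 25, 30))
  expect_equal(assign_weight_groups(s1)$group, c("normal", "normal", "overweight"))

  s2 <- data.frame(sample_id = 1:6, stratum = rep(1:2, each = 3),
                   bmi = c(20, 24, 28, 26, 29, 32))
  g2 <- assign_weight_groups(s2)$group
  expect_equal(g2[s2$stratum == 1], c("normal", "normal", "overweight"))
  expect_equal(g2[s2$stratum == 2], c("normal", "normal", "overweight"))
  # a BMI of 26 is overweight in stratum 1 (median 24) but normal in stratum 2 (median 29)
  s3 <- rbind(s2, data.frame(sample_id = 7, stratum = 1, bmi = 26),
              data.frame(sample_id = 8, stratum = 2, bmi = 26))
  g3 <- assign_weight_groups(s3)$group
  expect_equal(g3[7], "overweight")
  expect_equal(g3[8], "normal")

  # ties: everyone at the median is normal
  s4 <- data.frame(sample_id = 1:4, stratum = 1, bmi = rep(25, 4))
  expect_true(all(assign_weight_groups(s4)$group == "normal"))

  # strictness bounds the overweight count by floor(n/2) per stratum
  for (seed in 1:5) {
    n <- 21
    s5 <- withr::with_seed(seed, data.frame(sample_id = 1:n, stratum = 1,
                                            bmi = rnorm(n, 26, 4)))
    expect_lte(sum(assign_weight_groups(s5)$group == "overweight"), floor(n / 2))
  }

  s6 <- data.frame(sample_id = 1:3, stratum = 1, bmi = c(20, NA, 30))
  expect_warning(g6 <- assign_weight_groups(s6)$group, "missing BMI")
  expect_equal(g6[2], "unset")
})

test_that("PC-covariate diagnostics detect association and report variance", {
  m <- rmat(200, 40, seed = 9)
  sam <- data.frame(sample_id = colnames(m))
  z <- t(scale(t(m)))
  sv <- svd(z, nu = 0, nv = 1)
  sam$pc1_near <- sv$v[, 1] + withr::with_seed(4, rnorm(40, 0, 0.01))
  sam$noise <- withr::with_seed(1, rnorm(40))
  sam$const <- 1
  rep <- suppressWarnings(pc_covariate_association(m, sam, n_pcs = 3,
                                                   covariates = c("pc1_near", "noise", "const")))
  expect_warning(pc_covariate_association(m, sam, n_pcs = 1, covariates = "const"),
                 "constant")
  expect_lt(rep$p[rep$pc == 1 & rep$covariate == "pc1_near"], 1e-12)
  expect_equal(rep$p[rep$covariate == "const"], rep(1, 3))
  vf <- unique(rep[, c("pc", "var_frac")])$var_frac
  expect_true(all(diff(vf) <= 0))
  expect_lte(sum(vf), 1)
})
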