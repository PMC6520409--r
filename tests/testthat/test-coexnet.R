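test_that("soft adjacency is |r|^power with unit diagonal", {
  # binary construction with phi coefficient exactly 0.5
  m <- rbind(g1 = c(1, 1, 1, 1, 0, 0, 0, 0),
             g2 = c(1, 1, 1, 0, 1, 0, 0, 0))
  colnames(m) <- paste0("s", 1:8)
  a <- soft_adjacency(m, power = 6)
  expect_equal(a["g1", "g2"], 0.5^6, tolerance = 1e-12)

  # perfectly (anti)correlated pairs hit 1 at any power
  m2 <- rbind(g1 = c(1, 2, 3, 4), g2 = c(4, 3, 2, 1))
  colnames(m2) <- paste0("s", 1:4)
  expect_equal(unname(soft_adjacency(m2, 3)["g1", "g2"]), 1)

  m3 <- rmat(20, 15, seed = 1)
  a3 <- soft_adjacency(m3, 6)
  expect_true(isSymmetric(a3))
  expect_true(all(a3 >= 0 & a3 <= 1))

  m4 <- rmat(4, 6, seed = 2); m4["g0002", ] <- 5
  expect_error(soft_adjacency(m4, 6), "g0002")
})

test_that("the scale-free fit index separates power laws from flat degree distributions", {
  # connectivities sampled along a k^-2 density: bin counts decay as a power
  # of the bin centre, so the log-log regression is essentially exact
  k <- 1 / seq(0.01, 0.1, length.out = 1000)
  sf <- scale_free_fit(k = k)
  expect_gt(sf$sft_r2, 0.95)
  expect_lt(sf$slope, 0)

  expect_warning(sf0 <- scale_free_fit(k = rep(3, 100)), "equal")
  expect_equal(sf0$sft_r2, 0)

  # random-graph-like connectivities score far worse than the power law
  k_flat <- withr::with_seed(3, runif(1000, 50, 60))
  expect_lt(scale_free_fit(k = k_flat)$sft_r2, 0.5)
  expect_lt(scale_free_fit(k = k_flat)$sft_r2, sf$sft_r2)
})

test_that("soft power selection honours the fit-index floor", {
  prof <- data.frame(power = c(2, 4, 6, 8), sft_r2 = c(0.2, 0.5, 0.85, 0.9))
  expect_equal(pick_soft_power(prof, 0.8), 6)
  expect_equal(pick_soft_power(prof, 0), 2)
  expect_warning(pw <- pick_soft_power(prof, 0.95), "argmax")
  expect_equal(pw, 8)
})

test_that("TOM matches hand examples and the brute-force oracle", {
  # 3 genes fully connected
  a1 <- matrix(1, 3, 3, dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  expect_equal(unname(tom_similarity(a1)[1, 2]), 1)

  # a_12 = 0, a_13 = a_23 = 1 -> TOM_12 = (1 + 0)/(1 + 1 - 0) = 0.5
  a2 <- matrix(c(1, 0, 1, 0, 1, 1, 1, 1, 1), 3, 3,
               dimnames = dimnames(a1))
  expect_equal(unname(tom_similarity(a2)[1, 2]), 0.5)

  # random instances against the triple loop
  for (seed in 1:3) {
    cc <- abs(cor(t(rmat(15, 10, seed = seed))))^4
    diag(cc) <- 1
    expect_equal(tom_similarity(cc), brute_tom(cc), tolerance = 1e-12)
  }

  # no off-diagonal adjacency -> identity-like TOM
  a3 <- diag(4); dimnames(a3) <- list(paste0("g", 1:4), paste0("g", 1:4))
  expect_equal(unname(tom_similarity(a3)), diag(4))

  a_bad <- matrix(c(1, 0.5, 0.2, 1), 2, 2,
                  dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(tom_similarity(a_bad), "symmetric")
})

test_that("module detection separates planted blocks and tolerates no structure", {
  # two perfect blocks of 20
  tom <- matrix(0.02, 40, 40)
  tom[1:20, 1:20] <- 0.95; tom[21:40, 21:40] <- 0.95
  diag(tom) <- 1
  dimnames(tom) <- list(sprintf("g%02d", 1:40), sprintf("g%02d", 1:40))
  mods <- cluster_modules(tom, min_size = 10)
  expect_length(setdiff(unique(mods), "unassigned"), 2)
  expect_false(any(mods == "unassigned"))
  expect_length(unique(mods[1:20]), 1)
  expect_length(unique(mods[21:40]), 1)

  # structureless TOM: one module or everything unassigned, never fake splits
  tom2 <- matrix(0.3, 30, 30); diag(tom2) <- 1
  dimnames(tom2) <- list(sprintf("g%02d", 1:30), sprintf("g%02d", 1:30))
  mods2 <- cluster_modules(tom2, min_size = 10)
  expect_lte(length(setdiff(unique(mods2), "unassigned")), 1)

  # fewer genes than min_size: all unassigned
  expect_true(all(cluster_modules(tom2[1:5, 1:5], min_size = 10) == "unassigned"))
})

test_that("eigengenes are unit-variance, oriented first principal components", {
  # rank-1 module: eigengene reproduces the shared profile
  prof <- sin(seq_len(30))
  m <- t(sapply(1:5, function(i) 2 * prof + i))
  dimnames(m) <- list(paste0("g", 1:5), paste0("s", 1:30))
  e <- eigengene(m, rownames(m))
  expect_equal(abs(cor(e, prof)), 1, tolerance = 1e-10)
  expect_gt(cor(e, prof), 0)  # oriented with the mean profile
  expect_equal(stats::var(e), 1, tolerance = 1e-9)

  # flipping every gene flips the eigengene orientation with it
  e2 <- eigengene(-m, rownames(m))
  expect_gt(cor(e2, -prof), 0)
  expect_error(eigengene(m, "g1"), "at least 2")
})

test_that("module merging respects the eigengene dissimilarity cut", {
  withr::with_seed(11, {
    n <- 150
    f1 <- rnorm(n)
    f_sim <- 0.92 * f1 + sqrt(1 - 0.92^2) * rnorm(n)   # eigengene r ~ 0.92
    f_far <- 0.45 * f1 + sqrt(1 - 0.45^2) * rnorm(n)   # eigengene r ~ 0.45
    mk <- function(f, k) t(sapply(1:k, function(i) 0.97 * f + 0.1 * rnorm(n)))
    m <- rbind(mk(f1, 12), mk(f_sim, 12), mk(f_far, 12))
  })
  dimnames(m) <- list(sprintf("g%02d", 1:36), sprintf("s%03d", 1:150))
  assign <- setNames(rep(c("M1", "M2", "M3"), each = 12), rownames(m))

  merged <- merge_modules(m, assign, cut_height = 0.25)
  expect_length(unique(merged[1:24]), 1)          # the r ~ 0.92 pair merged
  expect_length(setdiff(unique(merged), "unassigned"), 2)  # the r ~ 0.45 one did not

  none <- merge_modules(m, assign, cut_height = 1e-6)
  expect_length(setdiff(unique(none), "unassigned"), 3)
})

test_that("module-trait statistics recover a perfect and a null association", {
  me <- rbind(M1 = sin(seq_len(40)))
  colnames(me) <- paste0("s", 1:40)
  sam <- data.frame(sample_id = colnames(me), trait = sin(seq_len(40)),
                    noise = withr::with_seed(2, rnorm(40)))
  mt <- module_trait_cor(me, sam, traits = c("trait", "noise"))
  expect_equal(unname(mt$r["M1", "trait"]), 1, tolerance = 1e-10)
  expect_lt(mt$p["M1", "trait"], 1e-20)
  expect_gt(mt$p["M1", "noise"], 1e-4)

  # fewer than 3 complete pairs -> NA
  sam$sparse <- c(1, 2, rep(NA, 38))
  mt2 <- module_trait_cor(me, sam, traits = "sparse")
  expect_true(is.na(mt2$r["M1", "sparse"]))
})

test_that("membership tracks significance inside the planted BMI module", {
  ch <- standard_cohort()
  expressed <- standard_expressed()
  modules <- cluster_modules(standard_tom(), min_size = 10)
  me <- module_eigengenes(expressed, modules)
  sam <- standard_samples()
  ms <- membership_and_significance(expressed, me, sam$bmi)

  planted <- intersect(names(ch$truth$module_of_gene)[ch$truth$module_of_gene == "M1"],
                       rownames(expressed))
  found <- names(which.max(table(modules[planted])))
  genes <- names(modules)[modules == found]
  expect_gt(cor(abs(ms$mm[genes, found]), ms$gs[genes]), 0.5)
})

test_that("tighter module loadings raise the within-module topological overlap", {
  med_tom <- vapply(c(0.6, 0.75, 0.9), function(l) {
    ch <- generate_cohort(sim_config(n_genes = 200, n_samples = 60, n_strata = 1,
                                     stratum_bmi_medians = 25,
                                     module_sizes = c(30, 25),
                                     module_loading = l, n_rewired_hubs = 0,
                                     n_synergy_triples = 0, seed = 71))
    tom <- tom_similarity(soft_adjacency(ch$expr, 6))
    mod <- ch$truth$module_of_gene
    assigned <- mod != "unassigned"
    within <- outer(mod, mod, "==") & outer(assigned, assigned, "&") & upper.tri(tom)
    median(tom[within])
  }, numeric(1))
  expect_true(all(diff(med_tom) > 0))
})

test_that("membership and significance behave at the extremes", {
  m <- rmat(30, 50, seed = 21)
  me <- rbind(M1 = m[1, ] / stats::sd(m[1, ]))
  ms <- membership_and_significance(m, me, trait = withr::with_seed(3, rnorm(50)))
  expect_equal(unname(ms$mm["g0001", "M1"]), 1, tolerance = 1e-12)
  expect_true(all(ms$gs >= 0 & ms$gs <= 1))

  # pure-noise genes have small membership at n = 84
  withr::with_seed(22, {
    e <- rnorm(84)
    mm_null <- replicate(200, abs(cor(rnorm(84), e)))
  })
  expect_gte(mean(mm_null < 0.3), 0.95)
})
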