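#' Configuration for the synthetic cohort generator
#'
#' Builds a validated configuration for [generate_cohort()]. The defaults
#' describe the package's standard validation cohort: 2,000 genes over 84
#' samples in three ancestry strata with distinct median BMIs, five planted
#' co-expression modules realized as latent-factor blocks, one module whose
#' factor drives BMI, two assay batches, twenty genes that are hubs in
#' exactly one weight group, and five planted XOR-style synergy triples.
#'
#' Module sizes are deliberately small relative to the 1%-percentile edge
#' budget of the downstream connectivity analysis, so that planted module
#' edges are retained in full in both group networks and per-gene
#' connectivity has a stable ground truth.
#'
#' @param n_genes Number of genes.
#' @param n_samples Number of samples (split evenly across strata).
#' @param n_strata Number of ancestry strata.
#' @param stratum_bmi_medians Target median BMI per stratum (kg/m^2).
#' @param bmi_sd Within-stratum BMI standard deviation (kg/m^2).
#' @param module_sizes Integer vector of planted module sizes.
#' @param module_loading Latent-factor loading of ordinary module genes, in (0,1).
#' @param bmi_modules Indices (into `module_sizes`) of modules whose factor
#'   drives BMI.
#' @param bmi_effect Target correlation between the (combined) BMI-module
#'   factor and BMI, on the within-stratum scale.
#' @param n_batches Number of assay batches.
#' @param batch_shift_sd SD of gene-wise additive batch shifts (log2 units).
#' @param batch_scale_sd SD of gene-wise multiplicative batch log-scale factors.
#' @param n_rewired_hubs Number of genes given a strong module loading in
#'   exactly one weight group and none in the other.
#' @param hub_loading Factor loading of rewired hubs inside their hub group.
#' @param n_synergy_triples Number of planted three-way (XOR) interactions.
#' @param synergy_amplitude Half-distance between the low and high expression
#'   states of planted synergy genes (log2 units).
#' @param synergy_jitter SD of within-state scatter of planted synergy genes.
#' @param noise_sd SD of the per-gene Gaussian noise term.
#' @param na_rate Fraction of clinical trait values set to NA (traits only;
#'   the expression matrix is always complete).
#' @param seed Integer seed; fixing it makes the output byte-identical.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_cohort()], [write_fixture_bundle()]
#' @export
sim_config <- function(n_genes = 2000L,
                       n_samples = 84L,
                       n_strata = 3L,
                       stratum_bmi_medians = c(24.83, 29.51, 23.46),
                       bmi_sd = 4,
                       module_sizes = c(45L, 40L, 32L, 27L, 22L),
                       module_loading = 0.82,
                       bmi_modules = 1L,
                       bmi_effect = 0.6,
                       n_batches = 2L,
                       batch_shift_sd = 0.3,
                       batch_scale_sd = 0.1,
                       n_rewired_hubs = 20L,
                       hub_loading = 0.95,
                       n_synergy_triples = 5L,
                       synergy_amplitude = 1.2,
                       synergy_jitter = 0.01,
                       noise_sd = 0.45,
                       na_rate = 0,
                       seed = 20190515L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
    n_strata = as.integer(n_strata), stratum_bmi_medians = stratum_bmi_medians,
    bmi_sd = bmi_sd, module_sizes = as.integer(module_sizes),
    module_loading = module_loading, bmi_modules = as.integer(bmi_modules),
    bmi_effect = bmi_effect, n_batches = as.integer(n_batches),
    batch_shift_sd = batch_shift_sd, batch_scale_sd = batch_scale_sd,
    n_rewired_hubs = as.integer(n_rewired_hubs), hub_loading = hub_loading,
    n_synergy_triples = as.integer(n_synergy_triples),
    synergy_amplitude = synergy_amplitude, synergy_jitter = synergy_jitter,
    noise_sd = noise_sd, na_rate = na_rate, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (sum(cfg$module_sizes) > cfg$n_genes) {
    stop("`module_sizes`: planted modules exceed n_genes", call. = FALSE)
  }
  if (length(cfg$stratum_bmi_medians) != cfg$n_strata) {
    stop("`stratum_bmi_medians`: need one median per stratum", call. = FALSE)
  }
  if (cfg$module_loading <= 0 || cfg$module_loading >= 1) {
    stop("`module_loading` must be in (0, 1)", call. = FALSE)
  }
  if (cfg$hub_loading <= 0 || cfg$hub_loading >= 1) {
    stop("`hub_loading` must be in (0, 1)", call. = FALSE)
  }
  if (any(cfg$bmi_modules < 1) || any(cfg$bmi_modules > length(cfg$module_sizes))) {
    stop("`bmi_modules`: module index out of range", call. = FALSE)
  }
  if (cfg$bmi_effect < 0 || cfg$bmi_effect > 1) {
    stop("`bmi_effect` must be in [0, 1]", call. = FALSE)
  }
  n_free <- cfg$n_genes - sum(cfg$module_sizes)
  if (3L * cfg$n_synergy_triples > n_free) {
    stop("`n_synergy_triples`: not enough genes outside modules", call. = FALSE)
  }
  if (cfg$n_rewired_hubs > sum(cfg$module_sizes)) {
    stop("`n_rewired_hubs`: more hubs than module genes", call. = FALSE)
  }
  invisible(cfg)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Simulates a log2-scale expression matrix and matching sample table under a
#' latent-factor model: each planted module has one standard-normal factor per
#' sample and module genes are `loading * factor + noise`. BMI is drawn per
#' stratum around the configured medians with a component proportional to the
#' BMI-module factor; weight groups follow the stratum-median rule (BMI
#' strictly above the stratum median is overweight). Batches add gene-wise
#' shift and scale distortions. Rewired hub genes carry `hub_loading` on their
#' module factor in one weight group and zero in the other. Synergy triples
#' are planted by [plant_synergy_triples()].
#'
#' Genes carrying planted structure receive higher baseline intensities than
#' filler genes so that the top-35% expressed-gene filter retains them, as it
#' retains biologically expressed genes on a real array.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `expr` (genes x samples matrix), `samples`
#'   (data.frame: sample_id, sex, stratum, age, batch, bmi, body_fat) and
#'   `truth` (list: module_of_gene, hub_table, synergy_triples, group, bmi,
#'   stratum, batch, factors).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  ng <- cfg$n_genes; ns <- cfg$n_samples; K <- length(cfg$module_sizes)
  gene_ids <- sprintf("G%05d", seq_len(ng))
  sample_ids <- sprintf("S%03d", seq_len(ns))

  stratum <- rep(seq_len(cfg$n_strata), length.out = ns)
  stratum <- sort(stratum)  # contiguous strata blocks
  batch <- sample(rep(seq_len(cfg$n_batches), length.out = ns))
  sex <- sample(c("F", "M"), ns, replace = TRUE)
  age <- pmax(18, pmin(65, round(stats::rnorm(ns, 26, 9))))

  factors <- matrix(stats::rnorm(K * ns), K, ns)

  # BMI: stratum median + bmi_sd * (bmi_effect * g + sqrt(1-eff^2) * e)
  g_bmi <- colSums(factors[cfg$bmi_modules, , drop = FALSE]) /
    sqrt(length(cfg$bmi_modules))
  bmi_noise <- stats::rnorm(ns)
  bmi <- cfg$stratum_bmi_medians[stratum] +
    cfg$bmi_sd * (cfg$bmi_effect * g_bmi + sqrt(1 - cfg$bmi_effect^2) * bmi_noise)
  bmi <- pmax(bmi, 13)  # plausible floor for an adult cohort

  # ground-truth weight group by the stratum-median rule
  group <- rep("normal", ns)
  for (s in unique(stratum)) {
    i <- stratum == s
    group[i][bmi[i] > stats::median(bmi[i])] <- "overweight"
  }

  body_fat <- 25 + 1.2 * (bmi - mean(bmi)) + stats::rnorm(ns, 0, 4)

  # module membership
  module_of_gene <- rep("unassigned", ng)
  idx <- 1L
  module_index <- vector("list", K)
  for (k in seq_len(K)) {
    rows <- idx:(idx + cfg$module_sizes[k] - 1L)
    module_of_gene[rows] <- sprintf("M%d", k)
    module_index[[k]] <- rows
    idx <- idx + cfg$module_sizes[k]
  }
  structure_rows <- unlist(module_index)

  # baseline intensities: structured genes high so the expressed-gene filter
  # keeps them, filler genes spread lower
  baseline <- stats::rnorm(ng, 7, 1)
  baseline[structure_rows] <- stats::rnorm(length(structure_rows), 10, 0.5)

  X <- matrix(stats::rnorm(ng * ns, sd = cfg$noise_sd), ng, ns)
  for (k in seq_len(K)) {
    X[module_index[[k]], ] <- X[module_index[[k]], ] +
      cfg$module_loading * matrix(factors[k, ], cfg$module_sizes[k], ns, byrow = TRUE)
  }

  # rewired hubs: strong loading inside one weight group, pure noise in the other
  hub_table <- data.frame(gene_id = character(0), module = character(0),
                          hub_group = character(0), stringsAsFactors = FALSE)
  if (cfg$n_rewired_hubs > 0) {
    hub_rows <- sample(structure_rows, cfg$n_rewired_hubs)
    hub_group <- rep(c("normal", "overweight"), length.out = cfg$n_rewired_hubs)
    for (i in seq_len(cfg$n_rewired_hubs)) {
      r <- hub_rows[i]
      k <- match(module_of_gene[r], sprintf("M%d", seq_len(K)))
      v <- stats::rnorm(ns, sd = cfg$noise_sd)
      in_grp <- group == hub_group[i]
      v[in_grp] <- v[in_grp] + cfg$hub_loading * factors[k, in_grp]
      X[r, ] <- v
    }
    hub_table <- data.frame(gene_id = gene_ids[hub_rows],
                            module = module_of_gene[hub_rows],
                            hub_group = hub_group, stringsAsFactors = FALSE)
  }

  # reserve filler genes for synergy triples; give them expressed-level baselines
  synergy_triples <- data.frame(gene_a = character(0), gene_b = character(0),
                                control_gene = character(0), stringsAsFactors = FALSE)
  if (cfg$n_synergy_triples > 0) {
    free_rows <- setdiff(seq_len(ng), structure_rows)
    syn_rows <- sample(free_rows, 3L * cfg$n_synergy_triples)
    # high enough to pass the expressed-gene filter, with both expression
    # states inside dense regions of the intensity distribution
    baseline[syn_rows] <- stats::rnorm(length(syn_rows), 8.8, 0.15)
    synergy_triples <- data.frame(
      gene_a = gene_ids[syn_rows[seq(1, length(syn_rows), by = 3)]],
      gene_b = gene_ids[syn_rows[seq(2, length(syn_rows), by = 3)]],
      control_gene = gene_ids[syn_rows[seq(3, length(syn_rows), by = 3)]],
      stringsAsFactors = FALSE)
  }

  X <- X + baseline
  dimnames(X) <- list(gene_ids, sample_ids)

  truth <- list(
    module_of_gene = stats::setNames(module_of_gene, gene_ids),
    hub_table = hub_table,
    synergy_triples = synergy_triples,
    group = stats::setNames(group, sample_ids),
    bmi = stats::setNames(bmi, sample_ids),
    stratum = stats::setNames(stratum, sample_ids),
    batch = stats::setNames(batch, sample_ids),
    factors = factors)

  # batch distortions: gene-wise shift and scale per batch
  if (cfg$n_batches > 1) {
    center <- rowMeans(X)
    for (b in seq_len(cfg$n_batches)) {
      shift <- stats::rnorm(ng, 0, cfg$batch_shift_sd)
      scale <- exp(stats::rnorm(ng, 0, cfg$batch_scale_sd))
      j <- batch == b
      X[, j] <- (X[, j] - center) * scale + center + shift
    }
  }

  # synergy triples are planted after the batch distortion, so the planted
  # XOR pattern is exactly what reaches the analysis
  X <- plant_synergy_triples(X, truth, cfg)

  samples <- data.frame(sample_id = sample_ids, sex = sex, stratum = stratum,
                        age = age, batch = batch, bmi = bmi, body_fat = body_fat,
                        stringsAsFactors = FALSE)
  if (cfg$na_rate > 0) {
    nna <- round(cfg$na_rate * ns)
    if (nna > 0) samples$body_fat[sample(ns, nna)] <- NA
  }

  list(expr = X, samples = samples, truth = truth)
}

#' Plant XOR-style three-way interactions into an expression matrix
#'
#' For each triple listed in `truth$synergy_triples` the gene pair (A, B) is
#' written as a four-quadrant pattern in which weight group equals the XOR of
#' the two genes' high/low states: overweight samples are split evenly between
#' the (high, high) and (low, low) quadrants, normal samples between
#' (high, low) and (low, high). Each gene's marginal high/low state is thereby
#' balanced within both groups, so it carries (almost) no single-gene
#' information about weight status, while the joint pattern determines it.
#' The control gene's high/low state matches gene A's state, so its
#' up/down status is constant within every quadrant cluster without being
#' marginally informative about group.
#'
#' @param expr Gene x sample expression matrix.
#' @param truth Ground-truth list with elements `synergy_triples` (data.frame
#'   with columns gene_a, gene_b, control_gene) and `group` (named vector of
#'   "normal"/"overweight" per sample).
#' @param config A [sim_config()]; uses `synergy_amplitude` and
#'   `synergy_jitter`.
#' @return The expression matrix with the triple rows replaced. With zero
#'   triples the matrix is returned unchanged.
#' @export
plant_synergy_triples <- function(expr, truth, config) {
  trip <- truth$synergy_triples
  if (is.null(trip) || nrow(trip) == 0) return(expr)
  missing <- setdiff(unlist(trip), rownames(expr))
  if (length(missing)) {
    stop("synergy triple genes absent from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  group <- truth$group[colnames(expr)]
  amp <- config$synergy_amplitude; jit <- config$synergy_jitter
  ow <- which(group == "overweight"); nw <- which(group != "overweight")
  for (i in seq_len(nrow(trip))) {
    # even split of each group across its two XOR quadrants, randomized per
    # triple so that genes of different triples carry independent patterns
    quad <- integer(ncol(expr))
    quad[ow] <- sample(rep(c(1L, 2L), length.out = length(ow)))  # 1 = HH, 2 = LL
    quad[nw] <- sample(rep(c(3L, 4L), length.out = length(nw)))  # 3 = HL, 4 = LH
    a_high <- quad %in% c(1L, 3L)
    b_high <- quad %in% c(1L, 4L)
    base_a <- mean(expr[trip$gene_a[i], ])
    base_b <- mean(expr[trip$gene_b[i], ])
    base_x <- mean(expr[trip$control_gene[i], ])
    expr[trip$gene_a[i], ] <- base_a + amp * ifelse(a_high, 1, -1) +
      stats::rnorm(ncol(expr), 0, jit)
    expr[trip$gene_b[i], ] <- base_b + amp * ifelse(b_high, 1, -1) +
      stats::rnorm(ncol(expr), 0, jit)
    expr[trip$control_gene[i], ] <- base_x + amp * ifelse(a_high, 1, -1) +
      stats::rnorm(ncol(expr), 0, jit)
  }
  expr
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Generates a cohort under `config` and writes five artifacts: the expression
#' TSV, the sample TSV, a gene-level truth TSV (module, hub group, synergy
#' role), a GMT file built from the true modules, and a key-value snapshot of
#' the configuration. Re-running with the same configuration reproduces the
#' files byte for byte.
#'
#' @param dir Output directory (created if needed).
#' @param config A [sim_config()] object.
#' @return Invisibly, a manifest data.frame with columns `file` and `md5`.
#' @export
write_fixture_bundle <- function(dir, config) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir, call. = FALSE)
  cohort <- generate_cohort(config)

  paths <- file.path(dir, c("expression.tsv", "samples.tsv", "truth.tsv",
                            "modules.gmt", "config.tsv"))
  write_expression_tsv(cohort$expr, paths[1])
  write_sample_tsv(cohort$samples, paths[2])

  truth <- cohort$truth
  role <- rep("", length(truth$module_of_gene))
  names(role) <- names(truth$module_of_gene)
  if (nrow(truth$synergy_triples)) {
    role[truth$synergy_triples$gene_a] <- "synergy_a"
    role[truth$synergy_triples$gene_b] <- "synergy_b"
    role[truth$synergy_triples$control_gene] <- "synergy_control"
  }
  hubgrp <- rep("", length(role)); names(hubgrp) <- names(role)
  if (nrow(truth$hub_table)) hubgrp[truth$hub_table$gene_id] <- truth$hub_table$hub_group
  truth_df <- data.frame(gene_id = names(truth$module_of_gene),
                         module = unname(truth$module_of_gene),
                         hub_group = unname(hubgrp),
                         synergy_role = unname(role), stringsAsFactors = FALSE)
  utils::write.table(truth_df, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)

  modules <- split(names(truth$module_of_gene), truth$module_of_gene)
  modules <- modules[setdiff(names(modules), "unassigned")]
  write_gmt(modules, paths[4])

  cfg_flat <- vapply(config, function(v) paste(v, collapse = ","), character(1))
  utils::write.table(data.frame(key = names(cfg_flat), value = unname(cfg_flat)),
                     paths[5], sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  invisible(manifest)
}
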