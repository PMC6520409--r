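#' Pipeline configuration
#'
#' Collects every tunable parameter of the analysis in one validated object.
#' The defaults are the study parameters: top-35% expressed genes, soft
#' power 6 (or automatic selection), minimum module size 10, module merge
#' height 0.25, 99th-percentile edges, hub-conversion threshold 0.5, DE FDR
#' cutoff 0.1, synergy tree height 0.02 over the top 100 entropy-ranked
#' genes with synergy threshold 0.9.
#'
#' @param expression_tsv,sample_tsv Paths to the input tables.
#' @param gmt Optional path to a gene-set collection for enrichment.
#' @param out_dir Output directory.
#' @param expressed_fraction Fraction of genes kept as expressed.
#' @param soft_power Soft-thresholding power; NA picks it from the
#'   scale-free fit profile.
#' @param min_module_size Minimum module size.
#' @param merge_cut_height Module-merge eigengene dissimilarity cutoff.
#' @param edge_percentile Percentile defining network edges.
#' @param hub_delta_threshold Hub-conversion threshold on delta-C.
#' @param de_fdr FDR cutoff flagging differentially expressed genes.
#' @param outlier_z Sample-outlier z-score cutoff.
#' @param tree_height,top_n,synergy_threshold,purity_threshold,min_cluster_size,entropy_sort
#'   Synergy parameters, see [synergy_params()].
#' @param seed Integer seed for any stochastic step.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(expression_tsv = NULL, sample_tsv = NULL,
                            gmt = NULL, out_dir = "bminet_out",
                            expressed_fraction = 0.35,
                            soft_power = 6,
                            min_module_size = 10,
                            merge_cut_height = 0.25,
                            edge_percentile = 0.99,
                            hub_delta_threshold = 0.5,
                            de_fdr = 0.1,
                            outlier_z = 2.5,
                            tree_height = 0.02,
                            top_n = 100,
                            synergy_threshold = 0.9,
                            purity_threshold = 0.5,
                            min_cluster_size = 5,
                            entropy_sort = "desc",
                            seed = 1L) {
  cfg <- list(expression_tsv = expression_tsv, sample_tsv = sample_tsv,
              gmt = gmt, out_dir = out_dir,
              expressed_fraction = expressed_fraction, soft_power = soft_power,
              min_module_size = min_module_size,
              merge_cut_height = merge_cut_height,
              edge_percentile = edge_percentile,
              hub_delta_threshold = hub_delta_threshold, de_fdr = de_fdr,
              outlier_z = outlier_z, tree_height = tree_height,
              top_n = top_n, synergy_threshold = synergy_threshold,
              purity_threshold = purity_threshold,
              min_cluster_size = min_cluster_size,
              entropy_sort = entropy_sort, seed = as.integer(seed))
  stopifnot(cfg$expressed_fraction > 0, cfg$expressed_fraction <= 1,
            cfg$min_module_size >= 2,
            cfg$merge_cut_height > 0, cfg$merge_cut_height < 1,
            cfg$edge_percentile > 0, cfg$edge_percentile < 1,
            cfg$hub_delta_threshold > 0, cfg$de_fdr > 0, cfg$de_fdr < 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write a pipeline configuration as a flat key-value TSV
#'
#' @param config A [pipeline_config()] object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  vals <- vapply(config, function(v) if (is.null(v)) "" else as.character(v),
                 character(1))
  utils::write.table(data.frame(key = names(vals), value = unname(vals)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration written by [write_pipeline_config()]
#'
#' Unknown keys are an error: the parameter surface is fixed.
#'
#' @param path Path to the key-value TSV.
#' @return A [pipeline_config()] object.
#' @export
read_pipeline_config <- function(path) {
  kv <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  known <- names(formals(pipeline_config))
  unknown <- setdiff(kv$key, known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  args <- stats::setNames(as.list(kv$value), kv$key)
  numeric_keys <- c("expressed_fraction", "soft_power", "min_module_size",
                    "merge_cut_height", "edge_percentile",
                    "hub_delta_threshold", "de_fdr", "outlier_z",
                    "tree_height", "top_n", "synergy_threshold",
                    "purity_threshold", "min_cluster_size", "seed")
  for (k in intersect(names(args), numeric_keys)) args[[k]] <- as.numeric(args[[k]])
  for (k in names(args)) if (identical(args[[k]], "")) args[[k]] <- NULL
  do.call(pipeline_config, args)
}

stage_done <- function(report, name, ...) {
  info <- list(...)
  message(sprintf("[bminet] stage %-12s %s", name,
                  paste(names(info), unlist(info), sep = "=", collapse = " ")))
  report$stages[[name]] <- info
  report
}

#' Run the complete analysis pipeline
#'
#' Stages, in order: preprocess (quantile normalization, batch adjustment,
#' outlier removal, weight-group assignment, expressed-gene selection),
#' differential expression, co-expression network and modules, differential
#' connectivity, three-way interactions, and (when a GMT is supplied)
#' module over-representation. Every stage writes its result table under
#' `out_dir`; the run report lists per-stage dimensions and output
#' checksums. Identical configuration and inputs give identical outputs.
#'
#' @param config A [pipeline_config()] object with input paths set.
#' @return Invisibly, the run report (list with `stages`, `files`, `md5`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(stages = list(), files = character(0))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  fail <- function(stage, msg) {
    writeLines(paste(stage, msg), file.path(config$out_dir, "FAILED"))
    stop(sprintf("stage `%s` failed: %s", stage, msg), call. = FALSE)
  }

  # ---- preprocess ----------------------------------------------------------
  if (is.null(config$expression_tsv) || !file.exists(config$expression_tsv)) {
    fail("preprocess", paste("missing expression input:",
                             config$expression_tsv %||% "<unset>"))
  }
  if (is.null(config$sample_tsv) || !file.exists(config$sample_tsv)) {
    fail("preprocess", paste("missing sample table:",
                             config$sample_tsv %||% "<unset>"))
  }
  expr <- read_expression_tsv(config$expression_tsv)
  samples <- read_sample_tsv(config$sample_tsv)
  samples <- samples[match(colnames(expr), samples$sample_id), , drop = FALSE]
  if (anyNA(samples$sample_id)) fail("preprocess", "sample table does not cover all samples")

  expr <- quantile_normalize(expr)
  if ("batch" %in% names(samples) && length(unique(samples$batch)) > 1) {
    expr <- adjust_batch(expr, samples$batch)
  }
  flagged <- detect_outlier_samples(expr, z_cut = config$outlier_z)
  if (length(flagged)) {
    keep <- setdiff(colnames(expr), flagged)
    expr <- expr[, keep, drop = FALSE]
    samples <- samples[samples$sample_id %in% keep, , drop = FALSE]
  }
  samples <- assign_weight_groups(samples)
  expressed <- select_expressed(expr, config$expressed_fraction)
  write_expression_tsv(expressed, file.path(config$out_dir, "expressed.tsv"))
  write_sample_tsv(samples, file.path(config$out_dir, "samples_processed.tsv"))
  report <- stage_done(report, "preprocess", genes_in = nrow(expr),
                       genes_expressed = nrow(expressed),
                       samples = ncol(expressed), outliers = length(flagged))

  # ---- differential expression --------------------------------------------
  de <- differential_expression(expressed, samples$group, fdr = config$de_fdr)
  utils::write.table(de, file.path(config$out_dir, "de.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  report <- stage_done(report, "diffexpr", n_significant = sum(de$significant),
                       pi0 = signif(attr(de, "pi0"), 4),
                       est_nonnull = attr(de, "estimated_nonnull"))

  # ---- co-expression network ----------------------------------------------
  power <- config$soft_power
  if (is.na(power)) {
    power <- pick_soft_power(soft_threshold_profile(expressed))
  }
  tom <- tom_similarity(soft_adjacency(expressed, power))
  assignment <- cluster_modules(tom, min_size = config$min_module_size)
  if (length(setdiff(unique(assignment), "unassigned")) > 1) {
    assignment <- merge_modules(expressed, assignment,
                                cut_height = config$merge_cut_height)
  }
  utils::write.table(
    data.frame(gene_id = names(assignment), module = unname(assignment)),
    file.path(config$out_dir, "modules.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  mods <- setdiff(unique(assignment), "unassigned")
  if (length(mods)) {
    me <- module_eigengenes(expressed, assignment)
    mt <- module_trait_cor(me, samples)
    utils::write.table(
      data.frame(module = rownames(mt$r),
                 as.data.frame(mt$r, optional = TRUE),
                 p = as.data.frame(mt$p, optional = TRUE)),
      file.path(config$out_dir, "module_trait.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
  }
  report <- stage_done(report, "coexnet", power = power,
                       n_modules = length(mods),
                       unassigned = sum(assignment == "unassigned"))

  # ---- differential connectivity ------------------------------------------
  conn <- differential_connectivity(expressed, samples, power = power,
                                    percentile = config$edge_percentile,
                                    threshold = config$hub_delta_threshold)
  utils::write.table(conn, file.path(config$out_dir, "connectivity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report <- stage_done(report, "connectivity",
                       hub_to_nonhub = sum(conn$conversion == "hub_to_nonhub"),
                       nonhub_to_hub = sum(conn$conversion == "nonhub_to_hub"),
                       s = signif(attr(conn, "s"), 4))

  # ---- synergy --------------------------------------------------------------
  sp <- synergy_params(tree_height = config$tree_height, top_n = config$top_n,
                       synergy_threshold = config$synergy_threshold,
                       purity_threshold = config$purity_threshold,
                       min_cluster_size = config$min_cluster_size,
                       entropy_sort = config$entropy_sort)
  triples <- find_three_way_interactions(expressed, samples$group, sp)
  utils::write.table(triples, file.path(config$out_dir, "synergy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report <- stage_done(report, "synergy", n_triples = nrow(triples))

  # ---- enrichment -----------------------------------------------------------
  if (!is.null(config$gmt) && file.exists(config$gmt) && length(mods)) {
    collection <- read_gmt(config$gmt)
    enr <- lapply(mods, function(m) {
      e <- enrich_collection(names(assignment)[assignment == m], collection,
                             rownames(expressed))
      if (nrow(e)) cbind(module = m, e) else NULL
    })
    enr <- do.call(rbind, enr[!vapply(enr, is.null, logical(1))])
    utils::write.table(enr, file.path(config$out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report <- stage_done(report, "enrichment",
                         n_tests = if (is.null(enr)) 0 else nrow(enr))
  } else {
    report <- stage_done(report, "enrichment", skipped = "no gene sets supplied")
  }

  files <- list.files(config$out_dir, pattern = "\\.tsv$", full.names = TRUE)
  report$files <- basename(files)
  report$md5 <- stats::setNames(unname(tools::md5sum(files)), basename(files))
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
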