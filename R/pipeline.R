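#' Run the full prioritization workflow
#'
#' Orchestrates the workflow GWAS summary data -> gene Z-scores -> BLR fit ->
#' prioritized gene sets from a single (JSON-serializable) configuration.
#' Inputs may be files (GWAS TSV, genes GTF, LD directory, GMT) or a
#' `simulate` block that generates them in memory. Every output TSV carries a
#' "#" metadata block with the package version and the configuration hash; a
#' manifest lists every artifact with its MD5 checksum.
#'
#' @param config A nested list (or path to a JSON file) with components:
#'   `seed`, `out_dir`, optional `simulate` (passed to the generator), or
#'   `inputs` (`gwas`, `genes`, `ld_dir`, `gmt`, optional `column_map`);
#'   `genestats` (`up_bp`, `down_bp`, `strict`); `model` (`type` =
#'   `"single"`/`"multi"`, sampler settings); `prioritize` (`pip_threshold`,
#'   `exclude_negative`).
#' @return Invisibly, a list with the fit, the prioritization table, the
#'   gene-statistics table and the manifest path.
#' @export
run_prioritization <- function(config) {
  config <- .load_config(config)
  out_dir <- config$out_dir %||% tempfile("gsblr_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  # hash the analysis-relevant configuration only: artifacts must be
  # reproducible regardless of where they are written
  chash <- config_hash(config[setdiff(names(config), "out_dir")])
  meta <- list(config_hash = chash, seed = seed)

  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop_gsblr("stage '", name, "' failed: ", conditionMessage(e),
                 class = "gsblr_stage_error"))
    gsblr_log("stage ", name, " done in ",
              sprintf("%.2fs", as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  dat <- stage("inputs", .resolve_inputs(config, seed))
  gs_cfg <- config$genestats %||% list()
  gstats <- stage("genestats", compute_gene_stats(
    dat$variants, dat$genes, dat$ld_source,
    up_bp = gs_cfg$up_bp %||% 35000L, down_bp = gs_cfg$down_bp %||% 10000L,
    strict = isTRUE(gs_cfg$strict)))
  if (nrow(gstats) == 0L)
    stop_gsblr("stage 'genestats' failed: no genes with mapped variants",
               class = "gsblr_stage_error")
  design <- stage("design",
                  gene_set_design(dat$sets, gstats$gene_id, drop_empty = TRUE))
  mdl <- config$model %||% list()
  type <- mdl$type %||% "single"
  fit <- stage("fit", {
    if (identical(type, "single")) {
      cfg <- sampler_config(n_iter = mdl$n_iter %||% 3000L,
                            burn_in = mdl$burn_in %||% 500L,
                            pi_prior = mdl$pi_prior %||% 0.001,
                            estimate_pi = mdl$estimate_pi %||% TRUE,
                            seed = seed, n_chains = mdl$n_chains %||% 1L,
                            keep_samples = FALSE)
      fit_single(gstats$z, design, cfg)
    } else stop_gsblr("multi-trait runs take a list of gene-statistics ",
                      "files; use fit_multi() directly or the CLI",
                      class = "gsblr_config_error")
  })
  pr_cfg <- config$prioritize %||% list()
  ranked <- stage("prioritize", prioritize(
    fit, pip_threshold = pr_cfg$pip_threshold %||% 0.1,
    exclude_negative = pr_cfg$exclude_negative %||% TRUE))

  gstats_path <- file.path(out_dir, "genestats.tsv")
  write_tsv_with_meta(gstats, gstats_path, meta)
  fit_df <- data.frame(set_id = fit$set_ids, n_genes = colSums(design$X),
                       pip = unname(fit$pip), b_mean = unname(fit$b_mean))
  fit_path <- file.path(out_dir, "fit.tsv")
  write_tsv_with_meta(fit_df, fit_path,
                      c(meta, list(pi_mean = fit$pi_mean,
                                   sigma_b2_mean = fit$sigma_b2_mean,
                                   sigma_e2_mean = fit$sigma_e2_mean)))
  ranked_path <- file.path(out_dir, "prioritized.tsv")
  write_tsv_with_meta(ranked, ranked_path, meta)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config[setdiff(names(config), "out_dir")], cfg_path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  files <- c(gstats_path, fit_path, ranked_path, cfg_path)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  manifest_path <- file.path(out_dir, "manifest.tsv")
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(fit = fit, prioritized = ranked, gene_stats = gstats,
                 design = design, out_dir = out_dir,
                 manifest = manifest_path))
}

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  config
}

.resolve_inputs <- function(config, seed) {
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    sc <- simulation_scenario(
      h2 = sim$h2 %||% 0.3, causal_prop = sim$causal_prop %||% 0.004,
      architecture = sim$architecture %||% "GA1",
      trait_type = sim$trait_type %||% "quantitative",
      prevalence = sim$prevalence,
      n_ind = sim$n_ind %||% 4000L, n_snp = sim$n_snp %||% 2500L,
      seed = seed)
    geno <- simulate_genotypes(sc$n_ind, sc$n_snp,
                               ld_block_size = sim$snps_per_gene %||% 5L,
                               seed = seed)
    eff <- simulate_effects(sc$n_snp, sc$causal_prop, sc$architecture,
                            seed = seed)
    phen <- simulate_phenotype(geno$G, eff, sc)
    gw <- gwas_scan(geno$G, geno$variants, phen$y, sc$trait_type,
                    n_folds = 5L, seed = seed)
    fold <- gw[[1L]]
    gs <- build_genes_and_sets(
      geno$variants, eff$causal_idx,
      set_sizes = sim$set_sizes %||% 20L,
      causal_counts = sim$causal_counts %||% 5L,
      n_control_sets = sim$n_control_sets %||% 40L,
      n_replicates = sim$n_replicates %||% 1L, seed = seed)
    mapping <- map_variants_to_genes(fold$variants, gs$genes)
    ld <- gene_ld_from_genotypes(geno$G[fold$train_idx, , drop = FALSE],
                                 mapping)
    return(list(variants = fold$variants, genes = gs$genes, ld_source = ld,
                sets = gs$sets, truth = gs$truth))
  }
  inp <- config$inputs
  if (is.null(inp$gwas) || is.null(inp$genes) || is.null(inp$ld_dir) ||
      is.null(inp$gmt))
    stop_gsblr("inputs must name gwas, genes, ld_dir and gmt",
               class = "gsblr_config_error")
  if (!dir.exists(inp$ld_dir))
    stop_gsblr("LD directory not found: ", inp$ld_dir,
               class = "gsblr_config_error")
  list(variants = read_gwas(inp$gwas, inp$column_map %||% list()),
       genes = read_gtf_genes(inp$genes),
       ld_source = inp$ld_dir,
       sets = read_gmt(inp$gmt), truth = NULL)
}

#' Benchmark the Bayesian model against the linear baseline
#'
#' Reproduces the simulation comparison at configurable scale: per seed, an
#' end-to-end simulation (genotypes -> phenotype -> training-fold GWAS ->
#' gene statistics) with gene sets extended by overlapping (or disjoint)
#' extra sets; both the spike-and-slab model and the joint linear baseline
#' are fitted, rankings scored by top-k true positives, and predictive
#' accuracy measured on the validation fold.
#'
#' @param seeds Integer vector of simulation seeds.
#' @param overlap_mode `"correlated"` or `"uncorrelated"` extra sets.
#' @param n_extra Number of extra sets (default 191).
#' @param n_ind,n_snp,snps_per_gene,h2,causal_prop,architecture Simulation
#'   scale parameters.
#' @param set_size Base set size (default 20).
#' @param n_causal_sets,causal_per_set Causal-set configuration (default 10
#'   sets with 5 causal genes each).
#' @param n_base_controls Non-causal base sets (default 190).
#' @param k_list Top-k cutoffs.
#' @param sampler Optional [sampler_config()].
#' @return List with `topk` (mean and sd per method and k), `accuracy`
#'   (mean prediction accuracy per method), and `per_seed` details.
#' @export
run_benchmark <- function(seeds = 1:5,
                          overlap_mode = c("correlated", "uncorrelated"),
                          n_extra = 191L,
                          n_ind = 8000L, n_snp = 3600L, snps_per_gene = 3L,
                          h2 = 0.3, causal_prop = 0.014, architecture = "GA1",
                          set_size = 50L, n_causal_sets = 10L,
                          causal_per_set = 25L, n_base_controls = 190L,
                          k_list = c(10L, 20L, 50L), sampler = NULL) {
  overlap_mode <- match.arg(overlap_mode)
  per_seed <- lapply(seeds, function(sd) {
    sc <- simulation_scenario(h2 = h2, causal_prop = causal_prop,
                              architecture = architecture,
                              trait_type = "quantitative",
                              n_ind = n_ind, n_snp = n_snp, seed = sd)
    geno <- simulate_genotypes(n_ind, n_snp, ld_block_size = snps_per_gene,
                               seed = sd)
    eff <- simulate_effects(n_snp, causal_prop, architecture, seed = sd)
    phen <- simulate_phenotype(geno$G, eff, sc)
    gw <- gwas_scan(geno$G, geno$variants, phen$y, "quantitative",
                    n_folds = 5L, seed = sd)
    fold <- gw[[1L]]
    gs <- build_genes_and_sets(
      geno$variants, eff$causal_idx,
      set_sizes = rep(set_size, n_causal_sets),
      causal_counts = rep(causal_per_set, n_causal_sets),
      n_control_sets = n_base_controls, n_replicates = 1L, seed = sd)
    ext <- build_overlapping_sets(gs$sets, gs$truth, gs$genes$gene_id,
                                  gs$causal_genes, n_extra = n_extra,
                                  overlap_mode = overlap_mode, seed = sd)
    mapping <- map_variants_to_genes(fold$variants, gs$genes)
    ld <- gene_ld_from_genotypes(geno$G[fold$train_idx, , drop = FALSE],
                                 mapping)
    gstats <- compute_gene_stats(fold$variants, gs$genes, ld)
    design <- gene_set_design(ext$sets, gstats$gene_id, drop_empty = TRUE)
    truth <- ext$truth[ext$truth$set_id %in% design$set_ids, ]

    cfg <- sampler %||% sampler_config(seed = sd, keep_samples = FALSE)
    cfg$seed <- cfg$seed %||% sd
    blr <- fit_single(gstats$z, design, cfg)
    covars <- default_covariates(gstats)
    lin <- fit_joint_linear(gstats$z, design, covariates = covars)

    # rank by PIP; among near-tied (excluded) sets the posterior mean effect
    # still orders real signal above noise
    blr_rank <- blr$set_ids[order(-blr$pip, -blr$b_mean, blr$set_ids)]
    lin_rank <- rank_by_pvalue(lin)
    # recovery AUC over the base configuration (causal vs control base sets)
    base_ids <- intersect(gs$truth$set_id, design$set_ids)
    base_truth <- gs$truth[match(base_ids, gs$truth$set_id), ]
    # validation-fold gene statistics for predictive accuracy
    val_variants <- fold$variants
    val_scan <- .gwas_linear(geno$G[fold$val_idx, , drop = FALSE],
                             phen$y[fold$val_idx])
    val_variants$z <- val_scan$z
    gstats_val <- compute_gene_stats(val_variants, gs$genes, ld)
    yv <- gstats_val$z[match(design$gene_ids, gstats_val$gene_id)]
    ok <- is.finite(yv)
    list(
      topk_blr = topk_true_positives(blr_rank, truth, k_list),
      topk_lin = topk_true_positives(lin_rank, truth, k_list),
      auc_blr = ranking_auc(unname(blr$pip[base_ids]),
                            base_truth$is_causal_set),
      acc_blr = prediction_accuracy(blr, design, ifelse(ok, yv, 0),
                                    gene_subset = which(ok)),
      acc_lin = prediction_accuracy(lin, design, ifelse(ok, yv, 0),
                                    gene_subset = which(ok)))
  })
  tk_blr <- do.call(rbind, lapply(per_seed, `[[`, "topk_blr"))
  tk_lin <- do.call(rbind, lapply(per_seed, `[[`, "topk_lin"))
  topk <- data.frame(
    k = rep(k_list, 2L),
    method = rep(c("blr", "baseline"), each = length(k_list)),
    mean_tp = c(colMeans(tk_blr), colMeans(tk_lin)),
    sd_tp = c(apply(tk_blr, 2, stats::sd), apply(tk_lin, 2, stats::sd)))
  accuracy <- data.frame(
    method = c("blr", "baseline"),
    mean_accuracy = c(mean(vapply(per_seed, `[[`, numeric(1), "acc_blr")),
                      mean(vapply(per_seed, `[[`, numeric(1), "acc_lin"))))
  list(topk = topk, accuracy = accuracy,
       auc = vapply(per_seed, `[[`, numeric(1), "auc_blr"),
       per_seed = per_seed)
}
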