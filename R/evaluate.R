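#' Precision, recall and F1 against simulation truth
#'
#' Scores a predicted-positive list of set ids against the truth labels:
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F1 = 2pr / (p + r)`; empty denominators give 0 by convention, so all three
#' scores are always defined.
#'
#' @param predicted_positive Character vector of set ids called associated.
#' @param truth Truth table with `set_id` and `is_causal_set`.
#' @return List with `tp`, `fp`, `fn`, `tn`, `precision`, `recall`, `f1`.
#' @export
classification_scores <- function(predicted_positive, truth) {
  pred <- unique(as.character(predicted_positive))
  unknown <- setdiff(pred, truth$set_id)
  if (length(unknown))
    stop_gsblr("prediction contains unknown set id(s): ",
               paste(utils::head(unknown, 3), collapse = ", "),
               class = "gsblr_validation_error")
  pos <- truth$set_id[truth$is_causal_set]
  neg <- truth$set_id[!truth$is_causal_set]
  tp <- length(intersect(pred, pos))
  fp <- length(intersect(pred, neg))
  fn <- length(setdiff(pos, pred))
  tn <- length(setdiff(neg, pred))
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       precision = p, recall = r, f1 = f1)
}

#' True positives among the top-k ranked sets
#'
#' @param ranking Character vector of set ids, best first.
#' @param truth Truth table with `set_id` and `is_causal_set`.
#' @param k_list Cutoffs (default 10, 20, 50); a `k` beyond the ranking
#'   length is truncated with a warning.
#' @return Named integer vector of causal-set counts, one per k.
#' @export
topk_true_positives <- function(ranking, truth, k_list = c(10L, 20L, 50L)) {
  ranking <- as.character(ranking)
  pos <- truth$set_id[truth$is_causal_set]
  out <- vapply(k_list, function(k) {
    if (k > length(ranking)) {
      warning("k = ", k, " exceeds ranking length ", length(ranking),
              "; truncated")
      k <- length(ranking)
    }
    sum(ranking[seq_len(k)] %in% pos)
  }, integer(1))
  names(out) <- paste0("top", k_list)
  out
}

#' PIP calibration table
#'
#' Assesses whether posterior inclusion probabilities behave like
#' probabilities: among sets with PIP near x, about a fraction x should be
#' truly causal. In `"rank"` mode sets are ordered by PIP within each
#' replicate and pooled across replicates by rank; each rank contributes its
#' mean PIP and the observed causal fraction with an exact (Clopper-Pearson)
#' 95% binomial interval. In `"bin"` mode PIPs are pooled into `n_bins`
#' quantile bins.
#'
#' @param results Data frame with columns `replicate`, `pip`, `is_causal`.
#' @param mode `"rank"` or `"bin"`.
#' @param n_bins Number of bins for bin mode.
#' @return A `data.frame` (class `calibration_table`) with `mean_pip`,
#'   `causal_fraction`, `ci_low`, `ci_high`, `n` per rank/bin.
#' @export
pip_calibration <- function(results, mode = c("rank", "bin"), n_bins = 10L) {
  mode <- match.arg(mode)
  stopifnot(all(c("replicate", "pip", "is_causal") %in% names(results)))
  if (mode == "rank") {
    reps <- split(results, results$replicate)
    if (length(reps) < 2L)
      stop_gsblr("rank mode needs at least 2 replicates",
                 class = "gsblr_argument_error")
    ranked <- lapply(reps, function(d) d[order(-d$pip), , drop = FALSE])
    n_rank <- min(vapply(ranked, nrow, integer(1)))
    tab <- do.call(rbind, lapply(seq_len(n_rank), function(r) {
      pips <- vapply(ranked, function(d) d$pip[r], numeric(1))
      caus <- vapply(ranked, function(d) as.logical(d$is_causal[r]), logical(1))
      .calib_row(pips, caus)
    }))
    tab <- cbind(rank = seq_len(n_rank), tab)
  } else {
    br <- unique(stats::quantile(results$pip, probs = seq(0, 1, length.out = n_bins + 1)))
    if (length(br) < 2L) br <- c(min(results$pip) - 1e-9, max(results$pip) + 1e-9)
    bin <- cut(results$pip, breaks = br, include.lowest = TRUE)
    tab <- do.call(rbind, lapply(split(results, bin), function(d) {
      if (nrow(d) == 0L) return(NULL)
      .calib_row(d$pip, as.logical(d$is_causal))
    }))
    tab <- cbind(bin = seq_len(nrow(tab)), tab)
  }
  rownames(tab) <- NULL
  class(tab) <- c("calibration_table", "data.frame")
  tab
}

.calib_row <- function(pips, causal) {
  n <- length(causal); k <- sum(causal)
  # exact Clopper-Pearson interval
  lo <- if (k == 0) 0 else stats::qbeta(0.025, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(0.975, k + 1, n - k)
  data.frame(mean_pip = mean(pips), causal_fraction = k / n,
             ci_low = lo, ci_high = hi, n = n)
}

#' Cross-validated prediction accuracy of a gene-set fit
#'
#' Predicted gene scores are `y_hat = X b` (posterior mean effects for the
#' Bayesian fit; OLS coefficients, aliased set to zero, for the linear
#' baseline); accuracy is the Pearson correlation between `y_hat` and the
#' validation-fold gene z-scores. A zero-variance prediction (e.g. a null
#' fit) returns 0 with a warning.
#'
#' @param fit_result A `blr_fit` or `joint_linear_fit`.
#' @param design The [gene_set_design] the fit used.
#' @param y_validation Gene z-scores from the validation-fold GWAS, aligned
#'   with `design$gene_ids`.
#' @param gene_subset Optional character vector (or logical/integer index) of
#'   genes to score on.
#' @return Scalar correlation (0 when prediction has zero variance).
#' @export
prediction_accuracy <- function(fit_result, design, y_validation,
                                gene_subset = NULL) {
  b <- if (inherits(fit_result, "blr_fit")) unname(fit_result$b_mean)
  else if (inherits(fit_result, "joint_linear_fit")) {
    bb <- fit_result$beta; bb[is.na(bb)] <- 0; bb
  } else stop_gsblr("unsupported fit object", class = "gsblr_argument_error")
  yhat <- as.numeric(design$X %*% b)
  yv <- as.numeric(y_validation)
  stopifnot(length(yv) == length(yhat))
  if (!is.null(gene_subset)) {
    idx <- if (is.character(gene_subset))
      match(gene_subset, design$gene_ids) else gene_subset
    yhat <- yhat[idx]; yv <- yv[idx]
  }
  if (stats::sd(yhat) == 0) {
    warning("prediction has zero variance; accuracy defined as 0")
    return(0)
  }
  stats::cor(yhat, yv)
}

#' Ranking AUC of PIPs against truth
#'
#' Probability that a randomly chosen causal set outranks a randomly chosen
#' non-causal one (Mann-Whitney form, ties counted half).
#'
#' @param scores Numeric vector (e.g. PIPs).
#' @param is_causal Logical vector.
#' @return AUC in `[0, 1]` (NA if a class is empty).
#' @export
ranking_auc <- function(scores, is_causal) {
  is_causal <- as.logical(is_causal)
  n1 <- sum(is_causal); n0 <- sum(!is_causal)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[is_causal]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' End-to-end PIP calibration experiment
#'
#' Drives the full simulation-to-fit pipeline repeatedly and aggregates a
#' rank-mode calibration table: per repeat, genotypes, causal effects and a
#' phenotype are simulated; a training-fold GWAS yields variant z-scores;
#' gene statistics are computed with empirical per-gene LD; causal gene sets
#' of the requested sizes (causal fraction drawn uniformly from
#' `causal_frac_range`) plus `n_control` non-causal sets are assembled; the
#' spike-and-slab model is fitted and the PIPs recorded with truth labels.
#'
#' @param sizes Causal-set sizes (default 20, 50, 100, 150; one causal set
#'   per size per repeat).
#' @param causal_frac_range Range of the causal-gene fraction within causal
#'   sets (default 5-50%).
#' @param n_control Number of non-causal sets (default 198).
#' @param n_repeats Number of repeats (default 50).
#' @param seed Integer seed; repeat r uses `seed + r`.
#' @param n_ind,n_snp,snps_per_gene,h2,causal_prop,architecture Simulation
#'   scale and trait parameters (desk-scale defaults).
#' @param sampler Optional [sampler_config()]; default uses 3000 iterations,
#'   500 burn-in.
#' @return List with `calibration` (the rank-mode [pip_calibration()] table)
#'   and `raw` (per-repeat PIP/truth rows).
#' @export
run_calibration_experiment <- function(sizes = c(20L, 50L, 100L, 150L),
                                       causal_frac_range = c(0.05, 0.5),
                                       n_control = 198L, n_repeats = 50L,
                                       seed = 1L,
                                       n_ind = 12000L, n_snp = 1600L,
                                       snps_per_gene = 2L,
                                       h2 = 0.3, causal_prop = 0.05,
                                       architecture = "GA1",
                                       sampler = NULL) {
  stopifnot(n_repeats >= 2L)
  raw <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    sr <- seed + r
    sc <- simulation_scenario(h2 = h2, causal_prop = causal_prop,
                              architecture = architecture,
                              trait_type = "quantitative",
                              n_ind = n_ind, n_snp = n_snp, seed = sr)
    geno <- simulate_genotypes(n_ind, n_snp, ld_block_size = snps_per_gene,
                               seed = sr)
    eff <- simulate_effects(n_snp, causal_prop, architecture, seed = sr)
    phen <- simulate_phenotype(geno$G, eff, sc)
    gw <- gwas_scan(geno$G, geno$variants, phen$y, "quantitative",
                    n_folds = 5L, seed = sr)
    fold <- gw[[1L]]
    set.seed(sr + 100000L)
    n_caus <- pmax(1L, round(sizes * stats::runif(length(sizes),
                                                  causal_frac_range[1],
                                                  causal_frac_range[2])))
    gs <- build_genes_and_sets(geno$variants, eff$causal_idx,
                               set_sizes = sizes, causal_counts = n_caus,
                               n_control_sets = n_control,
                               n_replicates = 1L, seed = sr + 200000L)
    mapping <- map_variants_to_genes(fold$variants, gs$genes)
    ld <- gene_ld_from_genotypes(geno$G[fold$train_idx, , drop = FALSE],
                                 mapping)
    gstats <- compute_gene_stats(fold$variants, gs$genes, ld)
    design <- gene_set_design(gs$sets, gstats$gene_id, drop_empty = TRUE)
    cfg <- sampler %||% sampler_config(seed = sr + 300000L)
    cfg$seed <- cfg$seed %||% (sr + 300000L)
    cfg$keep_samples <- FALSE
    fit <- fit_single(gstats$z, design, cfg)
    truth_match <- gs$truth[match(design$set_ids, gs$truth$set_id), ]
    raw[[r]] <- data.frame(replicate = r, set_id = design$set_ids,
                           pip = unname(fit$pip),
                           is_causal = truth_match$is_causal_set,
                           stringsAsFactors = FALSE)
  }
  raw <- do.call(rbind, raw)
  list(calibration = pip_calibration(raw, mode = "rank"), raw = raw)
}
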