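#' Define a phenotype simulation scenario
#'
#' Bundles the trait-level factors of the simulation design: heritability
#' (`h2` 0.1 or 0.3 in the study grid), proportion of causal variants
#' (`causal_prop` 0.01 or 0.001), genetic architecture (`GA1`: single normal
#' effect distribution; `GA2`: mixture of normals), trait type, and — for
#' binary traits — disease prevalence (0.05 or 0.15).
#'
#' @param h2 Heritability in (0, 1).
#' @param causal_prop Proportion of causal variants in (0, 1).
#' @param architecture `"GA1"` or `"GA2"`.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param prevalence Disease prevalence in (0, 1); required iff binary.
#' @param n_ind,n_snp Numbers of individuals and variants.
#' @param seed Integer seed driving the whole scenario.
#' @return Object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(h2, causal_prop,
                                architecture = c("GA1", "GA2"),
                                trait_type = c("quantitative", "binary"),
                                prevalence = NULL,
                                n_ind = 2000L, n_snp = 3000L, seed = 1L) {
  architecture <- match.arg(architecture)
  trait_type <- match.arg(trait_type)
  stopifnot(h2 > 0, h2 < 1, causal_prop > 0, causal_prop < 1,
            n_ind >= 2, n_snp >= 1)
  if (trait_type == "binary") {
    if (is.null(prevalence) || prevalence <= 0 || prevalence >= 1)
      stop_gsblr("binary traits require prevalence in (0, 1)",
                 class = "gsblr_argument_error")
  } else if (!is.null(prevalence)) {
    stop_gsblr("prevalence only applies to binary traits",
               class = "gsblr_argument_error")
  }
  structure(list(h2 = h2, causal_prop = causal_prop,
                 architecture = architecture, trait_type = trait_type,
                 prevalence = prevalence, n_ind = as.integer(n_ind),
                 n_snp = as.integer(n_snp), seed = as.integer(seed)),
            class = "simulation_scenario")
}

#' The full factorial scenario grid of the simulation design
#'
#' Crosses heritability \{0.3, 0.1\}, causal proportion \{0.001, 0.01\} and
#' architecture \{GA1, GA2\}, giving 8 quantitative scenarios; each binary
#' counterpart is further crossed with prevalence \{0.05, 0.15\}, giving 16
#' binary scenarios.
#'
#' @return A `data.frame` with one row per scenario and a `label` column
#'   (Sim1..Sim8 quantitative, sim1..sim16 binary).
#' @export
scenario_grid <- function() {
  base <- expand.grid(architecture = c("GA1", "GA2"),
                      causal_prop = c(0.001, 0.01),
                      h2 = c(0.3, 0.1),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base <- base[, c("h2", "causal_prop", "architecture")]
  quant <- cbind(base, trait_type = "quantitative", prevalence = NA_real_,
                 label = paste0("Sim", seq_len(nrow(base))))
  binr <- base[rep(seq_len(nrow(base)), each = 2L), ]
  binr$trait_type <- "binary"
  binr$prevalence <- rep(c(0.05, 0.15), times = nrow(base))
  binr$label <- paste0("sim", seq_len(nrow(binr)))
  out <- rbind(quant, binr)
  rownames(out) <- NULL
  out
}

#' Simulate block-correlated genotype dosages
#'
#' Generates 0/1/2 dosages for `n_ind` individuals at `n_snp` variants. Two
#' latent Gaussian haplotypes follow an AR(1) process (correlation `ld_rho`)
#' within blocks of `ld_block_size` consecutive SNPs and are independent
#' across blocks; each is thresholded at the allele frequency quantile for a
#' per-SNP MAF drawn uniformly in `[maf_low, maf_high]`, so genotypes are in
#' Hardy-Weinberg proportions with tetrachoric-induced LD that decays within a
#' block. Variants are placed on a synthetic map with blocks 1 Mb apart (SNPs
#' 1 kb apart within a block) so genes aligned to blocks do not capture their
#' neighbours' variants under the default mapping windows.
#'
#' @param n_ind,n_snp Dimensions.
#' @param maf_low,maf_high Per-SNP minor allele frequency range.
#' @param ld_block_size SNPs per LD block.
#' @param ld_rho AR(1) correlation of the latent process.
#' @param seed Integer seed.
#' @return List with `G` (n_ind x n_snp integer matrix) and `variants`
#'   (data frame: `variant_id`, `chrom`, `pos`, `a1`, `a2`, `maf`, `block`).
#' @export
simulate_genotypes <- function(n_ind, n_snp, maf_low = 0.01, maf_high = 0.5,
                               ld_block_size = 50L, ld_rho = 0.8, seed = 1L) {
  stopifnot(n_ind >= 1, n_snp >= 1, maf_low > 0, maf_high <= 0.5,
            maf_low <= maf_high, ld_block_size >= 1,
            ld_rho >= 0, ld_rho < 1)
  set.seed(seed)
  block <- ((seq_len(n_snp) - 1L) %/% ld_block_size) + 1L
  offset <- (seq_len(n_snp) - 1L) %% ld_block_size
  pos <- (block - 1L) * 1000000L + offset * 1000L + 1L
  maf <- stats::runif(n_snp, maf_low, maf_high)
  thr <- stats::qnorm(maf)
  G <- matrix(0L, n_ind, n_snp)
  a <- sqrt(1 - ld_rho^2)
  for (h in 1:2) {
    L <- matrix(stats::rnorm(n_ind * n_snp), n_ind, n_snp)
    for (j in seq_len(n_snp)[-1L]) {
      if (block[j] == block[j - 1L])
        L[, j] <- ld_rho * L[, j - 1L] + a * L[, j]
    }
    G <- G + (sweep(L, 2L, thr, `<`)) * 1L
  }
  variants <- data.frame(
    variant_id = paste0("snp", seq_len(n_snp)),
    chrom = "1", pos = pos, a1 = "A", a2 = "G",
    maf = maf, block = block, stringsAsFactors = FALSE)
  colnames(G) <- variants$variant_id
  list(G = G, variants = variants)
}

#' Simulate per-variant causal effects
#'
#' Each variant is causal independently with probability `causal_prop`
#' (expected count `causal_prop * n_snp`). Under GA1 causal effects are drawn
#' from a single standard normal; under GA2 from a 3-component normal mixture
#' (variances `ga2_variances`, weights `ga2_weights`), giving a heavier-tailed
#' architecture. Effects are rescaled later by [simulate_phenotype()] to hit
#' the target heritability, so only their relative magnitudes matter.
#'
#' @param n_snp Number of variants.
#' @param causal_prop Per-variant causal probability.
#' @param architecture `"GA1"` or `"GA2"`.
#' @param seed Integer seed.
#' @param ga2_variances,ga2_weights GA2 mixture parameters.
#' @return List with `beta` (length n_snp; zero for non-causal) and
#'   `causal_idx` (integer indices).
#' @export
simulate_effects <- function(n_snp, causal_prop,
                             architecture = c("GA1", "GA2"), seed = 1L,
                             ga2_variances = c(1, 0.1, 0.01),
                             ga2_weights = c(0.1, 0.2, 0.7)) {
  architecture <- match.arg(architecture)
  stopifnot(causal_prop > 0, causal_prop < 1,
            length(ga2_variances) == length(ga2_weights),
            all(ga2_weights > 0))
  set.seed(seed)
  causal <- which(stats::runif(n_snp) < causal_prop)
  if (length(causal) == 0L) causal <- which(stats::runif(n_snp) < causal_prop)
  if (length(causal) == 0L)
    stop_gsblr("no causal variants sampled after one resample; increase ",
               "causal_prop or n_snp", class = "gsblr_argument_error")
  k <- length(causal)
  eff <- if (architecture == "GA1") stats::rnorm(k) else {
    comp <- sample.int(length(ga2_weights), k, replace = TRUE,
                       prob = ga2_weights / sum(ga2_weights))
    stats::rnorm(k, sd = sqrt(ga2_variances[comp]))
  }
  beta <- numeric(n_snp)
  beta[causal] <- eff
  list(beta = beta, causal_idx = causal)
}

#' Simulate a phenotype from genotypes and effects
#'
#' Genetic values are `g = G_std %*% beta` on column-standardized dosages;
#' residuals are drawn with variance `var(g) * (1 - h2) / h2` so the realized
#' heritability matches the target. Binary traits use the liability threshold
#' model: the top `round(n * prevalence)` liabilities are cases (empirical
#' quantile, so the case fraction is exact).
#'
#' @param G Genotype dosage matrix.
#' @param effects Result of [simulate_effects()] (or a numeric effect vector).
#' @param scenario A [simulation_scenario()].
#' @return List with `y` (phenotype; 0/1 for binary), `liability`, `g`
#'   (genetic values), `h2_realized`.
#' @export
simulate_phenotype <- function(G, effects, scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  beta <- if (is.list(effects)) effects$beta else as.numeric(effects)
  stopifnot(ncol(G) == length(beta))
  set.seed(scenario$seed + 1L)
  nz <- which(beta != 0)
  if (length(nz) == 0L)
    stop_gsblr("all effects are zero", class = "gsblr_degenerate_error")
  Gc <- G[, nz, drop = FALSE]
  mu <- colMeans(Gc)
  sdv <- apply(Gc, 2, stats::sd)
  ok <- sdv > 0
  if (!any(ok))
    stop_gsblr("all causal variants are monomorphic: var(g) = 0",
               class = "gsblr_degenerate_error")
  Gs <- sweep(sweep(Gc[, ok, drop = FALSE], 2L, mu[ok]), 2L, sdv[ok], `/`)
  g <- as.numeric(Gs %*% beta[nz][ok])
  vg <- stats::var(g)
  if (vg == 0)
    stop_gsblr("var(g) = 0", class = "gsblr_degenerate_error")
  e <- stats::rnorm(nrow(G), 0, sqrt(vg * (1 - scenario$h2) / scenario$h2))
  liab <- g + e
  h2r <- vg / stats::var(liab)
  if (scenario$trait_type == "binary") {
    k <- max(1L, round(nrow(G) * scenario$prevalence))
    y <- as.integer(rank(-liab, ties.method = "first") <= k)
  } else {
    y <- liab
  }
  list(y = y, liability = liab, g = g, h2_realized = h2r)
}

#' Single-marker GWAS with cross-validation folds
#'
#' Partitions individuals into `n_folds` disjoint validation folds covering
#' everyone; for each fold the GWAS is run on the complementary training
#' subset (80% under the default 5 folds). Quantitative traits use per-SNP
#' simple linear regression (`z = beta_hat / se`); binary traits use per-SNP
#' logistic regression Wald z with a score-test fallback when the fit fails
#' to converge (e.g. quasi-separation). Monomorphic SNPs within a training
#' fold get `z = 0` and are flagged.
#'
#' @param G Genotype dosage matrix with variant ids as column names.
#' @param variants Variant metadata (from [simulate_genotypes()]).
#' @param y Phenotype vector (0/1 for binary).
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param n_folds Number of cross-validation folds (default 5, i.e. 80/20).
#' @param seed Integer seed for the fold partition.
#' @return List of folds; each fold is a list with `variants` (a
#'   variant-statistics data frame with `z`, `beta`, `se`, `n`,
#'   `monomorphic`), `train_idx`, `val_idx`.
#' @export
gwas_scan <- function(G, variants, y, trait_type = c("quantitative", "binary"),
                      n_folds = 5L, seed = 1L) {
  trait_type <- match.arg(trait_type)
  n <- nrow(G)
  stopifnot(length(y) == n, n_folds >= 2L)
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(n_folds), n))
  lapply(seq_len(n_folds), function(f) {
    val <- which(fold_of == f)
    trn <- which(fold_of != f)
    zres <- if (trait_type == "quantitative")
      .gwas_linear(G[trn, , drop = FALSE], y[trn])
    else
      .gwas_logistic(G[trn, , drop = FALSE], y[trn])
    vstats <- data.frame(
      variant_id = variants$variant_id, chrom = variants$chrom,
      pos = variants$pos, a1 = variants$a1, a2 = variants$a2,
      z = zres$z, beta = zres$beta, se = zres$se,
      n = length(trn), monomorphic = zres$mono,
      stringsAsFactors = FALSE)
    class(vstats) <- c("variant_stats", "data.frame")
    list(variants = vstats, train_idx = trn, val_idx = val)
  })
}

.gwas_linear <- function(G, y) {
  n <- nrow(G)
  yc <- y - mean(y)
  mu <- colMeans(G)
  Gxy <- as.numeric(crossprod(G, yc))                 # sum g*yc = sum gc*yc
  sxx <- as.numeric(colSums(G^2)) - n * mu^2
  mono <- sxx <= 0
  sxx_safe <- ifelse(mono, 1, sxx)
  beta <- Gxy / sxx_safe
  syy <- sum(yc^2)
  s2 <- pmax(0, (syy - beta * Gxy) / (n - 2))
  se <- sqrt(s2 / sxx_safe)
  z <- ifelse(mono | se == 0, 0, beta / se)
  list(z = z, beta = ifelse(mono, 0, beta), se = ifelse(mono, NA, se),
       mono = mono)
}

.gwas_logistic <- function(G, y) {
  p <- ncol(G); n <- nrow(G)
  z <- beta <- se <- numeric(p)
  mono <- logical(p)
  pbar <- mean(y)
  for (j in seq_len(p)) {
    g <- G[, j]
    if (stats::var(g) == 0) {
      mono[j] <- TRUE; z[j] <- 0; beta[j] <- 0; se[j] <- NA
      next
    }
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, g), y, family = stats::binomial()))
    ok <- fit$converged && all(is.finite(fit$coefficients)) &&
      abs(fit$coefficients[2L]) < 20
    if (ok) {
      # Wald z from the weighted information matrix
      w <- fit$weights
      XtWX <- crossprod(cbind(1, g) * sqrt(w))
      vc <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
      ok <- !is.null(vc) && vc[2L, 2L] > 0
      if (ok) {
        beta[j] <- fit$coefficients[2L]
        se[j] <- sqrt(vc[2L, 2L])
        z[j] <- beta[j] / se[j]
      }
    }
    if (!ok) {
      # score test under the null: robust to separation
      gc <- g - mean(g)
      U <- sum(gc * (y - pbar))
      V <- pbar * (1 - pbar) * sum(gc^2)
      z[j] <- U / sqrt(V)
      beta[j] <- NA; se[j] <- NA
    }
  }
  list(z = z, beta = beta, se = se, mono = mono)
}

#' Build synthetic genes and gene sets with truth labels
#'
#' Genes tile the synthetic map, one per LD block. Genes containing at least
#' one causal variant are causal genes; gene sets are assembled from requested
#' `(size, n_causal)` configurations (vectors recycled to equal length), each
#' replicated `n_replicates` times, by sampling the stated number of causal
#' and non-causal genes without replacement within a set (reuse across sets
#' gives the natural overlap of real pathway collections). `n_control_sets`
#' additional sets contain no causal genes.
#'
#' @param variants Variant metadata with a `block` column.
#' @param causal_idx Integer indices of causal variants.
#' @param set_sizes,causal_counts Configuration vectors (`causal_counts[i] <=
#'   set_sizes[i]`).
#' @param n_control_sets Number of extra all-non-causal sets (sizes sampled
#'   from `set_sizes`).
#' @param n_replicates Replicates per configuration.
#' @param seed Integer seed.
#' @return List with `genes` (gene records), `sets` ([gene_set_collection]),
#'   `truth` (data frame: `set_id`, `size`, `n_causal`, `is_causal_set`).
#' @export
build_genes_and_sets <- function(variants, causal_idx, set_sizes,
                                 causal_counts, n_control_sets = 0L,
                                 n_replicates = 1L, seed = 1L) {
  stopifnot("block" %in% names(variants), n_replicates >= 1L)
  cfg <- data.frame(size = as.integer(set_sizes),
                    n_causal = as.integer(causal_counts))
  if (any(cfg$n_causal > cfg$size) || any(cfg$size < 1L))
    stop_gsblr("invalid configuration: need 0 <= n_causal <= size",
               class = "gsblr_argument_error")
  set.seed(seed)
  genes <- .genes_from_blocks(variants)
  causal_blocks <- unique(variants$block[causal_idx])
  causal_genes <- genes$gene_id[genes$block %in% causal_blocks]
  other_genes <- setdiff(genes$gene_id, causal_genes)
  need_causal <- max(cfg$n_causal, 0L)
  need_other <- max(c(cfg$size - cfg$n_causal,
                      if (n_control_sets > 0L) max(cfg$size) else 0L))
  if (need_causal > length(causal_genes))
    stop_gsblr("configuration needs ", need_causal, " causal genes but only ",
               length(causal_genes), " exist", class = "gsblr_argument_error")
  if (need_other > length(other_genes))
    stop_gsblr("configuration needs ", need_other, " non-causal genes but ",
               "only ", length(other_genes), " exist",
               class = "gsblr_argument_error")
  ids <- character(0); members <- list(); truth <- list()
  for (i in seq_len(nrow(cfg))) {
    for (r in seq_len(n_replicates)) {
      sid <- sprintf("set%d_s%d_c%d_r%d", i, cfg$size[i], cfg$n_causal[i], r)
      g <- c(if (cfg$n_causal[i] > 0)
        sample(causal_genes, cfg$n_causal[i]) else character(0),
        sample(other_genes, cfg$size[i] - cfg$n_causal[i]))
      ids <- c(ids, sid); members <- c(members, list(g))
      truth[[sid]] <- data.frame(set_id = sid, size = cfg$size[i],
                                 n_causal = cfg$n_causal[i],
                                 is_causal_set = cfg$n_causal[i] > 0L)
    }
  }
  for (k in seq_len(n_control_sets)) {
    sid <- sprintf("ctrl%d", k)
    sz <- cfg$size[sample.int(nrow(cfg), 1L)]
    g <- sample(other_genes, sz)
    ids <- c(ids, sid); members <- c(members, list(g))
    truth[[sid]] <- data.frame(set_id = sid, size = sz, n_causal = 0L,
                               is_causal_set = FALSE)
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(genes = genes[, c("gene_id", "chrom", "start", "end", "strand", "block")],
       sets = gene_set_collection(ids, "simulated", members),
       truth = truth,
       causal_genes = causal_genes)
}

.genes_from_blocks <- function(variants) {
  agg_min <- tapply(variants$pos, variants$block, min)
  agg_max <- tapply(variants$pos, variants$block, max)
  blocks <- as.integer(names(agg_min))
  data.frame(gene_id = paste0("gene", blocks), chrom = "1",
             start = as.integer(agg_min), end = as.integer(agg_max),
             strand = "+", block = blocks, stringsAsFactors = FALSE)
}

#' Add overlapping or disjoint extra gene sets
#'
#' Extends a base collection with `n_extra` sets for the baseline-comparison
#' experiments. In `"correlated"` mode each extra set resamples a base set
#' and swaps a uniform 10-50% of its genes for random genes outside the set,
#' so extras share at least half their genes with their source. In
#' `"uncorrelated"` mode extras are drawn entirely from genes outside all
#' base sets (zero Jaccard overlap); an error is raised when too few outside
#' genes exist. Truth labels of the extras are recomputed from their causal
#' gene content.
#'
#' @param base_collection A [gene_set_collection].
#' @param base_truth Truth table of the base sets.
#' @param universe_genes Character vector of all gene ids.
#' @param causal_genes Character vector of causal gene ids.
#' @param n_extra Number of extra sets (default 191).
#' @param overlap_mode `"correlated"` or `"uncorrelated"`.
#' @param seed Integer seed.
#' @return List with `sets` (combined collection), `truth` (combined truth),
#'   `extra_ids`.
#' @export
build_overlapping_sets <- function(base_collection, base_truth,
                                   universe_genes, causal_genes,
                                   n_extra = 191L,
                                   overlap_mode = c("correlated",
                                                    "uncorrelated"),
                                   seed = 1L) {
  stopifnot(inherits(base_collection, "gene_set_collection"), n_extra >= 1L)
  overlap_mode <- match.arg(overlap_mode)
  set.seed(seed)
  n_base <- length(base_collection$set_id)
  base_genes <- unique(unlist(base_collection$genes))
  outside <- setdiff(universe_genes, base_genes)
  ids <- character(n_extra); members <- vector("list", n_extra)
  if (overlap_mode == "correlated") {
    src <- sample.int(n_base, n_extra, replace = TRUE)
    for (k in seq_len(n_extra)) {
      g0 <- base_collection$genes[[src[k]]]
      # swap 10-50% of the genes; cap at half so extras always share at
      # least 50% of their source set
      n_swap <- max(1L, min(floor(length(g0) / 2),
                            round(length(g0) * stats::runif(1, 0.1, 0.5))))
      keep <- sample(g0, length(g0) - n_swap)
      pool <- setdiff(universe_genes, g0)
      if (length(pool) < n_swap)
        stop_gsblr("not enough genes outside the source set to swap in",
                   class = "gsblr_argument_error")
      members[[k]] <- c(keep, sample(pool, n_swap))
      ids[k] <- sprintf("extra%d", k)
    }
  } else {
    sizes <- lengths(base_collection$genes)
    if (length(outside) < max(sizes))
      stop_gsblr("uncorrelated mode infeasible: only ", length(outside),
                 " genes outside the base sets but sets of size up to ",
                 max(sizes), " requested", class = "gsblr_argument_error")
    for (k in seq_len(n_extra)) {
      sz <- sizes[sample.int(length(sizes), 1L)]
      members[[k]] <- sample(outside, sz)
      ids[k] <- sprintf("extra%d", k)
    }
  }
  extra_truth <- do.call(rbind, lapply(seq_len(n_extra), function(k) {
    nc <- length(intersect(members[[k]], causal_genes))
    data.frame(set_id = ids[k], size = length(members[[k]]), n_causal = nc,
               is_causal_set = nc > 0L)
  }))
  combined <- gene_set_collection(
    c(base_collection$set_id, ids),
    c(base_collection$description, rep("extra", n_extra)),
    c(base_collection$genes, members))
  truth <- rbind(base_truth[, c("set_id", "size", "n_causal", "is_causal_set")],
                 extra_truth)
  rownames(truth) <- NULL
  list(sets = combined, truth = truth, extra_ids = ids)
}

#' Simulate a gene-set-level response directly
#'
#' Draws `y = X b + e` at the gene-set regression level: causal sets get a
#' fixed (or supplied) effect, all other effects are zero, residuals are
#' standard normal scaled by `sigma_e`. Used for sampler-level recovery and
#' power experiments where the genotype layer is not needed.
#'
#' @param design A [gene_set_design].
#' @param causal_sets Character ids (or integer indices) of causal sets.
#' @param effect_size Effect per causal set (scalar or vector).
#' @param sigma_e Residual standard deviation.
#' @param seed Integer seed.
#' @return List with `y`, `b` (true effects), `causal_sets`.
#' @export
simulate_set_response <- function(design, causal_sets, effect_size = 1,
                                  sigma_e = 1, seed = 1L) {
  stopifnot(inherits(design, "gene_set_design"))
  idx <- if (is.character(causal_sets))
    match(causal_sets, design$set_ids) else as.integer(causal_sets)
  if (any(is.na(idx)))
    stop_gsblr("unknown causal set id", class = "gsblr_argument_error")
  set.seed(seed)
  b <- numeric(ncol(design$X))
  b[idx] <- rep_len(effect_size, length(idx))
  y <- as.numeric(design$X %*% b) +
    stats::rnorm(nrow(design$X), 0, sigma_e)
  list(y = y, b = b, causal_sets = design$set_ids[idx])
}

#' Simulate correlated two-trait gene-set responses
#'
#' Shared causal sets receive effects drawn from a bivariate normal with
#' standard deviation `effect_sd` and correlation `effect_cor` across the two
#' traits; responses are `y_t = X b_t + e_t` with independent residuals.
#'
#' @param design A [gene_set_design].
#' @param causal_sets Causal set ids or indices (shared across traits).
#' @param effect_sd Effect standard deviation per trait.
#' @param effect_cor Effect correlation across traits.
#' @param sigma_e Residual standard deviation.
#' @param seed Integer seed.
#' @return List with `Y` (n x 2), `B` (m x 2 true effects), `causal_sets`.
#' @export
simulate_multitrait_response <- function(design, causal_sets,
                                         effect_sd = 1, effect_cor = 0.9,
                                         sigma_e = 1, seed = 1L) {
  stopifnot(inherits(design, "gene_set_design"),
            effect_cor >= -1, effect_cor <= 1)
  idx <- if (is.character(causal_sets))
    match(causal_sets, design$set_ids) else as.integer(causal_sets)
  set.seed(seed)
  k <- length(idx)
  z1 <- stats::rnorm(k); z2 <- stats::rnorm(k)
  b1 <- effect_sd * z1
  b2 <- effect_sd * (effect_cor * z1 + sqrt(1 - effect_cor^2) * z2)
  B <- matrix(0, ncol(design$X), 2L)
  B[idx, 1L] <- b1; B[idx, 2L] <- b2
  n <- nrow(design$X)
  Y <- design$X %*% B + matrix(stats::rnorm(2L * n, 0, sigma_e), n, 2L)
  colnames(Y) <- c("trait1", "trait2")
  list(Y = Y, B = B, causal_sets = design$set_ids[idx])
}

#' Empirical per-gene LD matrices from genotypes
#'
#' Computes the correlation matrix of the (training) genotype dosages for
#' each gene's mapped variants — the simulation's stand-in for a reference
#' panel. Monomorphic variants get zero off-diagonal correlation.
#'
#' @param G Genotype matrix with variant ids as column names.
#' @param mapping Gene-to-variant mapping from [map_variants_to_genes()].
#' @return Named list of [ld_matrix] objects.
#' @export
gene_ld_from_genotypes <- function(G, mapping) {
  lapply(mapping, function(vids) {
    K <- suppressWarnings(stats::cor(G[, vids, drop = FALSE]))
    K[!is.finite(K)] <- 0
    diag(K) <- 1
    ld_matrix(K, vids)
  })
}
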