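test_that("scenario construction enforces the design's constraints", {
  expect_error(simulation_scenario(h2 = 0.3, causal_prop = 0.01,
                                   trait_type = "binary"),
               class = "gsblr_argument_error")      # prevalence required
  expect_error(simulation_scenario(h2 = 0.3, causal_prop = 0.01,
                                   prevalence = 0.1),
               class = "gsblr_argument_error")      # only for binary
  sc <- simulation_scenario(0.3, 0.01, "GA1", "binary", prevalence = 0.05)
  expect_s3_class(sc, "simulation_scenario")
})

test_that("the full factorial grid has 8 quantitative and 16 binary scenarios", {
  g <- scenario_grid()
  expect_equal(sum(g$trait_type == "quantitative"), 8)
  expect_equal(sum(g$trait_type == "binary"), 16)
  expect_equal(sort(unique(g$h2)), c(0.1, 0.3))
  expect_equal(sort(unique(g$causal_prop)), c(0.001, 0.01))
  expect_setequal(unique(g$architecture), c("GA1", "GA2"))
  expect_equal(sort(unique(g$prevalence[g$trait_type == "binary"])),
               c(0.05, 0.15))
  # every row is constructible
  for (i in seq_len(nrow(g))) {
    sc <- simulation_scenario(
      g$h2[i], g$causal_prop[i], g$architecture[i], g$trait_type[i],
      prevalence = if (g$trait_type[i] == "binary") g$prevalence[i])
    expect_s3_class(sc, "simulation_scenario")
  }
})

test_that("genotypes respect allele-frequency bounds and block LD structure", {
  geno <- simulate_genotypes(n_ind = 5000, n_snp = 200, ld_block_size = 10,
                             ld_rho = 0.8, seed = 42)
  expect_true(all(geno$G %in% 0:2))
  emp_maf <- colMeans(geno$G) / 2
  expect_true(all(emp_maf >= 0.01 - 0.02 & emp_maf <= 0.5 + 0.02))
  # adjacent within-block correlation clearly positive, decaying with lag
  cors1 <- vapply(seq(1, 191, by = 10), function(j)
    cor(geno$G[, j], geno$G[, j + 1]), numeric(1))
  cors5 <- vapply(seq(1, 191, by = 10), function(j)
    cor(geno$G[, j], geno$G[, j + 5]), numeric(1))
  expect_gt(mean(cors1), 0.4)
  expect_gt(mean(cors1), mean(cors5))
  # cross-block correlation centred at zero
  crossb <- vapply(seq(10, 190, by = 10), function(j)
    cor(geno$G[, j], geno$G[, j + 1]), numeric(1))
  expect_lt(abs(mean(crossb)), 3 * stats::sd(crossb) / sqrt(length(crossb)))
  # determinism
  geno2 <- simulate_genotypes(5000, 200, ld_block_size = 10, ld_rho = 0.8,
                              seed = 42)
  expect_identical(geno$G, geno2$G)
})

test_that("effect architectures differ in tail weight as designed", {
  eff <- simulate_effects(100000, 0.001, "GA1", seed = 7)
  expect_gt(length(eff$causal_idx), 100 - 4 * sqrt(100))
  expect_lt(length(eff$causal_idx), 100 + 4 * sqrt(100))
  g1 <- simulate_effects(100000, 0.5, "GA1", seed = 8)
  g2 <- simulate_effects(100000, 0.5, "GA2", seed = 8)
  kurt <- function(x) mean((x - mean(x))^4) / stats::var(x)^2
  b1 <- g1$beta[g1$causal_idx]; b2 <- g2$beta[g2$causal_idx]
  expect_equal(kurt(b1), 3, tolerance = 0.2)
  expect_gt(kurt(b2), 4)     # mixture of normals is leptokurtic
  expect_identical(simulate_effects(1000, 0.01, "GA1", seed = 3)$beta,
                   simulate_effects(1000, 0.01, "GA1", seed = 3)$beta)
})

test_that("phenotypes hit the target heritability and prevalence", {
  geno <- simulate_genotypes(10000, 300, ld_block_size = 5, seed = 1)
  eff <- simulate_effects(300, 0.05, "GA1", seed = 1)
  sc <- simulation_scenario(0.3, 0.05, "GA1", "quantitative",
                            n_ind = 10000, n_snp = 300, seed = 1)
  ph <- simulate_phenotype(geno$G, eff, sc)
  expect_equal(ph$h2_realized, 0.3, tolerance = 0.02)
  # binary: exact case fraction by construction
  scb <- simulation_scenario(0.3, 0.05, "GA1", "binary", prevalence = 0.15,
                             n_ind = 10000, n_snp = 300, seed = 1)
  phb <- simulate_phenotype(geno$G, eff, scb)
  expect_equal(mean(phb$y), 0.15, tolerance = 1e-6)
  # h2 -> 1 limit: phenotype is the genetic value
  sch <- simulation_scenario(0.999, 0.05, "GA1", "quantitative",
                             n_ind = 10000, n_snp = 300, seed = 1)
  phh <- simulate_phenotype(geno$G, eff, sch)
  expect_gt(cor(phh$y, phh$g), 0.999)
})

test_that("GWAS folds partition individuals and give calibrated null z-scores", {
  geno <- simulate_genotypes(1500, 400, ld_block_size = 5, seed = 3)
  set.seed(3)
  y <- rnorm(1500)                      # pure noise phenotype
  gw <- gwas_scan(geno$G, geno$variants, y, "quantitative", n_folds = 5,
                  seed = 3)
  expect_length(gw, 5)
  vals <- lapply(gw, `[[`, "val_idx")
  expect_equal(sort(unlist(vals)), 1:1500)       # disjoint and covering
  expect_equal(length(unlist(vals)), length(unique(unlist(vals))))
  z <- gw[[1]]$variants$z
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)))
  expect_gt(stats::var(z), 0.9)
  expect_lt(stats::var(z), 1.1)
  # an injected strong effect ranks top within its block
  y2 <- y + 0.5 * scale(geno$G[, 200])[, 1]
  gw2 <- gwas_scan(geno$G, geno$variants, y2, "quantitative", seed = 3)
  blk <- geno$variants$block == geno$variants$block[200]
  expect_equal(which.max(abs(gw2[[1]]$variants$z[blk])),
               which(which(blk) == 200))
})

test_that("binary GWAS gives near-normal null z-scores via logistic fits", {
  geno <- simulate_genotypes(800, 60, ld_block_size = 5, seed = 5)
  set.seed(5)
  y <- rbinom(800, 1, 0.15)
  gw <- gwas_scan(geno$G, geno$variants, y, "binary", n_folds = 5, seed = 5)
  z <- gw[[1]]$variants$z
  expect_true(all(is.finite(z)))
  expect_lt(abs(mean(z)), 0.5)
  expect_gt(stats::var(z), 0.6)
  expect_lt(stats::var(z), 1.5)
})

test_that("gene sets are assembled to the requested causal composition", {
  geno <- simulate_genotypes(50, 500, ld_block_size = 5, seed = 9)
  eff <- simulate_effects(500, 0.05, "GA1", seed = 9)
  gs <- build_genes_and_sets(geno$variants, eff$causal_idx,
                             set_sizes = c(10, 20), causal_counts = c(5, 0),
                             n_control_sets = 8, n_replicates = 3, seed = 9)
  expect_equal(length(gs$sets$set_id), 2 * 3 + 8)
  cfg1 <- gs$truth[gs$truth$size == 10 & gs$truth$set_id != "", ]
  first <- gs$sets$genes[[1]]
  expect_equal(length(first), 10)
  expect_equal(sum(first %in% gs$causal_genes), 5)
  expect_equal(sum(!gs$truth$is_causal_set), 3 + 8)
  ctrl_genes <- unlist(gs$sets$genes[grepl("^ctrl", gs$sets$set_id)])
  expect_false(any(ctrl_genes %in% gs$causal_genes))
  # determinism
  gs2 <- build_genes_and_sets(geno$variants, eff$causal_idx,
                              set_sizes = c(10, 20), causal_counts = c(5, 0),
                              n_control_sets = 8, n_replicates = 3, seed = 9)
  expect_identical(gs$sets$genes, gs2$sets$genes)
  # infeasible configuration names the shortfall
  expect_error(build_genes_and_sets(geno$variants, eff$causal_idx,
                                    set_sizes = 1000, causal_counts = 0,
                                    seed = 9),
               "non-causal", class = "gsblr_argument_error")
})

test_that("overlapping extras share genes with sources; disjoint extras do not", {
  geno <- simulate_genotypes(50, 500, ld_block_size = 5, seed = 10)
  eff <- simulate_effects(500, 0.04, "GA1", seed = 10)
  gs <- build_genes_and_sets(geno$variants, eff$causal_idx,
                             set_sizes = 15, causal_counts = 5,
                             n_control_sets = 5, n_replicates = 2, seed = 10)
  ext <- build_overlapping_sets(gs$sets, gs$truth, gs$genes$gene_id,
                                gs$causal_genes, n_extra = 30,
                                overlap_mode = "correlated", seed = 10)
  expect_length(ext$extra_ids, 30)
  base_sets <- gs$sets$genes
  for (k in seq_along(ext$extra_ids)) {
    eg <- ext$sets$genes[[length(base_sets) + k]]
    shares <- vapply(base_sets, function(b)
      length(intersect(eg, b)) / length(eg), numeric(1))
    expect_gte(max(shares), 0.5)    # each extra keeps >= 50% of its source
  }
  ext2 <- build_overlapping_sets(gs$sets, gs$truth, gs$genes$gene_id,
                                 gs$causal_genes, n_extra = 10,
                                 overlap_mode = "uncorrelated", seed = 10)
  base_genes <- unique(unlist(base_sets))
  for (k in seq_along(ext2$extra_ids)) {
    eg <- ext2$sets$genes[[length(base_sets) + k]]
    expect_length(intersect(eg, base_genes), 0)   # zero Jaccard overlap
  }
  # truth labels recomputed from causal-gene content
  lab <- ext$truth[match(ext$extra_ids, ext$truth$set_id), ]
  ov <- vapply(seq_along(ext$extra_ids), function(k)
    length(intersect(ext$sets$genes[[length(base_sets) + k]],
                     gs$causal_genes)), integer(1))
  expect_equal(lab$n_causal, ov)
  expect_equal(lab$is_causal_set, ov > 0)
})

test_that("null GWAS z-scores pass a KS test against N(0,1) in most seeds", {
  pass <- vapply(1:10, function(sd) {
    geno <- simulate_genotypes(600, 120, ld_block_size = 5, seed = sd)
    set.seed(sd + 1000)
    y <- rnorm(600)
    z <- gwas_scan(geno$G, geno$variants, y, "quantitative",
                   seed = sd)[[1]]$variants$z
    suppressWarnings(stats::ks.test(z, "pnorm")$p.value) > 0.01
  }, logical(1))
  expect_gte(sum(pass), 9)
})
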