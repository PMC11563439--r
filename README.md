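# gsblr — gene-set prioritization from GWAS summary statistics

`gsblr` prioritizes gene sets (biological pathways) for association with
complex traits using GWAS summary statistics and LD reference information
only — no individual-level genotypes. It is aimed at statistical geneticists
who have per-variant z-scores for one or more traits, a gene annotation, a
pathway collection (GMT), and per-gene LD matrices, and want a ranked,
probabilistically interpretable list of trait-associated pathways.

## The method

**Stage 1 — gene-level statistics.** Variants are mapped to genes (gene body
plus 35 kb upstream / 10 kb downstream, strand-aware). For each gene the
VEGAS-type statistic is the sum of squared variant z-scores,

    T_g = sum_i z_i^2 ,   Z ~ N(0, K) under the null,

whose null distribution is the eigenvalue-weighted chi-square mixture
`sum_i lambda_i * chisq_1` with `lambda_i` from the LD matrix `K`. The
survival probability is evaluated exactly (chi-square for homogeneous
spectra, Imhof inversion centrally) with a Kuonen saddlepoint in the far
tail, and converted to a probit Z-score `z_g = qnorm(1 - p_g)`.

**Stage 2 — spike-and-slab regression.** Gene Z-scores are regressed on the
binary gene-by-set membership matrix `X` with a BayesC prior:

    y = X b + e ,   b_j = 0 with prob (1 - pi),  b_j ~ N(0, sigma_b^2) with prob pi .

Gibbs sampling (3000 iterations, 500 burn-in by default) yields a
**posterior inclusion probability (PIP)** per gene set — the prioritization
score. Sets with PIP >= 0.1 and a non-negative posterior mean effect are
reported as associated. A multi-trait extension with inverse-Wishart priors
on the effect and residual covariance matrices lets correlated traits borrow
strength; a MAGMA-style joint linear regression is included as the
comparison baseline, along with a full synthetic-data generator, evaluation
metrics (precision/recall/F1, top-k recovery, PIP calibration, prediction
accuracy) and exact hypergeometric enrichment tests against external disease
gene lists. The methods vignette (`vignettes/gene-set-prioritization.Rmd`)
documents the models, priors, numerical choices and limitations.

## Worked example

Simulate a small study (2500 individuals, 500 genes, one pathway of 20 genes
containing 10 causal genes planted among 49 null pathways), run the whole
workflow, and prioritize:

```r
library(gsblr)
res <- run_prioritization(list(
  seed = 42, out_dir = "demo",
  simulate = list(n_ind = 2500, n_snp = 2500, snps_per_gene = 5,
                  causal_prop = 0.004, set_sizes = 20, causal_counts = 10,
                  n_control_sets = 49),
  model = list(n_iter = 3000, burn_in = 500),
  prioritize = list(pip_threshold = 0.1)))

head(res$gene_stats[order(res$gene_stats$p), ], 3)
#>     gene_id chrom     start       end n_snps     T        p    z
#> 259 gene259     1 258000001 258004001      5 117.1 4.60e-13 7.14
#> 108 gene108     1 107000001 107004001      5  93.7 1.48e-10 6.30
#> 19   gene19     1  18000001  18004001      5  89.6 2.76e-10 6.20

res$fit
#> blr_fit: 50 sets, 500 genes
#>   pi_mean = 0.04128  sigma_b2 = 30.28  sigma_e2 = 1.453
#>   sets with PIP >= 0.1: 1

res$prioritized
#>            set_id   pip b_mean rank
#> 1 set1_s20_c10_r1 0.902   1.04    1
```

The planted causal pathway is the only set passing the association rule:
its PIP of 0.902 says the model places 90% posterior probability on this
set having a non-zero effect on the gene Z-scores, and the positive mean
effect (+1.04) says its member genes score above the genomic baseline. The
strongest genes (`gene259`, p = 4.6e-13) are members. An enrichment check of
the top set against an external gene list uses the exact hypergeometric
test:

```r
hypergeom_enrichment(set_genes, disease_genes, universe_genes)
#>            set_id universe_size set_size list_size overlap  p_value
#> 1 set1_s20_c10_r1           500       20        37       9 2.33e-06
```

Real data enter through the same surface: `read_gwas()` (TSV with z or
beta/se columns), `read_gtf_genes()`, `read_gmt()`, per-gene LD matrices via
`read_ld_matrix()` or a directory of `<gene_id>.ld` files, then
`compute_gene_stats()` → `fit_single()` / `fit_multi()` → `prioritize()`.
A command-line interface wrapping these functions is provided at
`inst/cli/gsblr.R` (`Rscript inst/cli/gsblr.R fit --genestats gs.tsv
--gmt sets.gmt --seed 1 --out fit.tsv`).

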