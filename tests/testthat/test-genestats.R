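test_that("gene quadratic statistic is the sum of squared z-scores", {
  expect_equal(gene_quadratic_stat(c(0, 0, 0)), 0)
  expect_equal(gene_quadratic_stat(1.96), 3.8416)
  expect_equal(gene_quadratic_stat(c(1, 2, 2)), 9)
  expect_error(gene_quadratic_stat(numeric(0)), class = "gsblr_argument_error")
  expect_error(gene_quadratic_stat(c(1, NA)), class = "gsblr_argument_error")
})

test_that("quadform p-value reduces to the chi-square survival for equal weights", {
  # identity-LD genes of every size up to 50, random q values
  set.seed(11)
  for (p in c(1, 2, 5, 17, 50)) {
    for (q in stats::rchisq(4, df = p)) {
      expect_equal(quadform_pvalue(q, rep(1, p)),
                   stats::pchisq(q, df = p, lower.tail = FALSE),
                   tolerance = 1e-8)
    }
  }
  expect_equal(quadform_pvalue(3.8416, 1), 0.05, tolerance = 1e-4)
  expect_equal(quadform_pvalue(0, c(0.3, 0.7)), 1)
  expect_error(quadform_pvalue(1, c(0, 0)), class = "gsblr_degenerate_error")
})

test_that("saddlepoint agrees with the frozen 1e7-draw Monte-Carlo oracle", {
  # oracle computed once with seed 777123:
  #   qmc <- 1.6*rchisq(1e7,1) + 0.4*rchisq(1e7,1); mean(qmc > 4)
  p_mc <- 0.139513
  expect_equal(quadform_pvalue(4, c(1.6, 0.4)), p_mc, tolerance = 0.02 * p_mc)
})

test_that("saddlepoint p is monotone in q and invariant to variant order", {
  lam <- c(2.5, 1.2, 0.6, 0.1)
  qs <- seq(0.5, 30, length.out = 12)
  ps <- vapply(qs, quadform_pvalue, numeric(1), lambdas = lam)
  expect_true(all(diff(ps) < 0))
  # permuting the spectrum (and so the variants) changes nothing
  expect_equal(quadform_pvalue(7, lam), quadform_pvalue(7, rev(lam)))
})

test_that("probit gene Z-score handles interior and extreme p-values", {
  expect_equal(gene_z(0.5), 0)
  expect_equal(gene_z(0.05), stats::qnorm(0.95), tolerance = 1e-9)
  expect_true(is.finite(gene_z(1)))          # capped, not -Inf
  expect_lt(gene_z(1), -8)
  expect_true(is.finite(gene_z(1e-320)))     # floored at 1e-300
  expect_equal(gene_z(1e-320), gene_z(1e-300))
  expect_error(gene_z(0), class = "gsblr_argument_error")
  expect_error(gene_z(1.1), class = "gsblr_argument_error")
})

test_that("variant-gene mapping applies strand-aware windows", {
  genes <- data.frame(gene_id = c("plus", "minus"), chrom = "1",
                      start = c(1000, 100000), end = c(2000, 101000),
                      strand = c("+", "-"))
  vpos <- c(970, 2010, 12001, 99000, 101030, 136001)
  variants <- data.frame(variant_id = paste0("v", seq_along(vpos)),
                         chrom = "1", pos = vpos, a1 = "A", a2 = "G",
                         z = 1, n = NA)
  mp <- suppressMessages(map_variants_to_genes(variants, genes,
                                               up_bp = 35000, down_bp = 10000))
  # + gene: upstream 35kb ok, downstream 10kb ok, 12001 is 1bp past the window
  expect_equal(mp$plus, c("v1", "v2"))
  # - gene: downstream window is below start, upstream above end
  expect_true(all(c("v4", "v5") %in% mp$minus))
  expect_false("v6" %in% mp$minus)   # 35001bp past the end
})

test_that("compute_gene_stats matches chi-square oracles on tiny genes", {
  genes <- data.frame(gene_id = c("g1", "g2", "gnone"), chrom = "1",
                      start = c(1000, 50000, 900000),
                      end = c(1000, 50100, 900100), strand = "+")
  variants <- data.frame(variant_id = c("a", "b", "c"), chrom = "1",
                         pos = c(1000, 50000, 50100), a1 = "A", a2 = "G",
                         z = c(2, 2, 2), n = NA)
  ld <- list(g1 = ld_matrix(matrix(1), "a"),
             g2 = ld_matrix(matrix(c(1, 1, 1, 1), 2), c("b", "c")))
  gs <- suppressMessages(
    compute_gene_stats(variants, genes, ld, up_bp = 0, down_bp = 0))
  # single-SNP gene: T = z^2, chi-square(1) p, probit z
  r1 <- gs[gs$gene_id == "g1", ]
  expect_equal(r1$T, 4)
  expect_equal(r1$p, stats::pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-9)
  expect_equal(r1$z, stats::qnorm(r1$p, lower.tail = FALSE), tolerance = 1e-9)
  # two perfectly correlated SNPs: rank-1 spectrum (2, 0) -> chi2_1 at T/2
  r2 <- gs[gs$gene_id == "g2", ]
  expect_equal(r2$T, 8)
  expect_equal(r2$p, stats::pchisq(8 / 2, 1, lower.tail = FALSE),
               tolerance = 1e-9)
  # gene with no variants is absent
  expect_false("gnone" %in% gs$gene_id)
})

test_that("gene statistics are invariant to variant order within a gene", {
  set.seed(21)
  A <- matrix(rnorm(25), 5)
  K <- stats::cov2cor(crossprod(A) + diag(5))
  ids <- paste0("v", 1:5)
  z <- rnorm(5, 1)
  genes <- data.frame(gene_id = "g", chrom = "1", start = 1, end = 5000,
                      strand = "+")
  perm <- c(3, 1, 5, 2, 4)
  mk <- function(ord) {
    variants <- data.frame(variant_id = ids[ord], chrom = "1",
                           pos = (1:5)[ord] * 1000, a1 = "A", a2 = "G",
                           z = z[ord], n = NA)
    ld <- list(g = ld_matrix(K[ord, ord], ids[ord]))
    compute_gene_stats(variants, genes, ld, up_bp = 0, down_bp = 0)
  }
  g1 <- mk(1:5)
  g2 <- mk(perm)
  expect_equal(g1$T, g2$T)
  expect_equal(g1$p, g2$p, tolerance = 1e-12)
  expect_equal(g1$z, g2$z, tolerance = 1e-9)
})

test_that("missing LD skips the gene unless strict mode is on", {
  genes <- data.frame(gene_id = "g1", chrom = "1", start = 100, end = 200,
                      strand = "+")
  variants <- data.frame(variant_id = "a", chrom = "1", pos = 150,
                         a1 = "A", a2 = "G", z = 1, n = NA)
  expect_warning(gs <- compute_gene_stats(variants, genes, list(),
                                          up_bp = 0, down_bp = 0),
                 "missing")
  expect_equal(nrow(gs), 0)
  expect_error(
    suppressWarnings(compute_gene_stats(variants, genes, list(),
                                        up_bp = 0, down_bp = 0,
                                        strict = TRUE)),
    class = "gsblr_ld_error")
})

test_that("eigen spectrum drops near-null directions but keeps the trace", {
  K <- matrix(c(1, 1, 1, 1), 2)           # rank 1
  lam <- eigen_spectrum(K)
  expect_equal(lam, 2)
  set.seed(5)
  A <- matrix(rnorm(36), 6)
  K2 <- stats::cov2cor(crossprod(A) + diag(6))
  lam2 <- eigen_spectrum(K2)
  expect_equal(sum(lam2), sum(diag(K2)), tolerance = 1e-6)
  expect_true(all(diff(lam2) <= 0))
})
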