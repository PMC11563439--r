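#' MAGMA-style joint linear gene-set regression
#'
#' Ordinary least squares of the gene z-scores on an intercept, optional
#' gene-level covariates, and all gene-set membership columns fitted jointly —
#' the comparison method for the Bayesian model. Per-set p-values are
#' one-sided (`H1: beta_j > 0`), matching the competitive-enrichment
#' direction and mirroring the negative-effect exclusion of the Bayesian
#' rule. Rank-deficient designs are handled by pivoted least squares; aliased
#' columns are reported as `NA`. This is a transparent stand-in for MAGMA's
#' gene-set regression, not a re-implementation of its gene-analysis
#' internals.
#'
#' @param y Numeric vector of gene z-scores aligned with `design$gene_ids`.
#' @param design A [gene_set_design].
#' @param covariates Optional n x c numeric matrix of gene-level covariates
#'   (e.g. from [default_covariates()]).
#' @return Object of class `joint_linear_fit` with `set_ids`, `beta`, `se`,
#'   `t_stat`, `p_one_sided`, `covariate_names`, `covariate_coef`, `df_residual`.
#' @export
fit_joint_linear <- function(y, design, covariates = NULL) {
  stopifnot(inherits(design, "gene_set_design"))
  y <- as.numeric(y)
  X <- design$X
  n <- nrow(X); m <- ncol(X)
  if (length(y) != n)
    stop_gsblr("length(y) does not match the design",
               class = "gsblr_argument_error")
  cc <- 0L
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    cc <- ncol(covariates)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("covar", seq_len(cc))
  }
  if (n <= m + cc + 1L)
    stop_gsblr("under-determined fit: n = ", n, " genes but ", m + cc + 1L,
               " coefficients (deficit ", m + cc + 2L - n, ")",
               class = "gsblr_underdetermined_error")
  M <- cbind(`(Intercept)` = 1, covariates, X)
  fit <- stats::lm.fit(M, y)
  coefs <- fit$coefficients                       # NA for aliased columns
  dfres <- n - fit$rank
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / dfres
  # standard errors from the pivoted R factor of the QR decomposition
  piv <- fit$qr$pivot[seq_len(fit$rank)]
  R <- fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE]
  R[lower.tri(R)] <- 0
  XtXinv <- chol2inv(R)
  se_all <- rep(NA_real_, ncol(M))
  se_all[piv] <- sqrt(diag(XtXinv) * sigma2)
  names(se_all) <- colnames(M)
  tval <- coefs / se_all
  pval <- stats::pt(tval, df = dfres, lower.tail = FALSE)
  set_idx <- (1L + cc) + seq_len(m)
  structure(list(set_ids = design$set_ids,
                 beta = unname(coefs[set_idx]),
                 se = unname(se_all[set_idx]),
                 t_stat = unname(tval[set_idx]),
                 p_one_sided = unname(pval[set_idx]),
                 covariate_names = colnames(M)[seq_len(1L + cc)],
                 covariate_coef = unname(coefs[seq_len(1L + cc)]),
                 df_residual = dfres, sigma2 = sigma2),
            class = "joint_linear_fit")
}

#' @export
print.joint_linear_fit <- function(x, ...) {
  cat("joint_linear_fit:", length(x$set_ids), "sets, residual df",
      x$df_residual, "\n")
  cat("  sets with one-sided p < 0.05:", sum(x$p_one_sided < 0.05, na.rm = TRUE),
      "(", sum(is.na(x$beta)), "aliased )\n")
  invisible(x)
}

#' Default gene-level covariates for the linear baseline
#'
#' The confounders the joint regression conditions on: log number of SNPs per
#' gene and log gene length (basepairs).
#'
#' @param gene_stats Gene-statistics table from [compute_gene_stats()] (needs
#'   `n_snps`, `start`, `end`).
#' @return Numeric matrix with columns `log_nsnps`, `log_length`.
#' @export
default_covariates <- function(gene_stats) {
  cbind(log_nsnps = log(gene_stats$n_snps),
        log_length = log(gene_stats$end - gene_stats$start + 1))
}

#' Rank gene sets by baseline p-value
#'
#' Ascending one-sided p, ties broken by `|t|` descending then set id;
#' aliased (NA) sets rank last.
#'
#' @param result A [fit_joint_linear()] result.
#' @return Character vector of set ids, best first.
#' @export
rank_by_pvalue <- function(result) {
  stopifnot(inherits(result, "joint_linear_fit"))
  p <- result$p_one_sided
  a <- abs(result$t_stat)
  ord <- order(is.na(p), p, -ifelse(is.na(a), -Inf, a), result$set_ids)
  result$set_ids[ord]
}
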