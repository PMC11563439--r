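#' Align per-trait gene statistics into a multi-trait response
#'
#' Builds the n-genes x t-traits response matrix Y of gene z-scores from a
#' list of gene-statistics tables (one per trait, as produced by
#' [compute_gene_stats()]). Genes missing a statistic for any trait are
#' dropped (complete-case) with a logged count.
#'
#' @param gene_stats_list Named list of gene-statistics data frames; names are
#'   the trait ids.
#' @return List with `trait_ids`, `gene_ids`, `Y` (class
#'   `multi_trait_response`).
#' @export
multi_trait_response <- function(gene_stats_list) {
  stopifnot(is.list(gene_stats_list), length(gene_stats_list) >= 2L)
  trait_ids <- names(gene_stats_list) %||%
    paste0("trait", seq_along(gene_stats_list))
  common <- Reduce(intersect, lapply(gene_stats_list, `[[`, "gene_id"))
  n_all <- length(unique(unlist(lapply(gene_stats_list, `[[`, "gene_id"))))
  if (length(common) == 0L)
    stop_gsblr("no genes shared across all traits",
               class = "gsblr_validation_error")
  if (n_all > length(common))
    gsblr_log("multi_trait_response: dropped ", n_all - length(common),
              " gene(s) not present for every trait (complete-case)")
  Y <- vapply(gene_stats_list, function(gs)
    gs$z[match(common, gs$gene_id)], numeric(length(common)))
  dimnames(Y) <- list(common, trait_ids)
  if (any(!is.finite(Y)))
    stop_gsblr("non-finite gene z-scores in response",
               class = "gsblr_validation_error")
  structure(list(trait_ids = trait_ids, gene_ids = common, Y = Y),
            class = "multi_trait_response")
}

#' Configuration for the multi-trait BLR model
#'
#' Extends [sampler_config()] with inverse-Wishart priors on the t x t effect
#' covariance `V_B` and residual covariance `V_E`, and the inclusion model for
#' the per-set trait-configuration indicator. With
#' `inclusion_model = "combination"` a set may affect any of the 2^t trait
#' combinations (Dirichlet(1) prior over configurations; restricted to
#' t <= 5); with `"per-trait"` each trait's indicator is independent with its
#' own Beta-updated inclusion probability. When `S_B`/`S_E` are `NULL` they
#' are scale-matched per trait at fit time so the prior means are
#' `0.5 * var(y_t) / (m * pi)` and `0.5 * var(y_t)`.
#'
#' @inheritParams sampler_config
#' @param nu_B,S_B Inverse-Wishart degrees of freedom (> t - 1; default
#'   t + 3) and t x t positive-definite scale for `V_B`.
#' @param nu_E,S_E Same for `V_E`.
#' @param inclusion_model `"combination"` or `"per-trait"`.
#' @param diagonal_cov Constrain `V_B` and `V_E` to be diagonal; the per-trait
#'   variances are then sampled from scaled inverse chi-square full
#'   conditionals with the single-trait defaults, so the model factorizes into
#'   independent single-trait fits when combined with `"per-trait"` inclusion.
#' @param estimate_VB,estimate_VE Sample the covariances? If `FALSE` they stay
#'   fixed at their initial values.
#' @param VB_init,VE_init Initial (or fixed) covariance matrices.
#' @return Object of class `multi_trait_config`.
#' @export
multi_trait_config <- function(n_iter = 3000L, burn_in = 500L,
                               pi_prior = 0.001,
                               nu_B = NULL, S_B = NULL,
                               nu_E = NULL, S_E = NULL,
                               inclusion_model = c("combination", "per-trait"),
                               diagonal_cov = FALSE,
                               estimate_VB = TRUE, estimate_VE = TRUE,
                               VB_init = NULL, VE_init = NULL,
                               estimate_pi = TRUE, seed = NULL,
                               keep_samples = TRUE) {
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  if (burn_in >= n_iter || burn_in < 0L)
    stop_gsblr("need 0 <= burn_in < n_iter", class = "gsblr_config_error")
  if (pi_prior <= 0 || pi_prior >= 1)
    stop_gsblr("pi_prior must lie in (0, 1)", class = "gsblr_config_error")
  inclusion_model <- match.arg(inclusion_model)
  structure(list(n_iter = n_iter, burn_in = burn_in, pi_prior = pi_prior,
                 nu_B = nu_B, S_B = S_B, nu_E = nu_E, S_E = S_E,
                 inclusion_model = inclusion_model,
                 diagonal_cov = diagonal_cov,
                 estimate_VB = estimate_VB, estimate_VE = estimate_VE,
                 VB_init = VB_init, VE_init = VE_init,
                 estimate_pi = estimate_pi, seed = seed,
                 keep_samples = keep_samples),
            class = "multi_trait_config")
}

.check_pd <- function(S, name, t) {
  if (!is.matrix(S) || nrow(S) != t || ncol(S) != t)
    stop_gsblr(name, " must be a ", t, "x", t, " matrix",
               class = "gsblr_config_error")
  if (max(abs(S - t(S))) > 1e-8 ||
      inherits(tryCatch(chol(S), error = function(e) e), "error"))
    stop_gsblr(name, " must be symmetric positive definite",
               class = "gsblr_config_error")
  (S + t(S)) / 2
}

#' Fit the multi-trait spike-and-slab gene-set model
#'
#' Gibbs sampler for the multi-trait BayesC model: each column of the
#' response (one trait's gene z-scores, centered internally) follows
#' `y_t = X b_t + e_t`, rows of the residual matrix are iid `N(0, V_E)`, and
#' each set's effect vector `b_j` is `N(0, V_B)` on its active traits and
#' zero elsewhere, with the active-trait configuration `delta_j` sampled from
#' its marginal full conditional (active effects integrated out). `V_B` and
#' `V_E` are drawn from inverse-Wishart full conditionals, so information is
#' borrowed across correlated traits. The per-trait PIP is the post-burn-in
#' mean of `delta_j[t]`.
#'
#' @param Y A [multi_trait_response()] or an n x t numeric matrix with column
#'   names as trait ids, row order matching `design$gene_ids`.
#' @param design A [gene_set_design].
#' @param config A [multi_trait_config()].
#' @return Object of class `mt_blr_fit` with `set_ids`, `trait_ids`, `pip`
#'   (m x t), `pip_any`, `B_mean` (m x t), `V_B_mean`, `V_E_mean`, `samples`,
#'   `diagnostics`.
#' @export
fit_multi <- function(Y, design, config = multi_trait_config()) {
  stopifnot(inherits(design, "gene_set_design"),
            inherits(config, "multi_trait_config"))
  if (inherits(Y, "multi_trait_response")) {
    trait_ids <- Y$trait_ids
    stopifnot(identical(Y$gene_ids, design$gene_ids))
    Y <- Y$Y
  } else {
    Y <- as.matrix(Y)
    trait_ids <- colnames(Y) %||% paste0("trait", seq_len(ncol(Y)))
  }
  n <- nrow(design$X); m <- ncol(design$X); t <- ncol(Y)
  if (nrow(Y) != n)
    stop_gsblr("response has ", nrow(Y), " genes but design has ", n,
               class = "gsblr_argument_error")
  if (t == 1L)
    stop_gsblr("single-column response: use fit_single()",
               class = "gsblr_argument_error")
  if (t > 9L)
    stop_gsblr("at most 9 traits supported", class = "gsblr_argument_error")
  if (config$inclusion_model == "combination" && t > 5L)
    stop_gsblr("combination inclusion model restricted to t <= 5; ",
               "use inclusion_model = 'per-trait'", class = "gsblr_config_error")
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  vy <- apply(Yc, 2, stats::var)
  vy[vy <= 0] <- 1
  nu_B <- config$nu_B %||% (t + 3)
  nu_E <- config$nu_E %||% (t + 3)
  if (nu_B <= t - 1 || nu_E <= t - 1)
    stop_gsblr("inverse-Wishart degrees of freedom must exceed t - 1",
               class = "gsblr_config_error")
  S_B <- config$S_B %||% diag(0.5 * vy / (m * config$pi_prior) * (nu_B - t - 1),
                              t)
  S_E <- config$S_E %||% diag(0.5 * vy * (nu_E - t - 1), t)
  S_B <- .check_pd(S_B, "S_B", t); S_E <- .check_pd(S_E, "S_E", t)
  VB0 <- config$VB_init %||% diag(0.5 * vy / (m * config$pi_prior), t)
  VE0 <- config$VE_init %||% diag(0.5 * vy, t)
  VB0 <- .check_pd(VB0, "VB_init", t); VE0 <- .check_pd(VE0, "VE_init", t)
  # diagonal mode: per-trait scaled inverse chi-square, single-trait defaults
  nu_b_diag <- 4; nu_e_diag <- 4
  Sb_diag <- .scale_from_mode(0.5 * vy / (m * config$pi_prior), nu_b_diag)
  Se_diag <- .scale_from_mode(0.5 * vy, nu_e_diag)

  if (!is.null(config$seed)) set.seed(config$seed)
  res <- blr_multi_gibbs(Yc, design$X, config$n_iter, config$burn_in,
                         config$pi_prior, config$estimate_pi,
                         config$inclusion_model == "combination",
                         config$diagonal_cov,
                         S_B, nu_B, config$estimate_VB, VB0,
                         S_E, nu_E, config$estimate_VE, VE0,
                         Sb_diag, nu_b_diag, Se_diag, nu_e_diag,
                         config$keep_samples)
  dimnames(res$pip) <- list(design$set_ids, trait_ids)
  dimnames(res$B_mean) <- list(design$set_ids, trait_ids)
  dimnames(res$V_B_mean) <- dimnames(res$V_E_mean) <- list(trait_ids, trait_ids)
  diagnostics <- list(
    V_E = c(ess = ess(res$samples_VE_diag[, 1]),
            rhat = split_rhat(res$samples_VE_diag[, 1])),
    max_rhat = max(apply(res$samples_VE_diag, 2, split_rhat), na.rm = TRUE))
  structure(list(set_ids = design$set_ids, trait_ids = trait_ids,
                 pip = res$pip,
                 pip_any = stats::setNames(as.numeric(res$pip_any),
                                           design$set_ids),
                 B_mean = res$B_mean,
                 V_B_mean = res$V_B_mean, V_E_mean = res$V_E_mean,
                 samples = list(VB_diag = res$samples_VB_diag,
                                VE_diag = res$samples_VE_diag,
                                B = res$B_samples),
                 diagnostics = diagnostics,
                 n_genes = n, config = config),
            class = "mt_blr_fit")
}

#' @export
print.mt_blr_fit <- function(x, ...) {
  cat("mt_blr_fit:", length(x$set_ids), "sets,", x$n_genes, "genes,",
      length(x$trait_ids), "traits\n")
  cat("  sets with PIP >= 0.1 in >= 1 trait:", sum(x$pip_any >= 0.1), "\n")
  invisible(x)
}

#' Rank associated gene sets per trait, with a cross-trait summary
#'
#' Applies the association rule per trait (see [prioritize()]): negative
#' posterior mean effects are excluded per trait, sets with
#' `PIP >= pip_threshold` are ranked by PIP. The cross-trait table flags sets
#' passing the threshold in at least one trait.
#'
#' @param result A [fit_multi()] result.
#' @param pip_threshold PIP cutoff (default 0.1).
#' @param exclude_negative Drop negative-effect sets from each trait's list.
#' @return List with `per_trait` (named list of ranked data frames) and
#'   `cross_trait` (data frame with per-trait PIPs and an `associated` flag).
#' @export
prioritize_multi <- function(result, pip_threshold = 0.1,
                             exclude_negative = TRUE) {
  stopifnot(inherits(result, "mt_blr_fit"))
  if (pip_threshold < 0 || pip_threshold > 1)
    stop_gsblr("pip_threshold must lie in [0, 1]",
               class = "gsblr_argument_error")
  per_trait <- lapply(seq_along(result$trait_ids), function(tt) {
    df <- data.frame(set_id = result$set_ids, pip = result$pip[, tt],
                     b_mean = result$B_mean[, tt], stringsAsFactors = FALSE)
    if (exclude_negative) df <- df[df$b_mean >= 0, , drop = FALSE]
    df <- df[df$pip >= pip_threshold, , drop = FALSE]
    df <- df[order(-df$pip, -abs(df$b_mean), df$set_id), , drop = FALSE]
    if (nrow(df)) df$rank <- seq_len(nrow(df))
    rownames(df) <- NULL
    df
  })
  names(per_trait) <- result$trait_ids
  pass <- matrix(FALSE, nrow = length(result$set_ids),
                 ncol = length(result$trait_ids))
  for (tt in seq_along(per_trait))
    pass[match(per_trait[[tt]]$set_id, result$set_ids), tt] <- TRUE
  cross <- data.frame(set_id = result$set_ids, result$pip,
                      pip_any = unname(result$pip_any),
                      associated = rowSums(pass) > 0,
                      stringsAsFactors = FALSE, check.names = FALSE)
  rownames(cross) <- NULL
  list(per_trait = per_trait, cross_trait = cross)
}
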