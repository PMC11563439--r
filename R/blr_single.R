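#' Sampler configuration for the single-trait BLR model
#'
#' Holds the MCMC and prior settings of the BayesC spike-and-slab gene-set
#' model. Defaults follow the reference analysis protocol: 3000 iterations
#' with a 500-iteration burn-in, prior inclusion probability `pi = 0.001`
#' (estimated from the data by default via its Beta/Dirichlet full
#' conditional with concentration `alpha = c(1, 1)`), and weakly informative
#' scaled inverse chi-square priors on the effect and residual variances.
#' When `S_b`/`S_e` are `NULL` they are scale-matched to the response at fit
#' time: the prior mode of `sigma_b^2` is set to `0.5 * var(y) / (m * pi)` and
#' the prior mode of `sigma_e^2` to `0.5 * var(y)`.
#'
#' @param n_iter Total Gibbs iterations (default 3000).
#' @param burn_in Burn-in iterations discarded from summaries (default 500).
#' @param pi_prior Prior (or fixed) inclusion probability in (0,1).
#' @param nu_b,S_b Degrees of freedom and scale of the inverse chi-square
#'   prior on the effect variance `sigma_b^2`.
#' @param nu_e,S_e Degrees of freedom and scale of the inverse chi-square
#'   prior on the residual variance `sigma_e^2`.
#' @param alpha Dirichlet concentration for the 2-component mixture
#'   proportions (default `c(1, 1)`).
#' @param seed Integer seed; `NULL` leaves the RNG stream untouched.
#' @param estimate_pi Sample `pi` from Beta(m1 + alpha[1], m0 + alpha[2])?
#'   If `FALSE`, `pi` stays fixed at `pi_prior`.
#' @param estimate_sigma_b2,estimate_sigma_e2 Sample the variances from their
#'   full conditionals? If `FALSE` they stay fixed at their initial values.
#' @param sigma_b2_init,sigma_e2_init Initial (or fixed) variance values;
#'   `NULL` uses the prior modes.
#' @param keep_samples Retain post-burn-in effect samples (needed for
#'   diagnostics and posterior intervals).
#' @param n_chains Number of independent chains (seeded `seed`, `seed + 1`,
#'   ...); summaries pool chains, split-Rhat uses them.
#' @return Object of class `sampler_config`.
#' @export
sampler_config <- function(n_iter = 3000L, burn_in = 500L, pi_prior = 0.001,
                           nu_b = 4, S_b = NULL, nu_e = 4, S_e = NULL,
                           alpha = c(1, 1), seed = NULL,
                           estimate_pi = TRUE,
                           estimate_sigma_b2 = TRUE, estimate_sigma_e2 = TRUE,
                           sigma_b2_init = NULL, sigma_e2_init = NULL,
                           keep_samples = TRUE, n_chains = 1L) {
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  if (n_iter <= 0L || burn_in < 0L || burn_in >= n_iter)
    stop_gsblr("need 0 <= burn_in < n_iter", class = "gsblr_config_error")
  if (pi_prior <= 0 || pi_prior >= 1)
    stop_gsblr("pi_prior must lie in (0, 1)", class = "gsblr_config_error")
  stopifnot(nu_b > 0, nu_e > 0, length(alpha) == 2L, all(alpha > 0),
            n_chains >= 1L)
  structure(list(n_iter = n_iter, burn_in = burn_in, pi_prior = pi_prior,
                 nu_b = nu_b, S_b = S_b, nu_e = nu_e, S_e = S_e,
                 alpha = alpha, seed = seed, estimate_pi = estimate_pi,
                 estimate_sigma_b2 = estimate_sigma_b2,
                 estimate_sigma_e2 = estimate_sigma_e2,
                 sigma_b2_init = sigma_b2_init, sigma_e2_init = sigma_e2_init,
                 keep_samples = keep_samples, n_chains = as.integer(n_chains)),
            class = "sampler_config")
}

# Prior mode of a scaled inverse chi-square(nu, S) is nu*S/(nu + 2);
# invert to get S from a target mode.
.scale_from_mode <- function(mode, nu) mode * (nu + 2) / nu

#' Fit the single-trait spike-and-slab gene-set model
#'
#' Gibbs sampler for the BayesC model `y = X b + e` with
#' `b_j = 0` with probability `1 - pi` and `b_j ~ N(0, sigma_b^2)` with
#' probability `pi`. The response is centered internally (intercept); the
#' binary design is used raw so effects keep the "enrichment above baseline"
#' sign interpretation. Each sweep updates, in fixed column order, the
#' inclusion indicator `d_j` from its Bernoulli full conditional with `b_j`
#' marginalized, then `b_j` given `d_j`; the variances are drawn from scaled
#' inverse chi-square full conditionals and `pi` from
#' Beta(m1 + 1, m0 + 1). The PIP of a set is the post-burn-in mean of `d_j`.
#'
#' @param y Numeric vector of gene z-scores, aligned with `design$gene_ids`.
#' @param design A [gene_set_design].
#' @param config A [sampler_config].
#' @return Object of class `blr_fit` with elements `set_ids`, `pip`,
#'   `b_mean`, `b_samples` (post-burn-in draws, if kept), `sigma_b2_mean`,
#'   `sigma_e2_mean`, `pi_mean`, `samples` (variance / pi traces) and
#'   `diagnostics` (per-parameter effective sample size and split-Rhat).
#' @export
fit_single <- function(y, design, config = sampler_config()) {
  stopifnot(inherits(design, "gene_set_design"),
            inherits(config, "sampler_config"))
  y <- as.numeric(y)
  n <- nrow(design$X); m <- ncol(design$X)
  if (length(y) != n)
    stop_gsblr("length(y) = ", length(y), " but design has ", n, " genes",
               class = "gsblr_argument_error")
  if (any(!is.finite(y)))
    stop_gsblr("non-finite values in y", class = "gsblr_validation_error")
  if (m == 0L) stop_gsblr("design has zero sets", class = "gsblr_argument_error")
  yc <- y - mean(y)
  vy <- stats::var(yc)
  if (vy <= 0) vy <- 1   # constant response: fall back to unit scale priors
  S_b <- config$S_b %||% .scale_from_mode(0.5 * vy / (m * config$pi_prior),
                                          config$nu_b)
  S_e <- config$S_e %||% .scale_from_mode(0.5 * vy, config$nu_e)
  sb2_0 <- config$sigma_b2_init %||% (config$nu_b * S_b / (config$nu_b + 2))
  se2_0 <- config$sigma_e2_init %||% (config$nu_e * S_e / (config$nu_e + 2))

  run_chain <- function(seed) {
    if (!is.null(seed)) set.seed(seed)
    blr_single_gibbs(yc, design$X, config$n_iter, config$burn_in,
                     config$pi_prior, config$estimate_pi,
                     config$alpha[1], config$alpha[2],
                     config$nu_b, S_b, config$estimate_sigma_b2, sb2_0,
                     config$nu_e, S_e, config$estimate_sigma_e2, se2_0,
                     config$keep_samples)
  }
  seeds <- if (is.null(config$seed)) rep(list(NULL), config$n_chains) else
    as.list(config$seed + seq_len(config$n_chains) - 1L)
  chains <- lapply(seeds, run_chain)

  pip <- Reduce(`+`, lapply(chains, `[[`, "pip")) / length(chains)
  b_mean <- Reduce(`+`, lapply(chains, `[[`, "b_mean")) / length(chains)
  sb2 <- unlist(lapply(chains, `[[`, "sigma_b2"))
  se2 <- unlist(lapply(chains, `[[`, "sigma_e2"))
  piv <- unlist(lapply(chains, `[[`, "pi"))
  b_samples <- if (config$keep_samples)
    do.call(rbind, lapply(chains, `[[`, "b_samples")) else NULL

  diagnostics <- .blr_diagnostics(chains, design$set_ids, config$keep_samples)
  structure(list(set_ids = design$set_ids,
                 pip = stats::setNames(as.numeric(pip), design$set_ids),
                 b_mean = stats::setNames(as.numeric(b_mean), design$set_ids),
                 b_samples = b_samples,
                 sigma_b2_mean = mean(sb2), sigma_e2_mean = mean(se2),
                 pi_mean = mean(piv),
                 samples = list(sigma_b2 = sb2, sigma_e2 = se2, pi = piv),
                 diagnostics = diagnostics,
                 n_genes = n, config = config),
            class = "blr_fit")
}

.blr_diagnostics <- function(chains, set_ids, kept) {
  scalars <- c("sigma_b2", "sigma_e2", "pi")
  out <- lapply(scalars, function(p) {
    mat <- do.call(cbind, lapply(chains, `[[`, p))
    c(ess = sum(apply(mat, 2, ess)), rhat = split_rhat(mat))
  })
  names(out) <- scalars
  if (kept) {
    bs <- lapply(chains, `[[`, "b_samples")
    b_ess <- rowSums(vapply(bs, function(b) apply(b, 2, ess),
                            numeric(ncol(bs[[1]]))))
    b_rhat <- vapply(seq_len(ncol(bs[[1]])), function(j)
      split_rhat(do.call(cbind, lapply(bs, function(b) b[, j]))), numeric(1))
    out$b <- data.frame(set_id = set_ids, ess = b_ess, rhat = b_rhat)
    out$max_rhat <- max(c(vapply(out[scalars], `[`, numeric(1), "rhat"),
                          b_rhat), na.rm = TRUE)
  } else {
    out$max_rhat <- max(vapply(out[scalars], `[`, numeric(1), "rhat"),
                        na.rm = TRUE)
  }
  out
}

#' @export
print.blr_fit <- function(x, ...) {
  cat("blr_fit:", length(x$set_ids), "sets,", x$n_genes, "genes\n")
  cat("  pi_mean =", signif(x$pi_mean, 4),
      " sigma_b2 =", signif(x$sigma_b2_mean, 4),
      " sigma_e2 =", signif(x$sigma_e2_mean, 4), "\n")
  cat("  sets with PIP >= 0.1:", sum(x$pip >= 0.1), "\n")
  invisible(x)
}

#' Rank associated gene sets by posterior inclusion probability
#'
#' Applies the association rule used for reporting: gene sets with a negative
#' posterior mean effect are enriched for non-associated genes and are
#' excluded (when `exclude_negative`); the remaining sets with
#' `PIP >= pip_threshold` are returned sorted by PIP (descending), ties broken
#' by `|b_mean|` (descending) then set id.
#'
#' @param result A [fit_single()] result (`blr_fit`).
#' @param pip_threshold PIP cutoff in `[0, 1]` (default 0.1).
#' @param exclude_negative Drop sets with negative posterior mean effect.
#' @return A `data.frame` with columns `set_id`, `pip`, `b_mean`, `rank`.
#' @export
prioritize <- function(result, pip_threshold = 0.1, exclude_negative = TRUE) {
  stopifnot(inherits(result, "blr_fit"))
  if (pip_threshold < 0 || pip_threshold > 1)
    stop_gsblr("pip_threshold must lie in [0, 1]",
               class = "gsblr_argument_error")
  df <- data.frame(set_id = result$set_ids, pip = unname(result$pip),
                   b_mean = unname(result$b_mean), stringsAsFactors = FALSE)
  if (exclude_negative) df <- df[df$b_mean >= 0, , drop = FALSE]
  df <- df[df$pip >= pip_threshold, , drop = FALSE]
  ord <- order(-df$pip, -abs(df$b_mean), df$set_id)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}
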