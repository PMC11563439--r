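test_that("sampler configuration is validated", {
  expect_error(sampler_config(n_iter = 100, burn_in = 100),
               class = "gsblr_config_error")
  expect_error(sampler_config(pi_prior = 0), class = "gsblr_config_error")
  expect_s3_class(sampler_config(), "sampler_config")
})

test_that("fit_single validates its inputs", {
  des <- toy_design()
  expect_error(fit_single(rnorm(10), des), class = "gsblr_argument_error")
  expect_error(fit_single(c(rnorm(59), NA), des),
               class = "gsblr_validation_error")
})

test_that("identical inputs and seed give bitwise-identical results", {
  des <- random_design(m = 15, n = 120, size = 10, seed = 2)
  set.seed(9); y <- rnorm(120) + as.numeric(des$X %*% rbinom(15, 1, 0.2))
  cfg <- sampler_config(n_iter = 800, burn_in = 200, seed = 31,
                        keep_samples = FALSE)
  f1 <- fit_single(y, des, cfg)
  f2 <- fit_single(y, des, cfg)
  expect_identical(f1$pip, f2$pip)
  expect_identical(f1$b_mean, f2$b_mean)
  expect_identical(f1$samples, f2$samples)
})

test_that("Gibbs PIPs match exact submodel enumeration on small problems", {
  # interior-probability case: sets cover only part of the gene universe,
  # moderate noise, fixed variances, fixed pi = 0.5
  gc <- gene_set_collection(paste0("S", 1:3), "d",
                            list(paste0("g", 1:15), paste0("g", 16:30),
                                 paste0("g", 31:45)))
  des <- gene_set_design(gc, paste0("g", 1:60))
  set.seed(8)
  y <- as.numeric(des$X %*% c(0.6, 0.25, 0)) + rnorm(60, 0, 1)
  oracle <- enum_pip(y, des$X, 0.5, 1, 1)
  fit <- fit_single(y, des, sampler_config(
    n_iter = 20000, burn_in = 1000, pi_prior = 0.5, estimate_pi = FALSE,
    estimate_sigma_b2 = FALSE, estimate_sigma_e2 = FALSE,
    sigma_b2_init = 1, sigma_e2_init = 1, seed = 99, keep_samples = FALSE))
  expect_lt(max(abs(unname(fit$pip) - oracle)), 0.02)
})

test_that("duplicated set columns split the inclusion the enumeration predicts", {
  gc <- gene_set_collection(c("A", "Adup", "B"), "d",
                            list(paste0("g", 1:15), paste0("g", 1:15),
                                 paste0("g", 31:45)))
  des <- gene_set_design(gc, paste0("g", 1:60))
  set.seed(3)
  y <- as.numeric(des$X[, 1] * 1.2) + rnorm(60, 0, 1)
  oracle <- enum_pip(y, des$X, 0.5, 1, 1)
  fit <- fit_single(y, des, sampler_config(
    n_iter = 20000, burn_in = 1000, pi_prior = 0.5, estimate_pi = FALSE,
    estimate_sigma_b2 = FALSE, estimate_sigma_e2 = FALSE,
    sigma_b2_init = 1, sigma_e2_init = 1, seed = 5, keep_samples = FALSE))
  expect_lt(max(abs(unname(fit$pip) - oracle)), 0.02)
  # each duplicate's individual PIP is below the PIP of a single copy
  gc1 <- gene_set_collection(c("A", "B"), "d",
                             list(paste0("g", 1:15), paste0("g", 31:45)))
  des1 <- gene_set_design(gc1, paste0("g", 1:60))
  single <- enum_pip(y, des1$X, 0.5, 1, 1)
  expect_lt(oracle[1], single[1])
  expect_lt(oracle[2], single[1])
})

test_that("with full inclusion the posterior mean is the ridge solution", {
  set.seed(5)
  des <- random_design(m = 20, n = 200, size = 30, seed = 5)
  y <- rnorm(200) + as.numeric(des$X %*% rnorm(20, 0, 0.3))
  sb2 <- 0.25; se2 <- 1
  fit <- fit_single(y, des, sampler_config(
    n_iter = 30000, burn_in = 2000, pi_prior = 1 - 1e-12,
    estimate_pi = FALSE, estimate_sigma_b2 = FALSE,
    estimate_sigma_e2 = FALSE, sigma_b2_init = sb2, sigma_e2_init = se2,
    seed = 77, keep_samples = FALSE))
  yc <- y - mean(y)
  ridge <- solve(crossprod(des$X) + diag(se2 / sb2, 20),
                 crossprod(des$X, yc))
  rel <- sqrt(sum((unname(fit$b_mean) - ridge)^2) / sum(ridge^2))
  expect_lt(rel, 0.01)
})

test_that("a null response keeps effects near zero and PIPs at the pi level", {
  des <- random_design(m = 30, n = 300, size = 15, seed = 4)
  y <- rep(0, 300)
  fit <- fit_single(y, des, sampler_config(seed = 10, keep_samples = FALSE))
  expect_true(all(abs(fit$b_mean) < 0.05))
  # near-flat slab: average PIP tracks the posterior mean of pi
  fit2 <- fit_single(rnorm(300), des, sampler_config(
    pi_prior = 0.5, estimate_sigma_b2 = FALSE, estimate_sigma_e2 = FALSE,
    sigma_b2_init = 0.001, sigma_e2_init = 1, seed = 11,
    keep_samples = FALSE))
  expect_lt(abs(mean(fit2$pip) - fit2$pi_mean), 0.05)
})

test_that("permuting set columns permutes the PIPs identically", {
  set.seed(12)
  genes <- paste0("g", 1:150)
  members <- lapply(1:10, function(j) sample(genes, 12))
  ids <- paste0("S", 1:10)
  y <- rnorm(150) + as.numeric(
    gene_set_design(gene_set_collection(ids, "d", members), genes)$X %*%
      c(1.5, rep(0, 9)))
  perm <- sample(10)
  d1 <- gene_set_design(gene_set_collection(ids, "d", members), genes)
  d2 <- gene_set_design(gene_set_collection(ids[perm], "d", members[perm]),
                        genes)
  cfg <- sampler_config(n_iter = 6000, burn_in = 500, seed = 8,
                        keep_samples = FALSE)
  f1 <- fit_single(y, d1, cfg)
  f2 <- fit_single(y, d2, cfg)
  # same sets keep the same posterior up to Monte-Carlo error
  expect_lt(max(abs(unname(f1$pip[ids[perm]]) - unname(f2$pip))), 0.06)
})

test_that("PIP ranking recovers planted causal sets", {
  des <- random_design(m = 200, n = 1000, size = 20, seed = 200)
  aucs <- vapply(1:3, function(sd) {
    sim <- simulate_set_response(des, paste0("S", 1:10), effect_size = 1,
                                 sigma_e = 1, seed = sd)
    f <- fit_single(sim$y, des, sampler_config(seed = sd,
                                               keep_samples = FALSE))
    ranking_auc(unname(f$pip), seq_len(200) <= 10)
  }, numeric(1))
  expect_gt(mean(aucs), 0.9)
})

test_that("prioritize applies the PIP threshold and negative-effect exclusion", {
  fake <- structure(list(set_ids = c("A", "B"), pip = c(A = 0.9, B = 0.05),
                         b_mean = c(A = 1, B = 1)), class = "blr_fit")
  expect_equal(prioritize(fake)$set_id, "A")
  fake2 <- structure(list(set_ids = c("A", "B"), pip = c(A = 0.9, B = 0.9),
                          b_mean = c(A = 1, B = -1)), class = "blr_fit")
  expect_equal(prioritize(fake2)$set_id, "A")
  expect_equal(prioritize(fake2, exclude_negative = FALSE)$set_id, c("A", "B"))
  # threshold 0 keeps everything, ordered by pip then |effect| then id
  fake3 <- structure(list(set_ids = c("A", "B", "C"),
                          pip = c(A = 0.2, B = 0.2, C = 0.5),
                          b_mean = c(A = 0.1, B = 0.4, C = 0.2)),
                     class = "blr_fit")
  out <- prioritize(fake3, pip_threshold = 0, exclude_negative = FALSE)
  expect_equal(out$set_id, c("C", "B", "A"))
  expect_error(prioritize(fake3, pip_threshold = 2),
               class = "gsblr_argument_error")
})

test_that("diagnostics report effective sample sizes and split-Rhat", {
  des <- toy_design()
  set.seed(2)
  y <- rnorm(60)
  fit <- fit_single(y, des, sampler_config(n_iter = 1200, burn_in = 200,
                                           seed = 3, n_chains = 2))
  expect_true(all(c("sigma_b2", "sigma_e2", "pi", "b", "max_rhat") %in%
                    names(fit$diagnostics)))
  expect_true(is.finite(fit$diagnostics$max_rhat))
  expect_equal(nrow(fit$b_samples), 2 * 1000)
})
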