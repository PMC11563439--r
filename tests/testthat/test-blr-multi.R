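test_that("multi-trait configuration and response validation", {
  expect_error(multi_trait_config(n_iter = 10, burn_in = 10),
               class = "gsblr_config_error")
  des <- toy_design()
  y <- rnorm(60)
  expect_error(fit_multi(matrix(y, ncol = 1), des),
               class = "gsblr_argument_error")  # single trait -> fit_single
  bad <- multi_trait_config(S_B = matrix(c(1, 2, 2, 1), 2))  # not PD
  expect_error(fit_multi(cbind(y, y), des, bad),
               class = "gsblr_config_error")
})

test_that("complete-case alignment drops genes missing a trait", {
  gs1 <- data.frame(gene_id = paste0("g", 1:5), z = rnorm(5))
  gs2 <- data.frame(gene_id = paste0("g", 2:5), z = rnorm(4))
  mt <- suppressMessages(multi_trait_response(list(t1 = gs1, t2 = gs2)))
  expect_equal(mt$gene_ids, paste0("g", 2:5))
  expect_equal(dim(mt$Y), c(4, 2))
})

test_that("identical traits receive identical PIPs up to Monte-Carlo error", {
  des <- random_design(m = 20, n = 200, size = 15, seed = 6)
  sim <- simulate_set_response(des, paste0("S", 1:2), effect_size = 1,
                               sigma_e = 1, seed = 2)
  diffs <- vapply(1:6, function(sd) {
    f <- fit_multi(cbind(a = sim$y, b = sim$y), des,
                   multi_trait_config(n_iter = 1500, burn_in = 300,
                                      seed = sd, keep_samples = FALSE))
    mean(abs(f$pip[, 1] - f$pip[, 2]))
  }, numeric(1))
  expect_lt(mean(diffs), 3 * stats::sd(diffs) / sqrt(length(diffs)) + 0.02)
})

test_that("independent null traits keep pip_any near the prior inclusion level", {
  des <- random_design(m = 40, n = 300, size = 15, seed = 7)
  res <- vapply(1:5, function(sd) {
    set.seed(sd)
    Y <- matrix(rnorm(600), 300, 2)
    f <- fit_multi(Y, des, multi_trait_config(seed = sd + 100,
                                              keep_samples = FALSE))
    mean(f$pip_any)
  }, numeric(1))
  # no set should light up under pure noise
  expect_lt(mean(res), 0.05)
})

test_that("correlated traits borrow strength over single-trait fits", {
  des <- random_design(m = 100, n = 1000, size = 20, seed = 500)
  gains <- vapply(1:4, function(sd) {
    sim <- simulate_multitrait_response(des, paste0("S", 1:10),
                                        effect_sd = 0.5, effect_cor = 0.9,
                                        sigma_e = 1, seed = sd)
    mt <- fit_multi(sim$Y, des, multi_trait_config(seed = sd,
                                                   keep_samples = FALSE))
    s1 <- fit_single(sim$Y[, 1], des, sampler_config(seed = sd,
                                                     keep_samples = FALSE))
    s2 <- fit_single(sim$Y[, 2], des, sampler_config(seed = sd,
                                                     keep_samples = FALSE))
    mean(mt$pip[1:10, ]) - mean(c(s1$pip[1:10], s2$pip[1:10]))
  }, numeric(1))
  expect_gt(mean(gains), 0)
})

test_that("diagonal covariances with per-trait indicators reduce to single-trait fits", {
  des <- random_design(m = 20, n = 100, size = 10, seed = 42)
  sim <- simulate_multitrait_response(des, paste0("S", 1:3), effect_sd = 1,
                                      effect_cor = 0, sigma_e = 1, seed = 9)
  diffs <- vapply(1:4, function(sd) {
    mt <- fit_multi(sim$Y, des, multi_trait_config(
      inclusion_model = "per-trait", diagonal_cov = TRUE, seed = sd,
      keep_samples = FALSE))
    s1 <- fit_single(sim$Y[, 1], des, sampler_config(seed = sd + 50,
                                                     keep_samples = FALSE))
    s2 <- fit_single(sim$Y[, 2], des, sampler_config(seed = sd + 90,
                                                     keep_samples = FALSE))
    max(abs(c(mt$pip[, 1] - s1$pip, mt$pip[, 2] - s2$pip)))
  }, numeric(1))
  expect_lt(mean(diffs), 0.05)
})

test_that("permuting trait order permutes the result columns", {
  des <- random_design(m = 15, n = 150, size = 10, seed = 3)
  sim <- simulate_multitrait_response(des, paste0("S", 1:3), effect_sd = 1,
                                      effect_cor = 0.5, sigma_e = 1, seed = 4)
  Y <- sim$Y
  cfg <- multi_trait_config(n_iter = 6000, burn_in = 500, seed = 5,
                            keep_samples = FALSE)
  f12 <- fit_multi(Y, des, cfg)
  f21 <- fit_multi(Y[, 2:1], des, cfg)
  expect_lt(max(abs(unname(f12$pip[, 1]) - unname(f21$pip[, 2]))), 0.06)
  expect_lt(max(abs(unname(f12$pip[, 2]) - unname(f21$pip[, 1]))), 0.06)
})

test_that("sampled residual covariance stays symmetric positive definite", {
  des <- random_design(m = 10, n = 100, size = 10, seed = 8)
  set.seed(3)
  Y <- matrix(rnorm(200), 100, 2)
  f <- fit_multi(Y, des, multi_trait_config(n_iter = 800, burn_in = 100,
                                            seed = 6, keep_samples = FALSE))
  expect_equal(f$V_E_mean, t(f$V_E_mean))
  expect_true(all(eigen(f$V_E_mean, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
  expect_true(all(f$samples$VE_diag > 0))
})

test_that("prioritize_multi flags association per trait and overall", {
  fake <- structure(list(
    set_ids = c("A", "B", "C"), trait_ids = c("t1", "t2"),
    pip = matrix(c(0.2, 0.05, 0.3, 0.05, 0.05, 0.4), 3, 2,
                 dimnames = list(c("A", "B", "C"), c("t1", "t2"))),
    pip_any = c(A = 0.22, B = 0.08, C = 0.5),
    B_mean = matrix(c(1, 1, 1, 1, 1, -1), 3, 2)), class = "mt_blr_fit")
  out <- prioritize_multi(fake)
  expect_equal(out$per_trait$t1$set_id, c("C", "A"))
  expect_equal(out$per_trait$t2$set_id, character(0))  # C negative in t2
  expect_equal(out$cross_trait$associated, c(TRUE, FALSE, TRUE))
  # all below threshold -> nothing associated
  fake$pip[] <- 0.01
  out2 <- prioritize_multi(fake)
  expect_false(any(out2$cross_trait$associated))
})
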