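# Fitting protocol, model averaging, bootstrap and shared-parameter tests.
# Simulation sizes here are kept small; the acceptance suite runs the larger
# calibration experiments.

fast_ctl <- list(n_nodes = 96, factr = 1e8)

test_that("fitting exact expected counts recovers the generating parameters", {
  truth <- dfe_params(b = 0.4, S_d = -1000, eps_anc = 0.05, theta = 0.008)
  pair <- exact_pair(truth, 40, 1e5, 4e4)
  f <- fit_dfe(pair, dfe_model_spec(FALSE, TRUE), n_starts = 1,
               control = list(round_counts = FALSE, factr = 1e5))
  expect_lt(abs(f$mle_params$b / truth$b - 1), 1e-3)
  expect_lt(abs(f$mle_params$S_d / truth$S_d - 1), 1e-2)
  expect_lt(abs(f$mle_params$eps_anc - truth$eps_anc), 1e-3)
  expect_lt(abs(f$mle_params$theta / truth$theta - 1), 1e-3)
  expect_true(f$converged)
  expect_false(f$near_bound)
  expect_equal(f$aic, 2 * f$n_free_params - 2 * f$loglik)
})

test_that("fits are bit-identical across reruns with the same seed", {
  truth <- dfe_params(b = 0.6, S_d = -300, theta = 0.008)
  d <- simulate_sfs_dataset(truth, n = 20, L_sel = 2e4, L_neut = 1e4, seed = 4)
  f1 <- fit_dfe(d$sfs_pair, dfe_model_spec(FALSE, FALSE), n_starts = 3,
                seed = 11, control = fast_ctl)
  f2 <- fit_dfe(d$sfs_pair, dfe_model_spec(FALSE, FALSE), n_starts = 3,
                seed = 11, control = fast_ctl)
  expect_identical(f1$mle_params, f2$mle_params)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("AIC weights follow the closed form and averaged scalars stay within per-model extremes", {
  # fabricate four fits differing only in AIC
  base <- function(aic, b) {
    structure(list(model = "m", spec = dfe_model_spec(FALSE, FALSE),
                   mle_params = dfe_params(b = b, S_d = -100, theta = 0.01),
                   loglik = -aic / 2, n_free_params = 0L, aic = aic,
                   gradient_norm = 0, converged = TRUE, near_bound = FALSE,
                   n = 10L, L_neut = 1e3, L_sel = 1e3),
              class = "dfe_fit")
  }
  eq <- model_average(list(base(10, 0.2), base(10, 0.4), base(10, 0.6),
                           base(10, 0.8)))
  expect_equal(eq$weights$weight, rep(0.25, 4))
  # two models with delta-AIC = 2 and two negligible ones
  two <- model_average(list(base(0, 0.2), base(2, 0.8), base(500, 1),
                            base(500, 1)))
  expect_equal(two$weights$weight[1:2],
               c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-10)
  expect_equal(two$avg_params$b,
               (0.2 + 0.8 * exp(-1)) / (1 + exp(-1)), tolerance = 1e-10)
  for (avg in list(eq, two)) {
    bs <- vapply(avg$fits, function(f) f$mle_params$b, numeric(1))
    expect_gte(avg$avg_params$b, min(bs))
    expect_lte(avg$avg_params$b, max(bs))
    expect_equal(sum(avg$weights$weight), 1, tolerance = 1e-12)
    expect_equal(sum(avg$avg_discretized$mass), 1, tolerance = 1e-9)
  }
  # deleterious-only models contribute zero alpha
  expect_equal(eq$per_model_alpha, rep(0, 4), ignore_attr = TRUE)
})

test_that("the four-model average on simulated data is finite and ordered sensibly", {
  truth <- dfe_params(b = 0.5, S_d = -400, eps_anc = 0.03, theta = 0.008)
  d <- simulate_sfs_dataset(truth, n = 20, L_sel = 3e4, L_neut = 1.2e4,
                            seed = 8)
  fits <- fit_dfe_models(d$sfs_pair, n_starts = 2, seed = 8,
                         control = fast_ctl)
  avg <- model_average(fits)
  expect_equal(sum(avg$weights$weight), 1, tolerance = 1e-12)
  expect_true(is.finite(avg$avg_alpha) && avg$avg_alpha >= 0 &&
                avg$avg_alpha <= 1)
  expect_lt(abs(avg$avg_params$b / truth$b - 1), 0.5)
  g <- glance(avg)
  expect_true(g$best_model %in% c("full_eps", "full", "del_eps", "del"))
})

test_that("degenerate two-replicate bootstrap spans its replicate values", {
  truth <- dfe_params(b = 0.6, S_d = -200, theta = 0.008)
  d <- simulate_sfs_dataset(truth, n = 10, L_sel = 5e3, L_neut = 2e3, seed = 2)
  bs <- bootstrap_ci(d$sfs_pair, B = 2, seed = 3,
                     models = list(dfe_model_spec(FALSE, FALSE)),
                     n_starts = 1, control = fast_ctl)
  expect_equal(nrow(bs$replicates), 2)
  ci_b <- bs$ci[bs$ci$quantity == "b", ]
  expect_equal(ci_b$lower, min(bs$replicates$b), tolerance = 1e-9)
  expect_equal(ci_b$upper, max(bs$replicates$b), tolerance = 1e-9)
})

test_that("identical datasets give zero deviance and p ~ 1 in the shared test", {
  truth <- dfe_params(b = 0.5, S_d = -500, eps_anc = 0.05, theta = 0.008)
  d <- simulate_sfs_dataset(truth, n = 16, L_sel = 2e4, L_neut = 8e3, seed = 9)
  r <- lrt_shared(list(d$sfs_pair, d$sfs_pair), n_starts = 1,
                  control = fast_ctl, n_shared_starts = 1)
  expect_lt(abs(r$deviance), 0.02)
  expect_gt(r$p_value, 0.9)
  expect_equal(r$df, 2)
  expect_gte(r$deviance, -1e-6)
  # df convention: |shared| * (K - 1)
  r1 <- lrt_shared(list(d$sfs_pair, d$sfs_pair), shared = "b", n_starts = 1,
                   control = fast_ctl, n_shared_starts = 1)
  expect_equal(r1$df, 1)
  # Bonferroni adjustment multiplies by the family size
  r2 <- lrt_shared(list(d$sfs_pair, d$sfs_pair), shared = "b", n_starts = 1,
                   control = fast_ctl, n_shared_starts = 1, n_tests = 10)
  expect_equal(r2$bonferroni_adjusted_p, min(1, r2$p_value * 10))
})

test_that("strongly different shapes are detected by the shared-b test", {
  t1 <- dfe_params(b = 0.2, S_d = -500, eps_anc = 0.05, theta = 0.008)
  t2 <- dfe_params(b = 1.5, S_d = -500, eps_anc = 0.05, theta = 0.008)
  d1 <- simulate_sfs_dataset(t1, n = 16, L_sel = 1e5, L_neut = 4e4, seed = 31)
  d2 <- simulate_sfs_dataset(t2, n = 16, L_sel = 1e5, L_neut = 4e4, seed = 32)
  r <- lrt_shared(list(d1$sfs_pair, d2$sfs_pair), shared = "b", n_starts = 2,
                  seed = 1, control = fast_ctl, n_shared_starts = 1)
  expect_lt(r$p_value, 0.05)
})
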