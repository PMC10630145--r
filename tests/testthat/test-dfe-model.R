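test_that("sampling weight reduces to the neutral 1/i limit and matches the adaptive oracle", {
  n <- 10
  expect_equal(sampling_weight(0, 1:9, n), 1 / (1:9), tolerance = 1e-12)
  # strong purifying selection, singleton class
  expect_equal(sampling_weight(-50, 1, 10), oracle_H(-50, 1, 10),
               tolerance = 1e-8)
  # a spread of effect sizes and frequency classes
  for (S in c(-1, -10, -1e3, 2, 25)) {
    for (i in c(1, 3, 9)) {
      expect_equal(sampling_weight(S, i, 10), oracle_H(S, i, 10),
                   tolerance = 1e-8)
    }
  }
})

test_that("sampling weight is strictly decreasing in |S| for deleterious mutations", {
  S <- -c(0.1, 1, 10, 100, 1000, 1e4)
  for (i in c(1, 5, 9)) {
    H <- sampling_weight(S, i, 10)
    expect_true(all(diff(H) < 0))
  }
})

test_that("DFE density integrates to its mixture weights and has the exponential special case", {
  p <- dfe_params(b = 1, S_d = -10)
  # b = 1: gamma reduces to an exponential with mean 10
  expect_equal(dfe_density(p, -1), 0.1 * exp(-0.1), tolerance = 1e-12)
  del_mass <- integrate(function(s) dfe_density(p, s), -Inf, 0)$value
  expect_equal(del_mass, 1, tolerance = 1e-6)
  p2 <- dfe_params(b = 0.4, S_d = -100, p_b = 0.02, S_b = 10)
  ben_mass <- integrate(function(s) dfe_density(p2, s), 0, Inf)$value
  expect_equal(ben_mass, 0.02, tolerance = 1e-6)
})

test_that("discretized DFE masses sum to one and match closed forms", {
  p <- dfe_params(b = 1, S_d = -10)
  d <- discretize_dfe(p)
  expect_equal(sum(d$mass), 1, tolerance = 1e-9)
  # exponential closed form on (-1, 0): 1 - e^(-1/10)
  m <- d$mass[d$lower == -1 & d$upper == 0]
  expect_equal(m, 1 - exp(-0.1), tolerance = 1e-10)
  # beneficial-free model puts no mass above 0
  expect_equal(sum(d$mass[d$lower >= 0]), 0)
  # with a beneficial component, mass above 0 equals p_b
  d2 <- discretize_dfe(dfe_params(b = 0.4, S_d = -100, p_b = 0.05, S_b = 10))
  expect_equal(sum(d2$mass[d2$lower >= 0]), 0.05, tolerance = 1e-9)
})

test_that("expected SFS has the neutral limit, eps-mixing symmetry and theta*L identifiability", {
  # near-neutral deleterious DFE: selected spectrum ~ theta L / i
  p <- dfe_params(b = 1, S_d = -1e-4, theta = 0.01)
  e <- expected_sfs(p, 10, L_sel = 1000, L_neut = 1000)
  sel <- e$expected[e$class == "selected_0fold"]
  expect_equal(sel, 0.01 * 1000 / (1:9), tolerance = 1e-3)
  # eps = 0.5 (boundary excluded in the constructor) approached: spectrum
  # becomes symmetric under i <-> n - i
  p2 <- dfe_params(b = 0.4, S_d = -100, eps_anc = 0.4999, theta = 0.01)
  e2 <- expected_sfs(p2, 10, 1000, 1000)
  sel2 <- e2$expected[e2$class == "selected_0fold"]
  expect_equal(sel2, rev(sel2), tolerance = 1e-3)
  # only the product theta * L enters the likelihood
  pair1 <- exact_pair(dfe_params(b = 0.4, S_d = -100, theta = 0.01),
                      10, 1000, 800)
  ll1 <- dfe_loglik(dfe_params(b = 0.4, S_d = -100, theta = 0.01), pair1,
                    round_counts = FALSE)
  pair2 <- sfs_pair(new_sfs(pair1$neutral$xi, 10, 400, "neutral_4fold"),
                    new_sfs(pair1$selected$xi, 10, 500, "selected_0fold"))
  ll2 <- dfe_loglik(dfe_params(b = 0.4, S_d = -100, theta = 0.02), pair2,
                    round_counts = FALSE)
  expect_equal(ll1, ll2, tolerance = 1e-10)
})

test_that("folded spectra are invariant to mirroring the misidentification rate", {
  mirror <- function(eps) {
    e <- expected_sfs(dfe_params(b = 0.4, S_d = -100, eps_anc = eps,
                                 theta = 0.01), 10, 1000, 1000)
    sel <- e$expected[e$class == "selected_0fold"]
    sel + rev(sel) # folded
  }
  # folding cancels the (1-eps)/eps mix entirely: any two rates agree
  expect_equal(mirror(0.1), mirror(0.4), tolerance = 1e-12)
  expect_equal(mirror(0.1), mirror(0.25), tolerance = 1e-12)
})

test_that("Poisson log-likelihood matches hand arithmetic and is maximal near truth", {
  # single-entry contribution 5 ln 5 - 5 - ln(5!)
  pair <- sfs_pair(new_sfs(c(5), 2, 10, "neutral_4fold"),
                   new_sfs(c(5), 2, 10, "selected_0fold"))
  p <- dfe_params(b = 1, S_d = -1e-6, theta = 0.5) # both expectations = 5
  expect_equal(dfe_loglik(p, pair), 2 * (5 * log(5) - 5 - log(factorial(5))),
               tolerance = 1e-4)
  # stationarity: at exact expected counts the gradient in b is ~ 0
  truth <- dfe_params(b = 0.5, S_d = -200, theta = 0.01)
  pair2 <- exact_pair(truth, 20, 2e4, 1e4)
  ll <- vapply(c(0.48, 0.5, 0.52), function(b) {
    dfe_loglik(dfe_params(b = b, S_d = -200, theta = 0.01), pair2,
               round_counts = FALSE)
  }, numeric(1))
  expect_true(ll[2] > ll[1] && ll[2] > ll[3])
})

test_that("expected selected spectrum agrees with an adaptive quadrature scheme to 1e-6", {
  n <- 40
  grid <- expand.grid(b = c(0.1, 0.4, 1.6), S_d = -c(64, 571, 47000))
  for (k in seq_len(nrow(grid))) {
    b <- grid$b[k]; S_d <- grid$S_d[k]
    s <- dfeload:::unit_selected_sfs(b, S_d, 0, 1, n)
    for (i in c(1, 5, 20, 39)) {
      if (s[i] / s[1] < 1e-9) next
      expect_equal(s[i], oracle_unit_selected(b, S_d, i, n),
                   tolerance = 1e-6,
                   label = sprintf("m_%d at b=%g S_d=%g", i, b, S_d))
    }
  }
})

test_that("expected selected spectrum matches a Monte-Carlo draw of the DFE within 3 SE", {
  n <- 20
  for (cfg in list(c(0.4, -1000), c(0.097, -47000))) {
    b <- cfg[1]; S_d <- cfg[2]
    s <- dfeload:::unit_selected_sfs(b, S_d, 0, 1, n)
    S_draws <- withr::with_seed(42, -rgamma(2e5, shape = b, scale = -S_d / b))
    H <- sampling_weight(S_draws, c(1, 5, 19), n)
    for (jj in 1:3) {
      i <- c(1, 5, 19)[jj]
      mc <- mean(H[, jj]); se <- sd(H[, jj]) / sqrt(length(S_draws))
      expect_lt(abs(s[i] - mc), 3 * se + 1e-12)
    }
  }
})

test_that("alpha_DFE vanishes without beneficial mass, decreases in S_min, and matches a Monte-Carlo oracle", {
  expect_equal(alpha_dfe(dfe_params(b = 0.4, S_d = -100)), 0)
  p <- dfe_params(b = 0.4, S_d = -100, p_b = 0.05, S_b = 10)
  a <- vapply(c(0, 5, 20, 100), function(sm) alpha_dfe(p, S_min = sm),
              numeric(1))
  expect_true(all(diff(a) <= 1e-12))
  expect_lt(a[4], a[1])
  # importance-sampling oracle: draw S from the mixture, weight by omega(S)
  draws <- withr::with_seed(7, {
    nben <- rbinom(1, 4e5, 0.05)
    c(qexp(runif(nben), rate = 1 / 10),
      -rgamma(4e5 - nben, shape = 0.4, scale = 100 / 0.4))
  })
  w <- dfeload:::fixation_weight(draws)
  mc_alpha <- sum(w[draws >= 5]) / sum(w)
  mc_se <- sd((draws >= 5) * w) / (mean(w) * sqrt(length(draws))) # rough
  expect_lt(abs(alpha_dfe(p, S_min = 5) - mc_alpha), 3 * mc_se + 0.01)
})
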