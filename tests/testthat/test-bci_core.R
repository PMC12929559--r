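test_that("common-cause pair likelihood matches quadrature of its defining integral", {
  # oracle: numerically integrate the Gaussian product over the latent
  # source for a handful of parameter points (the full randomized grid runs
  # in the acceptance suite)
  set.seed(101)
  for (i in 1:20) {
    sa <- runif(1, 0.5, 8); sv <- runif(1, 0.3, 5)
    sp <- runif(1, 2, 50); mu <- runif(1, -3, 3)
    a <- runif(1, -10, 10); v <- runif(1, -10, 10)
    num <- integrate(function(S) dnorm(a, S, sa) * dnorm(v, S, sv) *
                       dnorm(S, mu, sp),
                     -Inf, Inf, rel.tol = 1e-10)$value
    expect_equal(pair_likelihood_common(a, v, sa, sv, mu, sp), num,
                 tolerance = 1e-8)
  }
})

test_that("pair likelihoods have the closed-form symmetries", {
  # symmetric in (a, v) at equal sensory SDs
  expect_equal(pair_likelihood_common(1.3, -0.7, 2, 2, 0.5, 10),
               pair_likelihood_common(-0.7, 1.3, 2, 2, 0.5, 10))
  # maximised over a at a = v = mu
  grid <- seq(-6, 6, length.out = 241)
  dens <- pair_likelihood_common(grid, 1.5, 2, 1, 1.5, 8)
  expect_equal(grid[which.max(dens)], 1.5, tolerance = 0.06)
  dens2 <- pair_likelihood_common(grid, grid, 2, 1, 0, 8)
  expect_equal(grid[which.max(dens2)], 0, tolerance = 0.06)
  # independent-cause density factorises: ratio along a + v = const is
  # independent of the discrepancy only through the marginals
  p1 <- pair_likelihood_independent(1, 3, 2, 2, 0, 1e6)
  p2 <- pair_likelihood_independent(3, 1, 2, 2, 0, 1e6)
  expect_equal(p1, p2)
  expect_error(pair_likelihood_common(0, 0, -1, 1, 0, 1), "deviations")
})

test_that("independent-cause pair likelihood integrates to 1 and matches quadrature", {
  sa <- 2; sv <- 1.2; sp <- 4; mu <- 0.7
  f_a <- integrate(function(a) pair_likelihood_independent(a, 0.3, sa, sv,
                                                           mu, sp) /
                     dnorm(0.3, mu, sqrt(sv^2 + sp^2)),
                   -Inf, Inf, rel.tol = 1e-10)$value
  expect_equal(f_a, 1, tolerance = 1e-8)
  # matches the product of the two marginal integrals
  num <- integrate(function(S) dnorm(1.1, S, sa) * dnorm(S, mu, sp),
                   -Inf, Inf, rel.tol = 1e-10)$value *
         integrate(function(S) dnorm(0.3, S, sv) * dnorm(S, mu, sp),
                   -Inf, Inf, rel.tol = 1e-10)$value
  expect_equal(pair_likelihood_independent(1.1, 0.3, sa, sv, mu, sp), num,
               tolerance = 1e-8)
})

test_that("causal posterior behaves like Bayes rule", {
  cond <- get_condition(design28, "ILL-R-SYNC")
  s <- sensory_sample(sample_sensory_inputs(cond, rep_params, 5, seed = 3),
                      2)
  # degenerate priors
  p1 <- set_params(rep_params, p_common = 1)
  p0 <- set_params(rep_params, p_common = 0)
  expect_equal(causal_posterior(s, p1)$p_c1, 1)
  expect_equal(causal_posterior(s, p0)$p_c1, 0)
  expect_error(causal_posterior(s, rep_params, included_pairs = integer(0)),
               "nonempty")
  # log-space result agrees with the linear-space computation
  means <- prior_means()
  expect_equal(causal_posterior(s, rep_params)$p_c1,
               posterior_linear(s, rep_params, means), tolerance = 1e-10)
  # perfectly coincident audiovisual cues at the prior means favour C = 1
  coinc <- list(
    x_A = cbind(means$mu_S_P, means$mu_T_P, means$mu_I_P_A),
    x_V = cbind(means$mu_S_P, means$mu_T_P, means$mu_I_P_V))
  expect_gt(causal_posterior(coinc, rep_params)$p_c1,
            rep_params[["p_common"]])
})

test_that("p_c1 is monotone in p_common and decreases with asynchrony", {
  cond <- get_condition(design28, "INV-R-SYNC")
  samples <- sample_sensory_inputs(cond, rep_params, 12, seed = 9)
  pcs <- seq(0.05, 0.95, by = 0.1)
  for (i in 1:12) {
    s <- sensory_sample(samples, i)
    post <- vapply(pcs, function(pc)
      causal_posterior(s, set_params(rep_params, p_common = pc))$p_c1,
      numeric(1))
    expect_true(all(diff(post) > 0))
    # widen every pair's audiovisual time gap: evidence for C = 1 drops
    shifted <- s
    shifted$x_A[, 2] <- s$x_A[, 2] - 150
    shifted$x_V[, 2] <- s$x_V[, 2] + 150
    expect_lte(causal_posterior(shifted, rep_params)$p_c1,
               causal_posterior(s, rep_params)$p_c1)
  }
})

test_that("fusion, segregation and model averaging follow the weighted forms", {
  expect_equal(fusion_estimate(2, 0, 1, 1, 0, 1e6), 1, tolerance = 1e-6)
  expect_equal(fusion_estimate(2, 0, 1, 1e9, 0.5, 1e6),
               segregation_estimate(2, 1, 0.5, 1e6), tolerance = 1e-6)
  expect_equal(fusion_estimate(3, 3, 0.7, 2.2, 3, 5), 3)
  expect_equal(segregation_estimate(4, 1e6, 0, 1e6), 2)  # equal weights
  expect_equal(segregation_estimate(4, 1, 0, 1e6), 4, tolerance = 1e-5)
  expect_equal(model_average(0, 2, 0.5), 1)
  expect_equal(model_average(7, -3, 1), 7)
  x <- model_average(0.3, 0.9, 0.25)
  expect_true(x >= 0.3 && x <= 0.9)
  expect_error(model_average(0, 1, 1.2), "p_c1")
})

test_that("percepts are convex combinations and variants coincide when they must", {
  cond <- get_condition(design28, "ILL-L-SYNC")
  samples <- sample_sensory_inputs(cond, rep_params, 10, seed = 17)
  p1 <- set_params(rep_params, p_common = 1)
  for (i in 1:10) {
    s <- sensory_sample(samples, i)
    pc <- perceive_trial(s, cond, rep_params, variant = "BCI")
    lo <- pmin(pc$S_hat_AV_C1, pc$S_hat_V_C2)
    hi <- pmax(pc$S_hat_AV_C1, pc$S_hat_V_C2)
    expect_true(all(pc$S_hat_V >= lo - 1e-12 & pc$S_hat_V <= hi + 1e-12))
    # FF percept equals BCI percept at p_common = 1 on the same sample
    expect_equal(perceive_trial(s, cond, p1, variant = "BCI")$S_hat_V,
                 perceive_trial(s, cond, p1, variant = "FF")$S_hat_V)
  }
  expect_error(perceive_trial(sensory_sample(samples, 1), cond, rep_params,
                              variant = "XX"), "variant")
})

test_that("noise-free middle events reproduce the two illusions' arithmetic", {
  means <- prior_means()
  # invisible rabbit: flash present, beep absent; near-zero auditory
  # intensity noise drives the fused intensity to ~0 -> flash suppressed
  inv <- get_condition(design28, "INV-R-SYNC")
  p <- set_params(rep_params, sigma_iA = 1e-10)
  d <- distal_stimulus(inv)
  s <- list(x_A = d[, c("S_A", "T_A", "I_A")],
            x_V = d[, c("S_V", "T_V", "I_V")])
  pc <- perceive_trial(s, inv, set_params(p, p_common = 1), variant = "FF")
  expect_lt(pc$I_hat_V[2], 1e-6)
  expect_lt(pc$I_hat_V[2], p[["phi_I"]])
  # illusory rabbit: beep present, flash absent -> fused intensity ~1 and
  # the middle location pulled from the latent grid toward the auditory 0
  ill <- get_condition(design28, "ILL-R-SYNC")
  d2 <- distal_stimulus(ill)
  s2 <- list(x_A = d2[, c("S_A", "T_A", "I_A")],
             x_V = d2[, c("S_V", "T_V", "I_V")])
  pc2 <- perceive_trial(s2, ill, set_params(p, p_common = 1), variant = "FF")
  expect_gt(pc2$I_hat_V[2], 0.99)
  expect_gt(pc2$I_hat_V[2], p[["phi_I"]])
  expect_lt(pc2$S_hat_V[2], 2.84)
  expect_gt(pc2$S_hat_V[2], 0)
})

test_that("response mapping bins by threshold then nearest button", {
  p <- set_params(rep_params, phi_I = 0.5)
  mk <- function(S, I) structure(list(S_hat_V = rep(S, 3),
                                      I_hat_V = rep(I, 3)),
                                 class = "percept")
  expect_equal(map_to_response(mk(2.9, 0.9), p), rep(4L, 3))
  expect_equal(map_to_response(mk(2.9, 0.2), p), rep(6L, 3))
  expect_equal(map_to_response(mk(-10, 0.8), p), rep(1L, 3))
  # exact midpoint between buttons 3 and 4 -> lower index
  expect_equal(map_to_response(mk(1.42, 0.8), p), rep(3L, 3))
  # intensity exactly at threshold counts as not seen
  expect_equal(map_to_response(mk(0, 0.5), p), rep(6L, 3))
})
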