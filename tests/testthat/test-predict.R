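test_that("sensory sampling is centred on the distal stimuli and deterministic", {
  cond <- get_condition(design28, "INV-R-SYNC")
  # vanishing noise reproduces the distal values
  p0 <- model_params(sigma_sA = 1e-9, sigma_tA = 1e-9, sigma_iA = 1e-9,
                     sigma_sV = 1e-9, sigma_tV = 1e-9, sigma_iV = 1e-9)
  s <- sample_sensory_inputs(cond, p0, 4, seed = 1)
  d <- distal_stimulus(cond)
  for (j in 1:3) {
    expect_equal(unname(s$x_V[2, j, ]), unname(d[j, c("S_V", "T_V", "I_V")]),
                 tolerance = 1e-6)
    expect_equal(unname(s$x_A[2, j, ]), unname(d[j, c("S_A", "T_A", "I_A")]),
                 tolerance = 1e-6)
  }
  # law of large numbers: sample mean within 4 sigma/sqrt(n)
  n <- 1e5
  s2 <- sample_sensory_inputs(cond, rep_params, n, seed = 2)
  expect_lt(abs(mean(s2$x_V[, 1, 1]) - d[1, "S_V"]),
            4 * rep_params[["sigma_sV"]] / sqrt(n))
  expect_lt(abs(mean(s2$x_A[, 2, 2]) - d[2, "T_A"]),
            4 * rep_params[["sigma_tA"]] / sqrt(n))
  # determinism
  s3 <- sample_sensory_inputs(cond, rep_params, 10, seed = 5)
  s4 <- sample_sensory_inputs(cond, rep_params, 10, seed = 5)
  expect_identical(s3$x_V, s4$x_V)
  expect_error(sample_sensory_inputs(cond, rep_params, 0), "n must")
})

test_that("predicted distributions are normalised and match the R reference path", {
  for (id in c("ILL-R-SYNC", "INV-L-VLEAD", "U3F-T1", "M2F2B-R")) {
    cond <- get_condition(design28, id)
    for (v in c("BCI", "FS")) {
      s <- sample_sensory_inputs(cond, rep_params, 150, seed = 31)
      z <- attr(s, "z")
      pd <- predicted_distributions(cond, rep_params, variant = v, z = z,
                                    pseudocount = 0)
      expect_equal(unname(rowSums(pd$probs)), rep(1, 3), tolerance = 1e-12)
      expect_true(all(pd$probs >= 0))
      # reference path: perceive + map + press alignment, trial by trial
      cnt <- matrix(0, 3, 6)
      for (i in 1:150) {
        raw <- map_to_response(
          perceive_trial(sensory_sample(s, i), cond, rep_params,
                         variant = v), rep_params)
        aligned <- encode_trial_outcomes(
          list(presses = decode_outcomes(raw), is_catch = FALSE))
        for (j in 1:3) cnt[j, aligned[j]] <- cnt[j, aligned[j]] + 1
      }
      expect_equal(unname(pd$counts), cnt)
    }
  }
})

test_that("pseudocount flooring keeps every bin probability positive", {
  cond <- get_condition(design28, "M3F3B-R")
  pd <- predicted_distributions(cond, rep_params, n = 200, seed = 8,
                                pseudocount = 1)
  expect_true(all(pd$probs > 0))
  expect_equal(unname(rowSums(pd$probs)), rep(1, 3), tolerance = 1e-12)
  expect_equal(sum(pd$counts[1, ]), 200)
})

test_that("forced variants are exact limits of the causal observer", {
  # identical compute path: BCI at p_common = 1 is FF, at 0 is FS
  p1 <- set_params(rep_params, p_common = 1)
  p0 <- set_params(rep_params, p_common = 0)
  pred_ff <- predict_design(design28, rep_params, variant = "FF", n = 400,
                            seed = 21)
  pred_b1 <- predict_design(design28, p1, variant = "BCI", n = 400,
                            seed = 21)
  pred_fs <- predict_design(design28, rep_params, variant = "FS", n = 400,
                            seed = 21)
  pred_b0 <- predict_design(design28, p0, variant = "BCI", n = 400,
                            seed = 21)
  for (id in condition_ids(design28)) {
    expect_identical(pred_b1[[id]]$counts, pred_ff[[id]]$counts)
    expect_identical(pred_b0[[id]]$counts, pred_fs[[id]]$counts)
  }
})

test_that("unisensory conditions are variant-independent (visual-only path)", {
  uni <- condition_ids(design28)[design28$conditions$n_beeps == 0]
  for (v in c("BCI", "BCI_NP", "FF")) {
    a <- predict_design(design28, rep_params, variant = v, n = 300,
                        seed = 13, conditions = uni)
    b <- predict_design(design28, rep_params, variant = "FS", n = 300,
                        seed = 13, conditions = uni)
    for (id in uni) expect_identical(a[[id]]$counts, b[[id]]$counts)
  }
})

test_that("mirror conditions predict mirror distributions", {
  pairs <- list(c("ILL-R-SYNC", "ILL-L-SYNC"), c("INV-R-ALEAD", "INV-L-ALEAD"))
  n <- 6000
  for (pr in pairs) {
    r <- predicted_distributions(get_condition(design28, pr[1]), rep_params,
                                 n = n, seed = 3)
    l <- predicted_distributions(get_condition(design28, pr[2]), rep_params,
                                 n = n, seed = 4)
    # bins 1..5 mirror; absent bin maps to itself
    mirrored <- l$probs[, c(5:1, 6)]
    mc_err <- 5 * sqrt(0.25 / n) * 2
    expect_lt(max(abs(r$probs - mirrored)), mc_err)
  }
})

test_that("bin probabilities are stable when the simulation count grows tenfold", {
  ids <- c("ILL-R-SYNC", "INV-R-SYNC", "ILL-L-ALEAD", "U2F-R", "M3F3B-T2-VLEAD")
  n1 <- 1500
  small <- predict_design(design28, rep_params, n = n1, seed = 5,
                          conditions = ids)
  big <- predict_design(design28, rep_params, n = 10 * n1, seed = 6,
                        conditions = ids)
  cells <- 0; bad <- 0
  for (id in ids) {
    p1 <- small[[id]]$probs; p2 <- big[[id]]$probs
    se <- sqrt(p2 * (1 - p2) / n1) + 1e-4
    bad <- bad + sum(abs(p1 - p2) > 5 * se)
    cells <- cells + length(p1)
  }
  expect_lt(bad / cells, 0.01)
})

test_that("predicted illusion rates agree with per-trial scoring and mirror behaviour", {
  ids <- c("ILL-R-SYNC", "INV-R-SYNC")
  r <- predicted_illusion_rates(design28, rep_params, variant = "BCI",
                                n = 400, seed = 9, conditions = ids)
  expect_true(all(r$illusion_rate >= 0 & r$illusion_rate <= 1))
  # equivalent to score_trial_illusion applied to each simulated trial
  zs <- avrabbit:::crn_draws(ids, 400, 9, 0)
  for (id in ids) {
    cond <- get_condition(design28, id)
    outc <- simulate_outcomes(cond, rep_params, variant = "BCI",
                              z = zs[[id]])
    hits <- vapply(seq_len(nrow(outc)), function(i) {
      score_trial_illusion(list(presses = decode_outcomes(outc[i, ]),
                                is_catch = FALSE), cond)
    }, logical(1))
    expect_equal(r$illusion_rate[r$condition_id == id], mean(hits))
  }
})

test_that("spatial uncertainty scaling reduces the illusions", {
  ids <- c("ILL-R-SYNC", "ILL-L-SYNC", "INV-R-SYNC", "INV-L-SYNC")
  tab <- spatial_uncertainty_simulation(design28, rep_params,
                                        scale_factors = c(1, 4),
                                        n = 4000, seed = 12,
                                        conditions = ids)
  expect_equal(nrow(tab), length(ids) * 2)
  base <- predicted_illusion_rates(design28, rep_params, variant = "BCI",
                                   n = 4000, seed = 12, conditions = ids)
  # factor 1 reproduces the baseline at the matched seed
  expect_equal(tab$illusion_rate[tab$scale_factor == 1],
               base$illusion_rate)
  # a large factor lowers the mean illusion rate across illusion conditions
  expect_lt(mean(tab$illusion_rate[tab$scale_factor == 4]),
            mean(tab$illusion_rate[tab$scale_factor == 1]))
  expect_error(spatial_uncertainty_simulation(design28, rep_params,
                                              scale_factors = c(0, 1)),
               "scale_factors")
})
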