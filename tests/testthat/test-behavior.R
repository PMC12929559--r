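test_that("illusion scoring demands exact locations and order", {
  ill_r <- get_condition(design28, "ILL-R-SYNC")
  inv_r <- get_condition(design28, "INV-R-SYNC")
  resp <- function(p) list(presses = p, is_catch = FALSE)
  expect_true(score_trial_illusion(resp(c(3, 4, 5)), ill_r))
  expect_false(score_trial_illusion(resp(c(3, 5, 4)), ill_r))  # order
  expect_false(score_trial_illusion(resp(c(3, 5)), ill_r))     # veridical
  expect_true(score_trial_illusion(resp(c(3, 5)), inv_r))
  expect_false(score_trial_illusion(resp(c(3, 4, 5)), inv_r))  # no suppression
  expect_true(score_trial_illusion(resp(c(3, 4, 5)), inv_r, score = "match"))
  # left mirrors
  expect_true(score_trial_illusion(resp(c(3, 2, 1)),
                                   get_condition(design28, "ILL-L-SYNC")))
  expect_true(score_trial_illusion(resp(c(3, 1)),
                                   get_condition(design28, "INV-L-ALEAD")))
  # >3 presses and catch handling
  expect_false(score_trial_illusion(resp(c(3, 4, 5, 5)), ill_r))
  expect_error(score_trial_illusion(list(presses = 3, is_catch = TRUE),
                                    ill_r), "catch")
  expect_error(score_trial_illusion(resp(c(3, 6)), ill_r), "presses")
})

test_that("illusion rates are per-participant proportions over non-catch trials", {
  tr <- tiny_trials("ILL-R-SYNC",
                    c(rep("3-4-5", 14), rep("3-5", 14)))
  tr <- rbind(tr, data.frame(participant_id = "P01", block = 1,
                             condition_id = "CATCH", trial_index = 99,
                             response = "3", is_catch = TRUE))
  rates <- illusion_rates(tr, design28)
  expect_equal(rates$rate, 0.5)
  expect_equal(rates$n_trials, 28)
  expect_error(illusion_rates(tr[tr$is_catch, ], design28), "non-catch")
  tr_bad <- tiny_trials("NOPE", "3-4-5")
  expect_error(illusion_rates(tr_bad, design28), "unknown condition")
})

test_that("direction pooling weights by trials, is idempotent, yields 10 conditions", {
  # two mirror conditions with different rates and trial counts
  tr <- rbind(tiny_trials("ILL-R-SYNC", c(rep("3-4-5", 10), rep("3-5", 10))),
              tiny_trials("ILL-L-SYNC", rep("3-2-1", 10)))
  rates <- illusion_rates(tr, design28)
  pooled <- pool_directions(rates, design28)
  expect_equal(pooled$rate[pooled$analysis_condition == "illusory_sync"],
               (0.5 * 20 + 1 * 10) / 30)
  expect_identical(pool_directions(pooled, design28), pooled)
  # a full cohort covers exactly the ten analysis conditions
  full <- expand.grid(condition_id = condition_ids(design28),
                      stringsAsFactors = FALSE)
  tr2 <- do.call(rbind, lapply(full$condition_id, function(id)
    tiny_trials(id, c("3-4-5", "3-5"))))
  pooled2 <- pool_directions(illusion_rates(tr2, design28), design28)
  expect_equal(nrow(pooled2), 10)
})

test_that("participant screening flags only extreme control rates, order-invariantly", {
  set.seed(42)
  mk <- function(pid, rate) {
    data.frame(participant_id = pid,
               analysis_condition = c("illusory_uni_ctrl",
                                      "illusory_multi_ctrl",
                                      "invisible_uni_ctrl",
                                      "invisible_multi_ctrl",
                                      "illusory_sync"),
               n_trials = 56, rate = c(rep(rate, 4), 0.4),
               stringsAsFactors = FALSE)
  }
  base <- do.call(rbind, lapply(1:12, function(i)
    mk(sprintf("P%02d", i), 0.05 + 0.01 * (i %% 4))))
  res <- screen_participants(base)
  expect_length(res$excluded, 0)
  # planted outlier far above the cohort
  with_out <- rbind(base, mk("P99", 0.9))
  res2 <- screen_participants(with_out)
  expect_equal(res2$excluded, "P99")
  shuffled <- with_out[sample(nrow(with_out)), ]
  expect_equal(sort(screen_participants(shuffled)$kept), sort(res2$kept))
  expect_error(screen_participants(base[base$participant_id == "P01", ]),
               "3 participants")
})

test_that("condition contrasts gate on normality and apply Bonferroni", {
  # identical paired vectors: no difference, p = 1
  pooled <- do.call(rbind, lapply(1:10, function(i)
    data.frame(participant_id = sprintf("P%02d", i),
               analysis_condition = c("illusory_sync", "illusory_uni_ctrl"),
               n_trials = 56, rate = c(0.4, 0.4))))
  out <- condition_contrasts(pooled,
                             pairs = list(c("illusory_sync",
                                            "illusory_uni_ctrl")))
  expect_equal(out$p_raw, 1)
  # Bonferroni with 10 pairs multiplies raw p (0.0004 -> 0.004 < 0.005)
  expect_equal(min(0.0004 * 10, 1), 0.004)
  expect_error(condition_contrasts(pooled,
                                   pairs = list(c("illusory_sync",
                                                  "invisible_sync"))),
               "unpaired|missing")
})

test_that("the Wilcoxon machinery matches an independent reference implementation", {
  # fixed 28-participant rate vectors; reference values computed with
  # scipy.stats.wilcoxon (correction=True, method='approx') and
  # scipy.stats.shapiro, frozen here
  a <- c(0.528965, 0.109695, 0.161447, 0.037125, 0.658799, 0.548511,
         0.525555, 0.889286, 0.297105, 0.521536, 0.613737, 0.490158,
         0.663213, 0.396434, 0.376038, 0.370249, 0.479063, 0.469476,
         0.288349, 0.388025, 0.132714, 0.298148, 0.204854, 0.421429,
         0.50359, 0.178259, 0.335985, 0.31538)
  b <- c(0.338807, 0.0, 0.180141, 0.045748, 0.794584, 0.174619, 0.438397,
         0.857832, 0.072495, 0.396861, 0.561546, 0.512469, 0.78246,
         0.326828, 0.344132, 0.245868, 0.26111, 0.383733, 0.179354,
         0.321498, 0.106879, 0.178642, 0.117566, 0.479117, 0.357203,
         0.208072, 0.376518, 0.118122)
  wt <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                           correct = TRUE)
  # scipy reports the smaller rank sum (69); the two sides sum to n(n+1)/2
  expect_equal(unname(wt$statistic), 28 * 29 / 2 - 69)
  expect_equal(wt$p.value, 0.0023658991287411964, tolerance = 1e-12)
  expect_equal(abs(avrabbit:::wilcoxon_z(a - b)), 3.0399850237749084,
               tolerance = 1e-10)
  pooled <- do.call(rbind, lapply(1:28, function(i)
    data.frame(participant_id = sprintf("P%02d", i),
               analysis_condition = c("illusory_sync", "illusory_uni_ctrl"),
               n_trials = 56, rate = c(a[i], b[i]))))
  out <- condition_contrasts(pooled,
                             pairs = list(c("illusory_sync",
                                            "illusory_uni_ctrl")))
  if (out$test_name == "wilcoxon_signed_rank") {
    expect_equal(out$p_raw, wt$p.value, tolerance = 1e-12)
  }
  expect_equal(out$p_bonferroni, pmin(out$p_raw * 1, 1))
})

test_that("Shapiro-Wilk matches the independent reference on a fixed vector", {
  a <- c(0.528965, 0.109695, 0.161447, 0.037125, 0.658799, 0.548511,
         0.525555, 0.889286, 0.297105, 0.521536, 0.613737, 0.490158,
         0.663213, 0.396434, 0.376038, 0.370249, 0.479063, 0.469476,
         0.288349, 0.388025, 0.132714, 0.298148, 0.204854, 0.421429,
         0.50359, 0.178259, 0.335985, 0.31538)
  b <- c(0.338807, 0.0, 0.180141, 0.045748, 0.794584, 0.174619, 0.438397,
         0.857832, 0.072495, 0.396861, 0.561546, 0.512469, 0.78246,
         0.326828, 0.344132, 0.245868, 0.26111, 0.383733, 0.179354,
         0.321498, 0.106879, 0.178642, 0.117566, 0.479117, 0.357203,
         0.208072, 0.376518, 0.118122)
  sh <- stats::shapiro.test(a - b)
  expect_equal(unname(sh$statistic), 0.9759254823892592, tolerance = 1e-10)
  # the two implementations' p-value approximations agree to ~1e-8
  expect_equal(sh$p.value, 0.7442255025059357, tolerance = 1e-7)
})
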