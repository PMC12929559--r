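#' Deterministic sub-seed for one condition
#'
#' Counter-based scheme deriving one RNG sub-seed per (condition, stream)
#' from a master seed, so that model variants and parameter perturbations
#' can be compared with common random numbers and the Monte-Carlo fit
#' objective is deterministic. Always below 2^31.
#'
#' @param master_seed Integer master seed.
#' @param condition_index Integer counter (position of the condition).
#' @param stream Extra stream offset (e.g. per participant or evaluation).
#' @export
condition_seed <- function(master_seed, condition_index, stream = 0) {
  m <- as.numeric(master_seed) %% 2147483647
  as.integer((m * 1009 + as.numeric(condition_index) * 9973 +
              as.numeric(stream) * 999331) %% 2147483646 + 1)
}

# standard-normal draw matrices (n x 18) per condition, by sub-seed
crn_draws <- function(ids, n, seed, stream = 0) {
  out <- vector("list", length(ids))
  names(out) <- ids
  for (k in seq_along(ids)) {
    set.seed(condition_seed(seed, k, stream))
    out[[k]] <- matrix(stats::rnorm(n * 18L), n, 18L)
  }
  out
}

#' Sample proximal sensory inputs for one condition
#'
#' Draws `n` trials of noisy sensory inputs: per event and modality,
#' (space, time, intensity) triples sampled independently from Gaussians
#' centred on the experimentally defined distal values with the
#' modality/cue sensory SDs. Absent stimuli are sampled around intensity 0
#' (untruncated).
#'
#' @param condition Condition from [get_condition()].
#' @param params A [model_params()] vector.
#' @param n Number of simulated trials (>= 1).
#' @param seed RNG seed; same seed and inputs give bit-identical samples.
#' @param z Optional pre-drawn n x 18 standard-normal matrix (overrides
#'   `seed`); columns per event j: (sA, tA, iA, sV, tV, iV).
#' @return List with arrays `x_A`, `x_V` of dim (n, 3 events, 3 cues
#'   space/time/intensity), plus the draw matrix as attribute `"z"`.
#' @export
sample_sensory_inputs <- function(condition, params, n, seed = 1, z = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (is.null(z)) {
    set.seed(seed)
    z <- matrix(stats::rnorm(n * 18L), n, 18L)
  }
  d <- distal_stimulus(condition)
  sA <- c(params[["sigma_sA"]], params[["sigma_tA"]], params[["sigma_iA"]])
  sV <- c(params[["sigma_sV"]], params[["sigma_tV"]], params[["sigma_iV"]])
  x_A <- array(NA_real_, c(n, 3, 3),
               dimnames = list(NULL, paste0("event", 1:3), c("s", "t", "i")))
  x_V <- x_A
  for (j in 1:3) {
    b <- 6L * (j - 1L)
    for (cue in 1:3) {
      x_A[, j, cue] <- d[j, cue] + sA[cue] * z[, b + cue]
      x_V[, j, cue] <- d[j, cue + 3L] + sV[cue] * z[, b + cue + 3L]
    }
  }
  structure(list(x_A = x_A, x_V = x_V), z = z)
}

#' Extract one trial's sensory sample
#'
#' @param samples Output of [sample_sensory_inputs()].
#' @param i Trial index.
#' @return List with `x_A`, `x_V` as 3 x 3 matrices (event x cue).
#' @export
sensory_sample <- function(samples, i) {
  list(x_A = samples$x_A[i, , , drop = TRUE],
       x_V = samples$x_V[i, , , drop = TRUE])
}

engine_args <- function(condition, params, means) {
  list(distal = distal_stimulus(condition),
       params = as.numeric(params[c("p_common", "sigma_S_P", "sigma_T_P",
                                    "sigma_I_P", "sigma_sA", "sigma_tA",
                                    "sigma_iA", "sigma_sV", "sigma_tV",
                                    "sigma_iV", "phi_I")]),
       muT = means$mu_T_P, muIV = means$mu_I_P_V, muIA = means$mu_I_P_A,
       buttons = condition$layout,
       visual_only = is_visual_only(condition))
}

#' Predicted six-bin response distributions for one condition
#'
#' Monte-Carlo forward simulation: samples `n` sensory inputs, runs the
#' observer ([perceive_trial()] arithmetic, compiled) and bins the percepts
#' ([map_to_response()]) into the six outcome bins (buttons 1..5, no flash)
#' per event. By default each simulated trial's outcomes are passed through
#' the same press-to-event alignment applied to observed responses
#' ([encode_trial_outcomes()]): the model's responses are analysed exactly
#' like participants' responses, which keeps the fitted likelihood
#' consistent with the data representation (an observer who misses the
#' third flash produces the same two-press sequence as one who misses the
#' second). Bin probabilities are pseudocount-floored,
#' (count + pseudocount) / (n + 6 pseudocount), so Monte-Carlo-empty bins
#' never produce -Inf log likelihoods.
#'
#' @param condition Condition from [get_condition()].
#' @param params A [model_params()] vector.
#' @param means Prior means.
#' @param variant Model variant ("BCI", "BCI_NP", "FF", "FS").
#' @param n Simulated trials (default 5000).
#' @param seed RNG seed for the draws (ignored if `z` given).
#' @param z Optional pre-drawn n x 18 standard-normal matrix (common random
#'   numbers).
#' @param pseudocount Per-bin floor (default 1; 0 disables).
#' @param align Apply the press-to-event alignment to simulated outcomes
#'   (default TRUE; FALSE gives the raw per-event outcome distributions).
#' @return List with `probs` (3 x 6 matrix, rows events; columns bin1..bin5,
#'   absent), `counts`, `n_sim`, `seed`, `variant`, `condition_id`.
#' @export
predicted_distributions <- function(condition, params, means = prior_means(),
                                    variant = "BCI", n = 5000, seed = 1,
                                    z = NULL, pseudocount = 1,
                                    align = TRUE) {
  if (is.null(z)) {
    set.seed(seed)
    z <- matrix(stats::rnorm(n * 18L), n, 18L)
  } else {
    n <- nrow(z)
  }
  a <- engine_args(condition, params, means)
  counts <- .engine_condition(z, a$distal, a$params, a$muT, a$muIV, a$muIA,
                              a$buttons, variant_code(variant),
                              a$visual_only, FALSE, align)
  dimnames(counts) <- list(paste0("event", 1:3),
                           c(paste0("bin", 1:5), "absent"))
  probs <- (counts + pseudocount) / (n + 6 * pseudocount)
  list(probs = probs, counts = counts, n_sim = n, seed = seed,
       variant = variant, condition_id = condition$condition_id)
}

#' Simulate per-trial event outcomes for one condition
#'
#' Same engine as [predicted_distributions()] but returns the raw per-trial
#' outcomes (used by the synthetic-participant generator and the
#' illusion-rate scorer; their press sequences are unaffected by the
#' press-to-event alignment).
#'
#' @inheritParams predicted_distributions
#' @return n x 3 integer matrix of outcomes in 1..6 (6 = no flash).
#' @export
simulate_outcomes <- function(condition, params, means = prior_means(),
                              variant = "BCI", n = 28, seed = 1, z = NULL) {
  if (is.null(z)) {
    set.seed(seed)
    z <- matrix(stats::rnorm(n * 18L), n, 18L)
  }
  a <- engine_args(condition, params, means)
  .engine_condition(z, a$distal, a$params, a$muT, a$muIV, a$muIA,
                    a$buttons, variant_code(variant), a$visual_only, TRUE,
                    FALSE)
}

#' Predicted distributions for every condition of a design
#'
#' @inheritParams predicted_distributions
#' @param design A `rabbit_design`.
#' @param conditions Optional subset of condition ids.
#' @param stream Common-random-number stream offset.
#' @return Named list (by condition id) of [predicted_distributions()]
#'   results; sub-seeds derive from `seed` via [condition_seed()].
#' @export
predict_design <- function(design, params, means = prior_means(),
                           variant = "BCI", n = 5000, seed = 1,
                           conditions = NULL, stream = 0, pseudocount = 1) {
  ids <- if (is.null(conditions)) condition_ids(design) else conditions
  zs <- crn_draws(ids, n, seed, stream)
  out <- lapply(ids, function(id) {
    predicted_distributions(get_condition(design, id), params, means,
                            variant, z = zs[[id]], seed = seed,
                            pseudocount = pseudocount)
  })
  names(out) <- ids
  out
}

# press-sequence strings for a matrix of raw per-trial outcomes
outcomes_to_presses <- function(outc) {
  apply(outc, 1, function(o) paste(o[o < 6L], collapse = "-"))
}

#' Predicted illusion (or match) rates
#'
#' Simulates `n` trials per condition through the observer and analyses the
#' model's responses exactly like participants' responses: each simulated
#' trial's outcomes become an ordered press sequence (absent bins dropped)
#' which is scored against the condition's illusion-analog (or veridical
#' match) patterns, as in [score_trial_illusion()]. Deterministic given
#' `seed`; with common random numbers (shared `seed`/`stream`) rates are
#' directly comparable across variants and parameter settings.
#'
#' @inheritParams predict_design
#' @param score `"illusion"` (illusion-analog pattern) or `"match"`
#'   (veridical sequence).
#' @return data.frame with `condition_id`, `variant`, `illusion_rate`.
#' @export
predicted_illusion_rates <- function(design, params, means = prior_means(),
                                     variant = "BCI", n = 5000, seed = 1,
                                     conditions = NULL, score = "illusion",
                                     stream = 0) {
  ids <- if (is.null(conditions)) condition_ids(design) else conditions
  zs <- crn_draws(ids, n, seed, stream)
  rate <- vapply(ids, function(id) {
    cond <- get_condition(design, id)
    patterns <- if (score == "illusion") cond$illusion_patterns
                else list(cond$match_pattern)
    pat_str <- vapply(patterns, paste, character(1), collapse = "-")
    outc <- simulate_outcomes(cond, params, means, variant, z = zs[[id]])
    mean(outcomes_to_presses(outc) %in% pat_str)
  }, numeric(1))
  data.frame(condition_id = ids, variant = variant, illusion_rate = rate,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Illusion rates under scaled spatial uncertainty
#'
#' Multiplies the spatial sensory SDs (auditory and visual) by each scale
#' factor and recomputes the predicted illusion rates, probing how strongly
#' the illusions rely on precise spatial processing.
#'
#' @inheritParams predicted_illusion_rates
#' @param scale_factors Positive multipliers for `sigma_sA` and `sigma_sV`.
#' @return data.frame with one row per (condition, factor).
#' @export
spatial_uncertainty_simulation <- function(design, params,
                                           means = prior_means(),
                                           scale_factors = c(1, 2, 4),
                                           variant = "BCI", n = 5000,
                                           seed = 1, conditions = NULL) {
  if (any(scale_factors <= 0)) stop("scale_factors must be > 0")
  out <- lapply(scale_factors, function(f) {
    p <- set_params(params,
                    sigma_sA = params[["sigma_sA"]] * f,
                    sigma_sV = params[["sigma_sV"]] * f)
    r <- predicted_illusion_rates(design, p, means, variant, n, seed,
                                  conditions = conditions)
    r$scale_factor <- f
    r
  })
  do.call(rbind, out)
}

#' Tidy table of predicted distributions
#'
#' @param pred Output of [predict_design()].
#' @return data.frame (condition_id, event, bin, prob, variant, n_sim, seed).
#' @export
prediction_table <- function(pred) {
  do.call(rbind, lapply(pred, function(p) {
    data.frame(
      condition_id = p$condition_id,
      event = rep(1:3, times = 6),
      bin = rep(colnames(p$probs), each = 3),
      prob = as.vector(p$probs),
      variant = p$variant, n_sim = p$n_sim, seed = p$seed,
      stringsAsFactors = FALSE
    )
  }))
}
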