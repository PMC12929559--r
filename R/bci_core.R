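#' Analytic pair likelihood under a common cause
#'
#' Closed-form density of one audiovisual cue pair (e.g. the spatial cues of
#' one flash-beep event) under the common-cause structure: the marginal of
#' the product of two Gaussian likelihoods around a shared latent source and
#' a Gaussian prior over that source, integrated over the source.
#'
#' @param a_cue,v_cue Auditory and visual cue values (vectorised).
#' @param sigma_a,sigma_v Sensory SDs (> 0).
#' @param mu_p Prior mean of the latent source.
#' @param sigma_p Prior SD (> 0).
#' @param log Return the log density?
#' @return Density (strictly positive) or log density.
#' @export
pair_likelihood_common <- function(a_cue, v_cue, sigma_a, sigma_v,
                                   mu_p, sigma_p, log = FALSE) {
  check_sds(sigma_a, sigma_v, sigma_p)
  va <- sigma_a^2; vv <- sigma_v^2; vp <- sigma_p^2
  D <- vv * va + vv * vp + va * vp
  q <- ((v_cue - a_cue)^2 * vp +
        (v_cue - mu_p)^2 * va +
        (a_cue - mu_p)^2 * vv) / D
  ll <- -log(2 * pi) - 0.5 * log(D) - 0.5 * q
  if (log) ll else exp(ll)
}

#' Analytic pair likelihood under independent causes
#'
#' Product of the two marginal Gaussians obtained by integrating each
#' modality's likelihood against its own source prior: each marginal has
#' variance sigma^2 + sigma_p^2.
#'
#' @inheritParams pair_likelihood_common
#' @param mu_a,mu_v Per-modality prior means (both default to `mu_p`; the
#'   intensity dimension uses modality-specific prior means).
#' @export
pair_likelihood_independent <- function(a_cue, v_cue, sigma_a, sigma_v,
                                        mu_p, sigma_p, log = FALSE,
                                        mu_a = mu_p, mu_v = mu_p) {
  check_sds(sigma_a, sigma_v, sigma_p)
  va <- sigma_a^2 + sigma_p^2
  vv <- sigma_v^2 + sigma_p^2
  ll <- -log(2 * pi) - 0.5 * log(vv * va) -
    0.5 * ((v_cue - mu_v)^2 / vv + (a_cue - mu_a)^2 / va)
  if (log) ll else exp(ll)
}

check_sds <- function(...) {
  if (any(c(...) <= 0)) stop("standard deviations must be > 0")
}

# Per-pair, per-cue log likelihoods for one sensory sample.
# x_a, x_v: 3 x 3 matrices (event x cue, cues = space, time, intensity).
# Intensity cues are centred on their modality-specific prior means before
# the shared closed form (exact solution for a common latent intensity
# observed with modality offsets).
pair_loglik_matrix <- function(x_a, x_v, params, means, common = TRUE) {
  sa <- c(params[["sigma_sA"]], params[["sigma_tA"]], params[["sigma_iA"]])
  sv <- c(params[["sigma_sV"]], params[["sigma_tV"]], params[["sigma_iV"]])
  sp <- c(params[["sigma_S_P"]], params[["sigma_T_P"]], params[["sigma_I_P"]])
  mu <- cbind(means$mu_S_P, means$mu_T_P, 0)        # shared means (space, time)
  mu_a <- cbind(means$mu_S_P, means$mu_T_P, means$mu_I_P_A)
  mu_v <- cbind(means$mu_S_P, means$mu_T_P, means$mu_I_P_V)
  out <- matrix(NA_real_, 3, 3,
                dimnames = list(paste0("event", 1:3), c("s", "t", "i")))
  for (cue in 1:3) {
    a <- x_a[, cue] - mu_a[, cue]
    v <- x_v[, cue] - mu_v[, cue]
    out[, cue] <- if (common) {
      pair_likelihood_common(a, v, sa[cue], sv[cue], 0, sp[cue], log = TRUE)
    } else {
      pair_likelihood_independent(a, v, sa[cue], sv[cue], 0, sp[cue],
                                  log = TRUE)
    }
  }
  out
}

#' Posterior probability of a common cause
#'
#' Accumulates the per-pair, per-cue (space, time, intensity) log
#' likelihoods across the included flash-beep pairs under each causal
#' structure and combines them with the causal prior `p_common` by Bayes
#' rule. Computed in log space.
#'
#' @param sample A sensory sample: list with `x_A` and `x_V`, each a 3 x 3
#'   matrix (event x cue; cues space/time/intensity), see
#'   [sample_sensory_inputs()].
#' @param params A [model_params()] vector.
#' @param means Prior means, see [prior_means()].
#' @param included_pairs Subset of 1:3 over which causal evidence is
#'   accumulated (the non-postdictive observer uses 1:2).
#' @return List with `p_c1`, `log_lik_c1`, `log_lik_c2`, `included_pairs`.
#' @export
causal_posterior <- function(sample, params, means = prior_means(),
                             included_pairs = 1:3) {
  if (length(included_pairs) == 0) stop("included_pairs must be nonempty")
  pc <- params[["p_common"]]
  l1 <- pair_loglik_matrix(sample$x_A, sample$x_V, params, means, TRUE)
  l2 <- pair_loglik_matrix(sample$x_A, sample$x_V, params, means, FALSE)
  s1 <- sum(l1[included_pairs, ])
  s2 <- sum(l2[included_pairs, ])
  p_c1 <- if (pc >= 1) 1 else if (pc <= 0) 0 else {
    stats::plogis(log(pc) - log1p(-pc) + s1 - s2)
  }
  list(p_c1 = p_c1, log_lik_c1 = s1, log_lik_c2 = s2,
       included_pairs = included_pairs)
}

#' Reliability-weighted fusion estimate
#'
#' Inverse-variance-weighted combination of the visual cue, the auditory cue
#' and the prior mean (the common-cause estimate).
#'
#' @param v_cue,a_cue Cue values.
#' @param sigma_v,sigma_a,sigma_p SDs (> 0).
#' @param mu_p Prior mean.
#' @export
fusion_estimate <- function(v_cue, a_cue, sigma_v, sigma_a, mu_p, sigma_p) {
  check_sds(sigma_v, sigma_a, sigma_p)
  wv <- 1 / sigma_v^2; wa <- 1 / sigma_a^2; wp <- 1 / sigma_p^2
  (v_cue * wv + a_cue * wa + mu_p * wp) / (wv + wa + wp)
}

#' Segregation estimate
#'
#' Inverse-variance-weighted combination of the visual cue and the prior
#' mean only (the independent-causes estimate of the visual stimulus).
#'
#' @inheritParams fusion_estimate
#' @export
segregation_estimate <- function(v_cue, sigma_v, mu_p, sigma_p) {
  check_sds(sigma_v, sigma_p)
  wv <- 1 / sigma_v^2; wp <- 1 / sigma_p^2
  (v_cue * wv + mu_p * wp) / (wv + wp)
}

#' Model-averaged estimate
#'
#' Final percept under causal uncertainty: the fusion and segregation
#' estimates mixed in proportion to the causal posterior.
#'
#' @param fused,segregated Component estimates.
#' @param p_c1 Posterior probability of a common cause, in [0, 1].
#' @export
model_average <- function(fused, segregated, p_c1) {
  if (any(p_c1 < 0 | p_c1 > 1)) stop("p_c1 must be in [0, 1]")
  p_c1 * fused + (1 - p_c1) * segregated
}

#' Perceive one trial
#'
#' Runs the observer on one sensory sample of a condition: one causal
#' posterior per trial (pairs 1:3 for BCI; 1:2 for the non-postdictive
#' BCI_NP; forced to 1/0 for FF/FS), then per-event visual spatial and
#' intensity estimates by model averaging of the fusion and segregation
#' estimates. Unisensory (0-beep) conditions take the visual-only
#' segregation path for every variant. Temporal estimates are not produced
#' (no timing report is collected).
#'
#' @param sample Sensory sample (list `x_A`, `x_V`, 3 x 3 each).
#' @param condition Condition from [get_condition()].
#' @param params A [model_params()] vector.
#' @param means Prior means.
#' @param variant One of "BCI", "BCI_NP", "FF", "FS".
#' @return List of class `percept`: `S_hat_V`, `I_hat_V` (length 3), the
#'   intermediate fusion/segregation estimates, and `p_c1`.
#' @export
perceive_trial <- function(sample, condition, params, means = prior_means(),
                           variant = "BCI") {
  variant_code(variant)  # validates
  visual_only <- is_visual_only(condition)

  sv_s <- params[["sigma_sV"]]; sa_s <- params[["sigma_sA"]]
  sv_i <- params[["sigma_iV"]]; sa_i <- params[["sigma_iA"]]
  sp_s <- params[["sigma_S_P"]]; sp_i <- params[["sigma_I_P"]]

  seg_S <- segregation_estimate(sample$x_V[, 1], sv_s, means$mu_S_P, sp_s)
  seg_I <- segregation_estimate(sample$x_V[, 3], sv_i, means$mu_I_P_V, sp_i)

  if (visual_only) {
    p_c1 <- NA_real_
    fus_S <- fus_I <- rep(NA_real_, 3)
    S_hat <- seg_S; I_hat <- seg_I
  } else {
    p_c1 <- switch(variant,
      FF = 1,
      FS = 0,
      BCI = causal_posterior(sample, params, means, 1:3)$p_c1,
      BCI_NP = causal_posterior(sample, params, means, 1:2)$p_c1
    )
    fus_S <- fusion_estimate(sample$x_V[, 1], sample$x_A[, 1], sv_s, sa_s,
                             means$mu_S_P, sp_s)
    fus_I <- fusion_estimate(sample$x_V[, 3], sample$x_A[, 3], sv_i, sa_i,
                             means$mu_I_P_V, sp_i)
    S_hat <- model_average(fus_S, seg_S, p_c1)
    I_hat <- model_average(fus_I, seg_I, p_c1)
  }
  structure(list(S_hat_V = S_hat, I_hat_V = I_hat,
                 S_hat_AV_C1 = fus_S, I_hat_AV_C1 = fus_I,
                 S_hat_V_C2 = seg_S, I_hat_V_C2 = seg_I,
                 p_c1 = p_c1, variant = variant),
            class = "percept")
}

#' Map a percept to button responses
#'
#' Per event: if the inferred visual intensity is at or below the perceptual
#' threshold `phi_I` the event falls in the sixth ("no flash") bin;
#' otherwise the nearest button to the inferred azimuth is pressed. Exact
#' midpoints between two buttons break toward the lower-index button.
#'
#' @param percept A `percept` from [perceive_trial()].
#' @param params A [model_params()] vector (supplies `phi_I`).
#' @param layout Button layout.
#' @return Integer vector of 3 outcomes in 1..6 (6 = no flash).
#' @export
map_to_response <- function(percept, params, layout = button_layout()) {
  vapply(1:3, function(j) {
    if (percept$I_hat_V[j] <= params[["phi_I"]]) return(6L)
    d <- abs(layout - percept$S_hat_V[j])
    which.min(d)  # first minimum -> lower index on ties
  }, integer(1))
}
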