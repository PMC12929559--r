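# shared fixtures: the canonical design and representative observer
# parameters (moderate causal prior, precise audition in intensity,
# spatially precise vision)

design28 <- build_design()

rep_params <- model_params(p_common = 0.5, sigma_sA = 5, sigma_sV = 2,
                           sigma_tA = 60, sigma_tV = 60, sigma_iV = 0.3,
                           phi_I = 0.5)

# a tiny deterministic trial table: one participant, given conditions
tiny_trials <- function(conditions, responses, participant = "P01") {
  data.frame(participant_id = participant,
             block = 1L,
             condition_id = rep(conditions, each = length(responses)),
             trial_index = seq_len(length(conditions) * length(responses)),
             response = rep(responses, times = length(conditions)),
             is_catch = FALSE, stringsAsFactors = FALSE)
}

# brute-force (linear-space) causal posterior from the pair densities,
# independent of the log-space implementation path
posterior_linear <- function(sample, params, means, included = 1:3) {
  lik <- function(common) {
    out <- 1
    sa <- c(params[["sigma_sA"]], params[["sigma_tA"]], params[["sigma_iA"]])
    sv <- c(params[["sigma_sV"]], params[["sigma_tV"]], params[["sigma_iV"]])
    sp <- c(params[["sigma_S_P"]], params[["sigma_T_P"]], params[["sigma_I_P"]])
    mu_a <- cbind(means$mu_S_P, means$mu_T_P, means$mu_I_P_A)
    mu_v <- cbind(means$mu_S_P, means$mu_T_P, means$mu_I_P_V)
    for (j in included) for (cue in 1:3) {
      a <- sample$x_A[j, cue] - mu_a[j, cue]
      v <- sample$x_V[j, cue] - mu_v[j, cue]
      out <- out * if (common) {
        pair_likelihood_common(a, v, sa[cue], sv[cue], 0, sp[cue])
      } else {
        pair_likelihood_independent(a, v, sa[cue], sv[cue], 0, sp[cue])
      }
    }
    out
  }
  pc <- params[["p_common"]]
  l1 <- lik(TRUE); l2 <- lik(FALSE)
  pc * l1 / (pc * l1 + (1 - pc) * l2)
}
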