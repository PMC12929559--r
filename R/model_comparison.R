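#' Information criteria
#'
#' BIC = -2 LL + m ln(n); AIC = 2 m - 2 LL. `n` is the number of scored
#' event outcomes (3 per non-catch trial).
#'
#' @param LL Log likelihood.
#' @param m Number of free parameters (>= 0).
#' @param n Number of data points (>= 1).
#' @return Named vector with `BIC` and `AIC`.
#' @export
info_criteria <- function(LL, m, n) {
  if (n < 1) stop("n must be >= 1")
  if (m < 0) stop("m must be >= 0")
  LL <- unname(LL); m <- unname(m); n <- unname(n)
  c(BIC = -2 * LL + m * log(n), AIC = 2 * m - 2 * LL)
}

#' Nagelkerke pseudo-R-squared
#'
#' Likelihood-based coefficient of determination against a null model
#' (random guessing across the six response bins), normalised to [0, 1]:
#' R2 = (1 - exp((2/n)(LL0 - LL))) / (1 - exp((2/n) LL0)).
#'
#' @param LL_model Model log likelihood.
#' @param LL_null Null-model log likelihood on the same outcomes
#'   (uniform six-bin model: n_outcomes * log(1/6)).
#' @param n Number of data points.
#' @return R-squared in [0, 1].
#' @export
nagelkerke_r2 <- function(LL_model, LL_null, n) {
  if (n < 1) stop("n must be >= 1")
  r2 <- (1 - exp((2 / n) * (LL_null - LL_model))) /
        (1 - exp((2 / n) * LL_null))
  min(max(r2, 0), 1)
}

#' Group-relative information criteria
#'
#' Per participant, expresses each model's IC relative to that participant's
#' best model (minimum), then sums across participants.
#'
#' @param ic Participant x model matrix of ICs (same model set for all).
#' @return Named vector of summed relative ICs (>= 0, at least one zero per
#'   participant before summing).
#' @export
group_relative_ic <- function(ic) {
  ic <- as.matrix(ic)
  if (anyNA(ic)) stop("missing ICs")
  rel <- sweep(ic, 1, apply(ic, 1, min), "-")
  colSums(rel)
}

#' Random-effects Bayesian model selection
#'
#' Variational Dirichlet estimation of population model frequencies from
#' per-participant log model evidences, with exceedance probabilities by
#' Monte-Carlo sampling of the posterior Dirichlet, the Bayes omnibus risk
#' (BOR: posterior probability that all models are equally frequent,
#' computed from the variational free energy against the equal-frequency
#' null) and the protected exceedance probability
#' PEP_k = EP_k (1 - BOR) + BOR / K.
#'
#' @param log_evidence Participant x model matrix of log model evidences
#'   (e.g. -BIC/2, see [evidence_from_ic()]).
#' @param alpha0 Dirichlet prior counts (default 1 per model).
#' @param n_samples Dirichlet Monte-Carlo draws for the exceedance
#'   probabilities (default 1e6).
#' @param seed Seed for the Monte-Carlo draws.
#' @param tol,max_iter Variational stopping rule (frequency change < tol).
#' @return List: `alpha`, `expected_freq`, `exceedance_prob`, `bor`, `pep`,
#'   `model_attribution` (participant x model responsibilities).
#' @export
rfx_bms <- function(log_evidence, alpha0 = NULL, n_samples = 1e6, seed = 1,
                    tol = 1e-6, max_iter = 10000) {
  L <- as.matrix(log_evidence)
  if (ncol(L) < 2) stop("need at least 2 models")
  if (any(!is.finite(L))) stop("non-finite log evidences")
  N <- nrow(L); K <- ncol(L)
  if (is.null(alpha0)) alpha0 <- rep(1, K)
  # centre rows for numerical stability (invariant for all outputs)
  L <- L - apply(L, 1, max)

  alpha <- alpha0
  for (it in seq_len(max_iter)) {
    elogr <- digamma(alpha) - digamma(sum(alpha))
    u <- L + matrix(elogr, N, K, byrow = TRUE)
    u <- exp(u - apply(u, 1, max))
    z <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(z)
    if (max(abs(alpha_new / sum(alpha_new) - alpha / sum(alpha))) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  elogr <- digamma(alpha) - digamma(sum(alpha))
  u <- L + matrix(elogr, N, K, byrow = TRUE)
  u <- exp(u - apply(u, 1, max))
  z <- u / rowSums(u)

  # exceedance probabilities by Dirichlet sampling
  set.seed(condition_seed(seed, 424242, 0))
  g <- matrix(stats::rgamma(n_samples * K, shape = rep(alpha, each = 1)),
              ncol = K, byrow = TRUE)
  winner <- max.col(g, ties.method = "first")
  ep <- tabulate(winner, nbins = K) / n_samples

  # variational free energy of the RFX model (at convergence)
  zl <- z * (L + matrix(elogr, N, K, byrow = TRUE))
  ent <- z * log(z)
  ent[z == 0] <- 0
  F1 <- sum(zl) - sum(ent) +
    lgamma(sum(alpha0)) - sum(lgamma(alpha0)) -
    lgamma(sum(alpha)) + sum(lgamma(alpha)) +
    sum((alpha0 - alpha + colSums(z)) * elogr) - sum(colSums(z) * elogr)
  # null model: fixed equal frequencies
  F0 <- sum(apply(L, 1, function(r) log(sum(exp(r - max(r)))) + max(r)) -
              log(K))
  bor <- 1 / (1 + exp(F1 - F0))
  pep <- ep * (1 - bor) + bor / K

  names(ep) <- names(pep) <- colnames(L)
  list(alpha = stats::setNames(alpha, colnames(L)),
       expected_freq = stats::setNames(alpha / sum(alpha), colnames(L)),
       exceedance_prob = ep, bor = bor, pep = pep,
       model_attribution = z, n_samples = n_samples)
}

#' Log model evidence from an information criterion
#'
#' Standard approximation log p(y | model) ~ -IC/2 (BIC by default).
#'
#' @param ic Participant x model IC matrix.
#' @export
evidence_from_ic <- function(ic) {
  -as.matrix(ic) / 2
}

#' Group model-comparison table
#'
#' Builds the group summary over participants and model variants: summed
#' group-relative BIC and AIC, mean Nagelkerke R2, and protected exceedance
#' probabilities from BIC-based random-effects model selection.
#'
#' @param ll Participant x model matrix of maximised log likelihoods.
#' @param m Named vector (by model) of free-parameter counts.
#' @param n_points Per-participant data-point counts (length = participants).
#' @param evidence `"BIC"` (default) or `"AIC"` as the evidence
#'   approximation for the RFX-BMS step.
#' @param seed Seed for the exceedance Monte-Carlo.
#' @return List with `table` (one row per model: relBIC_Group, relAIC_Group,
#'   mean_R2, PEP) and the underlying `bic`, `aic`, `r2`, `bms` objects.
#' @export
comparison_table <- function(ll, m, n_points, evidence = "BIC", seed = 1) {
  ll <- as.matrix(ll)
  models <- colnames(ll)
  N <- nrow(ll)
  bic <- aic <- r2 <- matrix(NA_real_, N, length(models),
                             dimnames = dimnames(ll))
  for (i in seq_len(N)) {
    ll0 <- n_points[i] * log(1 / 6)
    for (k in seq_along(models)) {
      icv <- info_criteria(ll[i, k], m[[models[k]]], n_points[i])
      bic[i, k] <- icv[["BIC"]]
      aic[i, k] <- icv[["AIC"]]
      r2[i, k] <- nagelkerke_r2(ll[i, k], ll0, n_points[i])
    }
  }
  bms <- rfx_bms(evidence_from_ic(if (evidence == "AIC") aic else bic),
                 seed = seed)
  tab <- data.frame(
    model = models,
    relBIC_Group = as.numeric(group_relative_ic(bic)),
    relAIC_Group = as.numeric(group_relative_ic(aic)),
    mean_R2 = colMeans(r2),
    PEP = as.numeric(bms$pep),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(table = tab, bic = bic, aic = aic, r2 = r2, bms = bms)
}
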