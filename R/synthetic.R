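#' Specification of a synthetic cohort
#'
#' Defines the study conditions emulated by the generator: cohort size and
#' trials per condition as in the experiment (28 x 28), the catch-trial
#' rate (6.66% of all trials, i.e. 4 of 60 per block), the generating model
#' variant(s), and uniform sampling ranges for the free observer parameters
#' (chosen to span regimes from near-zero to near-ceiling illusion rates).
#'
#' @param n_participants Cohort size (default 28).
#' @param trials_per_condition Trials per condition (default 28).
#' @param variant Generating variant, recycled over participants.
#' @param catch_rate Proportion of catch trials (default 0.0666).
#' @param ranges Named list of c(lower, upper) sampling ranges.
#' @param seed Master seed.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 28, trials_per_condition = 28,
                        variant = "BCI", catch_rate = 0.0666,
                        ranges = default_param_ranges(), seed = 1) {
  if (n_participants < 1 || trials_per_condition < 1) {
    stop("counts must be >= 1")
  }
  b <- default_bounds()
  for (nm in names(ranges)) {
    i <- match(nm, b$param)
    if (!is.na(i) &&
        (ranges[[nm]][1] < b$lower[i] || ranges[[nm]][2] > b$upper[i])) {
      stop("sampling range for ", nm, " outside fitting bounds")
    }
  }
  structure(list(n_participants = n_participants,
                 trials_per_condition = trials_per_condition,
                 variant = rep_len(variant, n_participants),
                 catch_rate = catch_rate, ranges = ranges, seed = seed),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_param_ranges <- function() {
  list(p_common = c(0.2, 0.8),
       sigma_sA = c(1, 10), sigma_sV = c(0.5, 5),
       sigma_tA = c(20, 150), sigma_tV = c(20, 150),
       sigma_iV = c(0.1, 0.5))
}

#' Generate one synthetic participant
#'
#' For every condition of the design, simulates `trials_per_condition`
#' trials through the generative observer (sensory sampling, perception,
#' response mapping) and converts the per-event outcomes back into press
#' sequences (absent bins dropped, order preserved — the inverse of
#' [encode_trial_outcomes()]). Catch trials (centre press) are appended at
#' the catch rate (4 per block of 60, as in the session structure).
#'
#' @param params A [model_params()] vector (the ground truth).
#' @param design A `rabbit_design`.
#' @param variant Generating model variant.
#' @param trials_per_condition Trials per condition.
#' @param seed Seed (deterministic trial table).
#' @param participant_id Identifier for the output table.
#' @param means Prior means.
#' @return List with `trials` (trial table) and `ground_truth` (one-row
#'   data.frame of the generating parameters and variant).
#' @export
generate_participant <- function(params, design, variant = "BCI",
                                 trials_per_condition =
                                   design$trials_per_condition,
                                 seed = 1, participant_id = "P01",
                                 means = prior_means()) {
  validate_params(params)
  ids <- condition_ids(design)
  n <- trials_per_condition
  rows <- lapply(seq_along(ids), function(k) {
    cond <- get_condition(design, ids[k])
    set.seed(condition_seed(seed, k, 9000))
    z <- matrix(stats::rnorm(n * 18L), n, 18L)
    outc <- simulate_outcomes(cond, params, means, variant, z = z)
    resp <- apply(outc, 1, function(o) paste(o[o < 6L], collapse = "-"))
    data.frame(participant_id = participant_id, condition_id = ids[k],
               response = resp, is_catch = FALSE, stringsAsFactors = FALSE)
  })
  trials <- do.call(rbind, rows)
  # catch trials: same proportion as the session (4 per 60-trial block)
  n_main <- nrow(trials)
  n_catch <- round(design$catch_rate / (1 - design$catch_rate) * n_main)
  if (n_catch > 0) {
    trials <- rbind(trials, data.frame(
      participant_id = participant_id, condition_id = "CATCH",
      response = "3", is_catch = TRUE, stringsAsFactors = FALSE))
    trials <- trials[c(seq_len(n_main), rep(n_main + 1L, n_catch)), ]
  }
  set.seed(condition_seed(seed, 0, 9001))
  trials <- trials[sample.int(nrow(trials)), ]
  trials$trial_index <- seq_len(nrow(trials))
  trials$block <- ceiling(trials$trial_index / 60)
  rownames(trials) <- NULL
  gt <- data.frame(participant_id = participant_id,
                   variant = variant, t(as.numeric(params)),
                   stringsAsFactors = FALSE)
  names(gt)[-(1:2)] <- names(params)
  list(trials = trials[, c("participant_id", "block", "condition_id",
                           "trial_index", "response", "is_catch")],
       ground_truth = gt)
}

#' Generate a synthetic cohort
#'
#' Independent participants whose free parameters are drawn uniformly
#' within the spec's ranges (fixed parameters at their canonical values:
#' large prior SDs, sigma_iA = 1e-10, phi_I = 0.5).
#'
#' @param spec A [cohort_spec()].
#' @param design A `rabbit_design`.
#' @return List with `trials` (all participants) and `ground_truth`.
#' @export
generate_cohort <- function(spec, design = build_design()) {
  set.seed(condition_seed(spec$seed, 0, 9100))
  N <- spec$n_participants
  draw <- function(nm) {
    r <- spec$ranges[[nm]]
    stats::runif(N, r[1], r[2])
  }
  mat <- sapply(names(spec$ranges), draw)
  if (N == 1) mat <- matrix(mat, nrow = 1,
                            dimnames = list(NULL, names(spec$ranges)))
  out <- lapply(seq_len(N), function(i) {
    p <- model_params()
    p[colnames(mat)] <- mat[i, ]
    if (spec$variant[i] == "FF") p[["p_common"]] <- 1
    if (spec$variant[i] == "FS") p[["p_common"]] <- 0
    generate_participant(p, design, spec$variant[i],
                         spec$trials_per_condition,
                         seed = condition_seed(spec$seed, i, 9200),
                         participant_id = sprintf("P%02d", i))
  })
  list(trials = do.call(rbind, lapply(out, `[[`, "trials")),
       ground_truth = do.call(rbind, lapply(out, `[[`, "ground_truth")),
       spec = spec)
}

#' Parameter recovery study
#'
#' Generates a cohort from the BCI observer, refits every participant with
#' the two-stage procedure, and reports true vs recovered parameters with
#' per-parameter Spearman rank correlations.
#'
#' @param spec A [cohort_spec()] generating from BCI.
#' @param design A `rabbit_design`.
#' @param n_starts Length-2 multi-start counts for stages 1 and 2.
#' @param n_sim Simulated trials per condition per evaluation.
#' @param seed Fitting seed.
#' @return List with `recovered` (participant, parameter, true, recovered)
#'   and `correlations` (Spearman, per recovered parameter).
#' @export
parameter_recovery <- function(spec, design = build_design(),
                               n_starts = c(10, 20), n_sim = 2000,
                               seed = 1) {
  if (!all(spec$variant == "BCI")) stop("spec must generate from BCI")
  cohort <- generate_cohort(spec, design)
  gt <- cohort$ground_truth
  rec_params <- c("p_common", "sigma_sA", "sigma_tA", "sigma_sV",
                  "sigma_tV", "sigma_iV")
  rows <- lapply(seq_len(nrow(gt)), function(i) {
    pid <- gt$participant_id[i]
    tr <- cohort$trials[cohort$trials$participant_id == pid, ]
    fit <- fit_participant(tr, design, variants = "BCI",
                           n_starts = n_starts, n_sim = n_sim,
                           seed = condition_seed(seed, i, 9300), stream = i)
    rec <- c(fit$fits$BCI$params[c("p_common", "sigma_sA", "sigma_tA",
                                   "sigma_tV")],
             fit$stage1$free[c("sigma_sV", "sigma_iV")])
    data.frame(participant_id = pid, parameter = rec_params,
               true = as.numeric(gt[i, rec_params]),
               recovered = as.numeric(rec[rec_params]),
               stringsAsFactors = FALSE)
  })
  recovered <- do.call(rbind, rows)
  correlations <- vapply(rec_params, function(pm) {
    d <- recovered[recovered$parameter == pm, ]
    stats::cor(d$true, d$recovered, method = "spearman")
  }, numeric(1))
  list(recovered = recovered, correlations = correlations,
       n_starts = n_starts, n_sim = n_sim)
}

#' Model recovery study
#'
#' For cohorts generated from each variant in the spec mix, fits all four
#' variants to every participant, runs BIC-based random-effects model
#' selection, and records the winning model and its protected exceedance
#' probability.
#'
#' @param spec A [cohort_spec()]; its `variant` field gives the generating
#'   mix (one cohort per unique variant).
#' @param design A `rabbit_design`.
#' @param n_starts,n_sim Fit settings.
#' @param seed Fitting seed.
#' @return data.frame: generating variant, selected variant, winner PEP.
#' @export
model_recovery <- function(spec, design = build_design(),
                           n_starts = c(5, 8), n_sim = 1000, seed = 1) {
  gen_variants <- unique(spec$variant)
  if (length(gen_variants) < 2) stop("need >= 2 generating variants")
  variants <- c("BCI", "BCI_NP", "FF", "FS")
  rows <- lapply(seq_along(gen_variants), function(gi) {
    gv <- gen_variants[gi]
    sp <- spec
    sp$variant <- rep(gv, spec$n_participants)
    sp$seed <- condition_seed(spec$seed, gi, 9400)
    cohort <- generate_cohort(sp, design)
    pids <- unique(cohort$trials$participant_id)
    ll <- matrix(NA_real_, length(pids), length(variants),
                 dimnames = list(pids, variants))
    npts <- numeric(length(pids))
    for (i in seq_along(pids)) {
      tr <- cohort$trials[cohort$trials$participant_id == pids[i], ]
      fit <- fit_participant(tr, design, variants = variants,
                             n_starts = n_starts, n_sim = n_sim,
                             seed = condition_seed(seed, i, 9500 + gi),
                             stream = i)
      ll[i, ] <- vapply(fit$fits, `[[`, numeric(1), "log_likelihood")
      npts[i] <- fit$n_points_av
    }
    m <- c(BCI = 4, BCI_NP = 4, FF = 3, FS = 3)
    bic <- t(vapply(seq_along(pids), function(i) {
      vapply(variants, function(v)
        info_criteria(ll[i, v], m[[v]], npts[i])[["BIC"]], numeric(1))
    }, numeric(length(variants))))
    colnames(bic) <- variants
    bms <- rfx_bms(evidence_from_ic(bic), seed = seed)
    win <- names(which.max(bms$pep))
    data.frame(generating = gv, selected = win,
               winner_pep = max(bms$pep), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
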