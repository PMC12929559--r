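#' Align ordered presses to the three events
#'
#' Converts a press sequence into three event outcomes (bins 1..5 = buttons,
#' 6 = no flash): 3 presses map to events (1,2,3); 2 presses to events
#' (1,3) with event 2 absent (the invisible-rabbit coding); 1 press to
#' event 1; 0 presses to all absent; more than 3 presses: first three taken.
#'
#' @param response List with `presses` (integer vector 1..5) and `is_catch`.
#' @param condition Condition from [get_condition()] (validation only).
#' @return Integer vector of 3 outcomes in 1..6.
#' @export
encode_trial_outcomes <- function(response, condition = NULL) {
  if (isTRUE(response$is_catch)) stop("catch trials are not encoded")
  p <- as.integer(response$presses)
  if (any(p < 1 | p > 5)) stop("presses must be in 1..5")
  out <- rep(6L, 3)
  n <- length(p)
  if (n >= 3) out <- p[1:3]
  else if (n == 2) out[c(1, 3)] <- p
  else if (n == 1) out[1] <- p
  out
}

#' Inverse of [encode_trial_outcomes()]
#'
#' Drops absent bins and preserves event order; round-trips exactly for
#' responses of up to three presses.
#'
#' @param outcomes Integer vector of 3 outcomes in 1..6.
#' @return Integer press vector.
#' @export
decode_outcomes <- function(outcomes) {
  as.integer(outcomes[outcomes < 6L])
}

#' Observed outcome counts per condition
#'
#' @param trials Trial table (non-catch rows are used).
#' @param design A `rabbit_design`.
#' @param conditions Optional subset of condition ids.
#' @return Named list of 3 x 6 count matrices (event x bin).
#' @export
outcome_counts <- function(trials, design, conditions = NULL) {
  trials <- trials[!trials$is_catch, , drop = FALSE]
  ids <- if (is.null(conditions)) intersect(condition_ids(design),
                                            unique(trials$condition_id))
         else conditions
  out <- lapply(ids, function(id) {
    m <- matrix(0, 3, 6, dimnames = list(paste0("event", 1:3),
                                         c(paste0("bin", 1:5), "absent")))
    resp <- trials$response[trials$condition_id == id]
    for (r in resp) {
      oc <- encode_trial_outcomes(list(presses = parse_response(r),
                                       is_catch = FALSE))
      for (j in 1:3) m[j, oc[j]] <- m[j, oc[j]] + 1
    }
    m
  })
  names(out) <- ids
  out
}

# per-condition engine inputs for a deterministic (common-random-number)
# objective over the conditions present in `counts`
build_objective_data <- function(design, counts, params_template, means,
                                 n_sim, seed, stream = 0) {
  ids <- names(counts)
  all_ids <- condition_ids(design)
  z_list <- vector("list", length(ids))
  distal_list <- vector("list", length(ids))
  vis <- logical(length(ids))
  for (k in seq_along(ids)) {
    cond <- get_condition(design, ids[k])
    set.seed(condition_seed(seed, match(ids[k], all_ids), stream))
    z_list[[k]] <- matrix(stats::rnorm(n_sim * 18L), n_sim, 18L)
    distal_list[[k]] <- distal_stimulus(cond)
    vis[k] <- is_visual_only(cond)
  }
  list(ids = ids, z = z_list, distal = distal_list, visual_only = vis,
       obs = unname(counts), means = means)
}

param_order <- c("p_common", "sigma_S_P", "sigma_T_P", "sigma_I_P",
                 "sigma_sA", "sigma_tA", "sigma_iA", "sigma_sV", "sigma_tV",
                 "sigma_iV", "phi_I")

objective_ll <- function(par_full, dat, variant, pseudocount) {
  .engine_loglik(dat$z, dat$distal, dat$obs, dat$visual_only,
                 as.numeric(par_full[param_order]),
                 dat$means$mu_T_P, dat$means$mu_I_P_V, dat$means$mu_I_P_A,
                 button_layout(), variant_code(variant), pseudocount)
}

#' Monte-Carlo multinomial log likelihood of a trial set
#'
#' Sum over non-catch trials and their three event outcomes of the log
#' predicted bin probability (pseudocount-floored) under a model variant.
#' Deterministic given `seed` (common random numbers per condition).
#'
#' @param trials Trial table.
#' @param design A `rabbit_design`.
#' @param params A [model_params()] vector.
#' @param means Prior means.
#' @param variant Model variant.
#' @param n_sim Simulated trials per condition.
#' @param seed Master seed for the draws.
#' @param pseudocount Per-bin floor.
#' @param stream Common-random-number stream offset.
#' @return Log likelihood (scalar).
#' @export
log_likelihood <- function(trials, design, params, means = prior_means(),
                           variant = "BCI", n_sim = 5000, seed = 1,
                           pseudocount = 1, stream = 0) {
  counts <- outcome_counts(trials, design)
  if (length(counts) == 0) stop("no non-catch trials")
  dat <- build_objective_data(design, counts, params, means, n_sim, seed,
                              stream)
  objective_ll(params, dat, variant, pseudocount)
}

#' Log likelihood from precomputed predicted distributions
#'
#' @param trials Trial table.
#' @param design A `rabbit_design`.
#' @param pred Output of [predict_design()] covering the trial conditions.
#' @return Log likelihood (scalar).
#' @export
loglik_from_predictions <- function(trials, design, pred) {
  counts <- outcome_counts(trials, design)
  sum(vapply(names(counts), function(id) {
    if (is.null(pred[[id]])) stop("no predictions for condition ", id)
    sum(counts[[id]] * log(pred[[id]]$probs))
  }, numeric(1)))
}

# box transform: unconstrained u <-> bounded x
box_to_u <- function(x, lo, hi) stats::qlogis((x - lo) / (hi - lo))
u_to_box <- function(u, lo, hi) lo + (hi - lo) * stats::plogis(u)

bounds_for <- function(bounds, params) {
  i <- match(params, bounds$param)
  if (anyNA(i)) stop("no bounds for: ",
                     paste(params[is.na(i)], collapse = ", "))
  list(lo = bounds$lower[i], hi = bounds$upper[i])
}

# multi-start bounded Nelder-Mead maximization of a deterministic objective
multistart_fit <- function(obj, free_names, bounds, n_starts, seed,
                           maxit = 250, reltol = 1e-7) {
  b <- bounds_for(bounds, free_names)
  k <- length(free_names)
  set.seed(condition_seed(seed, 777, 31))
  grid <- lhs::randomLHS(n_starts, k)
  # optimise on log scale for SDs, logit for probabilities
  logish <- grepl("^sigma", free_names)
  lo <- ifelse(logish, log(b$lo), b$lo)
  hi <- ifelse(logish, log(b$hi), b$hi)
  to_x <- function(u) {
    x <- u_to_box(u, lo, hi)
    ifelse(logish, exp(x), x)
  }
  f <- function(u) obj(stats::setNames(to_x(u), free_names))
  best <- NULL
  start_ll <- numeric(n_starts)
  for (s in seq_len(n_starts)) {
    u0 <- box_to_u(lo + grid[s, ] * (hi - lo) * 0.998 +
                     0.001 * (hi - lo), lo, hi)
    fit <- stats::optim(u0, f, method = "Nelder-Mead",
                        control = list(fnscale = -1, maxit = maxit,
                                       reltol = reltol))
    start_ll[s] <- fit$value
    if (is.null(best) || fit$value > best$value) {
      best <- fit
      best$start <- s
    }
  }
  list(par = stats::setNames(to_x(best$par), free_names),
       log_likelihood = best$value, best_start = best$start,
       start_ll = start_ll)
}

#' Stage 1: fit the visual parameters on unisensory conditions
#'
#' Fits (sigma_sV, sigma_tV, sigma_iV) to the 0-beep (unisensory visual)
#' conditions with the intensity threshold fixed at 0.5. The returned
#' `fix` element carries (sigma_sV, sigma_iV) for fixing in stage 2;
#' sigma_tV is discarded (the unisensory conditions carry no asynchrony, so
#' fixing it here would underestimate asynchrony effects) and is re-fitted
#' in stage 2.
#'
#' @param trials Trial table containing only unisensory-condition trials.
#' @param design A `rabbit_design`.
#' @param bounds Bounds table, see [default_bounds()].
#' @param n_starts Random initialisations (default 50).
#' @param n_sim Simulated trials per condition per evaluation.
#' @param seed Master seed (draws and starts).
#' @param phi_I Fixed intensity threshold.
#' @param pseudocount Per-bin floor.
#' @param stream Common-random-number stream offset.
#' @return List of class `rabbit_fit` with `free` (all three fitted values),
#'   `fix` (sigma_sV, sigma_iV), `log_likelihood`, provenance fields.
#' @export
fit_unisensory_visual <- function(trials, design, bounds = default_bounds(),
                                  n_starts = 50, n_sim = 5000, seed = 1,
                                  phi_I = 0.5, pseudocount = 1, stream = 0) {
  ids <- unique(trials$condition_id[!trials$is_catch])
  nb <- design$conditions$n_beeps[match(ids, design$conditions$condition_id)]
  if (any(nb > 0)) stop("multisensory trials present in unisensory fit")
  counts <- outcome_counts(trials, design)
  base <- model_params(phi_I = phi_I)
  means <- prior_means()
  dat <- build_objective_data(design, counts, base, means, n_sim, seed,
                              stream)
  free_names <- c("sigma_sV", "sigma_tV", "sigma_iV")
  obj <- function(free) {
    p <- base
    p[names(free)] <- free
    objective_ll(p, dat, "FS", pseudocount)  # visual-only path regardless
  }
  res <- multistart_fit(obj, free_names, bounds, n_starts, seed)
  structure(list(
    stage = "unisensory", variant = NA_character_, free = res$par,
    fix = res$par[c("sigma_sV", "sigma_iV")],
    fixed = c(phi_I = phi_I),
    log_likelihood = res$log_likelihood, n_starts = n_starts,
    best_start = res$best_start, start_ll = res$start_ll,
    bounds = bounds[bounds$param %in% free_names, ],
    n_sim = n_sim, seed = seed, pseudocount = pseudocount,
    n_points = 3L * sum(!trials$is_catch)
  ), class = "rabbit_fit")
}

#' Stage 2: fit the multisensory parameters
#'
#' Fits (p_common, sigma_sA, sigma_tA, sigma_tV) for the BCI and BCI_NP
#' variants, or (sigma_sA, sigma_tA, sigma_tV) for FF/FS (whose causal
#' prior is pinned at 1/0: one free parameter less), to the audiovisual
#' conditions. Fixed throughout: sigma_sV and sigma_iV from stage 1,
#' sigma_iA = 1e-10 (near-perfect beep detection), the large prior SDs, and
#' phi_I = 0.5. Multi-start bounded Nelder-Mead on the deterministic
#' common-random-number objective; the best start is returned.
#'
#' @param trials Trial table containing only audiovisual-condition trials.
#' @param design A `rabbit_design`.
#' @param fixed Named vector with at least `sigma_sV`, `sigma_iV` (stage-1
#'   output), optionally overriding `sigma_iA`, `phi_I`.
#' @param variant Model variant.
#' @param bounds Bounds table.
#' @param n_starts Random initialisations (default 100).
#' @param n_sim Simulated trials per condition per evaluation (default
#'   5000).
#' @param seed Master seed.
#' @param pseudocount Per-bin floor.
#' @param stream Common-random-number stream offset.
#' @return List of class `rabbit_fit`: fitted `free` parameters, full
#'   `params` vector, `log_likelihood`, `n_points`, provenance.
#' @export
fit_multisensory <- function(trials, design, fixed, variant = "BCI",
                             bounds = default_bounds(), n_starts = 100,
                             n_sim = 5000, seed = 1, pseudocount = 1,
                             stream = 0) {
  if (!all(c("sigma_sV", "sigma_iV") %in% names(fixed))) {
    stop("fixed must carry sigma_sV and sigma_iV from the unisensory stage")
  }
  ids <- unique(trials$condition_id[!trials$is_catch])
  nb <- design$conditions$n_beeps[match(ids, design$conditions$condition_id)]
  if (any(nb == 0)) stop("unisensory trials present in multisensory fit")
  base <- model_params(
    p_common = switch(variant, FF = 1, FS = 0, 0.5),
    sigma_sV = unname(fixed[["sigma_sV"]]),
    sigma_iV = unname(fixed[["sigma_iV"]]),
    sigma_iA = if ("sigma_iA" %in% names(fixed)) unname(fixed[["sigma_iA"]])
               else 1e-10,
    phi_I = if ("phi_I" %in% names(fixed)) unname(fixed[["phi_I"]]) else 0.5
  )
  counts <- outcome_counts(trials, design)
  means <- prior_means()
  dat <- build_objective_data(design, counts, base, means, n_sim, seed,
                              stream)
  free_names <- if (variant %in% c("BCI", "BCI_NP")) {
    c("p_common", "sigma_sA", "sigma_tA", "sigma_tV")
  } else {
    c("sigma_sA", "sigma_tA", "sigma_tV")
  }
  obj <- function(free) {
    p <- base
    p[names(free)] <- free
    objective_ll(p, dat, variant, pseudocount)
  }
  res <- multistart_fit(obj, free_names, bounds, n_starts, seed)
  params <- base
  params[names(res$par)] <- res$par
  structure(list(
    stage = "multisensory", variant = variant, free = res$par,
    fixed = c(sigma_sV = base[["sigma_sV"]], sigma_iV = base[["sigma_iV"]],
              sigma_iA = base[["sigma_iA"]], phi_I = base[["phi_I"]],
              sigma_S_P = base[["sigma_S_P"]], sigma_T_P = base[["sigma_T_P"]],
              sigma_I_P = base[["sigma_I_P"]]),
    params = params,
    log_likelihood = res$log_likelihood, n_starts = n_starts,
    best_start = res$best_start, start_ll = res$start_ll,
    bounds = bounds[bounds$param %in% free_names, ],
    n_sim = n_sim, seed = seed, pseudocount = pseudocount,
    n_points = 3L * sum(!trials$is_catch)
  ), class = "rabbit_fit")
}

#' @export
print.rabbit_fit <- function(x, ...) {
  cat("Fit (", x$stage,
      if (!is.na(x$variant)) paste0(", ", x$variant), "): LL = ",
      formatC(x$log_likelihood, digits = 8), ", best start ",
      x$best_start, "/", x$n_starts, "\n", sep = "")
  print(round(x$free, 4))
  invisible(x)
}

#' Two-stage fit of one participant
#'
#' Runs the unisensory stage once, then the multisensory stage for each
#' requested variant with the stage-1 visual parameters fixed.
#'
#' @param trials One participant's trial table (all conditions).
#' @param design A `rabbit_design`.
#' @param variants Model variants to fit.
#' @param n_starts Length-2: starts for stages 1 and 2.
#' @param n_sim Simulated trials per condition per evaluation.
#' @param seed Master seed.
#' @param bounds Bounds table.
#' @param pseudocount Per-bin floor.
#' @param stream Common-random-number stream offset.
#' @return List with `stage1` and `fits` (one `rabbit_fit` per variant).
#' @export
fit_participant <- function(trials, design,
                            variants = c("BCI", "BCI_NP", "FF", "FS"),
                            n_starts = c(50, 100), n_sim = 5000, seed = 1,
                            bounds = default_bounds(), pseudocount = 1,
                            stream = 0) {
  trials <- trials[!trials$is_catch, , drop = FALSE]
  nb <- design$conditions$n_beeps[match(trials$condition_id,
                                        design$conditions$condition_id)]
  uni <- trials[nb == 0, , drop = FALSE]
  av <- trials[nb > 0, , drop = FALSE]
  stage1 <- fit_unisensory_visual(uni, design, bounds, n_starts[1], n_sim,
                                  seed, pseudocount = pseudocount,
                                  stream = stream)
  fits <- lapply(variants, function(v) {
    fit_multisensory(av, design, stage1$fix, v, bounds, n_starts[2], n_sim,
                     seed, pseudocount, stream)
  })
  names(fits) <- variants
  list(stage1 = stage1, fits = fits, n_points_av = 3L * nrow(av))
}

#' Serialize a fit result with provenance
#'
#' @param fit A `rabbit_fit`.
#' @param path Output path (key-value text).
#' @export
write_fit <- function(fit, path) {
  num <- function(x) sprintf("%.17g", x)
  lines <- c(
    paste0("stage = ", fit$stage),
    paste0("variant = ", fit$variant),
    paste0("log_likelihood = ", num(fit$log_likelihood)),
    paste0("n_starts = ", fit$n_starts),
    paste0("best_start = ", fit$best_start),
    paste0("n_sim = ", fit$n_sim),
    paste0("seed = ", fit$seed),
    paste0("pseudocount = ", fit$pseudocount),
    paste0("n_points = ", fit$n_points),
    paste0("free.", names(fit$free), " = ", num(fit$free)),
    paste0("fixed.", names(fit$fixed), " = ", num(fit$fixed)),
    paste0("bound.", fit$bounds$param, " = ", num(fit$bounds$lower), ",",
           num(fit$bounds$upper))
  )
  writeLines(lines, path)
  invisible(path)
}
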