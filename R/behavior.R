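#' Score one trial response
#'
#' A response scores as an illusion iff its ordered press sequence exactly
#' matches one of the condition's illusion-analog patterns (locations AND
#' order): the extra middle flash for 2-flash conditions (e.g. 3-4-5 /
#' 3-2-1), the suppressed middle flash for 3-flash conditions (e.g. 3-5 /
#' 3-1). With `score = "match"` the veridical presented sequence is scored
#' instead (a "match/hit"). Responses with more presses than events score
#' FALSE, never discarded.
#'
#' @param response List with `presses` (integer vector, each 1..5, ordered)
#'   and `is_catch` flag, or a trial-table row.
#' @param condition Condition from [get_condition()].
#' @param score `"illusion"` or `"match"`.
#' @return Logical flag.
#' @export
score_trial_illusion <- function(response, condition, score = "illusion") {
  if (isTRUE(response$is_catch)) stop("catch trials are not scored")
  presses <- as.integer(response$presses)
  if (any(presses < 1 | presses > 5)) stop("presses must be in 1..5")
  patterns <- if (score == "match") list(condition$match_pattern)
              else condition$illusion_patterns
  any(vapply(patterns, function(p) identical(as.integer(p), presses),
             logical(1)))
}

parse_response <- function(x) {
  if (is.na(x) || !nzchar(x)) return(integer(0))
  as.integer(strsplit(x, "-", fixed = TRUE)[[1]])
}

#' Per-participant, per-condition illusion rates
#'
#' Proportion of non-catch trials whose response matches the condition's
#' illusion (or match) pattern.
#'
#' @param trials Trial table (see [read_trials()]): columns participant_id,
#'   condition_id, response, is_catch.
#' @param design A `rabbit_design`.
#' @param score `"illusion"` or `"match"`.
#' @return data.frame with participant_id, condition_id, n_trials, rate.
#' @export
illusion_rates <- function(trials, design, score = "illusion") {
  trials <- trials[!trials$is_catch, , drop = FALSE]
  if (nrow(trials) == 0) stop("no non-catch trials")
  unknown <- setdiff(unique(trials$condition_id), condition_ids(design))
  if (length(unknown)) stop("unknown condition_id: ",
                            paste(unknown, collapse = ", "))
  conds <- lapply(condition_ids(design), get_condition, design = design)
  names(conds) <- condition_ids(design)
  key <- interaction(trials$participant_id, trials$condition_id, drop = TRUE)
  hit <- mapply(function(resp, cid) {
    score_trial_illusion(list(presses = parse_response(resp),
                              is_catch = FALSE),
                         conds[[cid]], score = score)
  }, trials$response, trials$condition_id, USE.NAMES = FALSE)
  agg <- aggregate(hit, by = list(key = key), FUN = function(x)
    c(n = length(x), rate = mean(x)))
  parts <- do.call(rbind, strsplit(as.character(agg$key), ".", fixed = TRUE))
  data.frame(participant_id = parts[, 1], condition_id = parts[, 2],
             n_trials = agg$x[, "n"], rate = agg$x[, "rate"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pool left/right mirror conditions
#'
#' Combines the left- and right-direction mirror conditions into the ten
#' analysis conditions (two illusions x \{uni ctrl, multi ctrl, sync,
#' A-lead, V-lead\}), weighting by trial counts. The direction-changing
#' bias-control conditions are excluded from the pooled set. Idempotent: a
#' table already carrying analysis-condition labels is returned unchanged.
#'
#' @param rate_table Output of [illusion_rates()].
#' @param design A `rabbit_design`.
#' @return data.frame with participant_id, analysis_condition, n_trials,
#'   rate.
#' @export
pool_directions <- function(rate_table, design) {
  if ("analysis_condition" %in% names(rate_table)) return(rate_table)
  lab <- analysis_condition(design)
  rate_table$analysis_condition <- lab[rate_table$condition_id]
  rt <- rate_table[!is.na(rate_table$analysis_condition), , drop = FALSE]
  key <- interaction(rt$participant_id, rt$analysis_condition, drop = TRUE)
  n <- tapply(rt$n_trials, key, sum)
  w <- tapply(rt$rate * rt$n_trials, key, sum)
  parts <- do.call(rbind, strsplit(names(n), ".", fixed = TRUE))
  out <- data.frame(participant_id = parts[, 1],
                    analysis_condition = parts[, 2],
                    n_trials = as.integer(n), rate = as.numeric(w / n),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$participant_id, out$analysis_condition), ]
}

#' Screen participants on control-condition illusion rates
#'
#' Excludes participants whose mean illusion rate across the control
#' analysis conditions exceeds the group mean by more than 3 group SDs
#' (single pass, not recursive).
#'
#' @param pooled Output of [pool_directions()].
#' @param controls Analysis-condition labels treated as controls.
#' @return List with `kept`, `excluded` (participant ids), `threshold`, and
#'   the per-participant control means.
#' @export
screen_participants <- function(pooled,
                                controls = c("illusory_uni_ctrl",
                                             "illusory_multi_ctrl",
                                             "invisible_uni_ctrl",
                                             "invisible_multi_ctrl")) {
  ctl <- pooled[pooled$analysis_condition %in% controls, , drop = FALSE]
  m <- tapply(ctl$rate, ctl$participant_id, mean)
  if (length(m) < 3) stop("need at least 3 participants")
  thr <- mean(m) + 3 * stats::sd(m)
  excluded <- names(m)[m > thr]
  list(kept = setdiff(names(m), excluded), excluded = excluded,
       threshold = thr, control_means = m)
}

#' Pairwise condition contrasts
#'
#' For each pair of analysis conditions, tests the paired per-participant
#' rate difference: a Shapiro-Wilk normality gate (alpha = 0.05) selects a
#' Wilcoxon signed-rank test (two-sided, zero differences dropped, normal
#' approximation with continuity correction) when the differences are
#' non-normal, else a paired t-test. P-values are Bonferroni-corrected by
#' the number of pairs (capped at 1). The z statistic of the Wilcoxon
#' normal approximation is reported alongside.
#'
#' @param pooled Output of [pool_directions()] (complete paired data).
#' @param pairs List of length-2 character vectors of analysis-condition
#'   labels; default: the ten contrasts of the main analysis (per illusion:
#'   sync vs uni ctrl, sync vs multi ctrl, uni vs multi ctrl, sync vs
#'   A-lead, sync vs V-lead).
#' @param alpha_normality Shapiro-Wilk gate level.
#' @return data.frame: pair, test_name, statistic, z, p_raw, p_bonferroni.
#' @export
condition_contrasts <- function(pooled, pairs = default_contrast_pairs(),
                                alpha_normality = 0.05) {
  wide <- stats::reshape(pooled[, c("participant_id", "analysis_condition",
                                    "rate")],
                         idvar = "participant_id",
                         timevar = "analysis_condition", direction = "wide")
  res <- lapply(pairs, function(pr) {
    a <- wide[[paste0("rate.", pr[1])]]
    b <- wide[[paste0("rate.", pr[2])]]
    if (is.null(a) || is.null(b) || anyNA(a) || anyNA(b)) {
      stop("unpaired or missing data for contrast ",
           pr[1], " vs ", pr[2])
    }
    d <- a - b
    if (all(d == 0)) {
      return(data.frame(condition_a = pr[1], condition_b = pr[2],
                        test_name = "none", statistic = NA_real_,
                        z = 0, p_raw = 1, stringsAsFactors = FALSE))
    }
    normal <- tryCatch(stats::shapiro.test(d)$p.value >= alpha_normality,
                       error = function(e) FALSE)  # e.g. all d identical
    if (normal) {
      tt <- stats::t.test(a, b, paired = TRUE)
      data.frame(condition_a = pr[1], condition_b = pr[2],
                 test_name = "paired_t", statistic = unname(tt$statistic),
                 z = NA_real_, p_raw = tt$p.value, stringsAsFactors = FALSE)
    } else {
      wt <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                               correct = TRUE)
      data.frame(condition_a = pr[1], condition_b = pr[2],
                 test_name = "wilcoxon_signed_rank",
                 statistic = unname(wt$statistic),
                 z = wilcoxon_z(d), p_raw = wt$p.value,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(out$p_raw * length(pairs), 1)
  out
}

#' @rdname condition_contrasts
#' @export
default_contrast_pairs <- function() {
  unlist(lapply(c("illusory", "invisible"), function(s) {
    list(c(paste0(s, "_sync"), paste0(s, "_uni_ctrl")),
         c(paste0(s, "_sync"), paste0(s, "_multi_ctrl")),
         c(paste0(s, "_uni_ctrl"), paste0(s, "_multi_ctrl")),
         c(paste0(s, "_sync"), paste0(s, "_a_lead")),
         c(paste0(s, "_sync"), paste0(s, "_v_lead")))
  }), recursive = FALSE)
}

# signed z of the Wilcoxon normal approximation (ties-corrected variance,
# continuity correction), matching wilcox.test(exact = FALSE, correct = TRUE)
wilcoxon_z <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(0)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  num <- V - mu
  num <- num - sign(num) * 0.5  # continuity correction
  num / sqrt(sig2)
}
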