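#' Observer model parameters
#'
#' The 11 parameters of the generative observer: the causal prior
#' `p_common`, the prior standard deviations (spatial, temporal, intensity —
#' fixed to large values to mimic non-informative priors), the auditory and
#' visual sensory standard deviations per cue, and the perceptual intensity
#' threshold `phi_I` above which an inferred visual intensity is reported as
#' a flash.
#'
#' Units: spatial SDs in degrees visual angle, temporal SDs in ms, intensity
#' SDs in units of the 0/1 stimulus intensity.
#'
#' @param p_common Prior probability of a common cause, in [0, 1].
#' @param sigma_S_P,sigma_T_P,sigma_I_P Prior SDs. Defaults (20 deg, 200 ms,
#'   1 intensity unit) are weakly informative: wide relative to the
#'   stimulus ranges (azimuths within +-5.68 deg, event times 47-388 ms,
#'   intensities 0/1), so they mimic uniform priors over plausible stimuli
#'   while keeping the causal marginal-likelihood ratio proper. Truly
#'   diffuse priors (e.g. 1e3) make the common-cause Occam factor diverge
#'   and collapse the BCI observer onto forced fusion for any causal prior
#'   in (0, 1); see the methods vignette.
#' @param sigma_sA,sigma_tA,sigma_iA Auditory sensory SDs (space, time,
#'   intensity). `sigma_iA` defaults to 1e-10: observers near-perfectly
#'   detect beep presence.
#' @param sigma_sV,sigma_tV,sigma_iV Visual sensory SDs.
#' @param phi_I Perceptual intensity threshold, in [0, 1].
#' @return Named numeric vector of class `model_params`.
#' @export
model_params <- function(p_common = 0.5,
                         sigma_S_P = 20, sigma_T_P = 200, sigma_I_P = 1,
                         sigma_sA = 5, sigma_tA = 60, sigma_iA = 1e-10,
                         sigma_sV = 2, sigma_tV = 60, sigma_iV = 0.3,
                         phi_I = 0.5) {
  p <- c(p_common = p_common,
         sigma_S_P = sigma_S_P, sigma_T_P = sigma_T_P, sigma_I_P = sigma_I_P,
         sigma_sA = sigma_sA, sigma_tA = sigma_tA, sigma_iA = sigma_iA,
         sigma_sV = sigma_sV, sigma_tV = sigma_tV, sigma_iV = sigma_iV,
         phi_I = phi_I)
  validate_params(p)
  class(p) <- c("model_params", "numeric")
  p
}

validate_params <- function(p) {
  need <- c("p_common", "sigma_S_P", "sigma_T_P", "sigma_I_P", "sigma_sA",
            "sigma_tA", "sigma_iA", "sigma_sV", "sigma_tV", "sigma_iV",
            "phi_I")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("missing parameters: ", paste(miss, collapse = ", "))
  if (p[["p_common"]] < 0 || p[["p_common"]] > 1) stop("p_common must be in [0, 1]")
  if (p[["phi_I"]] < 0 || p[["phi_I"]] > 1) stop("phi_I must be in [0, 1]")
  sds <- setdiff(need, c("p_common", "phi_I"))
  if (any(p[sds] <= 0)) stop("all standard deviations must be > 0")
  invisible(p)
}

#' Update parameters
#'
#' @param params A `model_params` vector.
#' @param ... Named replacements.
#' @export
set_params <- function(params, ...) {
  upd <- c(...)
  params[names(upd)] <- upd
  validate_params(params)
  params
}

#' Fixed prior means of the generative model
#'
#' Spatial prior mean 0 deg for all events; temporal prior means
#' \{47, 105, 163\} ms, centred on the synchronous stimuli; intensity prior
#' means fixed to the proportion of trials across the 28-condition design in
#' which the stimulus is presented: visual (1, 0.65, 1), auditory
#' (0.78, 0.5, 0.78) for events 1..3.
#'
#' @return List with `mu_S_P`, `mu_T_P`, `mu_I_P_V`, `mu_I_P_A` (length-3
#'   numeric vectors).
#' @export
prior_means <- function() {
  list(
    mu_S_P = c(0, 0, 0),
    mu_T_P = c(47, 105, 163),
    mu_I_P_V = c(1, 0.65, 1),
    mu_I_P_A = c(0.78, 0.5, 0.78)
  )
}

#' Default fitting bounds
#'
#' Plausible box bounds used by the multi-start maximum-likelihood fits:
#' p_common in [0.001, 0.999]; spatial SDs [0.1, 30] deg; temporal SDs
#' [1, 500] ms; intensity SDs [0.01, 2].
#'
#' @return data.frame with columns `param`, `lower`, `upper`.
#' @export
default_bounds <- function() {
  data.frame(
    param = c("p_common", "sigma_sA", "sigma_tA", "sigma_iA",
              "sigma_sV", "sigma_tV", "sigma_iV", "phi_I"),
    lower = c(0.001, 0.1, 1, 0.01, 0.1, 1, 0.01, 0),
    upper = c(0.999, 30, 500, 2, 30, 500, 2, 1),
    stringsAsFactors = FALSE
  )
}

#' Write / read parameters as a flat key-value config
#'
#' @param params A `model_params` vector.
#' @param path File path.
#' @export
write_params <- function(params, path) {
  writeLines(paste0(names(params), " = ",
                    formatC(as.numeric(params), digits = 17, format = "g")),
             path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- vapply(kv, function(x) as.numeric(x[2]), numeric(1))
  names(vals) <- vapply(kv, function(x) trimws(x[1]), character(1))
  validate_params(vals)
  class(vals) <- c("model_params", "numeric")
  vals
}

.variants <- c("BCI", "BCI_NP", "FF", "FS")

variant_code <- function(variant) {
  i <- match(variant, .variants)
  if (is.na(i)) stop("unknown model variant: ", variant)
  i - 1L
}
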