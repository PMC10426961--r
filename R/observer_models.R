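#' Specify an observer model
#'
#' Identifies one member of the model set: a family plus optional components.
#' Families: `"distance"` (unscaled evidence strength: fixed perceptual
#' boundaries `b_r = k_r`), `"linear"`, `"quadratic"`, `"free_exponent"`
#' (scaled evidence strength: `b_r(sigma) = k_r + m_r * sigma^a` with `a`
#' fixed at 1, fixed at 2, or free in (1, 10]), and `"bayes_lppr"` (boundaries
#' in log-posterior-probability-ratio space). Flags: `odn` adds
#' orientation-dependent measurement noise (visual modality only);
#' `decision_noise` adds Gaussian noise on the log posterior ratio
#' (`bayes_lppr` only); `free_prior` frees the observer's category
#' distribution beliefs (`bayes_lppr` only). `odn` and `decision_noise` are
#' mutually exclusive, matching the model set this package implements.
#'
#' @param family One of `"distance"`, `"linear"`, `"quadratic"`,
#'   `"free_exponent"`, `"bayes_lppr"`.
#' @param task `"different_means"` or `"different_sds"`.
#' @param odn,decision_noise,free_prior Logical flags, see Details.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family, task, odn = FALSE, decision_noise = FALSE,
                       free_prior = FALSE) {
  family <- match.arg(family,
                      c("distance", "linear", "quadratic", "free_exponent", "bayes_lppr"))
  task <- match.arg(task, .valid_tasks)
  if ((decision_noise || free_prior) && family != "bayes_lppr")
    stop("decision_noise and free_prior apply to the bayes_lppr family only",
         call. = FALSE)
  if (odn && decision_noise)
    stop("odn and decision_noise are not combined in this model set", call. = FALSE)
  structure(
    list(family = family, task = task, odn = isTRUE(odn),
         decision_noise = isTRUE(decision_noise), free_prior = isTRUE(free_prior)),
    class = "model_spec")
}

#' @rdname model_spec
#' @param spec A `model_spec`.
#' @return `model_token()`: a short string identity such as
#'   `"free_exponent+odn"` or `"bayes_lppr+dnoise"`, used in result tables.
#' @export
model_token <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  tok <- spec$family
  if (spec$odn) tok <- paste0(tok, "+odn")
  if (spec$decision_noise) tok <- paste0(tok, "+dnoise")
  if (spec$free_prior) tok <- paste0(tok, "+prior")
  tok
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s (%s)\n", model_token(x), x$task))
  invisible(x)
}

#' The nine core observer models for one task
#'
#' @param task `"different_means"` or `"different_sds"`.
#' @param modality Model sets differ by modality: the orientation-dependent
#'   noise variants exist only for `"visual"` data.
#' @return Named list of [model_spec()] objects (names are model tokens).
#' @export
core_model_set <- function(task, modality = "visual") {
  modality <- match.arg(modality, .valid_modalities)
  specs <- list(
    model_spec("distance", task),
    model_spec("linear", task),
    model_spec("quadratic", task),
    model_spec("free_exponent", task),
    model_spec("bayes_lppr", task),
    model_spec("bayes_lppr", task, decision_noise = TRUE),
    model_spec("bayes_lppr", task, free_prior = TRUE))
  if (modality == "visual") {
    specs <- append(specs,
                    list(model_spec("free_exponent", task, odn = TRUE),
                         model_spec("bayes_lppr", task, odn = TRUE)),
                    after = 4L)
  }
  names(specs) <- vapply(specs, model_token, character(1))
  specs
}

## ---- response regions ------------------------------------------------------

#' Map between response regions and category/confidence pairs
#'
#' Eight response regions index the unique category x confidence
#' combinations: regions 1..4 are category 1 with confidence 4..1 and regions
#' 5..8 are category 2 with confidence 1..4, so that region order follows the
#' stimulus axis (different-means task) or distance from the centre
#' (different-SDs task), with higher confidence at more extreme category
#' evidence.
#'
#' @param r Integer vector of regions in 1..8.
#' @param category,confidence Integer vectors (1..2 and 1..4).
#' @return `region_to_response()`: data.frame with columns `category` and
#'   `confidence`; `response_to_region()`: integer vector of regions.
#' @export
region_to_response <- function(r) {
  stopifnot(all(r %in% 1:8))
  data.frame(category = ifelse(r <= 4, 1L, 2L),
             confidence = ifelse(r <= 4, 5L - as.integer(r), as.integer(r) - 4L))
}

#' @rdname region_to_response
#' @export
response_to_region <- function(category, confidence) {
  stopifnot(all(category %in% 1:2), all(confidence %in% 1:4))
  ifelse(category == 1L, 5L - as.integer(confidence), 4L + as.integer(confidence))
}

#' Locate a measurement in the realized response regions
#'
#' @param x Standardized measurement(s).
#' @param boundaries Realized boundary vector from [perceptual_boundaries()]
#'   (7 increasing cut points for a different-means task; 7 non-decreasing
#'   positive half-widths for a different-SDs task).
#' @param task Task enum.
#' @return Integer vector of regions 1..8. Intervals are half-open, closed on
#'   the left (for the different-SDs task, on the inner edge of each band).
#' @export
response_region <- function(x, boundaries, task) {
  task <- match.arg(task, .valid_tasks)
  stopifnot(length(boundaries) == 7L)
  if (task == "different_means") {
    findInterval(x, boundaries, left.open = TRUE) + 1L
  } else {
    findInterval(abs(x), boundaries, left.open = TRUE) + 1L
  }
}

## ---- measurement noise -----------------------------------------------------

#' Measurement-noise SD for one trial
#'
#' Without orientation-dependent noise (ODN), the noise SD is the fitted
#' per-intensity value `sigma[intensity]`, already in standardized units.
#' With ODN, the SD is assembled in raw degrees as
#' `gamma[intensity] + psi * |sin(pi * s_deg / 90)|` (a rectified two-cycle
#' sinusoid of orientation, peaking at oblique orientations) and divided by
#' the standardizer SD (in degrees) to express it on the standardized axis.
#'
#' @param np Noise parameters: list with `sigma` (length 4, non-increasing
#'   over intensity) or, for ODN, `gamma` (length 4, degrees, non-increasing)
#'   and `psi` (>= 0, degrees).
#' @param intensity Integer intensity level(s) in 1..4 (4 = strongest signal,
#'   least noise).
#' @param s_deg Raw stimulus orientation(s) in degrees; required iff `odn`.
#' @param odn Logical; use the orientation-dependent rule.
#' @param sd_deg Standardizer SD in degrees; required iff `odn`.
#' @return Positive noise SD(s) in standardized units.
#' @export
sigma_for_trial <- function(np, intensity, s_deg = NULL, odn = FALSE, sd_deg = NULL) {
  stopifnot(all(intensity %in% 1:4))
  if (!odn) return(np$sigma[intensity])
  if (is.null(s_deg) || is.null(sd_deg))
    stop("ODN noise needs the raw orientation (s_deg) and the standardizer SD in degrees",
         call. = FALSE)
  (np$gamma[intensity] + np$psi * abs(sin(pi * s_deg / 90))) / sd_deg
}

## ---- perceptual boundaries (non-Bayesian families) -------------------------

#' Family exponent on sigma
#' @noRd
.family_exponent <- function(spec, pb) {
  switch(spec$family,
         linear = 1,
         quadratic = 2,
         free_exponent = pb$a,
         stop("family has no sigma exponent", call. = FALSE))
}

#' Realized perceptual boundaries of a non-Bayesian model
#'
#' For the distance family the boundaries are the base positions `k`; for the
#' scaled families each boundary is `b_r(sigma) = k_r + m_r * sigma^a` with
#' `a = 1` (linear), `a = 2` (quadratic) or free (free-exponent). In the
#' different-means task the return value is the 7 increasing cut points
#' `(-b4, -b3, -b2, b1, b2, b3, b4)` partitioning the standardized axis into
#' regions 1..8 left to right. In the different-SDs task it is the positive
#' half-widths `(b1, ..., b7)` about the centre `b0 = 0`: region r is the
#' two-sided band `b_{r-1} <= |x| < b_r` (with `b0 = 0`, `b8 = Inf`).
#'
#' @param spec A non-Bayesian [model_spec()].
#' @param pb Boundary parameters: list with `k` (length 4 for different
#'   means, 7 for different SDs), `m` (same length; absent for the distance
#'   family) and `a` (free-exponent family only).
#' @param sigma Positive measurement-noise SD (standardized units).
#' @return Numeric length-7 boundary vector as described above.
#' @export
perceptual_boundaries <- function(spec, pb, sigma) {
  stopifnot(inherits(spec, "model_spec"), sigma > 0)
  if (spec$family == "bayes_lppr")
    stop("use bayes_perceptual_boundaries() for the bayes_lppr family", call. = FALSE)
  nb <- if (spec$task == "different_means") 4L else 7L
  stopifnot(length(pb$k) == nb)
  b <- if (spec$family == "distance") pb$k
       else pb$k + pb$m * sigma ^ .family_exponent(spec, pb)
  cuts <- if (spec$task == "different_means") c(-rev(b[2:4]), b[1], b[2:4]) else b
  if (any(diff(cuts) <= 0) || (spec$task == "different_sds" && cuts[1] <= 0))
    stop("realized boundaries are not strictly increasing at this sigma",
         call. = FALSE)
  cuts
}

## ---- Bayesian decision variable --------------------------------------------

#' Log posterior probability ratio of the categories
#'
#' The Bayesian decision variable `d = log p(C=1|x) - log p(C=2|x)` for a
#' measurement `x` with Gaussian measurement noise `sigma`, in the
#' task-specific closed forms. For a different-means pair (standardized means
#' `+-mu1`, shared category SD `sigma1`):
#' `d = 2 * x * mu1 / (sigma^2 + sigma1^2)`. For a different-SDs pair
#' (shared standardized mean 0, `sigma1 < sigma2`):
#' `d = 0.5 * log((sigma^2 + sigma2^2) / (sigma^2 + sigma1^2)) -
#' (sigma2^2 - sigma1^2) / (2 (sigma^2 + sigma1^2) (sigma^2 + sigma2^2)) * x^2`.
#' A log-prior-ratio term `log(prior1 / (1 - prior1))` is added (zero under
#' the equal priors used throughout). Positive `d` favours category 1.
#'
#' @param x Standardized measurement(s). Vectorised.
#' @param sigma Positive measurement-noise SD (standardized units).
#' @param pair_std Category pair on the standardized axis (see
#'   [standardized_pair()]); only `mu1`/`sigma1` (different means) or
#'   `sigma1`/`sigma2` (different SDs) and `prior1` are used, so subjective
#'   beliefs can be substituted.
#' @param task Task enum.
#' @return Numeric vector of log posterior ratios.
#' @export
lppr <- function(x, sigma, pair_std, task) {
  task <- match.arg(task, .valid_tasks)
  stopifnot(sigma > 0)
  lp <- log(pair_std$prior1) - log(1 - pair_std$prior1)
  if (task == "different_means") {
    2 * x * pair_std$mu1 / (sigma^2 + pair_std$sigma1^2) + lp
  } else {
    v1 <- sigma^2 + pair_std$sigma1^2
    v2 <- sigma^2 + pair_std$sigma2^2
    0.5 * log(v2 / v1) - (pair_std$sigma2^2 - pair_std$sigma1^2) / (2 * v1 * v2) * x^2 + lp
  }
}

#' Convert a d-space boundary to perceptual space
#'
#' Solves `lppr(x) = k_d` for the measurement `x` at a given noise level.
#' Different means: the unique root of the linear form. Different SDs: the
#' half-width `|x| = sqrt((A - k_d) / B)` where `A` is the intercept and `B`
#' the positive coefficient on `x^2`; when `k_d >= A` the boundary is
#' unreachable (the log posterior ratio never gets that high) and 0 is
#' returned, marking an empty central region whose probability mass is zero.
#'
#' @param k_d d-space boundary value(s). Vectorised.
#' @inheritParams lppr
#' @return Perceptual boundary value(s): a signed cut point (different
#'   means) or a non-negative half-width (different SDs).
#' @export
invert_lppr <- function(k_d, sigma, pair_std, task) {
  task <- match.arg(task, .valid_tasks)
  stopifnot(is.finite(k_d), sigma > 0)
  lp <- log(pair_std$prior1) - log(1 - pair_std$prior1)
  if (task == "different_means") {
    (k_d - lp) * (sigma^2 + pair_std$sigma1^2) / (2 * pair_std$mu1)
  } else {
    v1 <- sigma^2 + pair_std$sigma1^2
    v2 <- sigma^2 + pair_std$sigma2^2
    A <- 0.5 * log(v2 / v1) + lp
    B <- (pair_std$sigma2^2 - pair_std$sigma1^2) / (2 * v1 * v2)
    sqrt(pmax(A - k_d, 0) / B)
  }
}

#' Realized perceptual boundaries of a Bayesian model
#'
#' Converts the 7 strictly decreasing d-space boundaries `k` into the same
#' length-7 perceptual boundary layout as [perceptual_boundaries()] at a
#' given noise level. `d` decreases from region 1 (category 1, confidence 4)
#' to region 8, so a decreasing `k` maps to increasing perceptual cuts
#' (different means) or non-decreasing half-widths with possible empty
#' central regions (different SDs).
#'
#' @param k Numeric length-7, strictly decreasing d-space boundaries.
#' @inheritParams lppr
#' @return Numeric length-7 realized boundary vector.
#' @export
bayes_perceptual_boundaries <- function(k, sigma, pair_std, task) {
  stopifnot(length(k) == 7L)
  if (any(diff(k) >= 0))
    stop("d-space boundaries k must be strictly decreasing", call. = FALSE)
  x <- invert_lppr(k, sigma, pair_std, task)
  if (task == "different_means" && any(diff(x) <= 0))
    stop("realized boundaries are not strictly increasing at this sigma",
         call. = FALSE)
  x
}
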