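.P_FLOOR <- 1e-12
.DNOISE_DRAWS <- 101L

#' Bundle trials with their task configuration
#'
#' A `conf_dataset` ties a table of trials to the generative configuration
#' they came from: the [category_pair()] and the [standardizer()] that maps
#' raw stimulus values to the standardized axis models operate on. The trial
#' table gains a standardized value `z` and a response region `r` (see
#' [response_to_region()]).
#'
#' @param trials Data frame with columns `participant`, `task`, `modality`,
#'   `s_raw`, `intensity` (1..4), `true_category` (1..2),
#'   `response_category` (1..2), `confidence` (1..4).
#' @param pair The [category_pair()] of the configuration.
#' @param std Optional [standardizer()]; when `NULL`, fitted to the
#'   presented stimulus values of `trials` (the usual empirical policy).
#' @return An object of class `conf_dataset` with fields `trials`, `pair`,
#'   `std` and `pair_std` (the pair on the standardized axis).
#' @export
conf_dataset <- function(trials, pair, std = NULL) {
  stopifnot(is.data.frame(trials), inherits(pair, "category_pair"))
  needed <- c("participant", "task", "modality", "s_raw", "intensity",
              "true_category", "response_category", "confidence")
  missing_cols <- setdiff(needed, names(trials))
  if (length(missing_cols))
    stop("trial table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(trials) == 0L) stop("empty trial table", call. = FALSE)
  if (!all(trials$intensity %in% 1:4)) stop("intensity must be in 1..4", call. = FALSE)
  if (!all(trials$true_category %in% 1:2)) stop("true_category must be 1 or 2", call. = FALSE)
  if (!all(trials$response_category %in% 1:2)) stop("response_category must be 1 or 2", call. = FALSE)
  if (!all(trials$confidence %in% 1:4)) stop("confidence must be in 1..4", call. = FALSE)
  if (!all(trials$task == pair$task) || !all(trials$modality == pair$modality))
    stop("trials do not match the configuration's task/modality", call. = FALSE)
  if (is.null(std)) std <- fit_standardizer(trials$s_raw)
  trials$z <- standardize(trials$s_raw, std)
  trials$r <- response_to_region(trials$response_category, trials$confidence)
  structure(list(trials = trials, pair = pair, std = std,
                 pair_std = standardized_pair(pair, std)),
            class = "conf_dataset")
}

#' @export
print.conf_dataset <- function(x, ...) {
  cat(sprintf("<conf_dataset> %s / %s: %d trials, %d participant(s)\n",
              x$pair$task, x$pair$modality, nrow(x$trials),
              length(unique(x$trials$participant))))
  invisible(x)
}

#' Read and write the delimited trial-record format
#'
#' One row per trial with header `participant, task, modality, s_raw,
#' intensity, true_category, response_category, confidence` (comma
#' separated). The reader validates ranges and attaches the configuration,
#' computing standardized values via its standardizer.
#'
#' @param path File path.
#' @param pair A [category_pair()] describing the configuration; defaults to
#'   [default_category_pair()] for the task/modality found in the file.
#' @param std Optional [standardizer()] (empirical fit when `NULL`).
#' @return `read_trials()`: a [conf_dataset()]. `write_trials()`: the path,
#'   invisibly.
#' @export
read_trials <- function(path, pair = NULL, std = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(pair)) {
    task <- unique(df$task); modality <- unique(df$modality)
    if (length(task) != 1L || length(modality) != 1L)
      stop("file mixes task-modality configurations; supply `pair` explicitly",
           call. = FALSE)
    pair <- default_category_pair(task, modality)
  }
  conf_dataset(df, pair, std)
}

#' @rdname read_trials
#' @param data A [conf_dataset()] or compatible data frame.
#' @export
write_trials <- function(data, path) {
  df <- if (inherits(data, "conf_dataset")) data$trials else data
  keep <- c("participant", "task", "modality", "s_raw", "intensity",
            "true_category", "response_category", "confidence")
  utils::write.csv(df[keep], path, row.names = FALSE)
  invisible(path)
}

## ---- internal: theta -> realized boundary geometry -------------------------

## Effective standardized pair a Bayesian observer believes in (subjective
## parameters substituted under free_prior).
.effective_pair <- function(spec, theta, pair_std) {
  if (!spec$free_prior) return(pair_std)
  p <- pair_std
  if (spec$task == "different_means") {
    p$mu1 <- theta$prior[["mu1"]]
    p$sigma1 <- theta$prior[["sigma1"]]
  } else {
    p$sigma1 <- theta$prior[["sigma1"]]
    p$sigma2 <- theta$prior[["sigma2"]]
  }
  p
}

## Per-trial measurement-noise SD in standardized units.
.trial_sigmas <- function(spec, theta, trials, sd_deg) {
  if (!spec$odn) return(theta$sigma[trials$intensity])
  sigma_for_trial(theta, trials$intensity, s_deg = trials$s_raw,
                  odn = TRUE, sd_deg = sd_deg)
}

## Realized cut rows for a vector of sigmas. Returns list(cuts = matrix
## length(sigmas) x 7, viol = non-negative total ordering violation).
## Ordering requirements: non-Bayesian rows strictly increasing (and first
## half-width positive in the two-sided layout); Bayesian different-means
## rows strictly increasing; Bayesian different-SDs rows are non-decreasing
## by construction (empty central regions allowed).
.realized_cuts <- function(spec, theta, sigmas, pair_std) {
  ns <- length(sigmas)
  ds <- spec$task == "different_sds"
  if (spec$family == "bayes_lppr") {
    pe <- .effective_pair(spec, theta, pair_std)
    cuts <- t(vapply(sigmas, function(s) invert_lppr(theta$k, s, pe, spec$task),
                     numeric(7)))
    if (!ds) {
      gaps <- cuts[, -1, drop = FALSE] - cuts[, -7, drop = FALSE]
      viol <- sum(pmax(0, -gaps))
      if (viol == 0 && any(gaps == 0)) viol <- 1e-3
    } else viol <- 0
    return(list(cuts = cuts, viol = viol))
  }
  expo <- if (spec$family == "distance") NULL else .family_exponent(spec, theta)
  b <- if (spec$family == "distance")
    matrix(theta$k, ns, length(theta$k), byrow = TRUE)
  else
    outer(sigmas^expo, theta$m) + matrix(theta$k, ns, length(theta$k), byrow = TRUE)
  cuts <- if (ds) b
          else cbind(-b[, 4], -b[, 3], -b[, 2], b[, 1], b[, 2], b[, 3], b[, 4])
  gaps <- cuts[, -1, drop = FALSE] - cuts[, -7, drop = FALSE]
  viol <- sum(pmax(0, -gaps))
  if (ds) viol <- viol + sum(pmax(0, -cuts[, 1]))
  if (viol == 0 && (any(gaps == 0) || (ds && any(cuts[, 1] == 0)))) viol <- 1e-3
  list(cuts = cuts, viol = viol)
}

## Quadrature grid for the decision-noise marginalisation: `nd` evenly
## spaced points spanning the 1st..99th percentiles of the standard normal,
## weighted by the normal density (normalised).
.dnoise_grid <- function(nd = .DNOISE_DRAWS) {
  q <- seq(qnorm(0.01), qnorm(0.99), length.out = nd)
  w <- dnorm(q)
  list(q = q, w = w / sum(w))
}

## Perceptual boundary draw cube for the decision-noise model:
## nd x 7 x 4 (draws x boundaries x intensity). Corresponding draws share
## the quantile offset, so d-space ordering is preserved draw by draw.
.dnoise_cube <- function(spec, theta, pair_std, nd = .DNOISE_DRAWS) {
  grid <- .dnoise_grid(nd)
  pe <- .effective_pair(spec, theta, pair_std)
  cube <- array(0, dim = c(nd, 7L, 4L))
  for (I in 1:4) {
    kd <- outer(theta$sigma_d * grid$q, theta$k, `+`)  # nd x 7 drawn d-boundaries
    cube[, , I] <- invert_lppr(kd, theta$sigma[I], pe, spec$task)
  }
  list(cube = cube, w = grid$w)
}

## ---- response probabilities ------------------------------------------------

.region_probs_one <- function(z, sig, cuts, twosided) {
  if (!twosided) {
    ph <- c(0, pnorm(cuts, z, sig), 1)
    diff(ph)
  } else {
    up <- c(pnorm(0, z, sig), pnorm(cuts, z, sig), 1)
    lo <- c(pnorm(0, z, sig), pnorm(-cuts, z, sig), 0)
    diff(up) - diff(lo)
  }
}

#' Predicted response probabilities for one trial
#'
#' The probability a model assigns to each of the eight category-confidence
#' responses for a trial with standardized stimulus value `z` at a given
#' intensity: the Gaussian measurement distribution's mass over each realized
#' response region (a single interval in the different-means task; the union
#' of two symmetric intervals in the different-SDs task), computed from
#' differences of the normal CDF. For decision-noise models the mass is
#' marginalised over boundary draws, see
#' [response_probabilities_dnoise()].
#'
#' @param spec A [model_spec()].
#' @param theta Model parameters (see [fit_model()] for the layout).
#' @param z Standardized stimulus value of the trial.
#' @param intensity Intensity level 1..4.
#' @param pair_std Standardized category pair (needed by Bayesian models).
#' @param s_raw Raw stimulus value in degrees (ODN models only).
#' @param sd_deg Standardizer SD in degrees (ODN models only).
#' @return Numeric length-8 probability vector summing to 1.
#' @export
response_probabilities <- function(spec, theta, z, intensity, pair_std = NULL,
                                   s_raw = NULL, sd_deg = NULL) {
  stopifnot(inherits(spec, "model_spec"), length(z) == 1L)
  if (spec$decision_noise)
    return(response_probabilities_dnoise(spec, theta, z, intensity, pair_std))
  fake <- data.frame(intensity = intensity, s_raw = if (is.null(s_raw)) NA_real_ else s_raw)
  sig <- .trial_sigmas(spec, theta, fake, sd_deg)
  rc <- .realized_cuts(spec, theta, sig, pair_std)
  if (rc$viol > 0)
    stop("realized boundaries violate ordering for these parameters", call. = FALSE)
  .region_probs_one(z, sig, rc$cuts[1, ], spec$task == "different_sds")
}

#' @rdname response_probabilities
#' @param ndraw Number of quadrature draws per boundary (default 101,
#'   spanning the 1st to 99th percentile of the boundary-noise normal,
#'   weighted by its density).
#' @export
response_probabilities_dnoise <- function(spec, theta, z, intensity,
                                          pair_std = NULL, ndraw = .DNOISE_DRAWS) {
  stopifnot(spec$decision_noise, theta$sigma_d >= 0, length(z) == 1L)
  if (theta$sigma_d == 0) {
    th0 <- theta; th0$sigma_d <- NULL
    spec0 <- spec; spec0$decision_noise <- FALSE
    return(response_probabilities(spec0, th0, z, intensity, pair_std))
  }
  dn <- .dnoise_cube(spec, theta, pair_std, ndraw)
  sig <- theta$sigma[intensity]
  twosided <- spec$task == "different_sds"
  p <- rep(0, 8)
  bad <- 0L
  for (j in seq_len(ndraw)) {
    pj <- .region_probs_one(z, sig, dn$cube[j, , intensity], twosided)
    if (any(pj < 0)) {
      bad <- bad + 1L
      pj <- pmax(pj, 0)
      pj <- pj / sum(pj)
    }
    p <- p + dn$w[j] * pj
  }
  if (bad > 0L)
    warning(sprintf("%d of %d boundary draws violated ordering; masses clipped and renormalised",
                    bad, ndraw))
  p
}

## ---- dataset log-likelihood ------------------------------------------------

## Internal fast path shared with the fitter: returns the log-likelihood, or
## a large negative penalty shaped by the ordering-violation magnitude so the
## optimizer is pushed back into the valid region.
.loglik_internal <- function(spec, theta, trials, pair_std, sd_deg) {
  twosided <- spec$task == "different_sds"
  sig <- .trial_sigmas(spec, theta, trials, sd_deg)
  if (any(!is.finite(sig)) || any(sig <= 0)) return(-1e10)
  if (spec$decision_noise) {
    dn <- .dnoise_cube(spec, theta, pair_std)
    return(.cc_loglik_dnoise(trials$z, sig, trials$r, trials$intensity,
                             as.numeric(dn$cube), dn$w, twosided, .P_FLOOR))
  }
  if (spec$odn) {
    rc <- .realized_cuts(spec, theta, sig, pair_std)
    if (rc$viol > 0) return(-1e9 * (1 + rc$viol))
    cuts <- rc$cuts
  } else {
    rc <- .realized_cuts(spec, theta, theta$sigma, pair_std)
    if (rc$viol > 0) return(-1e9 * (1 + rc$viol))
    cuts <- rc$cuts[trials$intensity, , drop = FALSE]
  }
  .cc_loglik(trials$z, sig, trials$r, cuts, twosided, .P_FLOOR)
}

#' Log-likelihood of a dataset under a model
#'
#' Sum over trials of the log probability the model assigns to the observed
#' category-confidence response, each probability floored at `1e-12` before
#' the log (the models have no lapse process, so a floor protects against
#' `-Inf` from extreme observations).
#'
#' @param data A [conf_dataset()].
#' @param spec A [model_spec()].
#' @param theta Model parameters (see [fit_model()]).
#' @return Scalar log-likelihood.
#' @export
dataset_loglik <- function(data, spec, theta) {
  stopifnot(inherits(data, "conf_dataset"), inherits(spec, "model_spec"))
  if (nrow(data$trials) == 0L) stop("empty trial set", call. = FALSE)
  if (spec$task != data$pair$task)
    stop("model and data disagree on the task", call. = FALSE)
  if (spec$odn && data$pair$modality != "visual")
    stop("orientation-dependent noise applies to visual data only", call. = FALSE)
  ll <- .loglik_internal(spec, theta, data$trials, data$pair_std, data$std$sd)
  if (ll <= -1e8)
    stop("parameters violate the realized-boundary ordering constraints", call. = FALSE)
  ll
}

#' Number of free parameters of a model
#'
#' Exact free-parameter count used by the information criteria: 4 noise SDs
#' (or 4 baselines + 1 amplitude under ODN), plus the boundary block (4 base
#' positions in the different-means task, 7 in the different-SDs task; a
#' scale per boundary for the scaled families; 7 d-space positions for the
#' Bayesian family), plus 1 for a free exponent, 1 for decision noise and 2
#' for free category-distribution beliefs. Cross-modal sharing modes count
#' the shared blocks once.
#'
#' @param spec A [model_spec()].
#' @param cross_modal_mode Optional: `"common"`, `"different_noise"` or
#'   `"flexible"` (free-exponent family only).
#' @return Integer parameter count.
#' @export
count_parameters <- function(spec, cross_modal_mode = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  nb <- if (spec$task == "different_means") 4L else 7L
  sigma_block <- if (spec$odn) 5L else 4L
  if (!is.null(cross_modal_mode)) {
    cross_modal_mode <- match.arg(cross_modal_mode,
                                  c("common", "different_noise", "flexible"))
    if (spec$family != "free_exponent" || spec$odn || spec$decision_noise || spec$free_prior)
      stop("cross-modal modes are defined for the plain free_exponent model",
           call. = FALSE)
    single <- 4L + 2L * nb + 1L
    return(switch(cross_modal_mode,
                  common = single,
                  different_noise = single + 4L,
                  flexible = 2L * single))
  }
  switch(spec$family,
         distance = sigma_block + nb,
         linear = sigma_block + 2L * nb,
         quadratic = sigma_block + 2L * nb,
         free_exponent = sigma_block + 2L * nb + 1L,
         bayes_lppr = sigma_block + 7L +
           (if (spec$decision_noise) 1L else 0L) +
           (if (spec$free_prior) 2L else 0L))
}
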