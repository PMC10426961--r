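#' Generate a balanced categorisation session design
#'
#' Emulates the session structure of the experiments this package models:
#' blocks of trials balanced over category x intensity (15 trials per cell in
#' the default 120-trial block), stimulus values drawn from the generating
#' category's Gaussian, and trial order shuffled within block. The default
#' session is 6 test blocks of 120 trials (720 trials).
#'
#' @param pair A [category_pair()] defining the configuration.
#' @param n_blocks Number of blocks (default 6).
#' @param trials_per_block Trials per block; must be divisible by 8
#'   (2 categories x 4 intensities). Default 120.
#' @param seed Optional integer seed; the design is deterministic given it.
#' @return Data frame with columns `block`, `trial`, `task`, `modality`,
#'   `s_raw`, `intensity`, `true_category`.
#' @export
generate_design <- function(pair, n_blocks = 6L, trials_per_block = 120L,
                            seed = NULL) {
  stopifnot(inherits(pair, "category_pair"), n_blocks >= 1L)
  if (trials_per_block %% 8L != 0L)
    stop("trials_per_block must be divisible by 8 (2 categories x 4 intensities)",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  per_cell <- trials_per_block %/% 8L
  blocks <- lapply(seq_len(n_blocks), function(b) {
    cells <- expand.grid(true_category = 1:2, intensity = 1:4)
    df <- cells[rep(seq_len(nrow(cells)), each = per_cell), ]
    mu <- ifelse(df$true_category == 1L, pair$mu1, pair$mu2)
    sdv <- ifelse(df$true_category == 1L, pair$sigma1, pair$sigma2)
    df$s_raw <- rnorm(nrow(df), mu, sdv)
    df <- df[sample.int(nrow(df)), ]
    df$block <- b
    df$trial <- seq_len(nrow(df))
    df
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out$task <- pair$task
  out$modality <- pair$modality
  out[, c("block", "trial", "task", "modality", "s_raw", "intensity", "true_category")]
}

#' Simulate observer responses under a model
#'
#' For each design trial the stimulus is standardized, one noisy measurement
#' `x ~ N(z, sigma_i^2)` is drawn, and the model's decision rule turns the
#' measurement into a category-confidence response: comparison with realized
#' perceptual boundaries (evidence-strength families), or computation of the
#' log posterior ratio `d` -- plus one decision-noise draw where the model has
#' it -- compared with the d-space boundaries.
#'
#' @param design Design table from [generate_design()].
#' @param spec A [model_spec()].
#' @param theta Generating parameters (see [fit_model()] for the layout).
#' @param pair The [category_pair()] of the configuration.
#' @param standardizer_policy `"empirical"` (z-score against this session's
#'   presented values, the default, matching how real sessions are
#'   standardized) or `"theoretical"` (use the design's theoretical mixture
#'   moments, reproducible across sessions).
#' @param seed Optional integer seed.
#' @param participant Participant id stored in the trial table.
#' @return A [conf_dataset()].
#' @export
simulate_dataset <- function(design, spec, theta, pair,
                             standardizer_policy = c("empirical", "theoretical"),
                             seed = NULL, participant = "sim01") {
  standardizer_policy <- match.arg(standardizer_policy)
  stopifnot(inherits(spec, "model_spec"), inherits(pair, "category_pair"))
  if (spec$task != pair$task)
    stop("model and design disagree on the task", call. = FALSE)
  if (spec$odn && pair$modality != "visual")
    stop("orientation-dependent noise applies to visual configurations only",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  std <- if (standardizer_policy == "empirical") fit_standardizer(design$s_raw)
         else theoretical_standardizer(pair)
  pair_std <- standardized_pair(pair, std)
  z <- standardize(design$s_raw, std)
  sig <- .trial_sigmas(spec, theta, design, std$sd)
  if (any(!is.finite(sig)) || any(sig < 0))
    stop("invalid noise parameters", call. = FALSE)
  x <- z + sig * rnorm(length(z))
  if (spec$family == "bayes_lppr" && spec$decision_noise) {
    pe <- .effective_pair(spec, theta, pair_std)
    d <- lppr_vec_sigma(x, sig, pe, spec$task) +
      theta$sigma_d * rnorm(length(x))
    r <- 1L + rowSums(outer(d, theta$k, `<`))
  } else {
    rc <- .realized_cuts(spec, theta, sig, pair_std)
    if (rc$viol > 0)
      stop("generating parameters violate realized-boundary ordering", call. = FALSE)
    v <- if (spec$task == "different_sds") abs(x) else x
    r <- 1L + rowSums(rc$cuts < v)
  }
  resp <- region_to_response(r)
  trials <- data.frame(participant = participant,
                       task = pair$task, modality = pair$modality,
                       s_raw = design$s_raw, intensity = design$intensity,
                       true_category = design$true_category,
                       response_category = resp$category,
                       confidence = resp$confidence,
                       block = design$block)
  conf_dataset(trials, pair, std)
}

## lppr with a per-observation sigma vector (internal; the exported lppr()
## takes one noise level at a time).
lppr_vec_sigma <- function(x, sigma, pair_std, task) {
  lp <- log(pair_std$prior1) - log(1 - pair_std$prior1)
  if (task == "different_means") {
    2 * x * pair_std$mu1 / (sigma^2 + pair_std$sigma1^2) + lp
  } else {
    v1 <- sigma^2 + pair_std$sigma1^2
    v2 <- sigma^2 + pair_std$sigma2^2
    0.5 * log(v2 / v1) - (pair_std$sigma2^2 - pair_std$sigma1^2) / (2 * v1 * v2) * x^2 + lp
  }
}

#' Draw plausible generating parameters for a model
#'
#' Samples a constraint-satisfying parameter set from documented ranges
#' chosen to resemble fitted values on human data: noise SDs spanning
#' roughly 0.4-6 standardized units and non-increasing over intensity,
#' boundary base positions and scales that keep realized boundaries ordered
#' at every drawn noise level, exponents in (1.1, 2.5), decision-noise SDs
#' in (0.1, 0.8) d-units, and subjective category beliefs within +-40% of
#' the true values. Draws are verified against the realized-ordering
#' constraint at all four drawn noise levels.
#'
#' @param spec A [model_spec()].
#' @param seed Optional integer seed.
#' @param pair The configuration the parameters are for; defaults to the
#'   standard pair of the model's task (visual modality).
#' @param std Standardizer used to express subjective beliefs and ODN
#'   baselines; defaults to the theoretical one for `pair`.
#' @return A parameter list `theta` in the layout [fit_model()] documents.
#' @export
sample_generating_params <- function(spec, seed = NULL, pair = NULL, std = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(pair)) pair <- default_category_pair(spec$task, "visual")
  if (is.null(std)) std <- theoretical_standardizer(pair)
  pair_std <- standardized_pair(pair, std)
  ds <- spec$task == "different_sds"

  for (attempt in 1:100) {
    sigma4 <- runif(1, 0.4, 1.0)
    sigma <- rev(cumprod(c(sigma4, runif(1, 1.0, 1.6), runif(1, 1.2, 2.2),
                           runif(1, 1.2, 2.2))))
    theta <- list()
    if (spec$odn) {
      theta$gamma <- sigma * std$sd
      theta$psi <- runif(1, 0, 0.25 * std$sd)
      sig_check <- (theta$gamma + theta$psi) / std$sd
    } else {
      theta$sigma <- sigma
      sig_check <- sigma
    }
    if (spec$family == "bayes_lppr") {
      if (!ds) {
        k1 <- runif(1, 1.0, 2.5)
        theta$k <- k1 - cumsum(c(0, runif(6, 0.3, 1.0)))
      } else {
        k1 <- runif(1, 0.25, 0.7)
        theta$k <- k1 - cumsum(c(0, runif(6, 0.15, 0.8)))
      }
      if (spec$decision_noise) theta$sigma_d <- runif(1, 0.1, 0.8)
      if (spec$free_prior) {
        if (!ds) {
          theta$prior <- c(mu1 = pair_std$mu1 * runif(1, 0.7, 1.3),
                           sigma1 = pair_std$sigma1 * runif(1, 0.7, 1.3))
        } else {
          s1 <- pair_std$sigma1 * runif(1, 0.6, 1.2)
          s2 <- pair_std$sigma2 * runif(1, 0.9, 1.4)
          theta$prior <- c(sigma1 = s1, sigma2 = max(s2, s1 * 1.5))
        }
      }
    } else {
      nb <- if (ds) 7L else 4L
      if (!ds) {
        theta$k <- cumsum(c(runif(1, -0.25, 0.25), runif(3, 0.15, 0.6)))
        m1 <- runif(1, 0.05, 0.35)
        m_inc <- runif(3, 0.05, 0.5)
      } else {
        theta$k <- cumsum(runif(7, c(0.01, 0.02, 0.05, 0.1, 0.15, 0.2, 0.2),
                                c(0.1, 0.2, 0.3, 0.5, 0.7, 0.8, 0.8)))
        m1 <- runif(1, 0.02, 0.2)
        m_inc <- runif(6, 0.03, 0.4)
      }
      if (spec$family != "distance") theta$m <- cumsum(c(m1, m_inc))
      if (spec$family == "free_exponent") theta$a <- runif(1, 1.1, 2.5)
    }
    rc <- try(.realized_cuts(spec, theta, sig_check, pair_std), silent = TRUE)
    if (!inherits(rc, "try-error") && rc$viol == 0) return(theta)
  }
  stop("failed to draw ordering-consistent generating parameters", call. = FALSE)
}

#' Above-chance accuracy screen for one participant-configuration
#'
#' One-sided exact binomial test of categorisation accuracy against chance
#' (0.5) on the highest-intensity trials, where a response counts as correct
#' if it matches the most probable generating category for the stimulus
#' value ([ideal_category()]). The participant is kept when accuracy is
#' significantly above chance (p < alpha) and excluded otherwise.
#'
#' @param data A [conf_dataset()] holding one participant's trials for one
#'   configuration.
#' @param alpha Significance level of the screen (default 0.05).
#' @return List with `keep` (logical), `p_value`, `n` and `n_correct`.
#' @export
exclude_by_accuracy <- function(data, alpha = 0.05) {
  stopifnot(inherits(data, "conf_dataset"))
  tr <- data$trials[data$trials$intensity == 4L, ]
  if (nrow(tr) == 0L) stop("no highest-intensity trials present", call. = FALSE)
  correct <- tr$response_category == ideal_category(tr$s_raw, data$pair)
  n_correct <- sum(correct)
  p <- stats::binom.test(n_correct, nrow(tr), p = 0.5,
                         alternative = "greater")$p.value
  list(keep = p < alpha, p_value = p, n = nrow(tr), n_correct = n_correct)
}
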