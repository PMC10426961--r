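## ---- parameter packing -----------------------------------------------------
##
## The optimizer works on an unconstrained vector u. Transforms:
##   noise SDs        sigma4 = exp(u), sigma_I = sigma_{I+1} + exp(u)
##                    (positive, non-increasing over intensity; intensity 4 is
##                    the strongest signal and lowest noise)
##   base positions k first cut free (different means) or log (different SDs),
##                    then log-gaps, enforcing ordering in the sigma -> 0 limit;
##                    Bayesian k: first value free, then log of the (positive)
##                    decrements, keeping k strictly decreasing in d space
##   scales m         unconstrained (sign free; realized-boundary ordering is
##                    enforced by a likelihood penalty at the fitted sigmas)
##   exponent a       a = 1 + 9 * plogis(u), keeping a in (1, 10)
##   sigma_d          log scale
##   subjective prior mu1 free, SDs on log / log-gap scale

.GAP_FLOOR <- 1e-8

.pack_increasing <- function(x, log_first = FALSE) {
  d <- pmax(diff(x), .GAP_FLOOR)
  c(if (log_first) log(max(x[1], .GAP_FLOOR)) else x[1], log(d))
}

.unpack_increasing <- function(u, log_first = FALSE) {
  first <- if (log_first) exp(u[1]) else u[1]
  cumsum(c(first, exp(u[-1])))
}

.pack_theta <- function(spec, theta) {
  ds <- spec$task == "different_sds"
  u <- if (spec$odn) {
    c(.pack_increasing(rev(theta$gamma), log_first = TRUE),
      log(max(theta$psi, .GAP_FLOOR)))
  } else {
    .pack_increasing(rev(theta$sigma), log_first = TRUE)
  }
  if (spec$family == "bayes_lppr") {
    u <- c(u, theta$k[1], log(pmax(-diff(theta$k), .GAP_FLOOR)))
    if (spec$decision_noise) u <- c(u, log(max(theta$sigma_d, .GAP_FLOOR)))
    if (spec$free_prior) {
      u <- if (!ds)
        c(u, theta$prior[["mu1"]], log(theta$prior[["sigma1"]]))
      else
        c(u, log(theta$prior[["sigma1"]]),
          log(max(theta$prior[["sigma2"]] - theta$prior[["sigma1"]], .GAP_FLOOR)))
    }
  } else {
    u <- if (!ds)
      c(u, theta$k[1],
        log(pmax(c(theta$k[2] - abs(theta$k[1]), diff(theta$k[-1])), .GAP_FLOOR)))
    else
      c(u, .pack_increasing(theta$k, log_first = TRUE))
    if (spec$family != "distance") u <- c(u, theta$m)
    if (spec$family == "free_exponent")
      u <- c(u, stats::qlogis(min(max((theta$a - 1) / 9, 1e-6), 1 - 1e-6)))
  }
  u
}

.unpack_theta <- function(spec, u) {
  theta <- list()
  i <- 0L
  take <- function(n) { v <- u[(i + 1L):(i + n)]; i <<- i + n; v }
  if (spec$odn) {
    theta$gamma <- rev(.unpack_increasing(take(4L), log_first = TRUE))
    theta$psi <- exp(take(1L))
  } else {
    theta$sigma <- rev(.unpack_increasing(take(4L), log_first = TRUE))
  }
  ds <- spec$task == "different_sds"
  if (spec$family == "bayes_lppr") {
    v <- take(7L)
    theta$k <- v[1] - cumsum(c(0, exp(v[2:7])))
    if (spec$decision_noise) theta$sigma_d <- exp(take(1L))
    if (spec$free_prior) {
      v <- take(2L)
      theta$prior <- if (!ds) c(mu1 = v[1], sigma1 = exp(v[2]))
                     else c(sigma1 = exp(v[1]), sigma2 = exp(v[1]) + exp(v[2]))
    }
  } else {
    if (!ds) {
      v <- take(4L)
      theta$k <- c(v[1], abs(v[1]) + cumsum(exp(v[2:4])))
    } else {
      theta$k <- .unpack_increasing(take(7L), log_first = TRUE)
    }
    if (spec$family != "distance") theta$m <- take(if (ds) 7L else 4L)
    if (spec$family == "free_exponent") theta$a <- 1 + 9 * stats::plogis(take(1L))
  }
  theta
}

## ---- random initial values -------------------------------------------------

## Initialization ranges (documented constants): noise SDs in [0.2, 6]
## standardized units, boundary bases and scales within the ranges fitted
## values occupy, exponents in (1.05, 3.5), decision-noise SD in (0.05, 1).
.random_theta <- function(spec, pair_std) {
  ds <- spec$task == "different_sds"
  theta <- list()
  sig <- sort(runif(4L, 0.2, 6), decreasing = TRUE)
  if (spec$odn) {
    sd_deg <- if (!is.null(pair_std)) attr(pair_std, "sd_deg") else NULL
    scale <- if (is.null(sd_deg)) 6 else sd_deg
    theta$gamma <- sig * scale
    theta$psi <- runif(1, 0.01, 0.3) * scale
  } else {
    theta$sigma <- sig
  }
  if (spec$family == "bayes_lppr") {
    k1 <- if (!ds) runif(1, 0.5, 3) else runif(1, 0.05, 0.8)
    theta$k <- k1 - cumsum(c(0, runif(6L, 0.1, 1)))
    if (spec$decision_noise) theta$sigma_d <- runif(1, 0.05, 1)
    if (spec$free_prior) {
      mu1 <- if (!is.null(pair_std)) pair_std$mu1 else -0.6
      s1 <- if (!is.null(pair_std)) pair_std$sigma1 else 0.5
      s2 <- if (!is.null(pair_std)) pair_std$sigma2 else 1.4
      theta$prior <- if (!ds)
        c(mu1 = mu1 * runif(1, 0.6, 1.4), sigma1 = s1 * runif(1, 0.6, 1.4))
      else {
        a1 <- s1 * runif(1, 0.6, 1.4)
        c(sigma1 = a1, sigma2 = max(s2 * runif(1, 0.6, 1.4), a1 * 1.2))
      }
    }
  } else {
    if (!ds) {
      theta$k <- cumsum(c(runif(1, -0.5, 0.5), runif(3L, 0.1, 1.2)))
    } else {
      theta$k <- cumsum(runif(7L, 0.03, 0.7))
    }
    if (spec$family != "distance")
      theta$m <- sort(runif(if (ds) 7L else 4L, 0, 1.2))
    if (spec$family == "free_exponent") theta$a <- runif(1, 1.05, 3.5)
  }
  theta
}

## Deterministic data-informed start: place the seven boundaries at the
## stimulus quantiles matching the observed cumulative response-region
## frequencies (on |z| for the two-sided task), with a moderate noise
## profile. Avoids the degenerate boundary-collapse basin that pure random
## starts can fall into.
.empirical_theta <- function(spec, trials, pair_std, sd_deg) {
  ds <- spec$task == "different_sds"
  freq <- tabulate(trials$r, 8L) + 0.5  # smoothing: no zero-width regions
  cum <- cumsum(freq / sum(freq))[1:7]
  v <- if (ds) abs(trials$z) else trials$z
  x <- as.numeric(stats::quantile(v, cum, names = FALSE))
  for (j in 2:7) if (x[j] <= x[j - 1]) x[j] <- x[j - 1] + 1e-3
  if (ds) x <- pmax(x, (1:7) * 1e-4)
  sigma0 <- c(1.2, 0.9, 0.7, 0.5)
  th <- list()
  if (spec$odn) {
    th$gamma <- sigma0 * sd_deg
    th$psi <- 0.01 * sd_deg
  } else th$sigma <- sigma0
  if (spec$family == "bayes_lppr") {
    pe <- pair_std
    if (spec$free_prior) {
      th$prior <- if (!ds) c(mu1 = pair_std$mu1, sigma1 = pair_std$sigma1)
                  else c(sigma1 = pair_std$sigma1, sigma2 = pair_std$sigma2)
    }
    k <- lppr(x, 0.8, pe, spec$task)
    for (j in 2:7) if (k[j] >= k[j - 1]) k[j] <- k[j - 1] - 1e-3
    th$k <- k
    if (spec$decision_noise) th$sigma_d <- 0.2
  } else {
    if (!ds) {
      b <- c(x[4], (x[5] - x[3]) / 2, (x[6] - x[2]) / 2, (x[7] - x[1]) / 2)
      b[2] <- max(b[2], abs(b[1]) + 1e-3)
      for (j in 3:4) b[j] <- max(b[j], b[j - 1] + 1e-3)
      th$k <- b
    } else th$k <- x
    if (spec$family != "distance")
      th$m <- rep(0.05, if (ds) 7L else 4L)
    if (spec$family == "free_exponent") th$a <- 1.5
  }
  th
}

## ---- single-dataset maximum-likelihood fit ---------------------------------

## Warm starts from fits of nested / simplified variants of the target
## model. The prefits use a reduced start count and their own derived seeds;
## the caller's RNG state is re-seeded afterwards, so determinism holds.
.ladder_inits <- function(data, spec, n_starts, seed) {
  pre_n <- max(2L, n_starts %/% 3L)
  pre <- function(s, sd_off) tryCatch(
    fit_model(data, s, n_starts = pre_n, seed = seed + sd_off, ladder = FALSE),
    error = function(e) NULL)
  inits <- list()
  add <- function(th) inits[[length(inits) + 1L]] <<- th
  to_odn <- function(th) {
    th$gamma <- th$sigma * data$std$sd
    th$psi <- 0.02 * data$std$sd
    th$sigma <- NULL
    th
  }
  if (spec$family == "free_exponent") {
    if (spec$odn) {
      f <- pre(model_spec("free_exponent", spec$task), 101L)
      if (!is.null(f)) add(to_odn(f$theta_hat))
    } else {
      f <- pre(model_spec("linear", spec$task), 102L)
      if (!is.null(f)) add(modifyList(f$theta_hat, list(a = 1.001)))
      f <- pre(model_spec("quadratic", spec$task), 103L)
      if (!is.null(f)) add(modifyList(f$theta_hat, list(a = 2)))
    }
  } else if (spec$family == "bayes_lppr" &&
             (spec$odn || spec$decision_noise || spec$free_prior)) {
    f <- pre(model_spec("bayes_lppr", spec$task), 104L)
    if (!is.null(f)) {
      th <- f$theta_hat
      if (spec$odn) th <- to_odn(th)
      if (spec$decision_noise) { add(modifyList(th, list(sigma_d = 0.05)))
                                 th$sigma_d <- 0.4 }
      if (spec$free_prior) {
        th$prior <- if (spec$task == "different_means")
          c(mu1 = data$pair_std$mu1, sigma1 = data$pair_std$sigma1)
        else
          c(sigma1 = data$pair_std$sigma1, sigma2 = data$pair_std$sigma2)
      }
      add(th)
    }
  }
  inits
}

#' Fit an observer model by maximum likelihood
#'
#' Maximises [dataset_loglik()] over the model's constrained parameter space
#' with `n_starts` local optimizations (PORT routines via [stats::nlminb()])
#' from random initial values, keeping the best. Constraints (non-increasing
#' noise SDs, ordered boundaries at every fitted noise level, exponent in
#' (1, 10], non-negative decision noise) are enforced by smooth
#' reparameterization plus a likelihood penalty on realized-boundary
#' ordering violations. Deterministic given `seed`.
#'
#' The parameter list `theta` has fields: `sigma` (4 noise SDs, intensity
#' 1..4, non-increasing) or `gamma` + `psi` for ODN models; `k` boundary
#' base positions (4 or 7 for evidence-strength models; 7 strictly
#' decreasing d-space positions for Bayesian models); `m` per-boundary
#' scales (scaled families); `a` exponent (free-exponent family); `sigma_d`
#' decision-noise SD; `prior` subjective category beliefs (free-prior
#' models).
#'
#' @param data A [conf_dataset()].
#' @param spec A [model_spec()].
#' @param n_starts Number of random starts (default 20).
#' @param seed Integer seed governing the starts.
#' @param extra_inits Optional list of additional `theta` values used as
#'   warm starts (e.g. the optimum of a nested model), tried in addition to
#'   the random starts.
#' @param ladder Use the nested-model warm-start ladder (default `TRUE`):
#'   before fitting, cheaper nested or simplified variants are fitted with a
#'   few starts and their optima seed the target fit (linear/quadratic seed
#'   the free-exponent model; the plain Bayesian fit seeds the
#'   decision-noise, free-prior and ODN Bayesian variants; the non-ODN fit
#'   seeds the ODN variant). Purely an optimization aid; the random starts
#'   are unchanged.
#' @return A `conf_fit`: list with `spec`, `token`, `participant`,
#'   `theta_hat`, `loglik`, `z`, `n`, `aic`, `bic`, `n_starts`,
#'   `converged_starts`, `seed`.
#' @export
fit_model <- function(data, spec, n_starts = 20L, seed = 1L, extra_inits = NULL,
                      ladder = TRUE) {
  stopifnot(inherits(data, "conf_dataset"), inherits(spec, "model_spec"))
  if (spec$task != data$pair$task)
    stop("model and data disagree on the task", call. = FALSE)
  if (spec$odn && data$pair$modality != "visual")
    stop("orientation-dependent noise applies to visual data only", call. = FALSE)
  if (isTRUE(ladder))
    extra_inits <- c(extra_inits, .ladder_inits(data, spec, n_starts, seed))
  set.seed(seed)
  trials <- data$trials
  pair_std <- data$pair_std
  attr(pair_std, "sd_deg") <- data$std$sd
  sd_deg <- data$std$sd
  negll <- function(u) {
    theta <- .unpack_theta(spec, u)
    v <- -.loglik_internal(spec, theta, trials, pair_std, sd_deg)
    if (is.finite(v)) v else 1e10
  }
  starts <- list()
  emp <- tryCatch(.pack_theta(spec, .empirical_theta(spec, trials, pair_std, sd_deg)),
                  error = function(e) NULL)
  if (!is.null(emp) && negll(emp) < 1e8) starts[[1L]] <- emp
  for (s in seq_len(n_starts)) {
    for (try_i in 1:50) {
      th0 <- .random_theta(spec, pair_std)
      u0 <- .pack_theta(spec, th0)
      if (negll(u0) < 1e8) break
    }
    starts[[length(starts) + 1L]] <- u0
  }
  for (th in extra_inits) starts[[length(starts) + 1L]] <- .pack_theta(spec, th)

  best <- NULL
  converged <- 0L
  for (u0 in starts) {
    res <- tryCatch(
      nlminb(u0, negll,
             control = list(iter.max = 500L, eval.max = 2000L, rel.tol = 1e-10)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$objective) || res$objective >= 1e8) next
    if (res$convergence == 0L) converged <- converged + 1L
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best))
    stop("all optimization starts failed for model ", model_token(spec), call. = FALSE)
  theta_hat <- .unpack_theta(spec, best$par)
  ll <- -best$objective
  z <- count_parameters(spec)
  n <- nrow(trials)
  ic <- information_criteria(ll, z, n)
  structure(
    list(spec = spec, token = model_token(spec), cross_modal_mode = NULL,
         participant = paste(unique(trials$participant), collapse = "+"),
         theta_hat = theta_hat, loglik = ll, z = z, n = n,
         aic = ic[["aic"]], bic = ic[["bic"]],
         n_starts = length(starts), converged_starts = converged, seed = seed),
    class = "conf_fit")
}

#' @export
print.conf_fit <- function(x, ...) {
  tok <- if (is.null(x$cross_modal_mode)) x$token
         else paste0(x$token, ":", x$cross_modal_mode)
  cat(sprintf("<conf_fit> %s  logLik = %.2f  z = %d  n = %d  AIC = %.2f  BIC = %.2f\n",
              tok, x$loglik, x$z, x$n, x$aic, x$bic))
  invisible(x)
}

#' Information criteria for one fitted model
#'
#' `AIC = 2 z - 2 logLik`; `BIC = -2 logLik + z log(n)` (per-participant
#' forms; see [compare_models()] for the group-level sums).
#'
#' @param loglik Achieved log-likelihood.
#' @param z Number of free parameters.
#' @param n Number of trials.
#' @return Named numeric vector `c(aic = ..., bic = ...)`.
#' @export
information_criteria <- function(loglik, z, n) {
  stopifnot(n >= 1, z >= 0)
  c(aic = 2 * z - 2 * loglik, bic = -2 * loglik + z * log(n))
}

## ---- model comparison ------------------------------------------------------

#' Compare fitted models across participants
#'
#' Aggregates per-participant fits of several models into a comparison
#' table: the summed AIC (sum of per-participant AICs), the summed BIC in
#' its pooled form (summed -2 logLik plus the total free-parameter count
#' across participants times the log of the total trial count), and the
#' per-participant preferred model. AIC is authoritative when AIC and BIC
#' disagree about a participant's best model.
#'
#' @param fits List of `conf_fit` objects, one per participant x model;
#'   every participant must have a fit for every model.
#' @return A `conf_comparison`: list with `table` (one row per model:
#'   `model`, `aic_sum`, `bic_sum`, `n_preferred`) and `per_participant`
#'   (long table with a `preferred` flag).
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, logical(1), "conf_fit")))
  long <- do.call(rbind, lapply(fits, function(f) {
    tok <- if (is.null(f$cross_modal_mode)) f$token
           else paste0(f$token, ":", f$cross_modal_mode)
    data.frame(participant = f$participant, model = tok, loglik = f$loglik,
               z = f$z, n = f$n, aic = f$aic, bic = f$bic)
  }))
  models <- unique(long$model)
  participants <- unique(long$participant)
  counts <- table(long$participant, long$model)
  if (any(counts != 1L))
    stop("incomplete comparison: need exactly one fit per participant per model",
         call. = FALSE)
  ## preferred model per participant: lowest AIC; ties broken by smaller z,
  ## then model token (deterministic)
  long$preferred <- FALSE
  for (p in participants) {
    idx <- which(long$participant == p)
    o <- idx[order(long$aic[idx], long$z[idx], long$model[idx])]
    long$preferred[o[1]] <- TRUE
  }
  tab <- do.call(rbind, lapply(models, function(mo) {
    sub <- long[long$model == mo, ]
    zB <- sum(sub$z)
    nB <- sum(sub$n)
    data.frame(model = mo,
               aic_sum = sum(sub$aic),
               bic_sum = sum(-2 * sub$loglik) + zB * log(nB),
               n_preferred = sum(sub$preferred))
  }))
  structure(list(table = tab, per_participant = long), class = "conf_comparison")
}

#' @export
print.conf_comparison <- function(x, ...) {
  cat("<conf_comparison>\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

## ---- cross-modal joint fits ------------------------------------------------

.pack_cross <- function(task, mode, theta) {
  shared <- function(th)
    c(if (task == "different_means")
        c(th$k[1], log(pmax(c(th$k[2] - abs(th$k[1]), diff(th$k[-1])), .GAP_FLOOR)))
      else .pack_increasing(th$k, log_first = TRUE),
      th$m,
      stats::qlogis(min(max((th$a - 1) / 9, 1e-6), 1 - 1e-6)))
  if (mode == "common") {
    c(.pack_increasing(rev(theta$sigma), log_first = TRUE), shared(theta))
  } else {  # different_noise
    c(.pack_increasing(rev(theta$sigma_visual), log_first = TRUE),
      .pack_increasing(rev(theta$sigma_auditory), log_first = TRUE),
      shared(theta))
  }
}

.unpack_cross <- function(task, mode, u) {
  nb <- if (task == "different_sds") 7L else 4L
  i <- 0L
  take <- function(n) { v <- u[(i + 1L):(i + n)]; i <<- i + n; v }
  theta <- list()
  if (mode == "common") {
    theta$sigma <- rev(.unpack_increasing(take(4L), log_first = TRUE))
  } else {
    theta$sigma_visual <- rev(.unpack_increasing(take(4L), log_first = TRUE))
    theta$sigma_auditory <- rev(.unpack_increasing(take(4L), log_first = TRUE))
  }
  if (task == "different_means") {
    v <- take(4L)
    theta$k <- c(v[1], abs(v[1]) + cumsum(exp(v[2:4])))
  } else {
    theta$k <- .unpack_increasing(take(7L), log_first = TRUE)
  }
  theta$m <- take(nb)
  theta$a <- 1 + 9 * stats::plogis(take(1L))
  theta
}

#' Fit the free-exponent model jointly across modalities
#'
#' Fits one free-exponent model to visual and auditory data from the same
#' task simultaneously, under three levels of parameter sharing: `"common"`
#' (one set of noise SDs and one boundary set `(k, m, a)` serve both
#' modalities), `"different_noise"` (noise SDs free per intensity per
#' modality; boundaries shared), `"flexible"` (every parameter free per
#' modality; the joint optimum is the sum of the two separate fits, and it
#' is computed that way). The joint log-likelihood is the sum over both
#' modalities' trials.
#'
#' @param data_visual,data_auditory [conf_dataset()]s sharing the task.
#' @param mode `"common"`, `"different_noise"` or `"flexible"`.
#' @inheritParams fit_model
#' @return A `conf_fit` with `cross_modal_mode` set; for `"flexible"`,
#'   `theta_hat` holds per-modality parameter lists.
#' @export
fit_cross_modal <- function(data_visual, data_auditory,
                            mode = c("common", "different_noise", "flexible"),
                            n_starts = 20L, seed = 1L, extra_inits = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(data_visual, "conf_dataset"), inherits(data_auditory, "conf_dataset"))
  task <- data_visual$pair$task
  if (data_auditory$pair$task != task)
    stop("cross-modal fit requires both datasets to share the task", call. = FALSE)
  if (data_visual$pair$modality != "visual" || data_auditory$pair$modality != "auditory")
    stop("pass the visual dataset first and the auditory dataset second", call. = FALSE)
  spec <- model_spec("free_exponent", task)
  n <- nrow(data_visual$trials) + nrow(data_auditory$trials)
  z <- count_parameters(spec, cross_modal_mode = mode)
  participant <- paste(unique(c(data_visual$trials$participant,
                                data_auditory$trials$participant)), collapse = "+")

  if (mode == "flexible") {
    fv <- fit_model(data_visual, spec, n_starts = n_starts, seed = seed,
                    extra_inits = extra_inits)
    fa <- fit_model(data_auditory, spec, n_starts = n_starts, seed = seed + 1L,
                    extra_inits = extra_inits)
    ll <- fv$loglik + fa$loglik
    ic <- information_criteria(ll, z, n)
    return(structure(
      list(spec = spec, token = model_token(spec), cross_modal_mode = mode,
           participant = participant,
           theta_hat = list(visual = fv$theta_hat, auditory = fa$theta_hat),
           loglik = ll, z = z, n = n, aic = ic[["aic"]], bic = ic[["bic"]],
           n_starts = fv$n_starts + fa$n_starts,
           converged_starts = fv$converged_starts + fa$converged_starts,
           seed = seed),
      class = "conf_fit"))
  }

  set.seed(seed)
  tv <- data_visual$trials; ta <- data_auditory$trials
  negll <- function(u) {
    th <- .unpack_cross(task, mode, u)
    thv <- tha <- list(k = th$k, m = th$m, a = th$a)
    if (mode == "common") {
      thv$sigma <- tha$sigma <- th$sigma
    } else {
      thv$sigma <- th$sigma_visual
      tha$sigma <- th$sigma_auditory
    }
    llv <- .loglik_internal(spec, thv, tv, data_visual$pair_std, data_visual$std$sd)
    lla <- .loglik_internal(spec, tha, ta, data_auditory$pair_std, data_auditory$std$sd)
    v <- -(llv + lla)
    if (is.finite(v)) v else 1e10
  }
  rand_cross <- function() {
    th <- .random_theta(spec, data_visual$pair_std)
    if (mode == "different_noise") {
      th$sigma_visual <- th$sigma
      th$sigma_auditory <- sort(runif(4L, 0.2, 6), decreasing = TRUE)
      th$sigma <- NULL
    }
    th
  }
  starts <- list()
  emp <- tryCatch({
    th <- .empirical_theta(spec, rbind(tv, ta), data_visual$pair_std,
                           data_visual$std$sd)
    if (mode == "different_noise") {
      th$sigma_visual <- th$sigma_auditory <- th$sigma
      th$sigma <- NULL
    }
    .pack_cross(task, mode, th)
  }, error = function(e) NULL)
  if (!is.null(emp) && negll(emp) < 1e8) starts[[1L]] <- emp
  for (s in seq_len(n_starts)) {
    for (try_i in 1:50) {
      th0 <- rand_cross()
      u0 <- .pack_cross(task, mode, th0)
      if (negll(u0) < 1e8) break
    }
    starts[[length(starts) + 1L]] <- u0
  }
  for (th in extra_inits) starts[[length(starts) + 1L]] <- .pack_cross(task, mode, th)

  best <- NULL
  converged <- 0L
  for (u0 in starts) {
    res <- tryCatch(
      nlminb(u0, negll,
             control = list(iter.max = 500L, eval.max = 2000L, rel.tol = 1e-10)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$objective) || res$objective >= 1e8) next
    if (res$convergence == 0L) converged <- converged + 1L
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best))
    stop("all optimization starts failed for cross-modal mode ", mode, call. = FALSE)
  ll <- -best$objective
  ic <- information_criteria(ll, z, n)
  structure(
    list(spec = spec, token = model_token(spec), cross_modal_mode = mode,
         participant = participant, theta_hat = .unpack_cross(task, mode, best$par),
         loglik = ll, z = z, n = n, aic = ic[["aic"]], bic = ic[["bic"]],
         n_starts = length(starts), converged_starts = converged, seed = seed),
    class = "conf_fit")
}
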