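## Flatten a theta list into a named numeric vector (for recovery tables).
.flatten_theta <- function(theta) {
  out <- c()
  for (nm in names(theta)) {
    v <- theta[[nm]]
    names(v) <- if (length(v) == 1L) nm else paste0(nm, seq_along(v))
    out <- c(out, v)
  }
  out
}

## Deterministic sub-seed streams derived from a master seed (kept below
## 2^31 - 1 so they remain valid R integer seeds).
.derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(2147483646L, n)
}

## Warm starts that exploit model nesting / simpler variants: the linear or
## quadratic optimum seeds the free-exponent fit; the plain Bayesian optimum
## (with a small decision-noise SD) seeds the decision-noise fit. Pure
## optimization aids; every model still gets its random starts.
.warm_inits <- function(spec, fitted_so_far) {
  inits <- list()
  if (spec$family == "free_exponent" && !spec$odn) {
    for (tok in c("linear", "quadratic")) {
      f <- fitted_so_far[[tok]]
      if (!is.null(f)) {
        th <- f$theta_hat
        th$a <- if (tok == "linear") 1.001 else 2
        inits[[length(inits) + 1L]] <- th
      }
    }
  }
  if (spec$family == "bayes_lppr" && spec$decision_noise) {
    f <- fitted_so_far[["bayes_lppr"]]
    if (!is.null(f)) {
      th <- f$theta_hat
      th$sigma_d <- 0.05
      inits[[length(inits) + 1L]] <- th
    }
  }
  if (spec$family == "bayes_lppr" && spec$free_prior) {
    f <- fitted_so_far[["bayes_lppr"]]
    if (!is.null(f)) {
      inits[[length(inits) + 1L]] <- f$theta_hat  # prior filled by caller
    }
  }
  inits
}

#' Model-recovery (confusability) study
#'
#' For each generating model: draw plausible parameters, simulate a dataset
#' of `n_trials` trials under the balanced design, fit every model in the
#' set, and record which fits best by the chosen criterion. Aggregated over
#' `n_datasets` replicates per generating model this yields the selection
#' probability that data generated by model X are best fit by model Y; good
#' recovery shows up as a dominant diagonal.
#'
#' @param model_set Named list of [model_spec()]s (names default to model
#'   tokens), all for the same task.
#' @param n_datasets Synthetic datasets per generating model (default 20).
#' @param n_trials Trials per dataset (default 360; must be divisible by 8).
#' @param criterion `"aic"` or `"bic"` for best-model selection. Ties are
#'   broken by smaller parameter count, then model token.
#' @param seed Master seed; the full study is deterministic given it.
#' @param pair Configuration to simulate under; defaults to the task's
#'   standard visual pair.
#' @param n_starts Optimizer starts per fit (default 10).
#' @return A `conf_confusability`: list with `matrix` (generating x fitting
#'   selection probabilities, rows summing to 1), `n_datasets`, `n_trials`,
#'   `criterion`, `seed`, and `failures` (fit failures per cell, excluded
#'   from the probabilities' numerators but not the denominators).
#' @export
model_recovery <- function(model_set, n_datasets = 20L, n_trials = 360L,
                           criterion = c("aic", "bic"), seed = 1L,
                           pair = NULL, n_starts = 10L) {
  criterion <- match.arg(criterion)
  stopifnot(length(model_set) >= 1L, n_datasets >= 1L, n_trials >= 8L)
  if (is.null(names(model_set)))
    names(model_set) <- vapply(model_set, model_token, character(1))
  task <- model_set[[1]]$task
  if (!all(vapply(model_set, function(s) s$task, character(1)) == task))
    stop("all models in the set must share the task", call. = FALSE)
  if (is.null(pair)) pair <- default_category_pair(task, "visual")
  toks <- names(model_set)
  mat <- matrix(0, length(toks), length(toks), dimnames = list(toks, toks))
  fails <- matrix(0L, length(toks), length(toks), dimnames = list(toks, toks))
  seeds <- .derive_seeds(seed, length(toks) * n_datasets * (length(toks) + 3L))
  si <- 0L
  nxt <- function() { si <<- si + 1L; seeds[si] }
  for (g in toks) {
    for (dsi in seq_len(n_datasets)) {
      theta <- sample_generating_params(model_set[[g]], seed = nxt(), pair = pair)
      design <- generate_design(pair, n_blocks = 1L, trials_per_block = n_trials,
                                seed = nxt())
      dat <- simulate_dataset(design, model_set[[g]], theta, pair, seed = nxt())
      fitted <- list()
      for (f in toks) {
        inits <- .warm_inits(model_set[[f]], fitted)
        if (model_set[[f]]$free_prior && length(inits)) {
          inits <- lapply(inits, function(th) {
            th$prior <- if (task == "different_means")
              c(mu1 = dat$pair_std$mu1, sigma1 = dat$pair_std$sigma1)
            else
              c(sigma1 = dat$pair_std$sigma1, sigma2 = dat$pair_std$sigma2)
            th
          })
        }
        fitted[[f]] <- tryCatch(
          fit_model(dat, model_set[[f]], n_starts = n_starts, seed = nxt(),
                    extra_inits = inits, ladder = length(inits) == 0L),
          error = function(e) NULL)
        if (is.null(fitted[[f]])) fails[g, f] <- fails[g, f] + 1L
      }
      ok <- !vapply(fitted, is.null, logical(1))
      if (!any(ok)) next
      crit <- vapply(fitted[ok], function(fi) fi[[criterion]], numeric(1))
      zs <- vapply(fitted[ok], function(fi) fi$z, numeric(1))
      winner <- names(crit)[order(crit, zs, names(crit))][1]
      mat[g, winner] <- mat[g, winner] + 1
    }
  }
  structure(list(matrix = mat / n_datasets, counts = mat,
                 n_datasets = n_datasets, n_trials = n_trials,
                 criterion = criterion, seed = seed, failures = fails),
            class = "conf_confusability")
}

#' @export
print.conf_confusability <- function(x, ...) {
  cat(sprintf("<conf_confusability> %d datasets x %d trials, criterion = %s\n",
              x$n_datasets, x$n_trials, toupper(x$criterion)))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Parameter-recovery study for one model
#'
#' Simulate-and-refit loop under a single model: draw generating parameters,
#' simulate a dataset, fit the same model, and correlate generating with
#' recovered values per parameter across replicates.
#'
#' @param spec A [model_spec()].
#' @inheritParams model_recovery
#' @param n_trials Trials per dataset (default 720).
#' @return List with `correlations` (named, per parameter), `generating`
#'   and `recovered` (matrices, one row per replicate) and `n_failures`.
#' @export
parameter_recovery <- function(spec, n_datasets = 20L, n_trials = 720L,
                               seed = 1L, pair = NULL, n_starts = 10L) {
  stopifnot(inherits(spec, "model_spec"))
  if (is.null(pair)) pair <- default_category_pair(spec$task, "visual")
  seeds <- .derive_seeds(seed, 4L * n_datasets)
  si <- 0L
  nxt <- function() { si <<- si + 1L; seeds[si] }
  gen <- rec <- NULL
  n_failures <- 0L
  for (dsi in seq_len(n_datasets)) {
    theta <- sample_generating_params(spec, seed = nxt(), pair = pair)
    design <- generate_design(pair, n_blocks = 1L, trials_per_block = n_trials,
                              seed = nxt())
    dat <- simulate_dataset(design, spec, theta, pair, seed = nxt())
    fit <- tryCatch(fit_model(dat, spec, n_starts = n_starts, seed = nxt()),
                    error = function(e) NULL)
    if (is.null(fit)) { n_failures <- n_failures + 1L; next }
    gen <- rbind(gen, .flatten_theta(theta))
    rec <- rbind(rec, .flatten_theta(fit$theta_hat))
  }
  if (is.null(gen)) stop("every replicate failed to fit", call. = FALSE)
  correlations <- vapply(seq_len(ncol(gen)), function(j) {
    if (stats::sd(gen[, j]) == 0 || stats::sd(rec[, j]) == 0) return(NA_real_)
    stats::cor(gen[, j], rec[, j])
  }, numeric(1))
  names(correlations) <- colnames(gen)
  list(correlations = correlations, generating = gen, recovered = rec,
       n_failures = n_failures)
}
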