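test_that("response probabilities form a distribution for every model variant", {
  for (task in c("different_means", "different_sds")) {
    pair <- default_category_pair(task, "visual")
    std <- theoretical_standardizer(pair)
    ps <- standardized_pair(pair, std)
    i <- 0L
    for (spec in core_model_set(task, "visual")) {
      i <- i + 1L
      theta <- sample_generating_params(spec, seed = 100 + i, pair = pair)
      for (z in c(-1.2, 0, 0.4, 2.1)) for (I in c(1L, 4L)) {
        p <- response_probabilities(spec, theta, z, I, pair_std = ps,
                                    s_raw = z * std$sd + std$mean, sd_deg = std$sd)
        expect_length(p, 8L)
        expect_true(all(p >= -1e-12))
        expect_equal(sum(p), 1, tolerance = 1e-10)
      }
    }
  }
})

test_that("symmetric parameters give mirror-symmetric probabilities at the criterion", {
  spec <- model_spec("linear", "different_means")
  theta <- list(sigma = c(2, 1.4, 0.9, 0.6),
                k = c(0, 0.5, 1.1, 1.9), m = c(0, 0.3, 0.5, 0.8))
  for (I in 1:4) {
    p <- response_probabilities(spec, theta, 0, I)
    expect_equal(p, rev(p), tolerance = 1e-12)
  }
})

test_that("analytic probabilities match Monte-Carlo response frequencies", {
  ## generator/likelihood cross-validation at moderate scale for one
  ## evidence-strength and one Bayesian model (the full model set is
  ## exercised in the acceptance suite)
  for (cfg in list(list(family = "free_exponent", task = "different_means"),
                   list(family = "bayes_lppr", task = "different_sds"))) {
    spec <- model_spec(cfg$family, cfg$task)
    pair <- default_category_pair(cfg$task, "visual")
    theta <- sample_generating_params(spec, seed = 41, pair = pair)
    design <- generate_design(pair, n_blocks = 1L, trials_per_block = 120L,
                              seed = 42)
    reps <- 2e4
    row <- design[17, ]
    dat <- simulate_dataset(row[rep(1, reps), ], spec, theta, pair,
                            standardizer_policy = "theoretical", seed = 43)
    freq <- tabulate(dat$trials$r, 8L) / reps
    p <- response_probabilities(spec, theta, dat$trials$z[1], row$intensity,
                                pair_std = dat$pair_std)
    se <- sqrt(p * (1 - p) / reps)
    expect_true(all(abs(freq - p) <= 3 * se + 2 / reps))
  }
})

test_that("decision-noise quadrature: degenerate limit, conservation, convergence", {
  spec <- model_spec("bayes_lppr", "different_means", decision_noise = TRUE)
  pair <- default_category_pair("different_means", "visual")
  ps <- standardized_pair(pair, theoretical_standardizer(pair))
  theta <- sample_generating_params(spec, seed = 51, pair = pair)
  ## sigma_d -> 0 equals the no-noise Bayesian model
  th0 <- theta; th0$sigma_d <- 0
  plain <- response_probabilities(model_spec("bayes_lppr", "different_means"),
                                  theta[c("sigma", "k")], 0.4, 2L, pair_std = ps)
  expect_equal(response_probabilities_dnoise(spec, th0, 0.4, 2L, pair_std = ps),
               plain, tolerance = 1e-12)
  ## conservation at every draw count
  for (nd in c(11L, 101L)) {
    p <- response_probabilities_dnoise(spec, theta, -0.7, 1L, pair_std = ps,
                                       ndraw = nd)
    expect_equal(sum(p), 1, tolerance = 1e-10)
  }
  ## quadrature converges in draw count toward dense-grid marginalisation
  ## over the same percentile span
  dense <- response_probabilities_dnoise(spec, theta, -0.7, 1L, pair_std = ps,
                                         ndraw = 4001L)
  errs <- vapply(c(11L, 31L, 101L), function(nd)
    max(abs(response_probabilities_dnoise(spec, theta, -0.7, 1L, pair_std = ps,
                                          ndraw = nd) - dense)), numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
  ## and agrees with a Monte-Carlo marginalisation over true Gaussian
  ## boundary noise up to the truncation error of the percentile span
  set.seed(99)
  nmc <- 2e4
  pmc <- rep(0, 8)
  for (j in seq_len(nmc)) {
    kj <- theta$k + theta$sigma_d * rnorm(1)
    cuts <- invert_lppr(kj, theta$sigma[1], ps, "different_means")
    pmc <- pmc + diff(c(0, pnorm(cuts, -0.7, theta$sigma[1]), 1)) / nmc
  }
  p101 <- response_probabilities_dnoise(spec, theta, -0.7, 1L, pair_std = ps)
  expect_lt(max(abs(p101 - pmc)), 0.02)
})

test_that("dataset log-likelihood is additive and matches a naive reference loop", {
  sim <- make_sim("quadratic", "different_sds", n_trials = 48L, seed = 61)
  one <- sim$data
  ## single trial, then the same trial twice
  tr1 <- one$trials[1, ]
  d1 <- conf_dataset(tr1, one$pair, one$std)
  d2 <- conf_dataset(tr1[c(1, 1), ], one$pair, one$std)
  ll1 <- dataset_loglik(d1, sim$spec, sim$theta)
  expect_equal(dataset_loglik(d2, sim$spec, sim$theta), 2 * ll1, tolerance = 1e-10)
  ## naive reference: per-trial probabilities via the R-side interval masses
  ref <- sum(vapply(seq_len(nrow(one$trials)), function(i) {
    p <- response_probabilities(sim$spec, sim$theta, one$trials$z[i],
                                one$trials$intensity[i], pair_std = one$pair_std)
    log(max(p[one$trials$r[i]], 1e-12))
  }, numeric(1)))
  expect_equal(dataset_loglik(one, sim$spec, sim$theta), ref, tolerance = 1e-8)
  expect_error(dataset_loglik(conf_dataset(one$trials[0, ], one$pair, one$std),
                              sim$spec, sim$theta), "empty")
})

test_that("probability floor keeps extreme observations finite", {
  spec <- model_spec("distance", "different_means")
  theta <- list(sigma = c(0.5, 0.4, 0.3, 0.2), k = c(0, 0.5, 1, 1.5))
  pair <- default_category_pair("different_means", "visual")
  tr <- data.frame(participant = "p", task = "different_means",
                   modality = "visual", s_raw = c(-40, 40), intensity = 4L,
                   true_category = 1:2, response_category = c(2L, 1L),
                   confidence = 4L)
  dat <- conf_dataset(tr, pair, standardizer(0, 6.4))
  ll <- dataset_loglik(dat, spec, theta)
  expect_true(is.finite(ll))
  expect_gte(ll, 2 * log(1e-12))
})

test_that("free-parameter counts enumerate the documented parameter lists", {
  dm <- function(family, ...) model_spec(family, "different_means", ...)
  ds <- function(family, ...) model_spec(family, "different_sds", ...)
  expect_equal(count_parameters(dm("distance")), 8L)
  expect_equal(count_parameters(ds("distance")), 11L)
  expect_equal(count_parameters(dm("linear")), 12L)
  expect_equal(count_parameters(ds("linear")), 18L)
  expect_equal(count_parameters(dm("free_exponent")), 13L)
  expect_equal(count_parameters(ds("free_exponent")), 19L)
  expect_equal(count_parameters(dm("free_exponent", odn = TRUE)), 14L)
  expect_equal(count_parameters(ds("bayes_lppr")), 11L)
  expect_equal(count_parameters(dm("bayes_lppr", decision_noise = TRUE)), 12L)
  expect_equal(count_parameters(ds("bayes_lppr", free_prior = TRUE)), 13L)
  expect_equal(count_parameters(dm("bayes_lppr", odn = TRUE)), 12L)
  ## one extra exponent parameter over the fixed-exponent families
  expect_equal(count_parameters(dm("free_exponent")) - count_parameters(dm("quadratic")), 1L)
  expect_equal(count_parameters(ds("free_exponent")) - count_parameters(ds("linear")), 1L)
  ## cross-modal sharing modes
  fe_dm <- dm("free_exponent"); fe_ds <- ds("free_exponent")
  expect_equal(count_parameters(fe_dm, "common"), 13L)
  expect_equal(count_parameters(fe_dm, "different_noise"), 17L)
  expect_equal(count_parameters(fe_dm, "flexible"), 26L)
  expect_equal(count_parameters(fe_ds, "flexible"), 38L)
  expect_error(count_parameters(dm("linear"), "common"), "free_exponent")
})

test_that("trial tables round-trip through the delimited format", {
  sim <- make_sim("linear", "different_means", n_trials = 40L, seed = 71)
  path <- tempfile(fileext = ".csv")
  write_trials(sim$data, path)
  back <- read_trials(path)
  expect_equal(back$trials$s_raw, sim$data$trials$s_raw, tolerance = 1e-12)
  expect_equal(back$trials$r, sim$data$trials$r)
  expect_equal(back$std$mean, sim$data$std$mean, tolerance = 1e-12)
  bad <- sim$data$trials
  bad$confidence[1] <- 9L
  expect_error(conf_dataset(bad, sim$pair), "confidence")
})
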