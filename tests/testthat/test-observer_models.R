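test_that("model_spec rejects invalid component combinations", {
  expect_error(model_spec("linear", "different_means", decision_noise = TRUE),
               "bayes_lppr")
  expect_error(model_spec("distance", "different_sds", free_prior = TRUE),
               "bayes_lppr")
  expect_error(model_spec("bayes_lppr", "different_means", odn = TRUE,
                          decision_noise = TRUE), "not combined")
  expect_equal(model_token(model_spec("bayes_lppr", "different_means",
                                      decision_noise = TRUE)),
               "bayes_lppr+dnoise")
})

test_that("core model set has 9 visual / 7 auditory members", {
  expect_length(core_model_set("different_means", "visual"), 9L)
  expect_length(core_model_set("different_sds", "auditory"), 7L)
  expect_false(any(grepl("odn", names(core_model_set("different_means", "auditory")))))
})

test_that("region <-> category/confidence mapping is the documented bijection", {
  resp <- region_to_response(1:8)
  expect_equal(resp$category, c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L))
  expect_equal(resp$confidence, c(4L, 3L, 2L, 1L, 1L, 2L, 3L, 4L))
  expect_equal(response_to_region(resp$category, resp$confidence), 1:8)
})

test_that("orientation-dependent noise follows the rectified 2-cycle sinusoid", {
  np <- list(gamma = c(4, 3, 2, 1), psi = 2)
  sd_deg <- 6
  expect_equal(sigma_for_trial(np, 2, s_deg = 0, odn = TRUE, sd_deg = sd_deg), 3 / 6)
  expect_equal(sigma_for_trial(np, 2, s_deg = 45, odn = TRUE, sd_deg = sd_deg), 5 / 6)
  expect_equal(sigma_for_trial(np, 2, s_deg = 90, odn = TRUE, sd_deg = sd_deg), 3 / 6,
               tolerance = 1e-12)
  expect_equal(sigma_for_trial(np, 2, s_deg = -45, odn = TRUE, sd_deg = sd_deg), 5 / 6)
  expect_error(sigma_for_trial(np, 2, odn = TRUE), "s_deg")
  expect_equal(sigma_for_trial(list(sigma = c(4, 3, 2, 1)), 3), 2)
})

test_that("distance boundaries ignore sigma; scaled families nest exactly", {
  spec_d <- model_spec("distance", "different_means")
  pb <- list(k = c(0.1, 0.5, 1.0, 1.8))
  expect_equal(perceptual_boundaries(spec_d, pb, 0.3),
               perceptual_boundaries(spec_d, pb, 3))
  pb2 <- list(k = c(0.1, 0.5, 1.0, 1.8), m = c(0.2, 0.4, 0.6, 0.9), a = 1)
  for (sig in c(0.4, 1.7)) {
    lin <- perceptual_boundaries(model_spec("linear", "different_means"),
                                 pb2[c("k", "m")], sig)
    fe1 <- perceptual_boundaries(model_spec("free_exponent", "different_means"),
                                 pb2, sig)
    expect_identical(lin, fe1)
    quad <- perceptual_boundaries(model_spec("quadratic", "different_means"),
                                  pb2[c("k", "m")], sig)
    fe2 <- perceptual_boundaries(model_spec("free_exponent", "different_means"),
                                 modifyList(pb2, list(a = 2)), sig)
    expect_identical(quad, fe2)
  }
})

test_that("linear boundary shifts scale with sigma as m_r * delta_sigma", {
  spec <- model_spec("linear", "different_sds")
  pb <- list(k = cumsum(rep(0.3, 7)), m = seq(0.1, 0.7, 0.1))
  b1 <- perceptual_boundaries(spec, pb, 0.5)
  b2 <- perceptual_boundaries(spec, pb, 2.0)
  expect_equal(b2 - b1, pb$m * 1.5)
})

test_that("realized boundary layout partitions the axis and flags disorder", {
  spec <- model_spec("linear", "different_means")
  pb <- list(k = c(0.0, 0.4, 0.9, 1.5), m = c(0.1, 0.2, 0.3, 0.4))
  cuts <- perceptual_boundaries(spec, pb, 1)
  expect_length(cuts, 7L)
  expect_true(all(diff(cuts) > 0))
  ## sweep hits every region in order
  x <- seq(-4, 4, length.out = 2001)
  r <- response_region(x, cuts, "different_means")
  expect_equal(sort(unique(r)), 1:8)
  expect_true(all(diff(r) >= 0))
  expect_equal(response_region(min(cuts) - 1, cuts, "different_means"), 1L)
  ## ordering violation rejected: negative scale collapses boundary 4 under 3
  bad <- list(k = c(0.0, 0.4, 0.9, 0.95), m = c(0.1, 0.2, 0.3, -0.4))
  expect_error(perceptual_boundaries(spec, bad, 2), "strictly increasing")
})

test_that("different-SDs response map is even in x with high confidence at the centre", {
  spec <- model_spec("linear", "different_sds")
  pb <- list(k = cumsum(rep(0.35, 7)), m = rep(0.2, 7))
  cuts <- perceptual_boundaries(spec, pb, 0.8)
  x <- seq(0.01, 5, length.out = 500)
  expect_equal(response_region(x, cuts, "different_sds"),
               response_region(-x, cuts, "different_sds"))
  expect_equal(response_region(0, cuts, "different_sds"), 1L)  # (C1, conf 4)
  expect_equal(sort(unique(response_region(c(-x, x), cuts, "different_sds"))), 1:8)
})

test_that("lppr closed forms agree with the predictive-density log-ratio", {
  x <- seq(-3.5, 3.5, length.out = 101)
  dm <- standardized_pair(default_category_pair("different_means", "visual"),
                          theoretical_standardizer(default_category_pair("different_means", "visual")))
  ds <- standardized_pair(default_category_pair("different_sds", "auditory"),
                          theoretical_standardizer(default_category_pair("different_sds", "auditory")))
  for (sig in c(0.3, 0.8, 2.5)) {
    d_dm <- lppr(x, sig, dm, "different_means")
    oracle_dm <- dnorm(x, dm$mu1, sqrt(sig^2 + dm$sigma1^2), log = TRUE) -
      dnorm(x, dm$mu2, sqrt(sig^2 + dm$sigma2^2), log = TRUE)
    expect_lt(max(abs(d_dm - oracle_dm)), 1e-9)
    d_ds <- lppr(x, sig, ds, "different_sds")
    oracle_ds <- dnorm(x, 0, sqrt(sig^2 + ds$sigma1^2), log = TRUE) -
      dnorm(x, 0, sqrt(sig^2 + ds$sigma2^2), log = TRUE)
    expect_lt(max(abs(d_ds - oracle_ds)), 1e-9)
  }
  ## symmetries: odd in x (different means), even in x (different SDs)
  expect_equal(lppr(0, 1, dm, "different_means"), 0)
  expect_equal(lppr(x, 1, dm, "different_means"), -lppr(-x, 1, dm, "different_means"))
  expect_equal(lppr(x, 1, ds, "different_sds"), lppr(-x, 1, ds, "different_sds"))
})

test_that("lppr is monotone in the direction that orders the boundaries", {
  dm <- standardized_pair(default_category_pair("different_means", "auditory"),
                          theoretical_standardizer(default_category_pair("different_means", "auditory")))
  ds <- standardized_pair(default_category_pair("different_sds", "visual"),
                          theoretical_standardizer(default_category_pair("different_sds", "visual")))
  x <- seq(-4, 4, length.out = 200)
  expect_true(all(diff(lppr(x, 0.7, dm, "different_means")) < 0))  # mu1 < 0
  xp <- seq(0.01, 4, length.out = 200)
  expect_true(all(diff(lppr(xp, 0.7, ds, "different_sds")) < 0))
})

test_that("invert_lppr round-trips and marks unreachable central regions", {
  dm <- standardized_pair(default_category_pair("different_means", "visual"),
                          theoretical_standardizer(default_category_pair("different_means", "visual")))
  ds <- standardized_pair(default_category_pair("different_sds", "visual"),
                          theoretical_standardizer(default_category_pair("different_sds", "visual")))
  sig <- 0.6
  expect_equal(invert_lppr(0, sig, dm, "different_means"), 0)
  kd <- c(1.2, 0.4, -0.8)
  xb <- invert_lppr(kd, sig, dm, "different_means")
  expect_equal(lppr(xb, sig, dm, "different_means"), kd, tolerance = 1e-12)
  ## different SDs: A is the lppr at x = 0; boundaries just below A have
  ## small half-width, verified against a bisection oracle
  A <- lppr(0, sig, ds, "different_sds")
  for (kd in c(A - 0.01, A - 0.3, -1)) {
    xb <- invert_lppr(kd, sig, ds, "different_sds")
    root <- uniroot(function(x) lppr(x, sig, ds, "different_sds") - kd,
                    c(0, 50), tol = 1e-12)$root
    expect_equal(xb, root, tolerance = 1e-6)
  }
  expect_equal(invert_lppr(A + 0.5, sig, ds, "different_sds"), 0)  # empty region
  ## bayes boundary layout: decreasing k maps to increasing cuts
  k <- seq(1.5, -1.5, length.out = 7)
  cuts <- bayes_perceptual_boundaries(k, sig, dm, "different_means")
  expect_true(all(diff(cuts) > 0))
  cuts_ds <- bayes_perceptual_boundaries(k, sig, ds, "different_sds")
  expect_true(all(diff(cuts_ds) >= 0))
  expect_error(bayes_perceptual_boundaries(rev(k), sig, dm, "different_means"),
               "decreasing")
})
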