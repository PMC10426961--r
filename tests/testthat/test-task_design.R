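test_that("default category pairs carry the published design parameters", {
  dm_aud <- default_category_pair("different_means", "auditory")
  expect_equal(c(dm_aud$mu1, dm_aud$sigma1, dm_aud$mu2, dm_aud$sigma2),
               c(2300, 475, 3100, 475))
  dm_vis <- default_category_pair("different_means", "visual")
  expect_equal(dm_vis$mu1, -dm_vis$mu2)  # symmetric about horizontal
  expect_equal(c(dm_vis$mu2, dm_vis$sigma1), c(4, 5))
  ds_vis <- default_category_pair("different_sds", "visual")
  expect_equal(c(ds_vis$mu1, ds_vis$sigma1, ds_vis$mu2, ds_vis$sigma2),
               c(0, 3, 0, 12))
  ds_aud <- default_category_pair("different_sds", "auditory")
  expect_equal(c(ds_aud$sigma1, ds_aud$sigma2), c(125, 500))
  expect_equal(dm_aud$prior1, 0.5)
})

test_that("category_pair enforces its structural invariants", {
  expect_error(category_pair("different_means", "visual", -4, 5, 4, 6),
               "equal category SDs")
  expect_error(category_pair("different_sds", "visual", 0, 12, 0, 3),
               "sigma1 < sigma2")
  expect_error(category_pair("different_means", "visual", -4, -5, 4, -5),
               "positive")
  expect_error(category_pair("different_means", "visual", -4, 5, 4, 5, prior1 = 1),
               "prior1")
})

test_that("evidence transform matches direct density evaluation and its closed-form extremes", {
  ds_aud <- default_category_pair("different_sds", "auditory")
  expect_equal(evidence_for_category2(2700, ds_aud), 0.2)
  dm_vis <- default_category_pair("different_means", "visual")
  expect_equal(evidence_for_category2(0, dm_vis), 0.5)
  ## independent oracle: direct evaluation of both Gaussian densities
  for (cp in list(dm_vis, ds_aud, default_category_pair("different_sds", "visual"))) {
    s <- seq(cp$mu1 - 3 * cp$sigma2, cp$mu1 + 3 * cp$sigma2, length.out = 41)
    direct <- dnorm(s, cp$mu2, cp$sigma2) /
      (dnorm(s, cp$mu1, cp$sigma1) + dnorm(s, cp$mu2, cp$sigma2))
    expect_equal(evidence_for_category2(s, cp), direct, tolerance = 1e-12)
  }
  ## complementarity: swapping the categories gives 1 - e
  swapped <- category_pair("different_means", "visual", 4, 5, -4, 5)
  s <- seq(-20, 20, length.out = 31)
  expect_equal(evidence_for_category2(s, dm_vis) +
                 evidence_for_category2(s, swapped), rep(1, 31))
})

test_that("different-SDs evidence is even in (s - mu) with minimum sigma1/(sigma1+sigma2)", {
  cp <- default_category_pair("different_sds", "visual")
  s <- seq(0.5, 30, length.out = 25)
  expect_equal(evidence_for_category2(cp$mu1 + s, cp),
               evidence_for_category2(cp$mu1 - s, cp))
  e <- evidence_for_category2(seq(-40, 40, length.out = 2001), cp)
  expect_equal(min(e), cp$sigma1 / (cp$sigma1 + cp$sigma2), tolerance = 1e-9)
  expect_equal(evidence_for_category2(cp$mu1, cp),
               cp$sigma1 / (cp$sigma1 + cp$sigma2))
})

test_that("diagnosticity is the larger normalised density, >= 0.5, 0.5 at crossings", {
  for (cp in list(default_category_pair("different_means", "auditory"),
                  default_category_pair("different_sds", "visual"))) {
    s <- seq(cp$mu1 - 3 * cp$sigma2, cp$mu1 + 3 * cp$sigma2, length.out = 101)
    e <- evidence_for_category2(s, cp)
    expect_equal(category_diagnosticity(s, cp), pmax(e, 1 - e))
    expect_true(all(category_diagnosticity(s, cp) >= 0.5))
    for (pt in intersection_points(cp))
      expect_equal(category_diagnosticity(pt, cp), 0.5, tolerance = 1e-12)
  }
})

test_that("standardizer z-scores, round-trips, and rejects degenerate input", {
  vals <- c(-1, 1)
  expect_equal(fit_standardizer(vals)$mean, 0)
  set.seed(7)
  x <- rnorm(500, 2700, 400)
  std <- fit_standardizer(x)
  z <- standardize(x, std)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(unstandardize(z, std), x, tolerance = 1e-9)
  expect_error(fit_standardizer(rep(5, 10)), "distinct")
})

test_that("session-level standardizer centres near the design's mixture mean", {
  pair <- default_category_pair("different_means", "auditory")
  design <- generate_design(pair, seed = 99)
  std <- fit_standardizer(design$s_raw)
  mix_sd <- theoretical_standardizer(pair)$sd
  expect_lt(abs(std$mean - 2700), 3 * mix_sd / sqrt(nrow(design)))
})

test_that("intersection points solve density equality in closed form", {
  expect_equal(intersection_points(default_category_pair("different_means", "auditory")),
               2700)
  ds_aud <- default_category_pair("different_sds", "auditory")
  expect_equal(round(intersection_points(ds_aud)), c(2485, 2915))
  expect_equal(intersection_points(default_category_pair("different_means", "visual")),
               0)
  ## root-bracketing oracle: intersections are exactly the 0.5-crossings of
  ## the evidence transform
  for (cp in list(ds_aud, default_category_pair("different_sds", "visual"))) {
    pts <- intersection_points(cp)
    expect_length(pts, 2L)
    for (pt in pts) {
      root <- uniroot(function(s) evidence_for_category2(s, cp) - 0.5,
                      c(pt - cp$sigma1, pt + cp$sigma1), tol = 1e-10)$root
      expect_equal(pt, root, tolerance = 1e-6)
    }
  }
})

test_that("ideal-category labels agree with the density argmax everywhere", {
  dm_aud <- default_category_pair("different_means", "auditory")
  expect_equal(ideal_category(3000, dm_aud), 2L)
  ds_aud <- default_category_pair("different_sds", "auditory")
  expect_equal(ideal_category(c(2500, 2700, 2900), ds_aud), rep(1L, 3))
  expect_equal(ideal_category(c(2400, 3000), ds_aud), rep(2L, 2))
  set.seed(31)
  for (cp in list(dm_aud, ds_aud)) {
    s <- runif(1000, cp$mu1 - 4 * cp$sigma2, cp$mu1 + 4 * cp$sigma2)
    brute <- ifelse(dnorm(s, cp$mu2, cp$sigma2) > dnorm(s, cp$mu1, cp$sigma1), 2L, 1L)
    expect_equal(ideal_category(s, cp), brute)
  }
})
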