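#' Category pair: the generative model of one task-modality configuration
#'
#' A `category_pair` holds the two Gaussian category distributions of a
#' two-alternative categorisation task. In a *different-means* task the
#' categories share a standard deviation and differ in mean; in a
#' *different-SDs* task they share a mean and category 1 is the narrower
#' distribution.
#'
#' @param task `"different_means"` or `"different_sds"`.
#' @param modality `"visual"` (stimulus values in degrees of orientation) or
#'   `"auditory"` (Hz).
#' @param mu1,sigma1 Mean and SD of the category-1 Gaussian (stimulus units).
#' @param mu2,sigma2 Mean and SD of the category-2 Gaussian (stimulus units).
#' @param prior1 Prior probability of category 1 (default 0.5; categories are
#'   sampled equally in the designs modelled here).
#'
#' @return An object of class `category_pair`.
#' @seealso [default_category_pair()] for the standard configurations.
#' @export
category_pair <- function(task, modality, mu1, sigma1, mu2, sigma2, prior1 = 0.5) {
  task <- match.arg(task, .valid_tasks)
  modality <- match.arg(modality, .valid_modalities)
  stopifnot(is.numeric(mu1), is.numeric(sigma1), is.numeric(mu2), is.numeric(sigma2))
  if (sigma1 <= 0 || sigma2 <= 0)
    stop("category SDs must be positive", call. = FALSE)
  if (prior1 <= 0 || prior1 >= 1)
    stop("prior1 must lie strictly between 0 and 1", call. = FALSE)
  if (task == "different_means") {
    if (sigma1 != sigma2)
      stop("different_means task requires equal category SDs", call. = FALSE)
    if (mu1 == mu2)
      stop("different_means task requires distinct category means", call. = FALSE)
  } else {
    if (mu1 != mu2)
      stop("different_sds task requires equal category means", call. = FALSE)
    if (sigma1 >= sigma2)
      stop("different_sds task requires sigma1 < sigma2", call. = FALSE)
  }
  structure(
    list(task = task, modality = modality,
         mu1 = mu1, sigma1 = sigma1, mu2 = mu2, sigma2 = sigma2,
         prior1 = prior1),
    class = "category_pair")
}

#' @export
print.category_pair <- function(x, ...) {
  unit <- if (x$modality == "visual") "deg" else "Hz"
  cat(sprintf("<category_pair> %s / %s\n", x$task, x$modality))
  cat(sprintf("  category 1: N(%g, %g^2) %s\n", x$mu1, x$sigma1, unit))
  cat(sprintf("  category 2: N(%g, %g^2) %s\n", x$mu2, x$sigma2, unit))
  cat(sprintf("  prior1 = %g\n", x$prior1))
  invisible(x)
}

#' Standard category distributions for each task-modality configuration
#'
#' Returns the category pair used in the experiments this package models:
#' different means, visual: -4 / +4 deg, common SD 5 deg; different means,
#' auditory: 2300 / 3100 Hz, common SD 475 Hz; different SDs, visual: mean 0
#' deg, SDs 3 and 12 deg; different SDs, auditory: mean 2700 Hz, SDs 125 and
#' 500 Hz.
#'
#' @inheritParams category_pair
#' @return A [category_pair()].
#' @examples
#' default_category_pair("different_means", "auditory")
#' @export
default_category_pair <- function(task, modality) {
  task <- match.arg(task, .valid_tasks)
  modality <- match.arg(modality, .valid_modalities)
  if (task == "different_means") {
    if (modality == "visual")
      category_pair(task, modality, mu1 = -4, sigma1 = 5, mu2 = 4, sigma2 = 5)
    else
      category_pair(task, modality, mu1 = 2300, sigma1 = 475, mu2 = 3100, sigma2 = 475)
  } else {
    if (modality == "visual")
      category_pair(task, modality, mu1 = 0, sigma1 = 3, mu2 = 0, sigma2 = 12)
    else
      category_pair(task, modality, mu1 = 2700, sigma1 = 125, mu2 = 2700, sigma2 = 500)
  }
}

#' Evidence that a stimulus was drawn from category 2
#'
#' The category-2 density at the stimulus value, normalised by the summed
#' density of both categories: `N(s; mu2, sigma2) / (N(s; mu1, sigma1) +
#' N(s; mu2, sigma2))`. Ranges over (0, 1); for a different-SDs pair it never
#' reaches 0 because the narrow category-1 distribution lies inside
#' category 2, and its minimum (at the shared mean) is
#' `sigma1 / (sigma1 + sigma2)`.
#'
#' @param s Stimulus value(s) in raw units (degrees or Hz). Vectorised.
#' @param cp A [category_pair()].
#' @return Numeric vector of evidence values in (0, 1).
#' @export
evidence_for_category2 <- function(s, cp) {
  stopifnot(inherits(cp, "category_pair"))
  ## work on log densities to stay stable far in the tails
  l1 <- dnorm(s, cp$mu1, cp$sigma1, log = TRUE)
  l2 <- dnorm(s, cp$mu2, cp$sigma2, log = TRUE)
  1 / (1 + exp(l1 - l2))
}

#' Category diagnosticity of a stimulus value
#'
#' The normalised density of the *most probable* category at the stimulus
#' value: `max(e, 1 - e)` where `e` is [evidence_for_category2()]. Ranges
#' from 0.5 (the categories are equally likely) to 1.
#'
#' @inheritParams evidence_for_category2
#' @return Numeric vector in \[0.5, 1\].
#' @export
category_diagnosticity <- function(s, cp) {
  e <- evidence_for_category2(s, cp)
  pmax(e, 1 - e)
}

#' Stimulus standardizer (z-scoring transform)
#'
#' Stimulus values are standardised per task-modality configuration before
#' modelling: the mean of all presented values is subtracted and the result
#' divided by their standard deviation, putting orientations and frequencies
#' on a common unit scale.
#'
#' `fit_standardizer()` estimates the transform from a set of presented
#' stimulus values; `standardizer()` builds one from known moments (e.g. the
#' theoretical moments of the design, see [theoretical_standardizer()]).
#'
#' @param values Numeric vector of presented stimulus values (all categories
#'   and intensities of one configuration pooled); at least two distinct
#'   values.
#' @param mean,sd Centre and scale of the transform, in stimulus units.
#' @return An object of class `standardizer` with fields `mean` and `sd`.
#' @export
standardizer <- function(mean, sd) {
  stopifnot(is.finite(mean), is.finite(sd))
  if (sd <= 0) stop("standardizer sd must be positive", call. = FALSE)
  structure(list(mean = mean, sd = sd), class = "standardizer")
}

#' @rdname standardizer
#' @export
fit_standardizer <- function(values) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 2)
    stop("need at least two distinct stimulus values to fit a standardizer",
         call. = FALSE)
  standardizer(mean(values), stats::sd(values))
}

#' @rdname standardizer
#' @param cp A [category_pair()]; the theoretical moments are those of the
#'   equal-weight mixture of its two category distributions.
#' @export
theoretical_standardizer <- function(cp) {
  stopifnot(inherits(cp, "category_pair"))
  p1 <- cp$prior1
  m <- p1 * cp$mu1 + (1 - p1) * cp$mu2
  v <- p1 * (cp$sigma1^2 + (cp$mu1 - m)^2) + (1 - p1) * (cp$sigma2^2 + (cp$mu2 - m)^2)
  standardizer(m, sqrt(v))
}

#' @rdname standardizer
#' @param std A `standardizer`.
#' @param s,z Values on the raw (`s`) or standardized (`z`) scale.
#' @export
standardize <- function(s, std) {
  stopifnot(inherits(std, "standardizer"))
  (s - std$mean) / std$sd
}

#' @rdname standardizer
#' @export
unstandardize <- function(z, std) {
  stopifnot(inherits(std, "standardizer"))
  z * std$sd + std$mean
}

#' Express a category pair on the standardized stimulus axis
#'
#' @param cp A [category_pair()].
#' @param std A [standardizer()].
#' @return A list with `mu1`, `sigma1`, `mu2`, `sigma2`, `prior1`, `task` on
#'   the standardized scale (means shifted and all parameters divided by the
#'   standardizer SD).
#' @export
standardized_pair <- function(cp, std) {
  list(task = cp$task,
       mu1 = standardize(cp$mu1, std), sigma1 = cp$sigma1 / std$sd,
       mu2 = standardize(cp$mu2, std), sigma2 = cp$sigma2 / std$sd,
       prior1 = cp$prior1)
}

#' Intersection points of the two category distributions
#'
#' Stimulus values where the prior-weighted category densities are equal,
#' found in closed form from the quadratic obtained by equating
#' log-densities. A different-means pair has one intersection (the midpoint
#' of the means under equal priors); a different-SDs pair has two, symmetric
#' about the shared mean.
#'
#' @param cp A [category_pair()].
#' @return Numeric vector of intersection points, increasing.
#' @export
intersection_points <- function(cp) {
  stopifnot(inherits(cp, "category_pair"))
  lp <- log(cp$prior1) - log(1 - cp$prior1)
  if (cp$task == "different_means") {
    ## equal SDs: log-density difference is linear in s
    ## (s - mu2)^2 - (s - mu1)^2 = 2 sigma^2 * lp
    s <- (cp$mu1 + cp$mu2) / 2 + cp$sigma1^2 * lp / (cp$mu2 - cp$mu1)
    return(s)
  }
  ## shared mean, sigma1 < sigma2: quadratic in (s - mu)^2
  a <- 0.5 * (1 / cp$sigma1^2 - 1 / cp$sigma2^2)
  c0 <- log(cp$sigma2 / cp$sigma1) + lp
  if (c0 <= 0)
    stop("no intersection: prior weighting leaves one category dominant everywhere",
         call. = FALSE)
  delta <- sqrt(c0 / a)
  cp$mu1 + c(-delta, delta)
}

#' Most probable generating category for a stimulus value
#'
#' Returns 2 where [evidence_for_category2()] exceeds 0.5 and 1 otherwise;
#' an exact tie is labelled category 1 (deterministic convention for a
#' measure-zero event).
#'
#' @inheritParams evidence_for_category2
#' @return Integer vector of categories (1 or 2).
#' @export
ideal_category <- function(s, cp) {
  ifelse(evidence_for_category2(s, cp) > 0.5, 2L, 1L)
}
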