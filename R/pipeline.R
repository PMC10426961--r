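#' Averaged predicted responses for visualisation
#'
#' The plotting device used to compare fitted models with data: for each
#' trial, draw `n_samples` measurements from the trial's measurement
#' distribution, turn each into a category-confidence response under the
#' model (for decision-noise models, each measurement is compared with
#' `n_draws` random boundary draws), and average the signed combined
#' response (confidence 1..4, negative for category 1, positive for
#' category 2). This sampling average is strictly a visualisation tool; the
#' analytic interval masses of [response_probabilities()] are what fitting
#' uses.
#'
#' @param data A [conf_dataset()].
#' @param spec A [model_spec()].
#' @param theta Parameters (typically `theta_hat` of a [fit_model()] fit).
#' @param n_samples Measurement samples per trial (default 100).
#' @param n_draws Boundary draws per sample for decision-noise models
#'   (default 100).
#' @param seed Optional seed.
#' @return The trial table with an added `predicted_signed` column (and
#'   `observed_signed` for the empirical responses).
#' @export
predict_responses <- function(data, spec, theta, n_samples = 100L,
                              n_draws = 100L, seed = NULL) {
  stopifnot(inherits(data, "conf_dataset"), inherits(spec, "model_spec"))
  if (!is.null(seed)) set.seed(seed)
  tr <- data$trials
  n <- nrow(tr)
  sig <- .trial_sigmas(spec, theta, tr, data$std$sd)
  signed <- function(r) ifelse(r <= 4L, -(5L - r), r - 4L)
  pred <- numeric(n)
  if (spec$family == "bayes_lppr" && spec$decision_noise) {
    pe <- .effective_pair(spec, theta, data$pair_std)
    for (i in seq_len(n)) {
      x <- rnorm(n_samples, tr$z[i], sig[i])
      d <- lppr_vec_sigma(x, sig[i], pe, spec$task)
      ## each sample against n_draws boundary-set draws (equal offsets)
      eps <- theta$sigma_d * rnorm(n_draws)
      vals <- vapply(eps, function(e)
        mean(signed(1L + rowSums(outer(d + e, theta$k, `<`)))), numeric(1))
      pred[i] <- mean(vals)
    }
  } else {
    rc <- .realized_cuts(spec, theta, sig, data$pair_std)
    if (rc$viol > 0)
      stop("parameters violate realized-boundary ordering", call. = FALSE)
    for (i in seq_len(n)) {
      x <- rnorm(n_samples, tr$z[i], sig[i])
      v <- if (spec$task == "different_sds") abs(x) else x
      r <- 1L + colSums(outer(rc$cuts[i, ], v, `<`))
      pred[i] <- mean(signed(r))
    }
  }
  tr$observed_signed <- signed(tr$r)
  tr$predicted_signed <- pred
  tr
}

#' Equal-count stimulus bins
#'
#' Bins values so every bin holds (as nearly as possible) the same number
#' of observations, the binning used for response-curve figures.
#'
#' @param x Numeric vector.
#' @param n_bins Number of bins (default 12).
#' @return Integer bin index per observation.
#' @export
equal_count_bins <- function(x, n_bins = 12L) {
  as.integer(cut(rank(x, ties.method = "first"),
                 breaks = n_bins, labels = FALSE, include.lowest = TRUE))
}

#' Predicted-vs-observed response curves
#'
#' Mean observed and model-predicted signed category/confidence response in
#' equal-count stimulus bins, split by intensity level.
#'
#' @param pred Output of [predict_responses()].
#' @param n_bins Equal-count bins along the stimulus axis (default 12).
#' @return A ggplot object.
#' @export
plot_model_fit <- function(pred, n_bins = 12L) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_model_fit needs the ggplot2 package", call. = FALSE)
  pieces <- lapply(split(pred, pred$intensity), function(d) {
    d$bin <- equal_count_bins(d$s_raw, n_bins)
    agg <- do.call(rbind, lapply(split(d, d$bin), function(b)
      data.frame(intensity = b$intensity[1],
                 s = mean(b$s_raw),
                 observed = mean(b$observed_signed),
                 predicted = mean(b$predicted_signed))))
    agg
  })
  df <- do.call(rbind, pieces)
  ggplot2::ggplot(df, ggplot2::aes(x = s)) +
    ggplot2::geom_point(ggplot2::aes(y = observed,
                                     colour = factor(intensity)), shape = 15) +
    ggplot2::geom_line(ggplot2::aes(y = predicted,
                                    colour = factor(intensity))) +
    ggplot2::labs(x = "stimulus value", y = "signed category/confidence response",
                  colour = "intensity") +
    ggplot2::theme_minimal()
}

#' Confusability heat map
#'
#' @param cm A `conf_confusability` from [model_recovery()].
#' @return A ggplot object.
#' @export
plot_confusability <- function(cm) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_confusability needs the ggplot2 package", call. = FALSE)
  m <- cm$matrix
  df <- expand.grid(generating = rownames(m), fitted = colnames(m),
                    stringsAsFactors = FALSE)
  df$p <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(x = generating, y = fitted,
                                   fill = p)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", p)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue", limits = c(0, 1)) +
    ggplot2::labs(x = "generating model", y = "best-fitting model",
                  fill = "selection\nprobability") +
    ggplot2::theme_minimal()
}

## ---- config-driven pipeline ------------------------------------------------

#' Run a configured analysis pipeline
#'
#' Executes the requested stages over one task-modality configuration and
#' writes delimited result tables plus a JSON run manifest (seeds, settings,
#' package version) to the output directory, so a saved configuration
#' re-executes to identical outputs.
#'
#' The configuration is a named list (or a YAML file path): `output_dir`;
#' `seed`; `task`; `modality`; optional `stages` (subset of `"simulate"`,
#' `"compare"`, `"crossmodal"`, `"recover"`, default `"simulate"` +
#' `"compare"`); `simulate`: `model` token, `n_blocks`, `trials_per_block`;
#' `compare`: `n_starts`; `crossmodal`: `n_starts`; `recover`: `models`,
#' `n_datasets`, `n_trials`, `n_starts`.
#'
#' @param config Named list or path to a YAML file.
#' @return Invisibly, a list of the stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML config needs the yaml package", call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  defaults <- list(seed = 1L, task = "different_means", modality = "visual",
                   stages = c("simulate", "compare"),
                   simulate = list(model = "free_exponent", n_blocks = 6L,
                                   trials_per_block = 120L),
                   compare = list(n_starts = 5L),
                   crossmodal = list(n_starts = 5L),
                   recover = list(models = c("distance", "free_exponent",
                                             "bayes_lppr", "bayes_lppr+dnoise"),
                                  n_datasets = 10L, n_trials = 360L,
                                  n_starts = 5L))
  bad <- setdiff(names(config), c(names(defaults), "output_dir"))
  if (length(bad))
    stop("unknown config fields: ", paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(config$output_dir))
    stop("config$output_dir is required", call. = FALSE)
  cfg <- modifyList(defaults, config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  pair <- default_category_pair(cfg$task, cfg$modality)
  out <- list()
  manifest <- list(package = "confcat",
                   version = as.character(utils::packageVersion("confcat")),
                   seed = cfg$seed, task = cfg$task, modality = cfg$modality,
                   stages = cfg$stages, settings = cfg[c("simulate", "compare",
                                                         "crossmodal", "recover")],
                   outputs = list())
  note <- function(file, stage)
    manifest$outputs[[length(manifest$outputs) + 1L]] <<-
      list(file = file, stage = stage)

  tok2spec <- function(tok, task) {
    parts <- strsplit(tok, "+", fixed = TRUE)[[1]]
    model_spec(parts[1], task,
               odn = "odn" %in% parts[-1],
               decision_noise = "dnoise" %in% parts[-1],
               free_prior = "prior" %in% parts[-1])
  }

  dat <- NULL
  if ("simulate" %in% cfg$stages) {
    spec <- tok2spec(cfg$simulate$model, cfg$task)
    theta <- sample_generating_params(spec, seed = cfg$seed + 1L, pair = pair)
    design <- generate_design(pair, n_blocks = cfg$simulate$n_blocks,
                              trials_per_block = cfg$simulate$trials_per_block,
                              seed = cfg$seed + 2L)
    dat <- simulate_dataset(design, spec, theta, pair, seed = cfg$seed + 3L)
    f <- file.path(cfg$output_dir, "trials.csv")
    write_trials(dat, f); note("trials.csv", "simulate")
    out$dataset <- dat
  }

  if ("compare" %in% cfg$stages) {
    if (is.null(dat)) stop("compare stage needs a simulate stage", call. = FALSE)
    models <- core_model_set(cfg$task, cfg$modality)
    fits <- list()
    for (tok in names(models)) {
      inits <- .warm_inits(models[[tok]], fits)
      fits[[tok]] <- fit_model(dat, models[[tok]],
                               n_starts = cfg$compare$n_starts,
                               seed = cfg$seed + 10L + match(tok, names(models)),
                               extra_inits = inits)
    }
    comp <- compare_models(fits)
    f <- file.path(cfg$output_dir, "model_comparison.csv")
    write.csv(comp$table, f, row.names = FALSE); note("model_comparison.csv", "compare")
    f <- file.path(cfg$output_dir, "fits_per_participant.csv")
    write.csv(comp$per_participant, f, row.names = FALSE)
    note("fits_per_participant.csv", "compare")
    out$comparison <- comp
  }

  if ("crossmodal" %in% cfg$stages) {
    pv <- default_category_pair(cfg$task, "visual")
    pa <- default_category_pair(cfg$task, "auditory")
    spec_fe <- model_spec("free_exponent", cfg$task)
    thv <- sample_generating_params(spec_fe, seed = cfg$seed + 20L, pair = pv)
    tha <- sample_generating_params(spec_fe, seed = cfg$seed + 21L, pair = pa)
    dv <- simulate_dataset(generate_design(pv, seed = cfg$seed + 22L),
                           spec_fe, thv, pv, seed = cfg$seed + 23L)
    da <- simulate_dataset(generate_design(pa, seed = cfg$seed + 24L),
                           spec_fe, tha, pa, seed = cfg$seed + 25L)
    cm_fits <- lapply(c("common", "different_noise", "flexible"), function(mode)
      fit_cross_modal(dv, da, mode, n_starts = cfg$crossmodal$n_starts,
                      seed = cfg$seed + 30L))
    tab <- do.call(rbind, lapply(cm_fits, function(f)
      data.frame(mode = f$cross_modal_mode, loglik = f$loglik, z = f$z, n = f$n,
                 aic = f$aic, bic = f$bic)))
    f <- file.path(cfg$output_dir, "crossmodal.csv")
    write.csv(tab, f, row.names = FALSE); note("crossmodal.csv", "crossmodal")
    out$crossmodal <- cm_fits
  }

  if ("recover" %in% cfg$stages) {
    models <- lapply(cfg$recover$models, tok2spec, task = cfg$task)
    names(models) <- cfg$recover$models
    cm <- model_recovery(models, n_datasets = cfg$recover$n_datasets,
                         n_trials = cfg$recover$n_trials,
                         seed = cfg$seed + 40L, pair = pair,
                         n_starts = cfg$recover$n_starts)
    f <- file.path(cfg$output_dir, "confusability.csv")
    write.csv(cm$matrix, f); note("confusability.csv", "recover")
    out$recovery <- cm
  }

  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(out)
}
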