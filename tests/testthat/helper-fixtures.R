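# One-call simulated fixture: model spec + generating parameters + balanced
# design + simulated observer responses, all deterministic in `seed`.
make_sim <- function(family = "linear", task = "different_means",
                     modality = "visual", n_trials = 360L, seed = 1L,
                     odn = FALSE, dnoise = FALSE, prior = FALSE,
                     n_blocks = 1L) {
  spec <- model_spec(family, task, odn = odn, decision_noise = dnoise,
                     free_prior = prior)
  pair <- default_category_pair(task, modality)
  theta <- sample_generating_params(spec, seed = seed, pair = pair)
  design <- generate_design(pair, n_blocks = n_blocks,
                            trials_per_block = n_trials, seed = seed + 1L)
  dat <- simulate_dataset(design, spec, theta, pair, seed = seed + 2L)
  list(spec = spec, pair = pair, theta = theta, design = design, data = dat)
}

# The nine core variants as (family, odn, dnoise, prior) rows, for loops.
variant_grid <- function(task, modality = "visual") {
  specs <- core_model_set(task, modality)
  lapply(specs, function(s) s)
}
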