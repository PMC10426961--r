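#!/usr/bin/env Rscript
## Cross-modal parameter-sharing analysis: simulate one observer per
## modality with modality-specific free-exponent parameters, fit the
## free-exponent model jointly to both modalities under the three sharing
## modes (common / different-noise / flexible) and compare. With
## modality-specific generating parameters the flexible mode should win.

library(confcat)

seed <- 77L
rows <- NULL
for (task in c("different_means", "different_sds")) {
  sp <- model_spec("free_exponent", task)
  pv <- default_category_pair(task, "visual")
  pa <- default_category_pair(task, "auditory")
  thv <- sample_generating_params(sp, seed = seed + 1L, pair = pv)
  tha <- sample_generating_params(sp, seed = seed + 2L, pair = pa)
  dv <- simulate_dataset(generate_design(pv, seed = seed + 3L), sp, thv, pv,
                         seed = seed + 4L)
  da <- simulate_dataset(generate_design(pa, seed = seed + 5L), sp, tha, pa,
                         seed = seed + 6L)
  f_com <- fit_cross_modal(dv, da, "common", n_starts = 4L, seed = seed)
  warm <- list({
    th <- f_com$theta_hat
    th$sigma_visual <- th$sigma; th$sigma_auditory <- th$sigma; th$sigma <- NULL
    th
  })
  f_dn <- fit_cross_modal(dv, da, "different_noise", n_starts = 3L,
                          seed = seed, extra_inits = warm)
  f_flex <- fit_cross_modal(dv, da, "flexible", n_starts = 4L, seed = seed)
  for (f in list(f_com, f_dn, f_flex)) {
    cat(sprintf("%-15s %-16s logLik %10.2f  z %2d  AIC %10.2f  BIC %10.2f\n",
                task, f$cross_modal_mode, f$loglik, f$z, f$aic, f$bic))
    rows <- rbind(rows, data.frame(task = task, mode = f$cross_modal_mode,
                                   loglik = f$loglik, z = f$z, n = f$n,
                                   aic = f$aic, bic = f$bic))
  }
  winner <- rows[rows$task == task, ]
  cat(sprintf("  -> best by AIC: %s\n", winner$mode[which.min(winner$aic)]))
}
dir.create("results", showWarnings = FALSE)
write.csv(rows, "results/crossmodal.csv", row.names = FALSE)
cat("\nFlexible (per-modality) settings winning by AIC mirrors the finding\n")
cat("that the confidence algorithm is shared but tuned per modality.\n")
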