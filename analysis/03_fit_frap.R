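#!/usr/bin/env Rscript
## FRAP normalization, exponential fitting and model selection.
##
## Simulates the published acquisition design (1 s interval, 90 s,
## 3 prebleach frames, 8 averaged replicates) for the kinetic regimes
## reported for droplet components -- Nck (single, 8 s), pCas (2/39 s),
## N-WASP (1/37 s), FAK (10/98 s), paxillin (7/78 s) -- plus a fluid
## bilayer control gated at t1/2 < 10 s. Writes fitted half-times,
## mobile fractions, the F-test selection and the nd flag per regime.

suppressMessages(library(condquant))
dir.create("results", showWarnings = FALSE)
seed <- 20260922L

regimes <- list(
  list(name = "Nck-like",     fr = 0.80,          th = 8),
  list(name = "pCas-like",    fr = c(0.45, 0.35), th = c(2, 39)),
  list(name = "N-WASP-like",  fr = c(0.50, 0.30), th = c(1, 37)),
  list(name = "FAK-like",     fr = c(0.30, 0.32), th = c(10, 98)),
  list(name = "paxillin-like", fr = c(0.40, 0.35), th = c(7, 78)),
  list(name = "bilayer-lipid", fr = 0.95,         th = 4))

rows <- NULL
for (i in seq_along(regimes)) {
  rg <- regimes[[i]]
  reps <- lapply(1:8, function(r) {
    g <- make_frap_series(rg$fr, log(2) / rg$th, bleach_depth = 0.1,
                          acquisition_bleach_rate = 0.002, noise_sd = 10,
                          seed = derive_seed(seed, i * 100 + r))
    normalize_trace(frap_trace(g$trace$t, g$trace$roi_intensity,
                               g$trace$reference_intensity,
                               g$trace$background_intensity))
  })
  av <- average_traces(reps)
  res <- fit_frap(av)
  fit <- res$fit
  gate <- if (fit$model == "single") qc_bilayer_fluidity(fit, 10) else NA
  message(sprintf(
    "%-14s truth t1/2 %-8s -> %s fit, t1/2 %s s, mobile %.2f, p(F) %.3g%s",
    rg$name, paste(rg$th, collapse = "/"), fit$model,
    paste(sprintf("%.1f", fit$t_half), collapse = "/"),
    fit$plateau, res$selection$p_value,
    if (!fit$plateau_resolved) " [plateau nd]" else ""))
  rows <- rbind(rows, data.frame(
    regime = rg$name, model_chosen = fit$model,
    truth_t_half = paste(rg$th, collapse = "/"),
    t_half_fast_s = fit$t_half[1],
    t_half_slow_s = if (length(fit$t_half) == 2) fit$t_half[2] else NA,
    mobile_fraction = fit$plateau,
    immobile_fraction = fit$immobile_fraction,
    f_statistic = res$selection$f_statistic,
    p_value = res$selection$p_value,
    plateau_resolved = fit$plateau_resolved,
    bilayer_gate_pass = gate,
    params = param_digest(list(interval_s = 1, duration_s = 90,
                               n_prebleach = 3, n_replicates = 8,
                               noise_sd = 10, alpha = 0.05, seed = seed))))
}
write.csv(rows, "results/frap_fits.csv", row.names = FALSE)
message("wrote results/frap_fits.csv")
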