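#!/usr/bin/env Rscript
# Sphere-of-action Stern-Volmer analysis of stepwise acrylamide titrations.
#
# Titrations are generated under the experimental protocol (five 1.9 uL
# additions of a 5.26 M stock into 90.5 uL, final volume 100 uL, ~0.1 M
# per step) for parameters in the published magnitude range
# (KSV = 7.3 1/M, V = 2 1/M, Yint = 1).  The noise-free round trip through
# dilution correction and the nonlinear fit is exact; 100 replicates with
# 2% multiplicative noise give a median KSV error below 5%.

suppressPackageStartupMessages(library(serpinkin))
dir.create("results", showWarnings = FALSE)

ksv_true <- 7.3; v_true <- 2.0

analyze <- function(noise) {
  sim <- simulate_quench(ksv_true, v_true, 1.0, noise = noise)
  tit <- build_titration(sim$data$f_raw, sim$data$added_ul, 90.5, 5.26)
  fit_sphere_of_action(tit)
}

f0 <- analyze(NULL)
cat(sprintf("noise-free: KSV = %.6f, V = %.6f, Yint = %.6f (truth %.1f / %.1f / 1)\n",
            f0$ksv, f0$v, f0$yint, ksv_true, v_true))

noisy <- do.call(rbind, lapply(1:100, function(seed) {
  f <- analyze(noise_model(mult = 0.02, seed = seed))
  data.frame(seed = seed, ksv = f$ksv, v = f$v, yint = f$yint,
             rel_err_ksv = abs(f$ksv - ksv_true) / ksv_true)
}))
write.csv(noisy, "results/quench_recovery.csv", row.names = FALSE)
cat(sprintf("2%% noise, 100 seeds: median KSV rel err %.4f\n",
            median(noisy$rel_err_ksv)))
cat("wrote results/quench_recovery.csv\n")
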