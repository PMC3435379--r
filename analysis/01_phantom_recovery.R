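#!/usr/bin/env Rscript
# Birefringence recovery on homogeneous phantoms.
#
# Simulates uniform-axis scleral phantoms at known birefringence (0.5-3 x
# 10^-3) and 30 dB detection SNR, runs the full processing chain (phase-
# aligned averaging, 8-pixel local matrices, Lu-Chipman retardance, bias
# correction, SNR > 10 dB and DOAU > 0.9 gating), and tabulates the recovery
# error of the gated volume mean.

library(optrheo)

dir.create("results", showWarnings = FALSE)
cfg <- pipeline_config()

rows <- lapply(c(0.5e-3, 1e-3, 2e-3, 3e-3), function(truth) {
  vol <- simulate_jones_volume(phantom_spec(dims = c(64, 64, 4), dn = truth,
                                            snr_db = 30, rng_seed = 20120906L))
  pv <- process_volume(vol, cfg)
  data.frame(true_dn = truth,
             estimated_dn = pv$mean_birefringence,
             rel_error_pct = 100 * (pv$mean_birefringence / truth - 1),
             n_valid_pixels = pv$n_valid)
})
tab <- do.call(rbind, rows)
print(tab, digits = 4)
write.csv(tab, "results/phantom_recovery.csv", row.names = FALSE)

cat(sprintf(
  "\nAll four phantoms recovered within %.2f%% of truth (gated volume mean, default config).\n",
  max(abs(tab$rel_error_pct))
))
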