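#!/usr/bin/env Rscript
# Noise-bias correction of the retardance estimator.
#
# The local-retardance estimator is nonnegative, so detection noise biases the
# volume mean upward. This study measures that bias on homogeneous phantoms at
# 15 dB SNR (true birefringence 1e-3) and shows the Monte-Carlo mean-estimator
# correction moving the estimate back towards truth, seed by seed.

library(optrheo)

dir.create("results", showWarnings = FALSE)
truth <- 1e-3
cfg_on <- pipeline_config()
cfg_off <- pipeline_config(bias_correction = FALSE)

rows <- lapply(1:10, function(s) {
  vol <- simulate_jones_volume(phantom_spec(dims = c(64, 64, 4), dn = truth,
                                            snr_db = 15, rng_seed = 500L + s))
  on <- process_volume(vol, cfg_on)$mean_birefringence
  off <- process_volume(vol, cfg_off)$mean_birefringence
  data.frame(seed = 500L + s, uncorrected = off, corrected = on,
             uncorrected_err = abs(off - truth), corrected_err = abs(on - truth))
})
tab <- do.call(rbind, rows)
print(tab, digits = 4)
write.csv(tab, "results/bias_correction.csv", row.names = FALSE)

cat(sprintf(
  "\nCorrection reduced |error| in %d of %d seeds (mean error %.3g -> %.3g, truth %.0e).\n",
  sum(tab$corrected_err < tab$uncorrected_err), nrow(tab),
  mean(tab$uncorrected_err), mean(tab$corrected_err), truth
))
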