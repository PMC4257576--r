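#!/usr/bin/env Rscript
# Monte-Carlo calibration of the three detectors: type-I error of the
# time-shift test on null communities and detection rates on communities
# generated under each coevolutionary regime. A quick-look version of
# the full calibration run by the test suite.

suppressMessages(library(coevorange))
started <- Sys.time()
dir.create("results", showWarnings = FALSE)

n_null <- 200; n_regime <- 50
seed0 <- 70000

null_p <- vapply(seq_len(n_null), function(i) {
  tn <- generate_community(synthetic_config("noise", treatments = "high",
                                            seed = seed0 + i))
  fit_time_shift_model(mean_infectivity(tn), "high")$p_value
}, numeric(1))

ard_hit <- vapply(seq_len(n_regime), function(i) {
  tn <- generate_community(synthetic_config("ard", treatments = "high",
                                            seed = seed0 + 1000 + i))
  fit <- fit_time_shift_model(mean_infectivity(tn), "high")
  fit$slope < 0 && fit$p_value < 0.05
}, logical(1))

fsd_hit <- vapply(seq_len(n_regime), function(i) {
  tn <- generate_community(synthetic_config("range_fsd", treatments = "high",
                                            seed = seed0 + 2000 + i))
  mi <- mean_infectivity(tn)
  fit <- fit_time_shift_model(mi, "high")
  rf <- range_fsd_anova(mi[mi$population == "high_1", ])
  fit$p_value >= 0.05 && rf$p_phage_time < 0.05 && rf$p_bacteria_time < 0.05
}, logical(1))

null_inc <- vapply(seq_len(n_regime), function(i) {
  tn <- generate_community(synthetic_config("noise", n_populations = 1,
                                            treatments = "high",
                                            seed = seed0 + 3000 + i))
  mean(inconsistency_profile(tn)$inconsistency_infectivity)
}, numeric(1))
spec_inc <- vapply(seq_len(n_regime), function(i) {
  tn <- generate_community(synthetic_config("specialism_fsd",
                                            n_populations = 1,
                                            treatments = "high",
                                            seed = seed0 + 4000 + i))
  mean(inconsistency_profile(tn)$inconsistency_infectivity)
}, numeric(1))
q95 <- quantile(null_inc, 0.95, names = FALSE)

summary <- data.frame(
  quantity = c("null_rejection_rate", "ard_detection", "range_fsd_detection",
               "specialism_inconsistency_exceedance"),
  value = c(mean(null_p < 0.05), mean(ard_hit), mean(fsd_hit),
            mean(spec_inc > q95)),
  n = c(n_null, n_regime, n_regime, n_regime))
print(summary, row.names = FALSE)
write.csv(summary, "results/06_calibration.csv", row.names = FALSE)

write_manifest("results/06_manifest.yaml", "calibration",
               config = list(n_null = n_null, n_regime = n_regime),
               seeds = list(base = seed0),
               outputs = "results/06_calibration.csv", started = started)
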