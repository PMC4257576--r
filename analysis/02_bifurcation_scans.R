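#!/usr/bin/env Rscript
# Grid continuation of the singular point along the two axes the model
# predicts should reorganise the coevolutionary dynamics: cost severity
# (a_min, the birth rate of a maximally resistant host) and crowding (q,
# which sets population size). Each scan is labelled with regimes and
# searched for Hopf bifurcations, refined by bisection.

suppressMessages(library(coevorange))
started <- Sys.time()
dir.create("results", showWarnings = FALSE)

p <- eco_params()

cat("== sweeping cost severity (a_min up = costs relaxing) ==\n")
sc_a <- scan_parameter(p, "a_min", seq(1.05, 3.35, by = 0.1))
print(sc_a)
hb_a <- detect_hopf(sc_a)
if (nrow(hb_a))
  cat(sprintf("refined Hopf at a_min in (%.5f, %.5f)\n",
              hb_a$lower, hb_a$upper))

cat("\n== sweeping crowding (q down = larger populations) ==\n")
sc_q <- scan_parameter(p, "q", seq(4, 0.1, by = -0.15))
print(sc_q)
hb_q <- detect_hopf(sc_q)
if (nrow(hb_q))
  cat(sprintf("refined Hopf at q in (%.5f, %.5f)\n",
              min(hb_q$lower, hb_q$upper), max(hb_q$lower, hb_q$upper)))

write.csv(sc_a$points, "results/02_scan_a_min.csv", row.names = FALSE)
write.csv(sc_q$points, "results/02_scan_q.csv", row.names = FALSE)
brackets <- rbind(
  if (nrow(hb_a)) cbind(parameter = "a_min", hb_a),
  if (nrow(hb_q)) cbind(parameter = "q", hb_q))
write.csv(brackets, "results/02_hopf_brackets.csv", row.names = FALSE)

write_manifest("results/02_manifest.yaml", "bifurcation_scans",
               config = list(a_min_grid = c(1.05, 3.35, 0.1),
                             q_grid = c(4, 0.1, -0.15)),
               outputs = c("results/02_scan_a_min.csv",
                           "results/02_scan_q.csv",
                           "results/02_hopf_brackets.csv"),
               started = started)
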