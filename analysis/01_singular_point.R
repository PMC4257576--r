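#!/usr/bin/env Rscript
# Locate and classify the coevolutionary singular point of the default
# parameter set, and tabulate the selection-gradient field around it.

suppressMessages(library(coevorange))
started <- Sys.time()
dir.create("results", showWarnings = FALSE)

p <- eco_params()
print(p)

sp <- classify_singular_point(find_singular_point(p), p)
print(sp)

res <- endemic_equilibrium(sp$traits, p)
cat(sprintf("equilibrium at the singular point: X* = %.4f, Y* = %.4f\n",
            res$X, res$Y))

point <- data.frame(u = sp$traits$u, v = sp$traits$v,
                    classification = sp$classification,
                    re1 = Re(sp$eigenvalues[1]), im1 = Im(sp$eigenvalues[1]),
                    curv_host = sp$curv_host,
                    curv_parasite = sp$curv_parasite,
                    X = res$X, Y = res$Y)
write.csv(point, "results/01_singular_point.csv", row.names = FALSE)

# gradient field on a trait grid (endemic region only)
g <- seq(0.02, 0.98, by = 0.04)
field <- do.call(rbind, lapply(g, function(u) do.call(rbind, lapply(g,
  function(v) {
    gr <- tryCatch(selection_gradients(trait_pair(u, v), p, "analytic"),
                   error = function(e) c(NA, NA))
    data.frame(u = u, v = v, g_host = gr[1], g_parasite = gr[2])
  }))))
write.csv(field, "results/01_gradient_field.csv", row.names = FALSE)
cat(sprintf("gradient field: %d grid points, %d endemic\n",
            nrow(field), sum(!is.na(field$g_host))))

write_manifest("results/01_manifest.yaml", "singular_point",
               config = unclass(p), seeds = list(),
               outputs = c("results/01_singular_point.csv",
                           "results/01_gradient_field.csv"),
               started = started)
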