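#!/usr/bin/env Rscript
# Nuclear co-localization of the two markers versus the planted level:
# mask-restricted Manders M1/M2 and PDM summaries per cell, across
# rho in {0, 0.25, 0.5, 0.75, 1}. Writes results/coloc_by_rho.csv.

suppressPackageStartupMessages(library(junctionquant))
dir.create("results", showWarnings = FALSE)

tabs <- list()
for (rho in c(0, 0.25, 0.5, 0.75, 1)) {
  sc <- generate_scene(scene_spec(n_cells = 20, seed = 3000 + 100 * rho,
                                  coloc_rho = rho,
                                  noise = list(poisson = TRUE,
                                               gaussian_sd = 4)))
  img <- subtract_background(sc$image)
  cp <- coloc_profile(img, truth_segmentation(sc$truth),
                      c("markerA", "markerB"), region = "nucleus")
  cp$planted_rho <- rho
  tabs[[as.character(rho)]] <- cp
  cat(sprintf(
    "rho = %.2f: nuclear M1 = %.3f, M2 = %.3f, mean PDM = %8.2f, +PDM frac = %.2f\n",
    rho, mean(cp$M1, na.rm = TRUE), mean(cp$M2, na.rm = TRUE),
    mean(cp$mean_pdm, na.rm = TRUE),
    mean(cp$positive_pdm_fraction, na.rm = TRUE)))
}
out <- do.call(rbind, tabs)
write.csv(out, "results/coloc_by_rho.csv", row.names = FALSE)
agg <- aggregate(M1 ~ planted_rho, out, mean)
stopifnot(all(diff(agg$M1) > 0))  # monotone recovery
cat("nuclear M1 rises monotonically with planted rho\n")
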