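#!/usr/bin/env Rscript
# Stage 4: AFM elasticity maps and the stress-stiffness relation.
#
# Per cell, a 16 x 16 force-volume (1 um pitch) is simulated with a true
# modulus coupled linearly to the cell's time-averaged traction stress
# (0.4 kPa + 0.025 kPa/Pa, spanning roughly 0.4-2.3 kPa).  Every curve is
# fitted with the Hertz cone model (30 degree half-angle, bending-corrected
# indentation, 20% fit-error quality control) and the per-cell mean modulus
# is paired with the traction stress.  Output: the paired table and its
# rank correlation.

library(neurotfm)

dir.create("results", showWarnings = FALSE)
co <- make_cohort(cohort_spec(n_cells = 10, growth_fraction = 0.6, seed = 21),
                  render = "none", afm = TRUE)

maps <- list()
sums <- list()
for (cl in co$cells) {
  maps[[cl$label]] <- build_elasticity_map(cl$force_volume)
  sums[[cl$label]] <- structure(
    list(mean_stress_pa = cl$mean_stress_pa, label = cl$label),
    class = "cell_traction_summary"
  )
}
labels <- sapply(co$cells, function(cl) {
  if (cl$growing) "growing" else "quiescent"
})
names(labels) <- sapply(co$cells, `[[`, "label")

tab <- pair_stress_modulus(sums, maps, growth_labels = labels)
tab$true_modulus_kPa <- sapply(co$cells, `[[`, "modulus_kpa")
write.csv(tab, "results/stress_vs_modulus.csv", row.names = FALSE)
print(tab, digits = 3)

rho <- cor(tab$mean_stress_Pa, tab$mean_modulus_kPa, method = "spearman")
err <- 100 * max(abs(tab$mean_modulus_kPa / tab$true_modulus_kPa - 1))
cat(sprintf("\nSpearman rho(stress, fitted modulus) = %.3f\n", rho))
cat(sprintf("Worst per-cell modulus recovery error: %.1f%%\n", err))
cat(sprintf("Growing cells average %.2f kPa vs %.2f kPa for quiescent.\n",
            mean(tab$mean_modulus_kPa[tab$growth_label == "growing"]),
            mean(tab$mean_modulus_kPa[tab$growth_label == "quiescent"])))
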