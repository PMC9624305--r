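#!/usr/bin/env Rscript
# Stage 2: measure the scene back from its images.
#
# Detect beads in both frames, link them, interpolate the sparse vectors to
# the analysis grid, invert by FTTC, and integrate over the cell mask; then
# score the reconstruction against the stored ground truth.  Requires the
# artifacts of 01_simulate_scene.R.

library(neurotfm)

run_pipeline(default_run_config(), stages = c("track", "invert", "metrics"),
             out_dir = "results/pipeline")

truth <- read_field("results/pipeline/truth_traction")
rec <- read_field("results/pipeline/traction")
digest <- jsonlite::read_json("results/pipeline/summary.json")

maskm <- as.matrix(read.table("results/pipeline/cell_mask.csv", sep = ",")) == 1
dimnames(maskm) <- NULL
mask <- cell_mask(maskm, truth$grid_spacing)
truth_sum <- integrate_force(truth, mask)

tab <- data.frame(
  quantity = c("mean_stress_Pa", "peak_stress_Pa", "force_nN", "area_um2"),
  truth = c(truth_sum$mean_stress_pa, truth_sum$peak_stress_pa,
            truth_sum$total_force_nn, truth_sum$contact_area_um2),
  recovered = c(digest$mean_stress_pa, digest$peak_stress_pa,
                digest$total_force_nn, digest$contact_area_um2)
)
tab$rel_err_pct <- 100 * (tab$recovered / tab$truth - 1)
write.csv(tab, "results/reconstruction_vs_truth.csv", row.names = FALSE)
print(tab, digits = 4)
cat(sprintf("\nMean stress recovered within %.1f%% of truth.\n",
            abs(tab$rel_err_pct[1])))
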