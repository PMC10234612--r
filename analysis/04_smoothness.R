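#!/usr/bin/env Rscript
# Spatial precision: is the global smoothness estimator calibrated, and
# how much effective blurring does each noise-reduction variant add to
# the GLM residuals?

library(llrfmri)

r <- eval_smoothness(seed = 4)
cat(sprintf("kernel recovery worst error: %.1f%% (kernels 1..3 voxels)\n",
            r$kernel_recovery_max_err_pct))
cat(sprintf("quadrature composition error: %.1f%%\n", r$composition_err_pct))
tab <- data.frame(
  variant = c("standard", "nordic", "+1 voxel", "+1.5 voxel"),
  residual_increase_pct = c(0, r$nordic_increase_pct,
                            r$smooth1_increase_pct,
                            r$smooth15_increase_pct))
print(tab, row.names = FALSE)

dir.create("results", showWarnings = FALSE)
write.table(tab, "results/smoothness.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
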