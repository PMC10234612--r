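#!/usr/bin/env Rscript
# Generate the reference phantom session and write it to disk, together
# with a quick summary of its ground truth. Everything downstream
# (02..07) regenerates its own phantoms from seeds, so this step exists to
# make the simulated data inspectable with standard NIfTI tools.

library(llrfmri)

spec <- phantom_spec()  # reference conditions, see the methods vignette
session <- simulate_session(spec)
out <- file.path("results", "phantom_session")
write_phantom_session(session, out)

labels <- session$truth$tissue_labels
cat("phantom session written to", out, "\n")
cat(sprintf("grid %s, %d runs x %d volumes, TR %.2f s\n",
            paste(spec$grid_dims, collapse = "x"), spec$n_runs,
            spec$n_volumes, spec$tr_s))
cat(sprintf("tissue voxels: CSF %d, GM %d, WM %d; vein voxels %d\n",
            sum(labels == 1), sum(labels == 2), sum(labels == 3),
            sum(session$truth$veins)))
cat(sprintf("Target ROI %d voxels, Non-Target ROI %d voxels\n",
            sum(session$truth$roi_target),
            sum(session$truth$roi_nontarget)))
cat(sprintf("thermal noise sd %.2f (GM baseline %.0f), g in [%.2f, %.2f]\n",
            spec$sigma_thermal, spec$baseline[["gm"]],
            min(session$truth$g_map), max(session$truth$g_map)))
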