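#!/usr/bin/env Rscript
# Exhaustive leave-p-out FIR cross-validation at the low-SNR regime: how
# many standard runs does one denoised run replace when predicting
# held-out standard data?

library(llrfmri)

r <- eval_crossval(seed = 1)
ss <- unlist(r[grep("^standard_r2_ntrain", names(r))])
ntr <- as.integer(sub(".*ntrain", "", names(ss)))
tab <- data.frame(n_train = ntr, standard_to_standard_r2 = as.numeric(ss))
tab <- tab[order(tab$n_train), ]
print(tab, row.names = FALSE)
cat(sprintf("one denoised run predicting standard data: R^2 = %.3f\n",
            r$nordic1_to_standard_r2))
cat(sprintf("equivalent standard runs: %s\n",
            format(r$equivalent_standard_runs)))

dir.create("results", showWarnings = FALSE)
write.table(tab, "results/crossval.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
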