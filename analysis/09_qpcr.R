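#!/usr/bin/env Rscript
# Relative expression across ripening stages by the 2^-ddCt method with
# Welch t-test significance flags, compared to the planted fold changes.

library(camtakit)

ct <- read.delim("results/demo_inputs/ct_table.tsv")
truth <- jsonlite::read_json("results/demo_inputs/truth.json",
                             simplifyVector = TRUE)$qpcr_true_fold

targets <- setdiff(unique(ct$gene_id), "EF1a")
folds <- do.call(rbind, lapply(targets, function(g)
  delta_delta_ct(ct, g, reference = "EF1a", calibrator_group = "M")))
write.table(folds, "results/qpcr_folds.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("2^-ddCt fold changes -> results/qpcr_folds.tsv\n")
for (i in seq_len(nrow(folds))) {
  true_fold <- truth[truth$gene == folds$gene_id[i], folds$group[i]]
  cat(sprintf(" %s %-3s fold %.2f +- %.2f  (true %.2f)  %s\n",
              folds$gene_id[i], folds$group[i], folds$fold_change[i],
              folds$se[i], true_fold, folds$flag[i]))
}
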