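#!/usr/bin/env Rscript
# Generate the synthetic study inputs (gene family, count matrix, Ct table)
# with known ground truth under a fixed seed. All later analysis steps read
# from results/demo_inputs/.

library(camtakit)

demo <- make_demo("results/demo_inputs")

cat("Synthetic inputs written to results/demo_inputs/\n")
cat(" genes:", length(demo$family$models),
    "on", length(demo$family$scaffolds), "scaffolds;",
    sum(demo$family$truth$strands == "-"), "on the minus strand\n")
cat(" paralog pairs planted:", nrow(demo$family$truth$pairs),
    "(realized Ks", paste(round(demo$family$truth$pairs$realized_ks, 3),
                          collapse = ", "), ")\n")
cat(" promoter motifs planted:", nrow(demo$family$truth$motifs),
    "occurrences across", length(unique(demo$family$truth$motifs$gene)),
    "genes\n")
cat(" count matrix:", nrow(demo$counts$counts), "genes x",
    ncol(demo$counts$counts), "samples;",
    nrow(demo$counts$truth$edges), "planted co-expression edges\n")
cat(" qPCR: true folds per stage:\n")
print(demo$qpcr$truth)
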