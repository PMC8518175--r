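#!/usr/bin/env Rscript
# TMM-normalized Pearson co-expression around the hub genes at the signed
# |r| >= 0.95 thresholds, plus cumulative-expression comparison of the
# positive partner set between the two stages.

library(camtakit)

raw <- read.delim("results/demo_inputs/counts.tsv", check.names = FALSE)
counts <- as.matrix(raw[, -1])
rownames(counts) <- raw[[1]]
truth <- jsonlite::read_json("results/demo_inputs/truth.json",
                             simplifyVector = TRUE)

norm <- normalize_counts(counts)
cat("TMM factors:",
    paste(names(attr(norm, "tmm_factors")),
          round(attr(norm, "tmm_factors"), 3), collapse = ", "), "\n")

hubs <- unique(truth$edges$hub)
partners <- correlation_partners(norm, hubs, r_pos = 0.95, r_neg = -0.95)
edges <- coexpression_edges(partners)
write.table(edges, "results/coexpression_edges.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

key_t <- paste(truth$edges$hub, truth$edges$partner)
key_f <- paste(edges$hub, edges$partner)
cat("Partner edges found:", nrow(edges), "->",
    "results/coexpression_edges.tsv\n")
cat(sprintf(" recall of planted partners: %.1f%%; false partners: %d\n",
            100 * mean(key_t %in% key_f), sum(!key_f %in% key_t)))

groups <- truth$groups
pos_set <- partners[[hubs[1]]]$positive_partners$gene
if (length(pos_set) >= 5) {
  cmp <- cumulative_expression_compare(norm, pos_set, groups,
                                       "mature", "ripe")
  cat(sprintf(" %s positive partners: cumulative expression %s (%s, p = %.2g)\n",
              hubs[1], cmp$direction, cmp$test, cmp$p))
}
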