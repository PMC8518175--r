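#!/usr/bin/env Rscript
# Degenerate motif scanning of the extracted promoters against the bundled
# cis-element library, recovery of the planted CAMTA recognition motifs,
# and Fisher exact enrichment between the two planted gene sets.

library(camtakit)

proms_df <- read_dna_fasta("results/promoters.fa")
promoters <- setNames(proms_df$sequence, proms_df$id)
library_tab <- read_motif_library()
counts <- count_motif_library(promoters, library_tab)
write.table(counts, "results/promoter_motif_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Motif counts (", nrow(library_tab), "motifs x", length(promoters),
    "promoters ) -> results/promoter_motif_counts.tsv\n")

truth <- jsonlite::read_json("results/demo_inputs/truth.json",
                             simplifyVector = TRUE)$motifs
camta <- counts[counts$pattern == "MCGTGT", ]
planted_n <- table(factor(truth$gene[truth$motif == "MCGTGT"],
                          levels = camta$gene))
cat("MCGTGT counts equal the planted truth in",
    sum(camta$n_total == as.integer(planted_n)), "of", nrow(camta),
    "promoters\n")

genes <- sort(names(promoters))
set_a <- genes[1:5]
set_b <- genes[6:10]
enr <- lapply(c("CAMTA-CGCG", "CAMTA-CGTG"), function(m) {
  pat <- library_tab$pattern[library_tab$name == m]
  ha <- sum(counts$n_total[counts$motif == m & counts$gene %in% set_a])
  hb <- sum(counts$n_total[counts$motif == m & counts$gene %in% set_b])
  fe <- fisher_enrichment(ha, scanned_positions(promoters[set_a], nchar(pat)),
                          hb, scanned_positions(promoters[set_b], nchar(pat)))
  data.frame(motif = m, hits_a = ha, hits_b = hb,
             odds_ratio = fe$odds_ratio, p = fe$p_two_sided)
})
enr <- do.call(rbind, enr)
write.table(enr, "results/promoter_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("CAMTA-motif enrichment between gene sets ->",
    "results/promoter_enrichment.tsv\n")
print(enr)
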