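small_config <- function(seed = 101, ...) {
  synth_config(seed = seed, n_genes = 4, exon_range = c(3, 4),
               cds_codon_range = c(120, 140), promoter_len = 200,
               paralog_specs = data.frame(target_ka = 0.05, target_ks = 0.2),
               ...)
}

test_that("config validation enforces the generator invariants", {
  expect_error(synth_config(), "seed is required")
  expect_error(synth_config(1, exon_range = c(0, 2)), ">= 1")
  expect_error(synth_config(1, promoter_len = 0), "promoter_len")
  expect_error(synth_config(1, n_genes = 4), "require 10 genes")
  expect_error(synth_config(1, motif_plant_specs = list(
    list(genes = 1, motif = "MCGXGB", n = 1))), "invalid IUPAC")
})

test_that("generated families are structurally valid and deterministic", {
  cfg <- small_config()
  fam1 <- make_gene_family(cfg)
  fam2 <- make_gene_family(cfg)
  expect_identical(fam1, fam2)  # byte-identical on the same (config, seed)
  expect_false(identical(fam1$scaffolds,
                         make_gene_family(small_config(seed = 102))$scaffolds))
  for (g in names(fam1$cds)) {
    cds <- fam1$cds[[g]]
    expect_identical(nchar(cds) %% 3L, 0L)
    expect_identical(substr(cds, 1, 3), "ATG")
    expect_true(substr(cds, nchar(cds) - 2, nchar(cds)) %in%
                  c("TAA", "TAG", "TGA"))
    # translation matches the emitted protein under an independent oracle
    expect_identical(oracle_translate(cds), fam1$proteins[[g]])
  }
  # GFF3 coordinates are consistent with scaffold lengths
  for (m in fam1$models) {
    expect_lte(max(m$exons$end), nchar(fam1$scaffolds[[m$scaffold_id]]))
    expect_gte(min(m$exons$start), 1L)
  }
})

test_that("exon counts and spliced CDS agree with the gene models", {
  cfg <- synth_config(seed = 103, n_genes = 3, exon_range = c(13, 13),
                      cds_codon_range = c(150, 160), promoter_len = 150,
                      paralog_specs = data.frame(target_ka = numeric(0),
                                                 target_ks = numeric(0)))
  fam <- make_gene_family(cfg)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(fam$models, path, scaffold_lengths = nchar(fam$scaffolds))
  expect_identical(sum(grepl("\texon\t", readLines(path))), 3L * 13L)
  # splicing the scaffold recovers each CDS on both strands
  for (m in fam$models) {
    scf <- fam$scaffolds[[m$scaffold_id]]
    pieces <- vapply(seq_len(nrow(m$exons)), function(i)
      substr(scf, m$exons$start[i], m$exons$end[i]), character(1))
    spliced <- paste(pieces, collapse = "")
    if (m$strand == "-") {
      spliced <- chartr("ACGT", "TGCA",
                        paste(rev(strsplit(spliced, "")[[1]]), collapse = ""))
    }
    expect_identical(spliced, unname(fam$cds[[m$gene_id]]))
  }
})

test_that("oversized genes are rejected against a fixed scaffold length", {
  cfg <- small_config(scaffold_len = 500)
  expect_error(make_gene_family(cfg), "exceeds the configured scaffold length")
})

test_that("paralog mutation honors its targets and classifications", {
  set.seed(104)
  cds <- camtakit:::random_cds(300)
  same <- mutate_paralog(cds, 0, 0, seed = 1)
  expect_identical(same$cds, cds)
  syn_only <- mutate_paralog(cds, 0, 0.15, seed = 2)
  expect_identical(translate_cds(syn_only$cds), translate_cds(cds))
  expect_identical(syn_only$nonsyn_events, 0L)
  expect_equal(syn_only$realized_ks, syn_only$syn_events / syn_only$syn_sites)
  both <- mutate_paralog(cds, 0.08, 0.2, seed = 3)
  expect_identical(nchar(both$cds), nchar(cds))
  expect_equal(both$realized_ka, both$nonsyn_events / both$nonsyn_sites)
  expect_error(mutate_paralog(cds, 0, 0.9, seed = 4), "synonymous")
  expect_error(mutate_paralog("ATGAAA", 0, 0.1, seed = 5), "stop codon")
})

test_that("motif planting produces exactly the planted landscape", {
  set.seed(105)
  proms <- c(g1 = random_promoter(400), g2 = random_promoter(400))
  res <- plant_promoter_motifs(
    proms,
    list(list(genes = "g1", motif = "MCGCGB", n = 3, strand = "+"),
         list(genes = "g2", motif = "MCGCGB", n = 0, strand = "+")),
    seed = 106)
  expect_identical(oracle_motif_count(res$promoters[["g1"]], "MCGCGB"), 3L)
  expect_identical(oracle_motif_count(res$promoters[["g2"]], "MCGCGB"), 0L)
  expect_identical(nrow(res$truth[res$truth$gene == "g1", ]), 3L)
  expect_error(plant_promoter_motifs(proms, list(
    list(genes = "g1", motif = "MCGXGB", n = 1)), seed = 1),
    "invalid IUPAC")
})

test_that("count simulation plants calibrated correlations and offsets", {
  expect_error(simulate_counts(list(n_samples = 2), seed = 1), ">= 3")
  expect_error(simulate_counts(list(target_r = 1.2), seed = 1), "target_r")
  # near-noiseless partners: r essentially 1 at 50 samples per group
  sim <- simulate_counts(list(n_samples = 25, target_r = 0.9999,
                              n_noise = 10, n_partners_pos = 5,
                              n_partners_neg = 5, n_hubs = 1), seed = 107)
  x <- log2(sim$counts + 1)
  r <- vapply(grep("pos", rownames(x), value = TRUE), function(p)
    cor(x["hub01", ], x[p, ]), numeric(1))
  expect_true(all(r > 0.99))
  # planted r = 0.97: mean recovered r within 0.03 over 20 seeds
  mean_r <- mean(vapply(1:20, function(s) {
    sim <- simulate_counts(list(n_samples = 15, n_noise = 50), seed = s)
    x <- log2(normalize_counts(sim$counts) + 1)
    mean(abs(vapply(seq_len(nrow(sim$truth$edges)), function(i)
      cor(x[sim$truth$edges$hub[i], ], x[sim$truth$edges$partner[i], ]),
      numeric(1))))
  }, numeric(1)))
  expect_lt(abs(mean_r - 0.97), 0.03)
  # library factors propagate to the truth bundle
  sim <- simulate_counts(list(n_samples = 3,
                              library_size_factors = c(1, 2, 1, 1, 1, 1)),
                         seed = 108)
  expect_equal(unname(sim$truth$library_size_factors[2]), 2)
})

test_that("qPCR simulation validates its spec and centers the calibrator", {
  expect_error(simulate_qpcr(list(reference = ""), seed = 1), "reference")
  expect_error(simulate_qpcr(list(ct_sd = -1), seed = 1), "ct_sd")
  sim <- simulate_qpcr(list(ct_sd = 0), seed = 109)
  expect_true(all(c("sample_group", "biological_rep", "technical_rep",
                    "gene_id", "ct") %in% names(sim$ct_table)))
  expect_true("EF1a" %in% sim$ct_table$gene_id)
  # fold 1 everywhere: every estimated fold is 1
  flat <- simulate_qpcr(list(ct_sd = 0, true_fold = rbind(g = c(1, 1, 1))),
                        seed = 110)
  res <- delta_delta_ct(flat$ct_table, "g", "EF1a", "M")
  expect_equal(res$fold_change, rep(1, 3))
})
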