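test_that("global alignment matches an exhaustive-enumeration oracle", {
  aln <- global_align("MKVLW", "MKVLW")
  expect_equal(aln$identity_pct, 100)
  expect_equal(aln$coverage_pct, 100)
  set.seed(41)
  for (i in 1:4) {
    a <- random_peptide(sample(4:6, 1))
    b <- random_peptide(sample(4:6, 1))
    expect_equal(global_align(a, b)$score, oracle_align_score(a, b))
  }
  # symmetry
  a <- random_peptide(12)
  b <- random_peptide(9)
  ab <- global_align(a, b)
  ba <- global_align(b, a)
  expect_equal(ab$score, ba$score)
  expect_equal(ab$identity_pct, ba$identity_pct)
  expect_equal(ab$coverage_pct, ba$coverage_pct)
  expect_error(global_align("", "MK"), "non-empty")
})

test_that("reciprocal best hits honor thresholds and input order", {
  set.seed(42)
  twin <- random_peptide(120)
  other <- random_peptide(120)
  prots <- data.frame(id = c("a1", "a2", "b1"),
                      sequence = c(twin, twin, other))
  pairs <- reciprocal_best_pairs(prots)
  expect_identical(nrow(pairs), 1L)
  expect_identical(c(pairs$gene_a, pairs$gene_b), c("a1", "a2"))

  unrelated <- data.frame(id = c("x", "y", "z"),
                          sequence = replicate(3, random_peptide(100)))
  expect_identical(nrow(reciprocal_best_pairs(unrelated)), 0L)

  # shuffling the input changes nothing
  shuffled <- prots[c(3, 1, 2), ]
  expect_identical(reciprocal_best_pairs(shuffled), pairs)
})

test_that("a planted family of mutated pairs yields disjoint RBH pairs", {
  cfg <- synth_config(seed = 77, n_genes = 10, exon_range = c(2, 3),
                      cds_codon_range = c(200, 240), promoter_len = 100)
  fam <- make_gene_family(cfg)
  prots <- data.frame(id = names(fam$proteins),
                      sequence = unname(fam$proteins))
  pairs <- reciprocal_best_pairs(prots)
  expect_identical(nrow(pairs), 5L)
  expect_identical(sort(c(pairs$gene_a, pairs$gene_b)), sort(prots$id))
  expect_identical(paste(pairs$gene_a, pairs$gene_b),
                   paste(fam$truth$pairs$gene_a, fam$truth$pairs$gene_b))
})

test_that("codon back-threading mirrors the protein alignment", {
  cds_a <- "ATGAAATTTTGA"        # M K F
  cds_b <- "ATGAAATGA"           # M K
  aln_a <- "MKF"
  aln_b <- "MK-"
  cal <- codon_align(aln_a, aln_b, cds_a, cds_b)
  expect_identical(cal$codon_a, "ATGAAATTT")
  expect_identical(cal$codon_b, "ATGAAA---")
  # gap-free: concatenated codons unchanged
  cal2 <- codon_align("MKF", "MKF", cds_a, cds_a)
  expect_identical(cal2$codon_a, "ATGAAATTT")
  # round-trip: removing gaps recovers the CDS (minus stop)
  expect_identical(gsub("-", "", cal$codon_b), "ATGAAA")
  expect_error(codon_align("MKY", "MK-", cds_a, cds_b),
               "mismatch for sequence a at protein position 3")
})

test_that("NG86 equals the exhaustive-pathway oracle", {
  # identical pair
  kk <- ng86_kaks("ATGAAATTT", "ATGAAATTT")
  expect_equal(kk$ka, 0)
  expect_equal(kk$ks, 0)
  # single third-position Phe/Leu change: TTT -> TTA is nonsynonymous
  kk <- ng86_kaks("TTT", "TTA")
  orc <- oracle_ng86("TTT", "TTA")
  expect_equal(kk$ks, orc$ks)
  expect_equal(kk$ka, orc$ka)
  expect_equal(kk$syn_sites, orc$S)
  # all sense-codon pairs at one codon, sampled 2-3 codon instances
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   c("TAA", "TAG", "TGA"))
  set.seed(43)
  pool <- expand.grid(a = sense, b = sense, stringsAsFactors = FALSE)
  pool <- pool[sample(nrow(pool), 150), ]
  for (i in seq_len(nrow(pool))) {
    a <- pool$a[i]
    b <- pool$b[i]
    res <- try(ng86_kaks(a, b), silent = TRUE)
    orc <- try(suppressWarnings(oracle_ng86(a, b)), silent = TRUE)
    if (inherits(res, "try-error")) {
      expect_true(inherits(orc, "try-error") || orc$S == 0 ||
                    orc$Sd / orc$S >= 0.75 || orc$Nd / orc$N >= 0.75)
    } else {
      expect_equal(res$ks, orc$ks, tolerance = 1e-12)
      expect_equal(res$ka, orc$ka, tolerance = 1e-12)
    }
  }
  for (i in 1:30) {
    n_codons <- sample(2:3, 1)
    a <- paste(sample(sense, n_codons, replace = TRUE), collapse = "")
    b <- paste(sample(sense, n_codons, replace = TRUE), collapse = "")
    res <- try(ng86_kaks(a, b), silent = TRUE)
    if (!inherits(res, "try-error")) {
      orc <- oracle_ng86(a, b)
      expect_equal(res$ks, orc$ks, tolerance = 1e-12)
      expect_equal(res$ka, orc$ka, tolerance = 1e-12)
    }
  }
})

test_that("NG86 flags degenerate inputs and drops gap columns pairwise", {
  expect_error(ng86_kaks("ATGTGG", "ATGTGG"), "zero synonymous sites")
  # a lone synonymous difference over a tiny synonymous-site count saturates
  expect_error(ng86_kaks("ATGAAA", "ATGAAG"), "saturation")
  # gapped column dropped: equivalent to the ungapped remainder
  kk_gap <- ng86_kaks("AAACTTGGGCCC---", "AAACTAGGGCCCTTT")
  kk_ref <- ng86_kaks("AAACTTGGGCCC", "AAACTAGGGCCC")
  expect_equal(kk_gap$ks, kk_ref$ks)
  expect_equal(kk_gap$ka, kk_ref$ka)
  expect_identical(kk_gap$codons_used, 4L)
})

test_that("synonymous-only divergence gives Ka = 0 and Ks > 0", {
  set.seed(44)
  cds <- camtakit:::random_cds(200)
  mut <- mutate_paralog(cds, target_ka = 0, target_ks = 0.1, seed = 45)
  expect_identical(translate_cds(mut$cds), translate_cds(cds))
  aln <- global_align(translate_cds(cds), translate_cds(mut$cds))
  cal <- codon_align(aln$aligned_a, aln$aligned_b, cds, mut$cds)
  kk <- ng86_kaks(cal$codon_a, cal$codon_b)
  expect_equal(kk$ka, 0)
  expect_gt(kk$ks, 0)
})

test_that("NG86 recovers the realized Ks of mutated pairs within 15%", {
  seeds <- 1:20
  ks_targets <- seq(0.05, 0.5, length.out = 20)
  rel_err <- mapply(function(s, kst) {
    cds <- camtakit:::with_seed(s, camtakit:::random_cds(1000))
    mut <- mutate_paralog(cds, target_ka = 0.3 * kst, target_ks = kst,
                          seed = s + 1000)
    aln <- global_align(translate_cds(cds), translate_cds(mut$cds))
    cal <- codon_align(aln$aligned_a, aln$aligned_b, cds, mut$cds)
    kk <- ng86_kaks(cal$codon_a, cal$codon_b)
    (kk$ks - mut$realized_ks) / mut$realized_ks
  }, seeds, ks_targets)
  expect_lt(max(abs(rel_err)), 0.15)
})

test_that("divergence time is linear in Ks and inverse in lambda", {
  expect_equal(divergence_time(0), 0)
  expect_equal(divergence_time(0.1830), 15)
  expect_equal(divergence_time(0.2), 2 * divergence_time(0.1))
  expect_equal(divergence_time(0.2, lam = 1.22e-8),
               divergence_time(0.2) / 2)
  expect_error(divergence_time(-0.1), "nonnegative")
})

test_that("selection classes follow the Ka/Ks rule", {
  expect_identical(classify_selection(0.3), "purifying")
  expect_identical(classify_selection(1), "neutral")
  expect_identical(classify_selection(1 + 1e-12), "neutral")
  expect_identical(classify_selection(2.5), "positive")
  expect_identical(classify_selection(c(0.1, 1, 3)),
                   c("purifying", "neutral", "positive"))
})
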