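test_that("IUPAC expansion enumerates the allowed words", {
  expect_identical(expand_iupac("MCGTGT"), c("ACGTGT", "CCGTGT"))
  expect_identical(length(expand_iupac("MCGCGB")), 6L)
  expect_identical(length(expand_iupac("NNN")), 64L)
  expect_error(expand_iupac("MCGXGT"), "invalid IUPAC")
})

test_that("scanning counts overlapping hits on both strands at forward coords", {
  expect_identical(nrow(scan_motif(strrep("A", 500), "MCGCGB")), 0L)
  # planted forward occurrences are recovered at their positions
  set.seed(61)
  planted <- plant_promoter_motifs(
    c(g1 = random_promoter(400)),
    list(list(genes = "g1", motif = "MCGTGT", n = 3, strand = "+")),
    seed = 62)
  hits <- scan_motif(planted$promoters[["g1"]], "MCGTGT")
  expect_identical(sum(hits$strand == "+"), 3L)
  expect_identical(sum(hits$strand == "-"), 0L)
  expect_setequal(hits$start[hits$strand == "+"], planted$truth$start)
  # a palindromic word is seen once per strand at the same locus
  pal <- paste0(strrep("A", 20), "ACGCGT", strrep("A", 20))
  hits <- scan_motif(pal, "ACGCGT")
  expect_identical(hits$strand[order(hits$strand)], c("+", "-"))
  expect_identical(unique(hits$start), 21L)
  # forward-only scanning ignores the reverse strand
  rev_planted <- plant_promoter_motifs(
    c(g1 = random_promoter(400)),
    list(list(genes = "g1", motif = "MCGCGB", n = 2, strand = "-")),
    seed = 63)
  fw <- scan_motif(rev_planted$promoters[["g1"]], "MCGCGB",
                   strands = "forward")
  expect_identical(nrow(fw), 0L)
  both <- scan_motif(rev_planted$promoters[["g1"]], "MCGCGB")
  expect_identical(sum(both$strand == "-"), 2L)
  # N never matches
  expect_identical(nrow(scan_motif("ANGTGTA", "NNGTGT")), 0L)
})

test_that("scan counts are strand-symmetric and grow by one per extra plant", {
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  set.seed(64)
  for (i in 1:5) {
    x <- random_promoter(300)
    expect_identical(nrow(scan_motif(x, "MCGTGT")),
                     nrow(scan_motif(revcomp(x), "MCGTGT")))
  }
  planted <- plant_promoter_motifs(
    c(g = random_promoter(500)),
    list(list(genes = "g", motif = "MCGCGB", n = 4, strand = "+")),
    seed = 65)
  n4 <- nrow(scan_motif(planted$promoters[["g"]], "MCGCGB"))
  expect_identical(n4, 4L)
})

test_that("expected hit counts on random sequence match the combinatorics", {
  # E[hits] per strand = (L - k + 1) * degeneracy / 4^k
  set.seed(66)
  L <- 200
  k <- 6
  n_prom <- 1000
  deg <- length(expand_iupac("MCGTGT"))
  counts <- vapply(seq_len(n_prom), function(i) {
    nrow(scan_motif(random_promoter(L), "MCGTGT"))
  }, numeric(1))
  expected <- 2 * (L - k + 1) * deg / 4^k
  se <- sd(counts) / sqrt(n_prom)
  expect_lt(abs(mean(counts) - expected), 3 * se + 1e-9)
})

test_that("library counting tabulates every gene x motif cell", {
  set.seed(67)
  proms <- c(g1 = random_promoter(150), g2 = random_promoter(150),
             g3 = random_promoter(150))
  lib <- data.frame(name = c("m1", "m2"), pattern = c("MCGTGT", "TATAWAW"))
  tab <- count_motif_library(proms, lib)
  expect_identical(nrow(tab), 6L)
  expect_true(all(tab$n_total == tab$n_fwd + tab$n_rev))
  expect_identical(nrow(count_motif_library(proms, lib[0, ])), 0L)
  expect_error(count_motif_library(proms, data.frame(
    name = c("m", "m"), pattern = c("ACGT", "TTTT"))), "duplicate")
  # regex-oracle recount over random promoters
  proms50 <- setNames(vapply(1:50, function(i) random_promoter(120),
                             character(1)), paste0("p", 1:50))
  tab50 <- count_motif_library(proms50, data.frame(name = "camta",
                                                   pattern = "MCGCGB"))
  oracle <- vapply(proms50, oracle_motif_count, numeric(1),
                   pattern = "MCGCGB")
  expect_identical(tab50$n_total, as.integer(unname(oracle)))
})

test_that("Fisher enrichment equals brute-force hypergeometric summation", {
  same <- fisher_enrichment(5, 100, 5, 100)
  expect_equal(same$p_two_sided, 1)
  fe <- fisher_enrichment(10, 1000, 2, 1000)
  expect_equal(fe$p_two_sided, oracle_fisher_p(fe$table), tolerance = 1e-9)
  set.seed(68)
  for (i in 1:10) {
    ha <- rpois(1, 6)
    hb <- rpois(1, 3)
    fe <- fisher_enrichment(ha, 400, hb, 600)
    expect_equal(fe$p_two_sided, oracle_fisher_p(fe$table), tolerance = 1e-9)
    # symmetry in set order
    expect_equal(fisher_enrichment(hb, 600, ha, 400)$p_two_sided,
                 fe$p_two_sided, tolerance = 1e-12)
  }
  zero <- fisher_enrichment(0, 100, 0, 100)
  expect_equal(zero$p_two_sided, 1)
  expect_equal(zero$odds_ratio, 1)
  expect_error(fisher_enrichment(-1, 10, 0, 10), "negative")
  expect_error(fisher_enrichment(11, 10, 0, 10), "exceed")
})

test_that("enrichment p falls as the frequency contrast grows", {
  p <- vapply(c(4, 8, 16, 32), function(h)
    fisher_enrichment(h, 1000, 4, 1000)$p_two_sided, numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("scanned position totals follow the sliding-window count", {
  proms <- c(a = strrep("A", 100), b = strrep("C", 50))
  expect_identical(scanned_positions(proms, 6), as.integer(2 * (95 + 45)))
  expect_identical(scanned_positions(proms, 6, "forward"),
                   as.integer(95 + 45))
})
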