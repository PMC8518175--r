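test_that("TMM factors are 1 for identical and depth-only differences", {
  set.seed(71)
  col <- rpois(500, 100)
  identical_samples <- cbind(s1 = col, s2 = col, s3 = col)
  expect_equal(unname(tmm_factors(identical_samples)), rep(1, 3),
               tolerance = 1e-8)
  # doubling the depth changes no M-value: factors stay 1, CPM values equal
  depth <- cbind(s1 = col, s2 = 2L * col, s3 = col)
  f <- tmm_factors(depth)
  expect_equal(unname(f), rep(1, 3), tolerance = 1e-8)
  norm <- normalize_counts(depth, f)
  expect_equal(norm[, "s1"], norm[, "s2"], tolerance = 1e-12,
               ignore_attr = TRUE)
  # factors are invariant to a global scalar on all counts
  expect_equal(unname(tmm_factors(3L * depth)), unname(f), tolerance = 1e-8)
  expect_error(tmm_factors(cbind(s1 = col, s0 = 0L * col)), "all-zero")
})

test_that("TMM recovers a planted composition offset within 5%", {
  # analytic factor: the shifted genes (library share s before the shift)
  # inflate the library by 1 + s*(fold-1); the shifted 10% are trimmed
  # out, so unshifted genes carry M = -log2(1 + s*(fold-1)) and the raw
  # factor is its inverse. Recovery is measured as the mean error over
  # seeds, since single draws carry the trim-window sampling noise.
  errs <- vapply(1:8, function(s) {
    sim <- simulate_counts(list(n_samples = 3, n_noise = 2000, n_hubs = 1,
                                n_partners_pos = 5, n_partners_neg = 5,
                                composition = list(sample = 2, frac = 0.10,
                                                   fold = 4)),
                           seed = 70 + s)
    f <- tmm_factors(sim$counts)
    share <- sum(sim$counts[sim$truth$composition_genes, 1]) /
      sum(sim$counts[, 1])
    expected <- c(1, 1 / (1 + share * (4 - 1)), 1, 1, 1, 1)
    expected <- expected / exp(mean(log(expected)))
    max(abs(f - expected) / expected)
  }, numeric(1))
  expect_lt(mean(errs), 0.05)
})

test_that("CPM normalization follows count / (libsize * factor) * 1e6", {
  counts <- matrix(c(10, 90, 20, 180), ncol = 2,
                   dimnames = list(c("g1", "g2"), c("a", "b")))
  norm <- normalize_counts(counts, factors = c(a = 1, b = 1))
  expect_equal(norm["g1", "a"], 10 / 100 * 1e6)
  expect_equal(norm["g1", "b"], 20 / 200 * 1e6)
  expect_equal(unname(colSums(norm)), c(1e6, 1e6))
  # doubling one library halves its values at unit factors
  expect_equal(norm[, "b"], norm[, "a"], ignore_attr = TRUE)
})

test_that("correlation partners split by signed thresholds", {
  set.seed(73)
  hub <- 2^rnorm(8, 8, 1)
  m <- rbind(hub = hub,
             mult = 3 * hub,                      # r = +1
             anti = max(hub) + min(hub) - hub,    # r = -1 on raw scale
             flat = rep(5, 8),
             noise = 2^rnorm(8, 8, 1))
  colnames(m) <- paste0("s", 1:8)
  expect_warning(
    res <- correlation_partners(m, "hub", log2_transform = FALSE),
    "zero-variance")
  expect_true("mult" %in% res$hub$positive_partners$gene)
  expect_true("anti" %in% res$hub$negative_partners$gene)
  expect_false("flat" %in% c(res$hub$positive_partners$gene,
                             res$hub$negative_partners$gene))
  expect_error(correlation_partners(rbind(m, zero = 0), "zero"),
               "zero variance")
  expect_error(correlation_partners(m[, 1:3], "hub"), "at least 4")
})

test_that("partner sets shrink as thresholds tighten and r is affine-invariant", {
  sim <- simulate_counts(list(n_samples = 10, n_noise = 50), seed = 74)
  norm <- normalize_counts(sim$counts)
  loose <- correlation_partners(norm, "hub01", r_pos = 0.90, r_neg = -0.90)
  tight <- correlation_partners(norm, "hub01", r_pos = 0.98, r_neg = -0.98)
  expect_true(all(tight$hub01$positive_partners$gene %in%
                    loose$hub01$positive_partners$gene))
  expect_true(all(tight$hub01$negative_partners$gene %in%
                    loose$hub01$negative_partners$gene))
  # positive affine rescaling of one partner row leaves r unchanged
  x <- log2(norm + 1)
  g <- loose$hub01$positive_partners$gene[1]
  r1 <- cor(x["hub01", ], x[g, ])
  r2 <- cor(x["hub01", ], 3 * x[g, ] + 7)
  expect_equal(r1, r2)
})

test_that("planted partners are recovered at the study thresholds", {
  stats <- vapply(1:20, function(s) {
    sim <- simulate_counts(list(n_samples = 15, n_noise = 500), seed = s)
    norm <- normalize_counts(sim$counts)
    res <- correlation_partners(norm, c("hub01", "hub02"))
    found <- coexpression_edges(res)
    truth <- sim$truth$edges
    key_t <- paste(truth$hub, truth$partner)
    key_f <- paste(found$hub, found$partner)
    sign_ok <- all(found$sign[match(key_t, key_f, nomatch = 0)] ==
                     ifelse(truth$sign[key_t %in% key_f] > 0, "+", "-"))
    c(recall = mean(key_t %in% key_f),
      false = sum(!key_f %in% key_t),
      sign_ok = as.numeric(sign_ok))
  }, numeric(3))
  expect_gte(mean(stats["recall", ]), 0.90)
  expect_lte(mean(stats["false", ]), 2)
  expect_true(all(stats["sign_ok", ] == 1))
})

test_that("cumulative expression comparison matches the permutation oracle", {
  set.seed(75)
  m <- matrix(2^rnorm(8 * 6, 8, 1), nrow = 8,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:6)))
  groups <- rep(c("mature", "ripe"), each = 3)
  # clean shift: every gene higher in ripe
  shifted <- m
  shifted[, 4:6] <- m[, 1:3] + 50
  res <- cumulative_expression_compare(shifted, rownames(m), groups,
                                       "mature", "ripe")
  expect_identical(res$direction, "b>a")
  expect_equal(res$p, 2 * (1 / 2^8))  # minimal two-sided signed-rank p at n=8
  # identical groups
  same <- m
  same[, 4:6] <- m[, 1:3]
  res <- cumulative_expression_compare(same, rownames(m), groups,
                                       "mature", "ripe")
  expect_identical(res$direction, "none")
  expect_equal(res$p, 1)
  # exact oracle on generic paired means
  res <- cumulative_expression_compare(m, rownames(m), groups,
                                       "mature", "ripe")
  diffs <- res$means$mean_b - res$means$mean_a
  expect_equal(res$p, oracle_signed_rank_p(diffs), tolerance = 1e-9)
  expect_warning(cumulative_expression_compare(m, rownames(m)[1:3], groups,
                                               "mature", "ripe"),
                 "smaller than 5")
})
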