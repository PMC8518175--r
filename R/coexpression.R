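# TMM normalization of raw count matrices (via edgeR), signed Pearson
# co-expression partner extraction around hub genes at the |r| >= 0.95
# thresholds, and cumulative-expression comparison between sample groups.

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values between-sample normalization factors (computed
#' with \pkg{edgeR}): per sample, a doubly-trimmed weighted mean of gene-wise
#' log-ratios against a reference sample, rescaled so the factors multiply
#' to 1 (geometric mean 1).
#'
#' @param counts Nonnegative integer matrix, genes x samples.
#' @param logratio_trim Fraction of extreme M-values trimmed (default 0.3).
#' @param abs_trim Fraction of extreme A-values (absolute expression)
#'   trimmed (default 0.05).
#' @return Named numeric vector of factors (one per sample, product 1).
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, abs_trim = 0.05) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  zero_samples <- colSums(counts) == 0
  if (any(zero_samples)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[zero_samples], collapse = ", "))
  }
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = logratio_trim,
                              sumTrim = abs_trim)
  stats::setNames(f / exp(mean(log(f))), colnames(counts))
}

#' Counts per million with TMM-scaled library sizes
#'
#' `value = count / (library_size * factor) * 1e6`.
#'
#' @param counts Genes x samples count matrix.
#' @param factors Normalization factors from [tmm_factors()] (default:
#'   computed).
#' @return Numeric matrix of normalized expression values; the factors are
#'   attached as attribute `tmm_factors`.
#' @export
normalize_counts <- function(counts, factors = NULL) {
  counts <- as.matrix(counts)
  factors <- factors %||% tmm_factors(counts)
  eff_lib <- colSums(counts) * factors
  out <- sweep(counts, 2L, eff_lib, `/`) * 1e6
  attr(out, "tmm_factors") <- factors
  out
}

#' Signed Pearson co-expression partners of hub genes
#'
#' For each hub, computes the Pearson correlation between the hub row and
#' every other gene across all samples (on `log2(x + 1)` by default) and
#' partitions partner genes by the signed thresholds: positively
#' interacting genes at `r >= r_pos`, negatively interacting genes at
#' `r <= r_neg`. Zero-variance genes are skipped with a warning; a
#' zero-variance hub is an error.
#'
#' @param norm Normalized expression matrix (genes x samples).
#' @param hub_ids Character vector of hub gene ids (rows of `norm`).
#' @param r_pos,r_neg Signed correlation thresholds (defaults 0.95 and
#'   -0.95).
#' @param min_samples Minimum number of samples required (default 4).
#' @param log2_transform Correlate on `log2(x + 1)` (default TRUE).
#' @return Named list (per hub) with data.frames `positive_partners` and
#'   `negative_partners` (columns `gene`, `r`), sorted by |r| descending.
#' @export
correlation_partners <- function(norm, hub_ids, r_pos = 0.95, r_neg = -0.95,
                                 min_samples = 4, log2_transform = TRUE) {
  norm <- as.matrix(norm)
  if (ncol(norm) < min_samples) {
    stop("need at least ", min_samples, " samples, got ", ncol(norm))
  }
  missing_hubs <- setdiff(hub_ids, rownames(norm))
  if (length(missing_hubs)) {
    stop("hub(s) not in matrix: ", paste(missing_hubs, collapse = ", "))
  }
  x <- if (log2_transform) log2(norm + 1) else norm
  vars <- apply(x, 1L, stats::var)
  if (any(vars[hub_ids] == 0)) {
    stop("hub with zero variance: ",
         paste(hub_ids[vars[hub_ids] == 0], collapse = ", "))
  }
  flat <- setdiff(rownames(x)[vars == 0], hub_ids)
  if (length(flat)) {
    warning(length(flat), " zero-variance gene(s) skipped")
  }
  usable <- setdiff(rownames(x), flat)
  out <- list()
  for (hub in hub_ids) {
    others <- setdiff(usable, hub)
    r <- as.vector(stats::cor(x[hub, ], t(x[others, , drop = FALSE])))
    names(r) <- others
    pos <- sort(r[r >= r_pos], decreasing = TRUE)
    neg <- sort(r[r <= r_neg])
    out[[hub]] <- list(
      hub_id = hub,
      positive_partners = data.frame(gene = names(pos), r = unname(pos),
                                     stringsAsFactors = FALSE),
      negative_partners = data.frame(gene = names(neg), r = unname(neg),
                                     stringsAsFactors = FALSE))
  }
  out
}

#' Edge list from co-expression results
#'
#' Flattens [correlation_partners()] output into a (hub, partner, r, sign)
#' table consumable by standard graph tools.
#'
#' @param partners Result of [correlation_partners()].
#' @return Data.frame with columns `hub`, `partner`, `r`, `sign`.
#' @export
coexpression_edges <- function(partners) {
  rows <- list()
  for (res in partners) {
    if (nrow(res$positive_partners)) {
      rows[[length(rows) + 1L]] <- data.frame(
        hub = res$hub_id, partner = res$positive_partners$gene,
        r = res$positive_partners$r, sign = "+", stringsAsFactors = FALSE)
    }
    if (nrow(res$negative_partners)) {
      rows[[length(rows) + 1L]] <- data.frame(
        hub = res$hub_id, partner = res$negative_partners$gene,
        r = res$negative_partners$r, sign = "-", stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows) %||%
    data.frame(hub = character(0), partner = character(0), r = numeric(0),
               sign = character(0), stringsAsFactors = FALSE)
}

#' Compare cumulative expression of a gene set between two groups
#'
#' Computes per-gene mean normalized expression within each group, then a
#' two-sided Wilcoxon signed-rank test across the gene set (genes paired
#' between groups). The direction reports which group is higher (by the
#' mean of the paired differences); for gene sets smaller than 5 a warning
#' is raised and the p-value is absent.
#'
#' @param norm Normalized expression matrix (genes x samples).
#' @param gene_set Character vector of gene ids.
#' @param groups Character vector of group labels, one per sample.
#' @param group_a,group_b The two group labels to compare.
#' @return List with `means` (data.frame gene, mean_a, mean_b),
#'   `direction` (`"a>b"`, `"b>a"` or `"none"`), `p` and `test`.
#' @export
cumulative_expression_compare <- function(norm, gene_set, groups,
                                          group_a, group_b) {
  norm <- as.matrix(norm)
  stopifnot(length(groups) == ncol(norm))
  if (!any(groups == group_a) || !any(groups == group_b)) {
    stop("both groups must be non-empty")
  }
  missing <- setdiff(gene_set, rownames(norm))
  if (length(missing)) {
    stop("gene(s) not in matrix: ", paste(missing, collapse = ", "))
  }
  mean_a <- rowMeans(norm[gene_set, groups == group_a, drop = FALSE])
  mean_b <- rowMeans(norm[gene_set, groups == group_b, drop = FALSE])
  diffs <- mean_b - mean_a
  direction <- if (all(diffs == 0)) "none" else
    if (mean(diffs) > 0) "b>a" else "a>b"
  p <- NA_real_
  if (length(gene_set) < 5L) {
    warning("gene set smaller than 5: p-value not computed")
  } else if (all(diffs == 0)) {
    p <- 1
  } else if (all(diffs > 0) || all(diffs < 0)) {
    # perfect separation: uniquely extreme under sign flips even with tied
    # magnitudes, so the exact two-sided p is 2/2^n
    p <- min(1, 2 / 2^length(diffs))
  } else {
    p <- stats::wilcox.test(mean_a, mean_b, paired = TRUE,
                            alternative = "two.sided", exact = NULL)$p.value
  }
  list(means = data.frame(gene = gene_set, mean_a = unname(mean_a),
                          mean_b = unname(mean_b), stringsAsFactors = FALSE),
       direction = direction, p = p, test = "Wilcoxon signed-rank")
}
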