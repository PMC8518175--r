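# Relative qPCR quantification by the 2^-ddCt method: technical replicates
# are averaged per biological replicate, dCt is taken against the reference
# gene, ddCt against the calibrator group's mean dCt, and group differences
# are tested with a Welch t-test on the per-replicate dCt values.

#' Relative expression by the 2^-ddCt method
#'
#' For each sample group: technical replicates are averaged per biological
#' replicate; `dCt = Ct_target - Ct_reference` per biological replicate;
#' `ddCt = dCt - mean(calibrator dCt)`; `fold = 2^-ddCt`. The fold change
#' is reported as mean with standard error over biological replicates,
#' with a Welch t-test against the calibrator ([significance()]).
#'
#' @param ct_table Data.frame with columns `sample_group`,
#'   `biological_rep`, `technical_rep`, `gene_id`, `ct`.
#' @param target Target gene id.
#' @param reference Reference (internal control) gene id; must be present
#'   in every (group, biological replicate).
#' @param calibrator_group Group used as the calibrator (fold = 1 by
#'   construction on average).
#' @return Data.frame with one row per group: `gene_id`, `group`,
#'   `fold_change`, `se`, `n_bio`, `p_vs_calibrator`, `flag`.
#' @export
delta_delta_ct <- function(ct_table, target, reference, calibrator_group) {
  needed <- c("sample_group", "biological_rep", "technical_rep", "gene_id", "ct")
  stopifnot(is.data.frame(ct_table), all(needed %in% names(ct_table)))
  if (any(ct_table$ct <= 0)) stop("Ct values must be positive")
  if (!calibrator_group %in% ct_table$sample_group) {
    stop("calibrator group ", calibrator_group, " not present")
  }
  if (!target %in% ct_table$gene_id) stop("target gene not present")
  # average technical replicates
  agg <- stats::aggregate(ct ~ sample_group + biological_rep + gene_id,
                          data = ct_table, FUN = mean)
  reps <- unique(agg[, c("sample_group", "biological_rep")])
  dct <- numeric(nrow(reps))
  for (i in seq_len(nrow(reps))) {
    sel <- agg$sample_group == reps$sample_group[i] &
      agg$biological_rep == reps$biological_rep[i]
    ct_ref <- agg$ct[sel & agg$gene_id == reference]
    ct_tgt <- agg$ct[sel & agg$gene_id == target]
    if (!length(ct_ref)) {
      stop("reference gene ", reference, " missing in group ",
           reps$sample_group[i], " biological replicate ",
           reps$biological_rep[i])
    }
    if (!length(ct_tgt)) {
      stop("target gene missing in group ", reps$sample_group[i],
           " biological replicate ", reps$biological_rep[i])
    }
    dct[i] <- ct_tgt - ct_ref
  }
  calib_dct <- dct[reps$sample_group == calibrator_group]
  calib_mean <- mean(calib_dct)
  groups <- unique(reps$sample_group)
  rows <- lapply(groups, function(g) {
    d <- dct[reps$sample_group == g]
    folds <- 2^(-(d - calib_mean))
    sig <- if (g == calibrator_group) {
      list(p = NA_real_, flag = "ns")
    } else {
      significance(d, calib_dct)
    }
    # group fold from the mean ddCt (so the calibrator is exactly 1 by
    # construction); SE from the per-replicate folds
    data.frame(gene_id = target, group = g,
               fold_change = 2^(-(mean(d) - calib_mean)),
               se = if (length(folds) > 1L)
                 stats::sd(folds) / sqrt(length(folds)) else NA_real_,
               n_bio = length(folds),
               p_vs_calibrator = sig$p, flag = sig$flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Welch t-test significance flags for dCt comparisons
#'
#' Two-sided Welch (unequal variance) t-test on per-replicate dCt values,
#' flagged at the conventional thresholds: `*` for p < 0.05, `**` for
#' p < 0.01, `ns` otherwise. With fewer than 2 replicates in either group
#' the p-value is absent and the flag is `ns`. Two degenerate zero-variance
#' cases are resolved by their limits: identical constant groups give
#' p = 1, separated constant groups give p = 0.
#'
#' @param dct_group,dct_calibrator Numeric vectors of per-replicate dCt.
#' @return List with `p` and `flag`.
#' @export
significance <- function(dct_group, dct_calibrator) {
  if (length(dct_group) < 2L || length(dct_calibrator) < 2L) {
    return(list(p = NA_real_, flag = "ns"))
  }
  if (stats::sd(dct_group) == 0 && stats::sd(dct_calibrator) == 0) {
    p <- if (mean(dct_group) == mean(dct_calibrator)) 1 else 0
  } else {
    p <- stats::t.test(dct_group, dct_calibrator, var.equal = FALSE,
                       alternative = "two.sided")$p.value
  }
  flag <- if (is.na(p)) "ns" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else "ns"
  list(p = p, flag = flag)
}
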