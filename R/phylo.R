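# Distance-based phylogeny: p / Poisson-corrected distances with pairwise
# gap deletion, Saitou-Nei neighbor joining (via ape), column-resampling
# bootstrap supports and newick output. This is a deliberate descriptive
# stand-in for likelihood tree inference; output trees carry a comment
# header saying so when written through the pipeline.

#' Pairwise distances on a multiple alignment
#'
#' Computes pairwise distances over an aligned set of sequences with
#' pairwise gap deletion: for each pair, columns where either sequence has
#' a gap (`-`) are dropped; `p` is the mismatch fraction and `poisson` the
#' correction `-ln(1 - p)`.
#'
#' @param alignment Named character vector of equal-length aligned
#'   sequences (>= 2).
#' @param model `"p"` or `"poisson"`.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
pairwise_distance <- function(alignment, model = c("p", "poisson")) {
  model <- match.arg(model)
  if (length(alignment) < 2L) stop("need at least 2 taxa")
  if (is.null(names(alignment))) stop("alignment rows must be named")
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L) stop("aligned rows differ in length")
  n <- length(alignment)
  chars <- lapply(alignment, function(s) strsplit(s, "")[[1]])
  d <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      ok <- chars[[i]] != "-" & chars[[j]] != "-"
      if (!any(ok)) {
        stop("no comparable columns between ", names(alignment)[i], " and ",
             names(alignment)[j])
      }
      p <- mean(chars[[i]][ok] != chars[[j]][ok])
      dist <- if (model == "p") p else {
        if (p >= 1) stop("saturated pair (p = 1): Poisson distance undefined")
        -log(1 - p)
      }
      d[i, j] <- d[j, i] <- dist
    }
  }
  d
}

#' Pairwise p-distances from unaligned proteins
#'
#' Aligns every pair globally with [global_align()] and measures the
#' mismatch fraction over columns where both sequences have a residue.
#' Useful when no multiple alignment is available.
#'
#' @param proteins Data.frame with `id`, `sequence`.
#' @param model `"p"` or `"poisson"`.
#' @return Symmetric distance matrix.
#' @export
pairwise_distance_from_proteins <- function(proteins, model = c("p", "poisson")) {
  model <- match.arg(model)
  n <- nrow(proteins)
  if (n < 2L) stop("need at least 2 proteins")
  d <- matrix(0, n, n, dimnames = list(proteins$id, proteins$id))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      aln <- global_align(proteins$sequence[i], proteins$sequence[j])
      a <- strsplit(aln$aligned_a, "")[[1]]
      b <- strsplit(aln$aligned_b, "")[[1]]
      ok <- a != "-" & b != "-"
      p <- mean(a[ok] != b[ok])
      d[i, j] <- d[j, i] <- if (model == "p") p else {
        if (p >= 1) stop("saturated pair") else -log(1 - p)
      }
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}). Negative branch lengths,
#' which NJ can produce on non-additive matrices, are clamped to zero with
#' a warning.
#'
#' @param d Symmetric distance matrix with taxa as dimnames (>= 3 taxa).
#' @return An \pkg{ape} `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  if (!is.matrix(d) || !isSymmetric(unname(d))) {
    stop("distance matrix must be symmetric")
  }
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (any(!is.finite(d))) stop("distances must be finite")
  tree <- ape::nj(stats::as.dist(d))
  if (any(tree$edge.length < 0)) {
    warning("negative NJ branch length(s) clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate, and reports for every internal bipartition of the full
#' tree the percentage of replicates containing it. The trivial all-taxa
#' partition (the root node) carries no support value.
#'
#' @param alignment Named character vector of aligned sequences.
#' @param n_reps Number of bootstrap replicates (0 for none).
#' @param seed Integer seed (required when `n_reps > 0`).
#' @param model Distance model passed to [pairwise_distance()].
#' @return A `phylo` tree; supports (0--100) in `node.label` when
#'   `n_reps > 0`.
#' @export
bootstrap_support <- function(alignment, n_reps = 1000, seed = NULL,
                              model = "poisson") {
  tree <- neighbor_joining(pairwise_distance(alignment, model))
  if (n_reps == 0) return(tree)
  if (is.null(seed)) stop("seed required for bootstrapping")
  chars <- do.call(rbind, strsplit(alignment, ""))
  rownames(chars) <- names(alignment)
  n_col <- ncol(chars)
  with_seed(seed, {
    rep_trees <- vector("list", n_reps)
    for (r in seq_len(n_reps)) {
      cols <- sample.int(n_col, n_col, replace = TRUE)
      boot_aln <- apply(chars[, cols, drop = FALSE], 1L, paste, collapse = "")
      rep_trees[[r]] <- suppressWarnings(
        neighbor_joining(pairwise_distance(boot_aln, model)))
    }
    counts <- ape::prop.clades(tree, rep_trees, rooted = FALSE)
    counts[is.na(counts)] <- 0
    support <- round(100 * counts / n_reps, 1)
    labels <- as.character(support)
    labels[1] <- ""  # root: the all-taxa partition is not a bipartition
    tree$node.label <- labels
    tree
  })
}

#' Write a tree to newick text
#'
#' Standard newick with branch lengths and any supports as internal node
#' labels; parseable by independent newick readers.
#'
#' @param tree A `phylo` tree.
#' @param path Optional path; when NULL the newick string is returned.
#' @return The newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  # labels containing spaces are emitted quoted (newick rule); route them
  # through placeholders so the writer does not mangle them
  needs_quote <- grepl("[ ()':;,]", tree$tip.label)
  originals <- tree$tip.label[needs_quote]
  tokens <- sprintf("QLBL%dQLBL", seq_along(originals))
  tree$tip.label[needs_quote] <- tokens
  txt <- ape::write.tree(tree)
  for (i in seq_along(tokens)) {
    txt <- sub(tokens[i], paste0("'", originals[i], "'"), txt, fixed = TRUE)
  }
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
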