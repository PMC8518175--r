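# Paralog detection and divergence dating: all-vs-all global protein
# alignment (Needleman-Wunsch, BLOSUM62, affine gaps via Biostrings),
# reciprocal-best-hit pairing under identity/coverage thresholds, PAL2NAL-
# style codon back-threading, Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor
# correction, clock dating T = Ks/(2*lambda) and selection classification.

STOP_CODONS <- c("TAA", "TAG", "TGA")

split_codons <- function(cds) {
  assert_dna_sequence(cds, extra = "", what = "CDS")
  n <- nchar(cds)
  if (n %% 3 != 0) stop("CDS length ", n, " is not a multiple of 3")
  substring(cds, seq(1, n, 3), seq(3, n, 3))
}

#' Translate a coding sequence
#'
#' Translates a CDS with the universal genetic code. A terminal stop codon
#' is dropped; an internal stop is an error.
#'
#' @param cds DNA string whose length is a multiple of 3.
#' @return Protein sequence (no terminal stop).
#' @export
translate_cds <- function(cds) {
  codons <- split_codons(cds)
  if (codons[length(codons)] %in% STOP_CODONS) {
    codons <- codons[-length(codons)]
  }
  aa <- Biostrings::GENETIC_CODE[codons]
  if (any(is.na(aa))) stop("invalid codon in CDS")
  if (any(aa == "*")) {
    stop("internal stop codon at codon ", which(aa == "*")[1])
  }
  paste(aa, collapse = "")
}

# Fraction of sense single-base changes that are synonymous, per codon
# position. Changes producing stop codons are excluded from both numerator
# and denominator; the synonymous site count of a codon is the sum of the
# three per-position fractions.
ng86_codon_syn_sites <- function(codon) {
  if (codon %in% STOP_CODONS) return(NA_real_)
  aa <- Biostrings::GENETIC_CODE[[codon]]
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0L
    sense <- 0L
    for (b in setdiff(bases, chars[pos])) {
      alt <- chars
      alt[pos] <- b
      alt_codon <- paste(alt, collapse = "")
      if (alt_codon %in% STOP_CODONS) next
      sense <- sense + 1L
      if (Biostrings::GENETIC_CODE[[alt_codon]] == aa) syn <- syn + 1L
    }
    s <- s + if (sense > 0L) syn / sense else 0
  }
  s
}

# Synonymous/nonsynonymous differences between two codons, averaged over
# all orderings of the single-base steps. Paths passing through a stop
# codon are excluded; if every path hits a stop, all paths are used with
# stop steps counted as nonsynonymous.
ng86_codon_diffs <- function(codon_a, codon_b) {
  pos <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- if (k == 1L) list(pos) else {
    if (k == 2L) list(pos, rev(pos)) else {
      idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                  c(3, 1, 2), c(3, 2, 1))
      lapply(idx, function(i) pos[i])
    }
  }
  walk <- function(order) {
    cur <- strsplit(codon_a, "")[[1]]
    target <- strsplit(codon_b, "")[[1]]
    sd <- 0
    nd <- 0
    hit_stop <- FALSE
    for (p in order) {
      prev_codon <- paste(cur, collapse = "")
      cur[p] <- target[p]
      next_codon <- paste(cur, collapse = "")
      if (next_codon %in% STOP_CODONS || prev_codon %in% STOP_CODONS) {
        hit_stop <- TRUE
        nd <- nd + 1
        next
      }
      if (Biostrings::GENETIC_CODE[[prev_codon]] ==
          Biostrings::GENETIC_CODE[[next_codon]]) {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
    }
    list(sd = sd, nd = nd, hit_stop = hit_stop)
  }
  paths <- lapply(perms, walk)
  ok <- !vapply(paths, `[[`, logical(1), "hit_stop")
  use <- if (any(ok)) paths[ok] else paths
  c(sd = mean(vapply(use, `[[`, numeric(1), "sd")),
    nd = mean(vapply(use, `[[`, numeric(1), "nd")))
}

jukes_cantor <- function(p, class) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) {
    stop("substitution saturation: proportion of ", class,
         " differences is ", signif(p, 3), " (>= 3/4)")
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori (1986) Ka/Ks from a codon alignment
#'
#' Counts fractional synonymous and nonsynonymous sites per codon (averaged
#' over the two sequences), classifies differences with pathway averaging
#' for codon pairs differing at more than one position, and corrects the
#' per-site proportions with the Jukes-Cantor formula
#' `d = -(3/4) ln(1 - (4/3) p)`. Codon columns containing gaps or ambiguity
#' letters are dropped pairwise.
#'
#' @param codon_a,codon_b Aligned codon sequences (equal length, length a
#'   multiple of 3; gaps as `-`).
#' @return List with `ka`, `ks`, `ratio` (NA when `ks` is 0), and the raw
#'   counts `syn_sites`, `nonsyn_sites`, `syn_diffs`, `nonsyn_diffs`,
#'   `codons_used`.
#' @export
ng86_kaks <- function(codon_a, codon_b) {
  if (nchar(codon_a) != nchar(codon_b)) {
    stop("aligned sequences differ in length")
  }
  n <- nchar(codon_a)
  if (n %% 3 != 0) stop("aligned length is not a multiple of 3")
  ca <- substring(codon_a, seq(1, n, 3), seq(3, n, 3))
  cb <- substring(codon_b, seq(1, n, 3), seq(3, n, 3))
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb) &
    !(ca %in% STOP_CODONS) & !(cb %in% STOP_CODONS)
  ca <- ca[clean]
  cb <- cb[clean]
  if (!length(ca)) stop("no comparable codon columns")
  s_a <- vapply(ca, ng86_codon_syn_sites, numeric(1))
  s_b <- vapply(cb, ng86_codon_syn_sites, numeric(1))
  S <- sum((s_a + s_b) / 2)
  N <- 3 * length(ca) - S
  diffs <- mapply(ng86_codon_diffs, ca, cb)
  Sd <- sum(diffs["sd", ])
  Nd <- sum(diffs["nd", ])
  if (S <= 0) stop("zero synonymous sites")
  ps <- Sd / S
  pn <- Nd / N
  ks <- jukes_cantor(ps, "synonymous")
  ka <- jukes_cantor(pn, "nonsynonymous")
  list(ka = ka, ks = ks,
       ratio = if (ks > 0) ka / ks else NA_real_,
       syn_sites = S, nonsyn_sites = N,
       syn_diffs = Sd, nonsyn_diffs = Nd, codons_used = length(ca))
}

#' Global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties on the
#' BLOSUM62 matrix (via Biostrings). Identity is the percentage of identical
#' columns over all aligned columns; coverage is the percentage of the
#' longer sequence falling inside the terminal-gap-trimmed aligned span.
#'
#' @param seq_a,seq_b Protein sequences.
#' @param id_a,id_b Identifiers carried into the result.
#' @param gap_open,gap_extend Affine gap penalties (a gap of length L costs
#'   `gap_open + gap_extend * L`).
#' @return List with `id_a`, `id_b`, `aligned_a`, `aligned_b`, `score`,
#'   `identity_pct`, `coverage_pct`.
#' @export
global_align <- function(seq_a, seq_b, id_a = "a", id_b = "b",
                         gap_open = 10, gap_extend = 0.5) {
  assert_protein_sequence(seq_a, what = "seq_a")
  assert_protein_sequence(seq_b, what = "seq_b")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = gap_open, gapExtension = gap_extend)
  a <- as.character(Biostrings::alignedPattern(aln))
  b <- as.character(Biostrings::alignedSubject(aln))
  stats <- alignment_stats(a, b, nchar(seq_a), nchar(seq_b))
  list(id_a = id_a, id_b = id_b, aligned_a = a, aligned_b = b,
       score = Biostrings::score(aln),
       identity_pct = stats$identity_pct, coverage_pct = stats$coverage_pct)
}

alignment_stats <- function(a, b, len_a, len_b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  both <- ca != "-" | cb != "-"
  ca <- ca[both]
  cb <- cb[both]
  identity <- 100 * sum(ca != "-" & ca == cb) / length(ca)
  # terminal-gap trimming: span where both sequences have started and not
  # yet ended
  a_res <- ca != "-"
  b_res <- cb != "-"
  span <- seq(max(which(a_res)[1], which(b_res)[1]),
              min(max(which(a_res)), max(which(b_res))))
  longer <- max(len_a, len_b)
  covered <- if (len_a >= len_b) sum(a_res[span]) else sum(b_res[span])
  list(identity_pct = identity, coverage_pct = 100 * covered / longer)
}

#' Reciprocal-best-hit paralog pairs
#'
#' All-vs-all global alignment of a protein set; a pair (a, b) is reported
#' iff b is a's best-scoring partner and a is b's (ties broken toward the
#' lower input index), and both the identity and the coverage of the
#' alignment exceed the thresholds. Each protein appears in at most one
#' pair; output order is independent of input order.
#'
#' @param proteins Data.frame with columns `id` and `sequence` (>= 2 rows).
#' @param min_identity,min_coverage Percent thresholds (strict `>`).
#' @param gap_open,gap_extend Passed to [global_align()].
#' @return Data.frame with columns `gene_a`, `gene_b`, `identity_pct`,
#'   `coverage_pct`, `score`, sorted by `gene_a`.
#' @export
reciprocal_best_pairs <- function(proteins, min_identity = 70,
                                  min_coverage = 70,
                                  gap_open = 10, gap_extend = 0.5) {
  stopifnot(is.data.frame(proteins), nrow(proteins) >= 2L,
            all(c("id", "sequence") %in% names(proteins)))
  proteins <- proteins[order(proteins$id), , drop = FALSE]
  n <- nrow(proteins)
  score <- matrix(-Inf, n, n)
  identity <- matrix(NA_real_, n, n)
  coverage <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      aln <- global_align(proteins$sequence[i], proteins$sequence[j],
                          proteins$id[i], proteins$id[j],
                          gap_open = gap_open, gap_extend = gap_extend)
      score[i, j] <- score[j, i] <- aln$score
      identity[i, j] <- identity[j, i] <- aln$identity_pct
      coverage[i, j] <- coverage[j, i] <- aln$coverage_pct
    }
  }
  best <- apply(score, 1L, which.max)  # ties -> lowest index
  rows <- list()
  for (i in seq_len(n)) {
    j <- best[i]
    if (j > i && best[j] == i &&
        identity[i, j] > min_identity && coverage[i, j] > min_coverage) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = proteins$id[i], gene_b = proteins$id[j],
        identity_pct = identity[i, j], coverage_pct = coverage[i, j],
        score = score[i, j], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      identity_pct = numeric(0), coverage_pct = numeric(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$gene_a), , drop = FALSE]
}

#' Back-thread a protein alignment onto coding sequences
#'
#' Converts a gapped protein alignment into a codon alignment: each aligned
#' amino-acid column maps to one codon column and protein gaps become `---`
#' triplets. The translation of each CDS (terminal stop dropped) must equal
#' the corresponding ungapped protein.
#'
#' @param aligned_a,aligned_b Gapped protein strings of equal length.
#' @param cds_a,cds_b Coding sequences for the ungapped proteins.
#' @return List with `codon_a` and `codon_b` (gapped codon strings).
#' @export
codon_align <- function(aligned_a, aligned_b, cds_a, cds_b) {
  if (nchar(aligned_a) != nchar(aligned_b)) {
    stop("aligned protein strings differ in length")
  }
  thread_one <- function(aligned, cds, label) {
    prot <- gsub("-", "", aligned, fixed = TRUE)
    trans <- translate_cds(cds)
    if (!identical(trans, prot)) {
      pa <- strsplit(prot, "")[[1]]
      pt <- strsplit(trans, "")[[1]]
      k <- min(length(pa), length(pt))
      mismatch <- which(pa[seq_len(k)] != pt[seq_len(k)])
      first <- if (length(mismatch)) mismatch[1] else k + 1L
      stop("CDS/protein mismatch for ", label, " at protein position ", first)
    }
    codons <- split_codons(cds)
    if (codons[length(codons)] %in% STOP_CODONS) {
      codons <- codons[-length(codons)]
    }
    cols <- strsplit(aligned, "")[[1]]
    out <- character(length(cols))
    ci <- 0L
    for (i in seq_along(cols)) {
      if (cols[i] == "-") {
        out[i] <- "---"
      } else {
        ci <- ci + 1L
        out[i] <- codons[ci]
      }
    }
    paste(out, collapse = "")
  }
  list(codon_a = thread_one(aligned_a, cds_a, "sequence a"),
       codon_b = thread_one(aligned_b, cds_b, "sequence b"))
}

#' Divergence time from synonymous divergence
#'
#' Converts a synonymous substitution rate into a duplication date in
#' million years with the molecular-clock formula `T = Ks / (2 * lambda)`.
#'
#' @param ks Synonymous substitutions per synonymous site (vectorized).
#' @param lam Clock rate in substitutions per site per year (default
#'   6.1e-9, the eudicot rate).
#' @return Divergence time(s) in million years (MYA).
#' @examples
#' divergence_time(0.1830)  # 15 MYA
#' @export
divergence_time <- function(ks, lam = 6.1e-9) {
  if (any(is.na(ks)) || any(ks < 0)) stop("ks must be nonnegative")
  if (lam <= 0) stop("lam must be positive")
  ks / (2 * lam) / 1e6
}

#' Classify selection from a Ka/Ks ratio
#'
#' `< 1` purifying (negative) selection, `> 1` positive selection, `= 1`
#' (within `tol`) neutral.
#'
#' @param ratio Ka/Ks ratio(s), nonnegative.
#' @param tol Equality tolerance around 1.
#' @return Character vector in `{purifying, positive, neutral}`.
#' @export
classify_selection <- function(ratio, tol = 1e-9) {
  if (any(is.na(ratio)) || any(ratio < 0)) stop("ratio must be nonnegative")
  ifelse(abs(ratio - 1) <= tol, "neutral",
         ifelse(ratio < 1, "purifying", "positive"))
}

#' Full paralog report for a gene family
#'
#' Runs [reciprocal_best_pairs()] on the proteins, back-threads each pair's
#' alignment onto its CDS, computes NG86 Ka/Ks, dates the duplication and
#' classifies selection.
#'
#' @param proteins Data.frame with `id`, `sequence` (amino acids).
#' @param cds Named character vector of coding sequences (names matching
#'   protein ids).
#' @param min_identity,min_coverage RBH thresholds (percent).
#' @param lam Clock rate for [divergence_time()].
#' @return Data.frame with one row per paralog pair: identity, coverage,
#'   Ka, Ks, Ka/Ks, divergence time (MYA) and selection class.
#' @export
paralog_report <- function(proteins, cds, min_identity = 70,
                           min_coverage = 70, lam = 6.1e-9) {
  pairs <- reciprocal_best_pairs(proteins, min_identity, min_coverage)
  if (!nrow(pairs)) {
    return(cbind(pairs, data.frame(ka = numeric(0), ks = numeric(0),
                                   ka_ks = numeric(0), mya = numeric(0),
                                   selection = character(0))))
  }
  seqs <- stats::setNames(proteins$sequence, proteins$id)
  extra <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$gene_a[i]
    b <- pairs$gene_b[i]
    aln <- global_align(seqs[[a]], seqs[[b]], a, b)
    cal <- codon_align(aln$aligned_a, aln$aligned_b, cds[[a]], cds[[b]])
    kk <- ng86_kaks(cal$codon_a, cal$codon_b)
    data.frame(ka = kk$ka, ks = kk$ks, ka_ks = kk$ratio,
               mya = divergence_time(kk$ks, lam),
               selection = if (is.na(kk$ratio)) NA_character_ else
                 classify_selection(kk$ratio),
               stringsAsFactors = FALSE)
  })
  cbind(pairs, do.call(rbind, extra))
}
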