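# Degenerate IUPAC motif scanning of promoters on both strands (Biostrings
# matching with the subject held literal, so N in a promoter never matches),
# per-gene count tables for a motif library, and Fisher exact enrichment
# between gene sets. Occurrences are counted with overlaps allowed; reverse-
# strand hits are reported at forward coordinates with strand "-".

#' Expand an IUPAC motif to its concrete words
#'
#' Cartesian expansion of the per-position allowed base sets of a
#' degenerate IUPAC pattern.
#'
#' @param pattern IUPAC string (A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N).
#' @return Character vector of concrete DNA words.
#' @examples
#' expand_iupac("MCGTGT")  # ACGTGT, CCGTGT
#' @export
expand_iupac <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(unique(chars), names(IUPAC_SETS))
  if (length(bad)) {
    stop("invalid IUPAC letter(s): ", paste(bad, collapse = ", "))
  }
  sets <- IUPAC_SETS[chars]
  degeneracy <- prod(lengths(sets))
  if (degeneracy > 65536) stop("motif too degenerate to expand")
  words <- do.call(expand.grid,
                   c(rev(sets), list(stringsAsFactors = FALSE)))
  words <- words[, rev(seq_len(ncol(words))), drop = FALSE]
  sort(apply(words, 1L, paste, collapse = ""))
}

#' Scan a promoter for a degenerate motif
#'
#' Slides the IUPAC pattern along the promoter at every offset (overlapping
#' matches counted). Reverse-strand hits are found by scanning the reverse
#' complement and reported at forward coordinates with strand `"-"`. `N`
#' in the promoter never matches.
#'
#' @param promoter DNA string over A/C/G/T/N.
#' @param pattern IUPAC motif string.
#' @param strands `"both"` (default) or `"forward"`.
#' @param gene Optional gene id carried into the output.
#' @return Data.frame with columns `gene`, `motif`, `strand`, `start`
#'   (1-based forward coordinate of the match start), one row per hit.
#' @export
scan_motif <- function(promoter, pattern, strands = c("both", "forward"),
                       gene = NA_character_) {
  strands <- match.arg(strands)
  assert_dna_sequence(promoter, extra = "N", what = "promoter")
  iupac_to_regex(pattern)  # validates
  k <- nchar(pattern)
  L <- nchar(promoter)
  subject <- Biostrings::DNAString(promoter)
  # windows containing N are dropped: N never matches any motif letter
  drop_n <- function(starts) {
    starts[!vapply(starts, function(s)
      grepl("N", substr(promoter, s, s + k - 1L), fixed = TRUE), logical(1))]
  }
  fwd <- if (L >= k) {
    drop_n(Biostrings::start(Biostrings::matchPattern(pattern, subject,
                                                      fixed = "subject")))
  } else {
    integer(0)
  }
  rows <- data.frame(gene = rep(gene, length(fwd)),
                     motif = rep(pattern, length(fwd)),
                     strand = rep("+", length(fwd)),
                     start = as.integer(fwd), stringsAsFactors = FALSE)
  if (strands == "both" && L >= k) {
    rc_hits <- Biostrings::start(Biostrings::matchPattern(
      pattern, Biostrings::reverseComplement(subject), fixed = "subject"))
    rev_start <- drop_n(sort(L - (as.integer(rc_hits) + k - 1L) + 1L))
    rows <- rbind(rows, data.frame(
      gene = rep(gene, length(rev_start)),
      motif = rep(pattern, length(rev_start)),
      strand = rep("-", length(rev_start)),
      start = rev_start, stringsAsFactors = FALSE))
  }
  rows[order(rows$start, rows$strand), , drop = FALSE]
}

#' Count a motif library across a promoter set
#'
#' Scans every promoter for every motif of a library (both strands) and
#' tabulates per-gene, per-motif counts; zero-count combinations are
#' included.
#'
#' @param promoters Named character vector of promoter sequences.
#' @param library Data.frame with columns `name` and `pattern` (unique
#'   names required), e.g. the bundled example library
#'   (`read_motif_library()`).
#' @return Data.frame with one row per (gene, motif): `gene`, `motif`,
#'   `pattern`, `n_fwd`, `n_rev`, `n_total`, and comma-separated 1-based
#'   start positions `positions_fwd`, `positions_rev`.
#' @export
count_motif_library <- function(promoters, library) {
  stopifnot(is.data.frame(library),
            all(c("name", "pattern") %in% names(library)))
  if (anyDuplicated(library$name)) {
    stop("duplicate motif names in library: ",
         paste(unique(library$name[duplicated(library$name)]), collapse = ", "))
  }
  if (!nrow(library) || !length(promoters)) {
    return(data.frame(gene = character(0), motif = character(0),
                      pattern = character(0), n_fwd = integer(0),
                      n_rev = integer(0), n_total = integer(0),
                      positions_fwd = character(0),
                      positions_rev = character(0), stringsAsFactors = FALSE))
  }
  rows <- list()
  for (gene in names(promoters)) {
    for (i in seq_len(nrow(library))) {
      hits <- scan_motif(promoters[[gene]], library$pattern[i], gene = gene)
      f <- hits$start[hits$strand == "+"]
      r <- hits$start[hits$strand == "-"]
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, motif = library$name[i], pattern = library$pattern[i],
        n_fwd = length(f), n_rev = length(r), n_total = length(f) + length(r),
        positions_fwd = paste(f, collapse = ","),
        positions_rev = paste(r, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Bundled example cis-element motif library
#'
#' Reads the example motif library shipped with the package: common plant
#' cis-regulatory element core consensus sequences plus the two CAMTA
#' recognition motifs (MCGCGB, MCGTGT). In real analyses the library is
#' user-supplied (two-column TSV: name, IUPAC pattern).
#'
#' @param path Optional path to a custom two-column TSV.
#' @return Data.frame with columns `name`, `pattern`.
#' @export
read_motif_library <- function(path = NULL) {
  utils::read.delim(path %||% extdata_path("cis_element_library.tsv"),
                    stringsAsFactors = FALSE)
}

#' Fisher exact test for motif-frequency enrichment
#'
#' Two-sided Fisher exact test on the 2x2 table
#' `[[hits_a, scanned_a - hits_a], [hits_b, scanned_b - hits_b]]`, where
#' `scanned` totals are the numbers of scanned positions in each gene set.
#' The odds ratio is the sample (unconditional) odds ratio, with a Haldane
#' correction of 0.5 added to every cell when any cell is zero.
#'
#' @param hits_a,scanned_a Occurrences and scanned-position total, set A.
#' @param hits_b,scanned_b Same for set B.
#' @return List with `table`, `odds_ratio` and `p_two_sided`.
#' @export
fisher_enrichment <- function(hits_a, scanned_a, hits_b, scanned_b) {
  vals <- c(hits_a, scanned_a, hits_b, scanned_b)
  if (any(vals < 0)) stop("negative entries")
  if (hits_a > scanned_a || hits_b > scanned_b) {
    stop("hits cannot exceed scanned positions")
  }
  tab <- matrix(c(hits_a, scanned_a - hits_a,
                  hits_b, scanned_b - hits_b),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("set_a", "set_b"), c("hit", "no_hit")))
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  or_tab <- tab
  if (any(or_tab == 0)) or_tab <- or_tab + 0.5
  odds_ratio <- (or_tab[1, 1] * or_tab[2, 2]) / (or_tab[1, 2] * or_tab[2, 1])
  list(table = tab, odds_ratio = odds_ratio, p_two_sided = min(p, 1))
}

#' Scanned-position total for a promoter set
#'
#' Number of window positions a `k`-long motif is slid across in a set of
#' promoters: `sum(L_i - k + 1)` per strand, doubled for both strands.
#'
#' @param promoters Named character vector of promoters.
#' @param k Motif width.
#' @param strands `"both"` or `"forward"`.
#' @return Integer total of scanned positions.
#' @export
scanned_positions <- function(promoters, k, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  per <- pmax(0L, nchar(promoters) - as.integer(k) + 1L)
  tot <- sum(per)
  if (strands == "both") tot <- 2L * tot
  as.integer(tot)
}
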