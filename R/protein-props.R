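# Protein physicochemistry in the ProtParam convention: length from the ORF,
# average molecular weight, and the Bjellqvist theoretical pI. The residue
# masses and pKa values are shipped as plain-text tables under inst/extdata
# rather than hard-coded, so the numeric convention is inspectable data.

WATER_AVG_MASS <- 18.0153

residue_masses <- function() {
  if (is.null(.camta_cache$residue_masses)) {
    tab <- utils::read.delim(extdata_path("residue_masses.tsv"),
                             stringsAsFactors = FALSE)
    .camta_cache$residue_masses <- stats::setNames(tab$mass, tab$residue)
  }
  .camta_cache$residue_masses
}

pka_table <- function() {
  if (is.null(.camta_cache$pka)) {
    tab <- utils::read.delim(extdata_path("pka_bjellqvist.tsv"),
                             stringsAsFactors = FALSE)
    .camta_cache$pka <- tab
  }
  .camta_cache$pka
}

pka_value <- function(role, key) {
  tab <- pka_table()
  hit <- tab$pka[tab$role == role & tab$key == key]
  if (length(hit) != 1L) stop("pKa lookup failed for ", role, "/", key)
  hit
}

#' Protein length from ORF length
#'
#' Converts an open-reading-frame length in base pairs to the encoded protein
#' length in amino acids, excluding the terminal stop codon:
#' `aa = orf_length / 3 - 1`.
#'
#' @param orf_length Integer vector of ORF lengths in bp (including the stop
#'   codon). Each must exceed 3 and be divisible by 3.
#' @return Integer vector of protein lengths (aa).
#' @examples
#' protein_length_from_orf(2676)  # 891
#' @export
protein_length_from_orf <- function(orf_length) {
  if (!is.numeric(orf_length) || any(is.na(orf_length))) {
    stop("orf_length must be numeric and non-missing")
  }
  rem <- orf_length %% 3
  if (any(rem != 0)) {
    bad <- which(rem != 0)[1]
    stop("ORF length ", orf_length[bad], " is not divisible by 3 (remainder ",
         rem[bad], ")")
  }
  if (any(orf_length <= 3)) stop("ORF length must exceed 3 bp")
  as.integer(orf_length / 3 - 1)
}

#' Average molecular weight of a protein
#'
#' Sum of average residue masses plus one water (18.0153 Da), matching the
#' ProtParam convention. Non-canonical letters (including X) are an error:
#' no silent mass is guessed.
#'
#' @param sequence Amino-acid sequence (single string, 20 canonical letters).
#' @return Molecular weight in Da, rounded to 2 decimals.
#' @examples
#' molecular_weight("G")  # 75.07
#' @export
molecular_weight <- function(sequence) {
  chars <- assert_protein_sequence(sequence)
  masses <- residue_masses()
  round(sum(masses[chars]) + WATER_AVG_MASS, 2)
}

# Net charge at a given pH from the Henderson-Hasselbalch equation over the
# N-terminus, C-terminus and the D/E/C/Y/H/K/R side chains (Bjellqvist pKa
# set). Strictly decreasing in pH, so the pI root is unique.
protein_net_charge <- function(sequence, pH) {
  chars <- assert_protein_sequence(sequence)
  counts <- table(factor(chars, levels = AA_CANONICAL))
  nterm_res <- chars[1]
  cterm_res <- chars[length(chars)]
  nterm_tab <- pka_table()
  nterm_pka <- if (any(nterm_tab$role == "nterm" & nterm_tab$key == nterm_res)) {
    pka_value("nterm", nterm_res)
  } else {
    pka_value("positive", "Nterm_default")
  }
  cterm_pka <- if (any(nterm_tab$role == "cterm" & nterm_tab$key == cterm_res)) {
    pka_value("cterm", cterm_res)
  } else {
    pka_value("negative", "Cterm_default")
  }
  pos_frac <- function(pka) 1 / (1 + 10^(pH - pka))
  neg_frac <- function(pka) 1 / (1 + 10^(pka - pH))
  positive <- pos_frac(nterm_pka) +
    counts[["K"]] * pos_frac(pka_value("positive", "K")) +
    counts[["R"]] * pos_frac(pka_value("positive", "R")) +
    counts[["H"]] * pos_frac(pka_value("positive", "H"))
  negative <- neg_frac(cterm_pka) +
    counts[["D"]] * neg_frac(pka_value("negative", "D")) +
    counts[["E"]] * neg_frac(pka_value("negative", "E")) +
    counts[["C"]] * neg_frac(pka_value("negative", "C")) +
    counts[["Y"]] * neg_frac(pka_value("negative", "Y"))
  positive - negative
}

#' Theoretical isoelectric point
#'
#' pH at which the net charge of the protein crosses zero, computed over the
#' termini and charged side chains with the Bjellqvist pKa set used by
#' ProtParam, found by bisection on \[0, 14\] to an interval width below
#' 0.005.
#'
#' @inheritParams molecular_weight
#' @return Theoretical pI in pH units, rounded to 2 decimals.
#' @export
isoelectric_point <- function(sequence) {
  assert_protein_sequence(sequence)
  lo <- 0
  hi <- 14
  while (hi - lo >= 0.0005) {
    mid <- (lo + hi) / 2
    if (protein_net_charge(sequence, mid) > 0) lo <- mid else hi <- mid
  }
  round((lo + hi) / 2, 2)
}

#' Physicochemical summary table
#'
#' Computes, for a set of proteins, the summary mirrored on published CAMTA
#' family tables: protein length (aa), average molecular weight (Da) and
#' theoretical pI.
#'
#' @param proteins Data.frame with columns `id` and `sequence` (e.g. from
#'   [read_protein_fasta()]).
#' @return Data.frame with columns `id`, `length_aa`, `molecular_weight_da`,
#'   `pi`.
#' @export
physchem_table <- function(proteins) {
  stopifnot(is.data.frame(proteins), all(c("id", "sequence") %in% names(proteins)))
  data.frame(
    id = proteins$id,
    length_aa = nchar(proteins$sequence),
    molecular_weight_da = vapply(proteins$sequence, molecular_weight, numeric(1),
                                 USE.NAMES = FALSE),
    pi = vapply(proteins$sequence, isoelectric_point, numeric(1),
                USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Published durian CAMTA gene table
#'
#' Returns the published summary table for the ten durian CAMTA genes
#' (accessions, scaffold, strand, ORF length, protein length, molecular
#' weight, pI and exon count), bundled as plain-text data. Useful as the
#' reference for consistency checks on the ORF arithmetic and
#' physicochemistry conventions.
#'
#' @return Data.frame with one row per DzCAMTA gene.
#' @export
dzcamta_table <- function() {
  utils::read.delim(extdata_path("dzcamta_table1.tsv"), stringsAsFactors = FALSE)
}
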