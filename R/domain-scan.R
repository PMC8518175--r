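# Domain-architecture annotation for CAMTA proteins. The CG-1/TIG/ANK hits
# are ingested from hmmscan per-domain tabular output (the HMM search itself
# is upstream of this package); the calmodulin-binding domain, the
# calmodulin-binding functional motif, the IQ motif and the bipartite NLS
# are located by consensus/pattern matching; the CaMBD amphipathic helix is
# quantified by the Eisenberg hydrophobic moment on an 18-residue window.

# Eisenberg consensus hydrophobicity scale (dimensionless).
EISENBERG_SCALE <- c(
  I = 0.73, F = 0.61, V = 0.54, L = 0.53, W = 0.37, M = 0.26, A = 0.25,
  G = 0.16, C = 0.04, Y = 0.02, P = -0.07, T = -0.18, S = -0.26, H = -0.40,
  E = -0.62, N = -0.64, Q = -0.69, D = -0.72, K = -1.10, R = -1.76
)

# 22-position degenerate consensus of the CAMTA calmodulin-binding domain;
# bracketed positions are allowed residue sets.
CAMBD_CONSENSUS <- list(
  "W", "S", "V", "G", c("I", "V"), "L", "E", "K", c("V", "A"), c("I", "V"),
  "L", "R", "W", "R", "R", "K", c("G", "R"), c("S", "K"), "G", "L", "R", "G"
)

domain_annotation <- function(protein_id, domain_name, start, end, evidence,
                              score = NA_real_, note = NA_character_) {
  data.frame(protein_id = protein_id, domain_name = domain_name,
             start = as.integer(start), end = as.integer(end),
             evidence = evidence, score = score, note = note,
             stringsAsFactors = FALSE)
}

empty_annotation <- function() {
  domain_annotation(character(0), character(0), integer(0), integer(0),
                    character(0), numeric(0), character(0))
}

sort_annotations <- function(ann) {
  ann[order(ann$protein_id, ann$start, ann$end), , drop = FALSE]
}

#' Read hmmscan per-domain tabular output
#'
#' Parses hmmscan `--domtblout` files into domain annotations using the
#' alignment (ali) coordinate columns. Comment lines starting with `#` are
#' skipped.
#'
#' @param path Path to a domtblout file.
#' @return Data.frame of domain annotations (protein_id, domain_name, start,
#'   end, evidence = "hmm", score) sorted by protein and start.
#' @export
read_domtblout <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  if (!any(keep)) return(empty_annotation())
  idx <- which(keep)
  rows <- lapply(idx, function(i) {
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    # domtblout has 22 fixed columns + free-text description
    if (length(fields) < 22L) {
      stop("malformed domtblout line ", i, ": expected >= 22 fields, got ",
           length(fields))
    }
    ali_from <- suppressWarnings(as.integer(fields[18]))
    ali_to <- suppressWarnings(as.integer(fields[19]))
    score <- suppressWarnings(as.numeric(fields[14]))
    if (is.na(ali_from) || is.na(ali_to)) {
      stop("malformed domtblout line ", i, ": non-numeric ali coordinates")
    }
    domain_annotation(protein_id = fields[4], domain_name = fields[1],
                      start = ali_from, end = ali_to, evidence = "hmm",
                      score = score)
  })
  sort_annotations(do.call(rbind, rows))
}

match_consensus <- function(chars, consensus, max_mismatch) {
  k <- length(consensus)
  n <- length(chars)
  if (n < k) return(list(starts = integer(0), mismatches = integer(0)))
  starts <- integer(0)
  mism <- integer(0)
  for (s in seq_len(n - k + 1L)) {
    m <- 0L
    for (j in seq_len(k)) {
      if (!(chars[s + j - 1L] %in% consensus[[j]])) m <- m + 1L
      if (m > max_mismatch) break
    }
    if (m <= max_mismatch) {
      starts <- c(starts, s)
      mism <- c(mism, m)
    }
  }
  list(starts = starts, mismatches = mism)
}

#' Find the calmodulin-binding domain by degenerate consensus
#'
#' Scans a protein for the 22-position CAMTA CaMBD consensus
#' `WSVG[IV]LEK[VA][IV]LRWRRK[GR][SK]GLRG`, allowing up to `max_mismatch`
#' mismatching positions. Overlapping hits are all reported; the mismatch
#' count is returned as the score.
#'
#' @param sequence Protein sequence (canonical letters).
#' @param protein_id Identifier used in the output annotation.
#' @param max_mismatch Maximum number of consensus positions allowed to
#'   mismatch (default 2; the family consensus is near- but not fully
#'   identical across members).
#' @return Data.frame of domain annotations with `domain_name = "CaMBD"`,
#'   `evidence = "consensus"` and the mismatch count in `score`.
#' @export
find_cambd <- function(sequence, protein_id = "protein", max_mismatch = 2) {
  chars <- assert_protein_sequence(sequence)
  hits <- match_consensus(chars, CAMBD_CONSENSUS, max_mismatch)
  if (!length(hits$starts)) return(empty_annotation())
  k <- length(CAMBD_CONSENSUS)
  sort_annotations(domain_annotation(
    protein_id = protein_id, domain_name = "CaMBD", start = hits$starts,
    end = hits$starts + k - 1L, evidence = "consensus",
    score = as.numeric(hits$mismatches)
  ))
}

all_regex_hits <- function(sequence, pattern, width = NULL) {
  # overlapping matches via lookahead-free manual scan
  chars_n <- nchar(sequence)
  starts <- integer(0)
  ends <- integer(0)
  from <- 1L
  repeat {
    m <- regexpr(pattern, substr(sequence, from, chars_n), perl = TRUE)
    if (m == -1L) break
    s <- from + as.integer(m) - 1L
    w <- if (is.null(width)) attr(m, "match.length") else width
    starts <- c(starts, s)
    ends <- c(ends, s + w - 1L)
    from <- s + 1L  # allow overlaps
  }
  list(starts = starts, ends = ends)
}

#' Find the calmodulin-binding functional motif
#'
#' Exact pattern matches of the CaM-binding functional motif
#' `WXVX(2)LXKX(2)[LF]RWRX[KR]X(3)[FL]RX` (X = any residue). Overlapping
#' matches are all reported.
#'
#' @inheritParams find_cambd
#' @return Data.frame of annotations with `domain_name = "CaM-motif"`.
#' @export
find_functional_cam_motif <- function(sequence, protein_id = "protein") {
  assert_protein_sequence(sequence)
  pattern <- "W.V.{2}L.K.{2}[LF]RWR.[KR].{3}[FL]R."
  hits <- all_regex_hits(sequence, pattern, width = 22L)
  if (!length(hits$starts)) return(empty_annotation())
  sort_annotations(domain_annotation(
    protein_id = protein_id, domain_name = "CaM-motif", start = hits$starts,
    end = hits$ends, evidence = "consensus"
  ))
}

#' Find bipartite nuclear localization signals
#'
#' Matches the classical bipartite NLS rule: two adjacent basic residues
#' (K/R), a spacer of 10--12 arbitrary residues, then at least 3 basic
#' residues within the next 5 positions. This classical rule is a stand-in
#' for server-based NLS prediction and is flagged as such in the `note`
#' column. One hit is reported per start position (the shortest matching
#' spacer).
#'
#' @inheritParams find_cambd
#' @return Data.frame of annotations with `domain_name = "NLS"`.
#' @export
find_bipartite_nls <- function(sequence, protein_id = "protein") {
  chars <- assert_protein_sequence(sequence)
  n <- length(chars)
  basic <- chars %in% c("K", "R")
  starts <- integer(0)
  ends <- integer(0)
  for (s in seq_len(max(0L, n - 1L))) {
    if (!(basic[s] && basic[s + 1L])) next
    for (spacer in 10:12) {
      w_start <- s + 2L + spacer
      w_end <- w_start + 4L
      if (w_end > n) next
      if (sum(basic[w_start:w_end]) >= 3L) {
        starts <- c(starts, s)
        ends <- c(ends, w_end)
        break
      }
    }
  }
  if (!length(starts)) return(empty_annotation())
  sort_annotations(domain_annotation(
    protein_id = protein_id, domain_name = "NLS", start = starts, end = ends,
    evidence = "consensus", note = "classical bipartite rule"
  ))
}

#' Find IQ motifs
#'
#' Matches the conventional IQ calmodulin-interaction pattern
#' `[FILV]Qxxx[RK]Gxxx[RK]xx[FILVWY]`. Overlapping matches are all reported.
#'
#' @inheritParams find_cambd
#' @return Data.frame of annotations with `domain_name = "IQ"`.
#' @export
find_iq_motif <- function(sequence, protein_id = "protein") {
  assert_protein_sequence(sequence)
  pattern <- "[FILV]Q.{3}[RK]G.{3}[RK].{2}[FILVWY]"
  hits <- all_regex_hits(sequence, pattern, width = 14L)
  if (!length(hits$starts)) return(empty_annotation())
  sort_annotations(domain_annotation(
    protein_id = protein_id, domain_name = "IQ", start = hits$starts,
    end = hits$ends, evidence = "consensus"
  ))
}

#' Hydrophobic moment of an 18-residue helix window
#'
#' Computes the Eisenberg hydrophobic moment of an 18-residue window mapped
#' onto an ideal alpha-helix (default 100 degrees per residue): the magnitude
#' of the vector sum of per-residue hydrophobicities at successive wheel
#' angles. Residues whose wheel angle lies within 90 degrees of the resultant
#' vector are reported as the hydrophobic (apolar) face.
#'
#' @param window 18-residue amino-acid string.
#' @param angle_deg Rotation per residue in degrees (default 100, the ideal
#'   alpha-helix).
#' @return List with `window`, `hydrophobic_moment` (dimensionless, >= 0),
#'   `moment_angle_deg`, and `hydrophobic_face` (1-based window positions on
#'   the apolar face).
#' @export
hydrophobic_moment <- function(window, angle_deg = 100) {
  chars <- assert_protein_sequence(window, what = "window")
  if (length(chars) != 18L) {
    stop("window must be exactly 18 residues, got ", length(chars))
  }
  h <- EISENBERG_SCALE[chars]
  theta <- (seq_along(chars) - 1L) * angle_deg * pi / 180
  mx <- sum(h * cos(theta))
  my <- sum(h * sin(theta))
  mu <- sqrt(mx^2 + my^2)
  face <- integer(0)
  moment_angle <- NA_real_
  if (mu > 1e-12) {
    moment_angle <- atan2(my, mx)
    delta <- (theta - moment_angle + pi) %% (2 * pi) - pi
    face <- which(abs(delta) <= pi / 2)
  }
  list(window = window,
       hydrophobic_moment = mu,
       moment_angle_deg = if (is.na(moment_angle)) NA_real_ else
         (moment_angle * 180 / pi) %% 360,
       hydrophobic_face = face)
}

#' Classify a CAMTA domain architecture
#'
#' Classifies one protein's domain complement: `canonical` if CG-1, TIG,
#' ANK, IQ and CaMBD are all present; `non-TIG` if everything but TIG is
#' present; otherwise `incomplete` with the list of missing domains.
#' Classification is independent of the order of the input annotations.
#'
#' @param domains Data.frame of domain annotations for one protein (as from
#'   the find/read functions; domain names matched case-insensitively,
#'   ankyrin hits may be named `ANK` or `Ank`).
#' @param protein_id Identifier reported in the result.
#' @return List with `protein_id`, `class` and `missing`.
#' @export
classify_architecture <- function(domains, protein_id = "protein") {
  required <- c("CG-1", "TIG", "ANK", "IQ", "CaMBD")
  present_raw <- unique(toupper(domains$domain_name))
  present <- required[toupper(required) %in% present_raw]
  missing <- setdiff(required, present)
  class <- if (!length(missing)) {
    "canonical"
  } else if (identical(missing, "TIG")) {
    "non-TIG"
  } else {
    "incomplete"
  }
  list(protein_id = protein_id, class = class, missing = missing)
}

#' Annotate one protein with all consensus-based CAMTA features
#'
#' Convenience wrapper running [find_cambd()], [find_functional_cam_motif()],
#' [find_iq_motif()] and [find_bipartite_nls()] on one sequence.
#'
#' @inheritParams find_cambd
#' @return Combined annotation data.frame sorted by start.
#' @export
annotate_consensus_domains <- function(sequence, protein_id = "protein",
                                       max_mismatch = 2) {
  sort_annotations(rbind(
    find_cambd(sequence, protein_id, max_mismatch),
    find_functional_cam_motif(sequence, protein_id),
    find_iq_motif(sequence, protein_id),
    find_bipartite_nls(sequence, protein_id)
  ))
}
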