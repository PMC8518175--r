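# Seeded synthetic-data generator. Emits every input the pipeline consumes
# (genome scaffolds, GFF3 gene models, CDS/protein FASTA, motif-planted
# promoters, RNA-seq count matrices, qPCR Ct tables) together with a truth
# bundle, so each downstream stage can be tested against known ground truth
# without any external download. All randomness flows from the config seed.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

iupac_to_regex <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(unique(chars), names(IUPAC_SETS))
  if (length(bad)) {
    stop("invalid IUPAC letter(s) in motif: ", paste(bad, collapse = ", "))
  }
  paste(vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1)), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Overlapping forward-strand match starts (1-based) of an IUPAC motif,
# regex-based; used by the generator as a matcher independent of the
# Biostrings-based scanner module.
regex_match_starts <- function(seq, pattern) {
  rex <- paste0("(?=", iupac_to_regex(pattern), ")")
  hits <- gregexpr(rex, seq, perl = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

regex_match_both <- function(seq, pattern) {
  k <- nchar(pattern)
  L <- nchar(seq)
  fwd <- regex_match_starts(seq, pattern)
  rc <- regex_match_starts(revcomp_chr(seq), pattern)
  rev <- if (length(rc)) sort(L - (rc + k - 1L) + 1L) else integer(0)
  list(fwd = fwd, rev = rev)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)


sample_range <- function(lo, hi) {
  if (lo >= hi) lo else sample(seq(lo, hi), 1L)
}

random_cds <- function(n_codons) {
  stopifnot(n_codons >= 3)
  paste0("ATG",
         paste(sample(SENSE_CODONS, n_codons - 2L, replace = TRUE),
               collapse = ""),
         sample(STOP_CODONS, 1L))
}

#' Synthetic gene-family configuration
#'
#' Bundles and validates every parameter of the synthetic-data generator.
#' The defaults emulate the durian CAMTA study conditions: 10 genes with
#' 12--13 exons, 1000 bp promoters, five paralog pairs under purifying
#' selection with synonymous divergence spanning duplication dates of about
#' 14.6--18 MYA at the eudicot clock rate.
#'
#' @param seed Integer seed; required (no hidden global randomness).
#' @param n_genes Number of genes.
#' @param exon_range Integer range of exons per gene (default 12--13).
#' @param scaffold_count Number of scaffolds genes are distributed over.
#' @param promoter_len Promoter length in bp (default 1000).
#' @param cds_codon_range Range of CDS lengths in codons (incl. stop).
#' @param intron_range Range of intron lengths in bp.
#' @param paralog_specs Data.frame with columns `target_ka`, `target_ks`
#'   (substitutions per nonsynonymous/synonymous site) defining the planted
#'   paralog pairs; the first `2 * nrow` genes form the pairs.
#' @param motif_plant_specs Optional list of lists with fields `genes`
#'   (gene indices), `motif` (IUPAC string), `n` (occurrences per promoter)
#'   and `strand` (`"+"` or `"-"`).
#' @param minus_strand_frac Fraction of genes placed on the minus strand.
#' @param scaffold_len Optional fixed scaffold length; scaffolds are padded
#'   to it, and a gene that does not fit is rejected with an error.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(seed,
                         n_genes = 10L,
                         exon_range = c(12L, 13L),
                         scaffold_count = 8L,
                         promoter_len = 1000L,
                         cds_codon_range = c(892L, 1084L),
                         intron_range = c(80L, 300L),
                         paralog_specs = NULL,
                         motif_plant_specs = NULL,
                         minus_strand_frac = 0.4,
                         scaffold_len = NULL) {
  if (missing(seed) || is.null(seed)) stop("seed is required")
  if (n_genes < 1L) stop("n_genes must be >= 1")
  if (any(exon_range < 1L)) stop("exon counts must be >= 1")
  if (promoter_len <= 0L) stop("promoter_len must be > 0")
  if (is.null(paralog_specs)) {
    # study conditions: five pairs, dates spanning 14.64-17.95 MYA at
    # lambda = 6.1e-9, Ka/Ks ~ 0.3 (purifying)
    ks <- 2 * 6.1e-9 * c(14.64, 15.5, 16.3, 17.1, 17.95) * 1e6
    paralog_specs <- data.frame(target_ka = 0.3 * ks, target_ks = ks)
  }
  stopifnot(is.data.frame(paralog_specs),
            all(c("target_ka", "target_ks") %in% names(paralog_specs)))
  if (any(paralog_specs$target_ka < 0) || any(paralog_specs$target_ks < 0)) {
    stop("paralog targets must be nonnegative")
  }
  if (2L * nrow(paralog_specs) > n_genes) {
    stop("paralog_specs require ", 2L * nrow(paralog_specs),
         " genes but n_genes is ", n_genes)
  }
  if (!is.null(motif_plant_specs)) {
    for (sp in motif_plant_specs) {
      iupac_to_regex(sp$motif)  # validates letters
      stopifnot(sp$n >= 0, all(sp$genes >= 1), all(sp$genes <= n_genes))
    }
  }
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 exon_range = as.integer(exon_range),
                 scaffold_count = as.integer(scaffold_count),
                 promoter_len = as.integer(promoter_len),
                 cds_codon_range = as.integer(cds_codon_range),
                 intron_range = as.integer(intron_range),
                 paralog_specs = paralog_specs,
                 motif_plant_specs = motif_plant_specs,
                 minus_strand_frac = minus_strand_frac,
                 scaffold_len = scaffold_len),
            class = "synth_config")
}

#' Introduce targeted synonymous/nonsynonymous divergence into a CDS
#'
#' Applies random point substitutions to a valid ORF, classifying each
#' substitution as synonymous or nonsynonymous against the universal code
#' at the moment of introduction, until the realized per-site proportions
#' meet the targets (to within rounding to whole substitutions). Stop
#' codons are never created and the terminal stop is never touched.
#'
#' @param cds A valid ORF (starts ATG, ends with a stop, no internal stop).
#' @param target_ka,target_ks Target substitutions per nonsynonymous /
#'   synonymous site (NG86 site counting).
#' @param seed Integer seed.
#' @return List with `cds` (mutated), and realized counts: `syn_events`,
#'   `nonsyn_events`, `syn_sites`, `nonsyn_sites`, `realized_ks`,
#'   `realized_ka` (events per site of the original sequence).
#' @export
mutate_paralog <- function(cds, target_ka, target_ks, seed) {
  codons <- split_codons(cds)
  if (codons[1] != "ATG") stop("CDS must start with ATG")
  if (!(codons[length(codons)] %in% STOP_CODONS)) {
    stop("CDS must end with a stop codon")
  }
  translate_cds(cds)  # validates no internal stop
  if (target_ka < 0 || target_ks < 0) stop("targets must be nonnegative")
  if (target_ks >= 0.75) stop("impossible target: synonymous class saturates")
  if (target_ka >= 0.75) stop("impossible target: nonsynonymous class saturates")
  body <- codons[-length(codons)]
  s_sites <- vapply(body, ng86_codon_syn_sites, numeric(1))
  S <- sum(s_sites)
  N <- 3 * length(body) - S
  syn_target <- round(target_ks * S)
  nonsyn_target <- round(target_ka * N)
  with_seed(seed, {
    cur <- body
    syn_done <- 0L
    nonsyn_done <- 0L
    attempts <- 0L
    max_attempts <- 2000L * (syn_target + nonsyn_target + 1L)
    while (syn_done < syn_target || nonsyn_done < nonsyn_target) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        limiting <- if (syn_done < syn_target) "synonymous" else "nonsynonymous"
        stop("impossible target: could not place required ", limiting,
             " substitutions")
      }
      ci <- sample.int(length(cur), 1L)
      pos <- sample.int(3L, 1L)
      chars <- strsplit(cur[ci], "")[[1]]
      new_base <- sample(setdiff(c("A", "C", "G", "T"), chars[pos]), 1L)
      chars[pos] <- new_base
      new_codon <- paste(chars, collapse = "")
      if (new_codon %in% STOP_CODONS) next
      syn <- Biostrings::GENETIC_CODE[[cur[ci]]] ==
        Biostrings::GENETIC_CODE[[new_codon]]
      if (syn && syn_done < syn_target) {
        cur[ci] <- new_codon
        syn_done <- syn_done + 1L
      } else if (!syn && nonsyn_done < nonsyn_target) {
        cur[ci] <- new_codon
        nonsyn_done <- nonsyn_done + 1L
      }
    }
    list(cds = paste0(paste(cur, collapse = ""), codons[length(codons)]),
         syn_events = syn_done, nonsyn_events = nonsyn_done,
         syn_sites = S, nonsyn_sites = N,
         realized_ks = if (S > 0) syn_done / S else 0,
         realized_ka = if (N > 0) nonsyn_done / N else 0)
  })
}

#' Plant IUPAC motif occurrences into promoter sequences
#'
#' Scrubs each promoter of accidental occurrences (both strands) of every
#' motif in the plant specification by resampling offending windows, then plants the
#' requested number of non-overlapping concrete instantiations, so that a
#' both-strand scanner recovers exactly the planted counts.
#'
#' @param promoters Named character vector of promoter sequences.
#' @param specs List of lists with fields `genes` (names into `promoters`),
#'   `motif` (IUPAC string), `n` (occurrences per promoter) and `strand`
#'   (`"+"` plants the word itself, `"-"` its reverse complement).
#' @param seed Integer seed.
#' @return List with `promoters` (modified) and `truth`: a data.frame
#'   (gene, motif, strand, start) of planted occurrences, `start` being the
#'   1-based forward-coordinate start.
#' @export
plant_promoter_motifs <- function(promoters, specs, seed) {
  stopifnot(!is.null(names(promoters)))
  for (sp in specs) iupac_to_regex(sp$motif)
  motifs <- unique(vapply(specs, `[[`, character(1), "motif"))
  with_seed(seed, {
    truth <- list()
    for (gene in names(promoters)) {
      gene_specs <- Filter(function(sp) gene %in% sp$genes, specs)
      for (retry in 1:100) {
        seqv <- strsplit(promoters[[gene]], "")[[1]]
        # scrub accidental occurrences of every motif, both strands
        for (pass in 1:1000) {
          seq <- paste(seqv, collapse = "")
          dirty <- FALSE
          for (m in motifs) {
            hits <- regex_match_both(seq, m)
            for (s in c(hits$fwd, hits$rev)) {
              idx <- s:(s + nchar(m) - 1L)
              seqv[idx] <- sample(c("A", "C", "G", "T"), length(idx),
                                  replace = TRUE)
              dirty <- TRUE
            }
          }
          if (!dirty) break
          if (pass == 1000) stop("could not scrub promoter of ", gene)
        }
        # plant
        planted <- data.frame(gene = character(0), motif = character(0),
                              strand = character(0), start = integer(0))
        occupied <- integer(0)
        ok <- TRUE
        for (sp in gene_specs) {
          if (sp$n == 0) next
          k <- nchar(sp$motif)
          words <- expand_iupac(sp$motif)
          for (i in seq_len(sp$n)) {
            placed <- FALSE
            for (tries in 1:200) {
              start <- sample.int(length(seqv) - k + 1L, 1L)
              span <- start:(start + k - 1L)
              if (length(intersect(span, occupied))) next
              word <- sample(words, 1L)
              insert <- if (identical(sp$strand, "-")) revcomp_chr(word) else word
              seqv[span] <- strsplit(insert, "")[[1]]
              occupied <- c(occupied, span)
              planted <- rbind(planted, data.frame(
                gene = gene, motif = sp$motif,
                strand = sp$strand %||% "+", start = start,
                stringsAsFactors = FALSE))
              placed <- TRUE
              break
            }
            if (!placed) {
              stop("could not place ", sp$n, " occurrences of ", sp$motif,
                   " in the promoter of ", gene, " without overlap")
            }
          }
        }
        # verify: per motif, both-strand counts equal planted counts
        seq <- paste(seqv, collapse = "")
        for (m in motifs) {
          hits <- regex_match_both(seq, m)
          want_f <- sum(planted$motif == m & planted$strand == "+")
          want_r <- sum(planted$motif == m & planted$strand == "-")
          if (length(hits$fwd) != want_f || length(hits$rev) != want_r) {
            ok <- FALSE
            break
          }
        }
        if (ok) {
          promoters[[gene]] <- seq
          truth[[gene]] <- planted
          break
        }
        if (retry == 100) stop("could not realize planted counts for ", gene)
      }
    }
    truth_df <- do.call(rbind, unname(truth)) %||%
      data.frame(gene = character(0), motif = character(0),
                 strand = character(0), start = integer(0))
    rownames(truth_df) <- NULL
    list(promoters = promoters, truth = truth_df)
  })
}

#' Generate a synthetic gene family with genome, models and truth
#'
#' Builds a full synthetic input set: paralog pairs with controlled
#' synonymous/nonsynonymous divergence, multi-exon gene models embedded on
#' scaffolds (both strands), motif-planted promoters upstream of each TSS,
#' and the matching CDS/protein sets. Every planted quantity is recorded in
#' the returned truth bundle.
#'
#' @param config A [synth_config()].
#' @return List with `scaffolds` (named character), `models` (named list of
#'   `gene_model`), `cds`, `proteins` (named character), `promoters`
#'   (named character, coding-strand orientation), and `truth` (paralog
#'   realized counts, planted motif positions, strand assignments).
#' @export
make_gene_family <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  P <- nrow(config$paralog_specs)
  gene_ids <- sprintf("syng%02d", seq_len(config$n_genes))
  with_seed(config$seed, {
    # coding sequences: P mutated pairs + independent singletons
    cds <- character(config$n_genes)
    names(cds) <- gene_ids
    pair_truth <- list()
    for (p in seq_len(P)) {
      n_codons <- sample_range(config$cds_codon_range[1],
                               config$cds_codon_range[2])
      anc <- random_cds(n_codons)
      mut <- mutate_paralog(anc, config$paralog_specs$target_ka[p],
                            config$paralog_specs$target_ks[p],
                            seed = sample.int(2^30, 1L))
      a <- 2L * p - 1L
      b <- 2L * p
      cds[a] <- anc
      cds[b] <- mut$cds
      pair_truth[[p]] <- data.frame(
        gene_a = gene_ids[a], gene_b = gene_ids[b],
        target_ka = config$paralog_specs$target_ka[p],
        target_ks = config$paralog_specs$target_ks[p],
        syn_events = mut$syn_events, nonsyn_events = mut$nonsyn_events,
        syn_sites = mut$syn_sites, nonsyn_sites = mut$nonsyn_sites,
        realized_ks = mut$realized_ks, realized_ka = mut$realized_ka,
        stringsAsFactors = FALSE)
    }
    for (i in seq((2L * P + 1L), length.out = config$n_genes - 2L * P)) {
      n_codons <- sample_range(config$cds_codon_range[1],
                               config$cds_codon_range[2])
      cds[i] <- random_cds(n_codons)
    }
    proteins <- vapply(cds, translate_cds, character(1))

    # promoters (coding-strand orientation), motif planting
    promoters <- vapply(gene_ids, function(g) random_dna(config$promoter_len),
                        character(1))
    motif_truth <- data.frame(gene = character(0), motif = character(0),
                              strand = character(0), start = integer(0))
    if (!is.null(config$motif_plant_specs)) {
      specs <- lapply(config$motif_plant_specs, function(sp) {
        sp$genes <- gene_ids[sp$genes]
        sp
      })
      planted <- plant_promoter_motifs(promoters, specs,
                                       seed = sample.int(2^30, 1L))
      promoters <- planted$promoters
      motif_truth <- planted$truth
    }

    # strand assignment and scaffold layout
    strands <- ifelse(stats::runif(config$n_genes) < config$minus_strand_frac,
                      "-", "+")
    scaffold_of <- ((seq_len(config$n_genes) - 1L) %% config$scaffold_count) + 1L
    scaffold_ids <- sprintf("synscf%02d", seq_len(config$scaffold_count))
    scaffold_seq <- stats::setNames(rep("", config$scaffold_count), scaffold_ids)
    models <- list()
    flank <- 200L
    for (i in seq_len(config$n_genes)) {
      n_exons <- sample_range(config$exon_range[1], config$exon_range[2])
      len_cds <- nchar(cds[i])
      # exon piece lengths >= 10 bp
      repeat {
        cuts <- sort(sample(seq(2L, len_cds - 1L), n_exons - 1L))
        pieces <- diff(c(0L, cuts, len_cds))
        if (all(pieces >= 10L)) break
      }
      introns <- vapply(seq_len(n_exons - 1L), function(k) {
        random_dna(sample_range(config$intron_range[1],
                                config$intron_range[2]))
      }, character(1))
      # assemble gene unit on the coding strand
      unit <- random_dna(flank)
      unit <- paste0(unit, promoters[i])
      exon_rel <- matrix(0L, n_exons, 2L)
      offset <- nchar(unit)
      cds_pos <- 1L
      for (k in seq_len(n_exons)) {
        piece <- substr(cds[i], cds_pos, cds_pos + pieces[k] - 1L)
        exon_rel[k, ] <- c(offset + 1L, offset + pieces[k])
        unit <- paste0(unit, piece)
        offset <- offset + pieces[k]
        cds_pos <- cds_pos + pieces[k]
        if (k < n_exons) {
          unit <- paste0(unit, introns[k])
          offset <- offset + nchar(introns[k])
        }
      }
      unit <- paste0(unit, random_dna(flank))
      unit_len <- nchar(unit)
      if (strands[i] == "-") {
        unit <- revcomp_chr(unit)
        exon_rel <- cbind(unit_len - exon_rel[, 2L] + 1L,
                          unit_len - exon_rel[, 1L] + 1L)
        exon_rel <- exon_rel[order(exon_rel[, 1L]), , drop = FALSE]
      }
      scf <- scaffold_of[i]
      base <- nchar(scaffold_seq[scf])
      spacer <- random_dna(100L)
      scaffold_seq[scf] <- paste0(scaffold_seq[scf], spacer, unit)
      shift <- base + nchar(spacer)
      models[[gene_ids[i]]] <- new_gene_model(
        gene_id = gene_ids[i],
        transcript_id = paste0(gene_ids[i], ".t1"),
        scaffold_id = scaffold_ids[scf], strand = strands[i],
        exons = data.frame(start = exon_rel[, 1L] + shift,
                           end = exon_rel[, 2L] + shift))
    }
    scaffold_seq <- vapply(scaffold_seq, function(s) paste0(s, random_dna(100L)),
                           character(1))
    if (!is.null(config$scaffold_len)) {
      too_long <- nchar(scaffold_seq) > config$scaffold_len
      if (any(too_long)) {
        stop("gene content of ", names(scaffold_seq)[too_long][1],
             " (", nchar(scaffold_seq)[too_long][1],
             " bp) exceeds the configured scaffold length ",
             config$scaffold_len)
      }
      scaffold_seq <- vapply(scaffold_seq, function(s) {
        paste0(s, random_dna(config$scaffold_len - nchar(s)))
      }, character(1))
    }
    pair_df <- do.call(rbind, pair_truth) %||% data.frame()
    list(scaffolds = scaffold_seq, models = models, cds = cds,
         proteins = proteins, promoters = promoters,
         truth = list(pairs = pair_df, motifs = motif_truth,
                      strands = stats::setNames(strands, gene_ids)))
  })
}

#' Simulate an RNA-seq count matrix with planted co-expression structure
#'
#' Hub genes get a latent log2 expression signal (with a group shift from
#' the first to the second sample group); positive/negative partner genes
#' respond linearly to the hub signal with Gaussian noise calibrated to the
#' target Pearson correlation; all genes are then Poisson-sampled with
#' per-sample library-size factors. Non-partner noise genes are
#' independent.
#'
#' @param spec List with fields `n_hubs`, `n_partners_pos`,
#'   `n_partners_neg`, `n_samples` (per group, >= 3), `n_noise`,
#'   `target_r` (|r| < 1), `groups` (2 labels), `hub_shift` (log2 shift of
#'   hubs between groups), `library_size_factors` (length = total samples,
#'   or NULL for all 1), `composition` (optional list(sample, frac, fold)
#'   planting a composition offset into one sample's noise genes).
#' @param seed Integer seed.
#' @return List with `counts` (integer matrix genes x samples), `groups`
#'   (character vector per sample) and `truth` (edges, library factors,
#'   composition genes).
#' @export
simulate_counts <- function(spec, seed) {
  defaults <- list(n_hubs = 2L, n_partners_pos = 30L, n_partners_neg = 30L,
                   n_samples = 3L, n_noise = 500L, target_r = 0.97,
                   groups = c("mature", "ripe"), hub_shift = 2,
                   library_size_factors = NULL, composition = NULL,
                   base_log2 = 8, sample_sd = 1, noise_sd = 0.3)
  spec <- utils::modifyList(defaults, spec %||% list())
  if (spec$n_samples < 3L) stop("n_samples per group must be >= 3")
  if (abs(spec$target_r) >= 1) stop("target_r must lie in (-1, 1)")
  n_samp <- 2L * spec$n_samples
  groups <- rep(spec$groups, each = spec$n_samples)
  sample_ids <- paste0(groups, "_", rep(seq_len(spec$n_samples), 2L))
  lib <- spec$library_size_factors %||% rep(1, n_samp)
  stopifnot(length(lib) == n_samp, all(lib > 0))
  with_seed(seed, {
    rows <- list()
    edges <- list()
    group_shift <- ifelse(groups == spec$groups[2], spec$hub_shift, 0)
    for (h in seq_len(spec$n_hubs)) {
      hub_id <- sprintf("hub%02d", h)
      z <- spec$base_log2 + group_shift +
        stats::rnorm(n_samp, 0, spec$sample_sd)
      rows[[hub_id]] <- z
      zc <- z - mean(z)
      # calibrate partner noise so the OBSERVED log2 correlation (including
      # Poisson shot noise at the baseline mean) meets target_r:
      # r^2 = V^2 / ((V+w)(V+s^2+w))  =>  s^2 = V^2/(r^2 (V+w)) - V - w
      V <- spec$sample_sd^2 + spec$hub_shift^2 / 4
      # E[1/lambda] for log2(lambda) ~ N(base_log2, V): lognormal correction
      w <- (log2(exp(1)))^2 / 2^spec$base_log2 * exp(log(2)^2 * V / 2)
      s2 <- V^2 / (spec$target_r^2 * (V + w)) - V - w
      sd_eps <- sqrt(max(0, s2))
      for (j in seq_len(spec$n_partners_pos)) {
        id <- sprintf("%s.pos%02d", hub_id, j)
        rows[[id]] <- spec$base_log2 + zc + stats::rnorm(n_samp, 0, sd_eps)
        edges[[id]] <- data.frame(hub = hub_id, partner = id, sign = 1,
                                  target_r = spec$target_r)
      }
      for (j in seq_len(spec$n_partners_neg)) {
        id <- sprintf("%s.neg%02d", hub_id, j)
        rows[[id]] <- spec$base_log2 - zc + stats::rnorm(n_samp, 0, sd_eps)
        edges[[id]] <- data.frame(hub = hub_id, partner = id, sign = -1,
                                  target_r = -spec$target_r)
      }
    }
    for (g in seq_len(spec$n_noise)) {
      id <- sprintf("noise%04d", g)
      base <- stats::runif(1, 4, 10)
      # background genes vary between replicate samples with the modest
      # log-scale spread of biological replicates (noise_sd), not with the
      # hub's signal variance
      rows[[id]] <- base + stats::rnorm(n_samp, 0, spec$noise_sd)
    }
    latent <- do.call(rbind, rows)
    colnames(latent) <- sample_ids
    lambda <- 2^latent
    comp_genes <- character(0)
    if (!is.null(spec$composition)) {
      comp <- spec$composition
      noise_ids <- grep("^noise", rownames(lambda), value = TRUE)
      comp_genes <- sample(noise_ids, floor(comp$frac * length(noise_ids)))
      lambda[comp_genes, comp$sample] <- lambda[comp_genes, comp$sample] *
        comp$fold
    }
    lambda <- sweep(lambda, 2L, lib, `*`)
    counts <- matrix(stats::rpois(length(lambda), lambda),
                     nrow = nrow(lambda), dimnames = dimnames(lambda))
    list(counts = counts, groups = groups,
         truth = list(edges = do.call(rbind, unname(edges)) %||%
                        data.frame(),
                      library_size_factors = stats::setNames(lib, sample_ids),
                      composition_genes = comp_genes))
  })
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Reference-gene Ct values are drawn around a fixed baseline; target-gene
#' Ct values are offset by `-log2(fold)` relative to the calibrator group,
#' so the 2^-ddCt method recovers the planted fold changes. With
#' `ct_sd = 0` recovery is exact.
#'
#' @param spec List with fields `true_fold` (matrix genes x groups; the
#'   calibrator column must be 1), `groups` (column names; first is the
#'   calibrator), `reference` (reference gene id), `n_bio`, `n_tech`,
#'   `ct_sd`, `ref_ct` (baseline reference Ct), `base_dct` (baseline
#'   target-minus-reference Ct).
#' @param seed Integer seed.
#' @return List with `ct_table` (data.frame: sample_group, biological_rep,
#'   technical_rep, gene_id, ct) and `truth` (the fold matrix).
#' @export
simulate_qpcr <- function(spec, seed) {
  defaults <- list(groups = c("M", "MR", "R"), reference = "EF1a",
                   n_bio = 3L, n_tech = 3L, ct_sd = 0.2,
                   ref_ct = 20, base_dct = 2, true_fold = NULL)
  spec <- utils::modifyList(defaults, spec %||% list())
  if (is.null(spec$reference) || !nzchar(spec$reference)) {
    stop("spec must name a reference gene")
  }
  if (spec$ct_sd < 0) stop("ct_sd must be >= 0")
  if (is.null(spec$true_fold)) {
    spec$true_fold <- rbind(
      geneA = c(1, 3, 8),
      geneB = c(1, 2, 6),
      geneC = c(1, 0.6, 0.3))
    colnames(spec$true_fold) <- spec$groups
  }
  stopifnot(ncol(spec$true_fold) == length(spec$groups),
            all(spec$true_fold > 0),
            all(spec$true_fold[, 1] == 1))
  colnames(spec$true_fold) <- spec$groups
  with_seed(seed, {
    rows <- list()
    for (g in spec$groups) {
      for (b in seq_len(spec$n_bio)) {
        for (tech in seq_len(spec$n_tech)) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample_group = g, biological_rep = b, technical_rep = tech,
            gene_id = spec$reference,
            ct = spec$ref_ct + stats::rnorm(1, 0, spec$ct_sd))
          for (gene in rownames(spec$true_fold)) {
            rows[[length(rows) + 1L]] <- data.frame(
              sample_group = g, biological_rep = b, technical_rep = tech,
              gene_id = gene,
              ct = spec$ref_ct + spec$base_dct -
                log2(spec$true_fold[gene, g]) +
                stats::rnorm(1, 0, spec$ct_sd))
          }
        }
      }
    }
    list(ct_table = do.call(rbind, rows), truth = spec$true_fold)
  })
}
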