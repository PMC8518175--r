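# Orchestration: write a complete synthetic demo input set, and run the
# characterization stages in dependency order over an input directory,
# emitting per-stage TSVs plus a JSON run summary. Stage order:
# props -> domains -> structure -> paralogs -> phylo -> promoters ->
# coexpression -> qpcr.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a complete synthetic demo input set
#'
#' Generates a synthetic gene family, count matrix and Ct table with known
#' ground truth and writes every file the pipeline consumes: genome FASTA,
#' GFF3 gene models, CDS/protein FASTA, count matrix TSV, Ct table TSV and
#' a truth JSON.
#'
#' @param dir Output directory (created if needed).
#' @param config A [synth_config()]; the default plants the two CAMTA
#'   recognition motifs at different per-set frequencies in the first and
#'   second half of the gene family.
#' @param expression_spec,qpcr_spec Passed to [simulate_counts()] and
#'   [simulate_qpcr()] (seeds are derived from `config$seed`).
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
make_demo <- function(dir, config = NULL, expression_spec = NULL,
                      qpcr_spec = NULL) {
  if (is.null(config)) {
    config <- synth_config(
      seed = 20211014L,
      motif_plant_specs = list(
        list(genes = 1:5, motif = "MCGTGT", n = 3, strand = "+"),
        list(genes = 1:5, motif = "MCGCGB", n = 1, strand = "+"),
        list(genes = 6:10, motif = "MCGTGT", n = 1, strand = "+")))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fam <- make_gene_family(config)
  counts_sim <- simulate_counts(expression_spec,
                                seed = child_seed(config$seed, 1L))
  qpcr_sim <- simulate_qpcr(qpcr_spec, seed = child_seed(config$seed, 2L))
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    gff3 = file.path(dir, "genes.gff3"),
    cds = file.path(dir, "cds.fa"),
    proteins = file.path(dir, "proteins.fa"),
    counts = file.path(dir, "counts.tsv"),
    ct_table = file.path(dir, "ct_table.tsv"),
    truth = file.path(dir, "truth.json"))
  write_fasta(fam$scaffolds, paths$genome, type = "dna")
  write_gff3(fam$models, paths$gff3,
             scaffold_lengths = nchar(fam$scaffolds))
  write_fasta(fam$cds, paths$cds, type = "dna")
  write_fasta(fam$proteins, paths$proteins, type = "protein")
  counts_df <- data.frame(gene_id = rownames(counts_sim$counts),
                          counts_sim$counts, check.names = FALSE)
  write_tsv(counts_df, paths$counts)
  write_tsv(qpcr_sim$ct_table, paths$ct_table)
  truth <- list(seed = config$seed,
                pairs = fam$truth$pairs,
                motifs = fam$truth$motifs,
                strands = as.list(fam$truth$strands),
                edges = counts_sim$truth$edges,
                groups = counts_sim$groups,
                library_size_factors =
                  as.list(counts_sim$truth$library_size_factors),
                qpcr_true_fold = data.frame(gene = rownames(qpcr_sim$truth),
                                            qpcr_sim$truth,
                                            check.names = FALSE))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(list(config = config, family = fam, counts = counts_sim,
                 qpcr = qpcr_sim, paths = paths))
}

#' Run the full characterization pipeline over an input directory
#'
#' Executes the enabled stages in dependency order over the files written
#' by [make_demo()] (or equivalently structured real inputs), writing one
#' TSV per stage plus a JSON run summary into `out_dir`.
#'
#' @param input_dir Directory holding `genome.fa`, `genes.gff3`, `cds.fa`,
#'   `proteins.fa`, `counts.tsv`, `ct_table.tsv`.
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector of stages to run; any of `props`,
#'   `domains`, `structure`, `paralogs`, `phylo`, `promoters`,
#'   `coexpression`, `qpcr`.
#' @param params List of parameter overrides: `promoter_len` (1000),
#'   `min_identity`/`min_coverage` (70), `lam` (6.1e-9), `r_pos` (0.95),
#'   `r_neg` (-0.95), `hub_ids` (default: the two most highly expressed
#'   genes), `qpcr_reference` ("EF1a"), `qpcr_calibrator` (first group),
#'   `groups` (sample-to-group map inferred from sample names).
#' @param domtblout Optional hmmscan domtblout path merged into the domain
#'   stage.
#' @return List of per-stage results; written files are listed in the
#'   `summary` element.
#' @export
run_camta_pipeline <- function(input_dir, out_dir,
                               stages = c("props", "domains", "structure",
                                          "paralogs", "phylo", "promoters",
                                          "coexpression", "qpcr"),
                               params = list(), domtblout = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  defaults <- list(promoter_len = 1000L, min_identity = 70,
                   min_coverage = 70, lam = 6.1e-9, r_pos = 0.95,
                   r_neg = -0.95, hub_ids = NULL,
                   qpcr_reference = "EF1a", qpcr_calibrator = NULL,
                   max_mismatch = 2)
  params <- utils::modifyList(defaults, params)
  results <- list()
  written <- character(0)
  warnings_log <- character(0)
  note <- function(w) warnings_log <<- c(warnings_log, conditionMessage(w))

  proteins <- read_protein_fasta(file.path(input_dir, "proteins.fa"))
  cds <- NULL
  cds_path <- file.path(input_dir, "cds.fa")
  if (file.exists(cds_path)) {
    cds_df <- read_dna_fasta(cds_path)
    cds <- stats::setNames(cds_df$sequence, cds_df$id)
  }

  if ("props" %in% stages) {
    results$props <- physchem_table(proteins)
    written <- c(written, write_tsv(results$props,
                                    file.path(out_dir, "protein_props.tsv")))
  }

  if ("domains" %in% stages) {
    ann <- do.call(rbind, lapply(seq_len(nrow(proteins)), function(i) {
      annotate_consensus_domains(proteins$sequence[i], proteins$id[i],
                                 max_mismatch = params$max_mismatch)
    }))
    if (!is.null(domtblout)) ann <- sort_annotations(rbind(ann, read_domtblout(domtblout)))
    results$domains <- ann
    written <- c(written, write_tsv(ann, file.path(out_dir, "domains.tsv")))
  }

  models <- NULL
  scaffolds <- NULL
  if (any(c("structure", "promoters") %in% stages)) {
    models <- read_gff3(file.path(input_dir, "genes.gff3"))
    genome <- read_dna_fasta(file.path(input_dir, "genome.fa"))
    scaffolds <- stats::setNames(genome$sequence, genome$id)
  }

  if ("structure" %in% stages) {
    stats_rows <- lapply(models, function(m) {
      st <- structure_stats(m)
      data.frame(gene_id = m$gene_id, transcript_id = m$transcript_id,
                 scaffold = m$scaffold_id, strand = m$strand,
                 n_exons = st$n_exons, n_introns = st$n_introns,
                 exon_bp = sum(st$exon_lengths),
                 intron_bp = sum(st$intron_lengths), stringsAsFactors = FALSE)
    })
    results$structure <- do.call(rbind, c(stats_rows,
                                          list(make.row.names = FALSE)))
    written <- c(written, write_tsv(results$structure,
                                    file.path(out_dir, "gene_structure.tsv")))
  }

  if ("paralogs" %in% stages) {
    if (is.null(cds)) stop("paralogs stage requires cds.fa")
    rep <- paralog_report(proteins, cds, params$min_identity,
                          params$min_coverage, params$lam)
    rep$aligned_a <- NULL
    rep$aligned_b <- NULL
    results$paralogs <- rep
    written <- c(written, write_tsv(rep, file.path(out_dir, "paralogs.tsv")))
  }

  if ("phylo" %in% stages) {
    d <- pairwise_distance_from_proteins(proteins, model = "p")
    tree <- withCallingHandlers(neighbor_joining(d),
                                warning = function(w) {
                                  note(w)
                                  invokeRestart("muffleWarning")
                                })
    results$phylo <- tree
    tree_path <- file.path(out_dir, "family_nj.nwk")
    writeLines(c("# neighbor-joining tree on pairwise p-distances (distance-based stand-in for likelihood inference)",
                 write_newick(tree)), tree_path)
    written <- c(written, tree_path)
  }

  if ("promoters" %in% stages) {
    promoters <- withCallingHandlers(
      extract_promoters(models, scaffolds, length = params$promoter_len),
      warning = function(w) {
        note(w)
        invokeRestart("muffleWarning")
      })
    library <- read_motif_library()
    counts_tab <- count_motif_library(promoters, library)
    results$promoter_counts <- counts_tab
    written <- c(written, write_tsv(counts_tab,
                                    file.path(out_dir, "promoter_motifs.tsv")))
    # enrichment of the CAMTA recognition motifs: first half vs second
    # half of the family (the demo's planted contrast)
    genes <- names(promoters)
    half <- ceiling(length(genes) / 2)
    set_a <- genes[seq_len(half)]
    set_b <- setdiff(genes, set_a)
    enr <- lapply(c("CAMTA-CGCG", "CAMTA-CGTG"), function(m) {
      pat <- library$pattern[library$name == m]
      k <- nchar(pat)
      ha <- sum(counts_tab$n_total[counts_tab$motif == m &
                                     counts_tab$gene %in% set_a])
      hb <- sum(counts_tab$n_total[counts_tab$motif == m &
                                     counts_tab$gene %in% set_b])
      fe <- fisher_enrichment(ha, scanned_positions(promoters[set_a], k),
                              hb, scanned_positions(promoters[set_b], k))
      data.frame(motif = m, hits_a = ha, hits_b = hb,
                 odds_ratio = fe$odds_ratio, p = fe$p_two_sided,
                 stringsAsFactors = FALSE)
    })
    results$promoter_enrichment <- do.call(rbind, enr)
    written <- c(written, write_tsv(results$promoter_enrichment,
                                    file.path(out_dir,
                                              "promoter_enrichment.tsv")))
  }

  if ("coexpression" %in% stages) {
    raw <- utils::read.delim(file.path(input_dir, "counts.tsv"),
                             check.names = FALSE)
    counts <- as.matrix(raw[, -1, drop = FALSE])
    rownames(counts) <- raw[[1]]
    norm <- normalize_counts(counts)
    hub_ids <- params$hub_ids %||%
      rownames(counts)[order(rowMeans(counts), decreasing = TRUE)[1:2]]
    partners <- withCallingHandlers(
      correlation_partners(norm, hub_ids, params$r_pos, params$r_neg),
      warning = function(w) {
        note(w)
        invokeRestart("muffleWarning")
      })
    edges <- coexpression_edges(partners)
    results$coexpression <- list(factors = attr(norm, "tmm_factors"),
                                 partners = partners, edges = edges)
    written <- c(written, write_tsv(edges,
                                    file.path(out_dir,
                                              "coexpression_edges.tsv")))
  }

  if ("qpcr" %in% stages) {
    ct <- utils::read.delim(file.path(input_dir, "ct_table.tsv"))
    calib <- params$qpcr_calibrator %||% ct$sample_group[1]
    targets <- setdiff(unique(ct$gene_id), params$qpcr_reference)
    fold <- do.call(rbind, lapply(targets, function(g) {
      delta_delta_ct(ct, g, params$qpcr_reference, calib)
    }))
    results$qpcr <- fold
    written <- c(written, write_tsv(fold,
                                    file.path(out_dir, "qpcr_folds.tsv")))
  }

  summary <- list(package = "camtakit",
                  version = as.character(utils::packageVersion("camtakit")),
                  stages = stages, parameters = params[
                    vapply(params, function(p)
                      is.numeric(p) || is.character(p) || is.null(p),
                      logical(1))],
                  warnings = warnings_log, outputs = basename(written),
                  n_errors = 0L)
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  results$summary <- summary
  invisible(results)
}
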