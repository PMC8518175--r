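# Gene models from GFF3, exon-intron statistics and strand-aware promoter
# intervals. Coordinates are 1-based inclusive throughout (the GFF3 and
# IRanges convention); the BED-style exports subtract 1 from starts at the
# writing boundary only.

new_gene_model <- function(gene_id, transcript_id, scaffold_id, strand,
                           exons, cds_span = NULL) {
  stopifnot(strand %in% c("+", "-"))
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] <= exons$end[-nrow(exons)])) {
    stop("exons of ", transcript_id, " overlap")
  }
  if (any(exons$end < exons$start)) stop("exon with end < start in ", transcript_id)
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 scaffold_id = scaffold_id, strand = strand, exons = exons,
                 cds_span = cds_span %||%
                   c(min(exons$start), max(exons$end))),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$transcript_id, " (", x$gene_id, ") ", x$scaffold_id,
      x$strand, " ", nrow(x$exons), " exon(s), span ",
      min(x$exons$start), "-", max(x$exons$end), "\n", sep = "")
  invisible(x)
}

parse_gff_attributes <- function(attr) {
  fields <- strsplit(attr, ";", fixed = TRUE)[[1]]
  fields <- fields[nzchar(fields)]
  kv <- strsplit(fields, "=", fixed = TRUE)
  stats::setNames(vapply(kv, function(x) paste(x[-1], collapse = "="),
                         character(1)),
                  vapply(kv, `[`, character(1), 1L))
}

gff_attr <- function(attrs, key) {
  if (key %in% names(attrs)) attrs[[key]] else NULL
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon/CDS features linked by `ID=`/`Parent=` attributes
#' into one gene model per mRNA. Coordinates are kept 1-based inclusive.
#'
#' @param path Path to a GFF3 file.
#' @return Named list of `gene_model` objects (one per mRNA, named by
#'   transcript id).
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  feats <- lapply(body, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L) stop("malformed GFF3 line ", i, ": expected 9 columns")
    list(line = i, seqid = f[1], type = f[3],
         start = as.integer(f[4]), end = as.integer(f[5]),
         strand = f[7], attrs = parse_gff_attributes(f[9]))
  })
  types <- vapply(feats, `[[`, character(1), "type")
  genes <- feats[types == "gene"]
  mrnas <- feats[types == "mRNA"]
  exons <- feats[types == "exon"]
  cdss <- feats[types == "CDS"]
  gene_span <- stats::setNames(
    lapply(genes, function(g) c(g$start, g$end)),
    vapply(genes, function(g) gff_attr(g$attrs, "ID") %||% NA_character_, character(1)))
  models <- list()
  for (m in mrnas) {
    mid <- gff_attr(m$attrs, "ID")
    parent <- gff_attr(m$attrs, "Parent")
    if (is.null(parent)) {
      stop("mRNA without Parent at GFF3 line ", m$line)
    }
    my_exons <- Filter(function(e) {
      p <- gff_attr(e$attrs, "Parent")
      if (is.null(p)) stop("exon without Parent at GFF3 line ", e$line)
      identical(p, mid)
    }, exons)
    if (!length(my_exons)) stop("mRNA ", mid, " has no exons")
    span <- gene_span[[parent]]
    if (!is.null(span)) {
      for (e in my_exons) {
        if (e$start < span[1] || e$end > span[2]) {
          stop("exon outside its gene span at GFF3 line ", e$line)
        }
      }
    }
    exon_df <- data.frame(
      start = vapply(my_exons, `[[`, integer(1), "start"),
      end = vapply(my_exons, `[[`, integer(1), "end"))
    my_cds <- Filter(function(e) identical(gff_attr(e$attrs, "Parent"), mid), cdss)
    cds_span <- if (length(my_cds)) {
      c(min(vapply(my_cds, `[[`, integer(1), "start")),
        max(vapply(my_cds, `[[`, integer(1), "end")))
    } else {
      NULL
    }
    models[[mid]] <- new_gene_model(
      gene_id = parent, transcript_id = mid, scaffold_id = m$seqid,
      strand = m$strand, exons = exon_df, cds_span = cds_span)
  }
  models
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA, exon and CDS features (1-based inclusive) with
#' `ID=`/`Parent=` attributes. The inverse of [read_gff3()].
#'
#' @param models Named list of `gene_model` objects.
#' @param path Output path.
#' @param scaffold_lengths Optional named integer vector used to emit
#'   `##sequence-region` pragmas.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path, scaffold_lengths = NULL) {
  out <- "##gff-version 3"
  if (!is.null(scaffold_lengths)) {
    out <- c(out, sprintf("##sequence-region %s 1 %d",
                          names(scaffold_lengths), scaffold_lengths))
  }
  for (m in models) {
    span <- c(min(m$exons$start), max(m$exons$end))
    line <- function(type, s, e, attrs) {
      sprintf("%s\tcamtakit\t%s\t%d\t%d\t.\t%s\t.\t%s",
              m$scaffold_id, type, s, e, m$strand, attrs)
    }
    out <- c(out,
             line("gene", span[1], span[2], paste0("ID=", m$gene_id)),
             line("mRNA", span[1], span[2],
                  paste0("ID=", m$transcript_id, ";Parent=", m$gene_id)))
    for (i in seq_len(nrow(m$exons))) {
      out <- c(out,
               line("exon", m$exons$start[i], m$exons$end[i],
                    paste0("ID=", m$transcript_id, ".exon", i,
                           ";Parent=", m$transcript_id)))
    }
    out <- c(out,
             line("CDS", m$cds_span[1], m$cds_span[2],
                  paste0("ID=", m$transcript_id, ".cds;Parent=",
                         m$transcript_id)))
  }
  writeLines(out, path)
  invisible(path)
}

#' Exon-intron structure statistics
#'
#' @param model A `gene_model`.
#' @return List with `n_exons`, `n_introns`, `exon_lengths` and
#'   `intron_lengths` (bp; intron i is the gap between exons i and i+1).
#' @export
structure_stats <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  ex <- model$exons
  exon_lengths <- ex$end - ex$start + 1L
  n <- nrow(ex)
  intron_lengths <- if (n > 1L) ex$start[-1L] - ex$end[-n] - 1L else integer(0)
  if (any(intron_lengths <= 0L)) stop("abutting or overlapping exons")
  list(n_exons = n, n_introns = n - 1L,
       exon_lengths = as.integer(exon_lengths),
       intron_lengths = as.integer(intron_lengths))
}

#' Strand-aware upstream promoter interval
#'
#' Derives the promoter interval of a gene: the `length` bp immediately
#' upstream of the transcription start site (the gene-feature 5' end). For
#' `+` strand genes this is the interval ending just before the gene start;
#' for `-` strand genes it is the forward-coordinate interval starting just
#' after the gene end, with `revcomp = TRUE` flagging that the promoter
#' sequence must be reverse-complemented. Intervals are clipped at scaffold
#' edges; a zero-length result raises a warning and returns an empty
#' interval.
#'
#' @param model A `gene_model`.
#' @param length Promoter length in bp (default 1000).
#' @param scaffold_len Length of the scaffold, used for clipping.
#' @return List with `scaffold_id`, `start`, `end` (1-based inclusive;
#'   `start > end` denotes an empty interval), `strand`, `revcomp`,
#'   `length` (actual, after clipping) and `clipped`.
#' @export
upstream_region <- function(model, length = 1000, scaffold_len) {
  stopifnot(inherits(model, "gene_model"), length > 0)
  span <- c(min(model$exons$start), max(model$exons$end))
  if (span[2] > scaffold_len) stop("gene extends beyond scaffold length")
  if (model$strand == "+") {
    start <- max(1L, span[1] - as.integer(length))
    end <- span[1] - 1L
  } else {
    start <- span[2] + 1L
    end <- min(as.integer(scaffold_len), span[2] + as.integer(length))
  }
  actual <- max(0L, end - start + 1L)
  if (actual == 0L) {
    warning("empty promoter interval for ", model$transcript_id,
            " (gene at scaffold edge)")
  }
  list(scaffold_id = model$scaffold_id,
       start = if (actual) start else 1L,
       end = if (actual) end else 0L,
       strand = model$strand, revcomp = model$strand == "-",
       length = actual, clipped = actual < length)
}

#' Extract promoter sequences for a set of gene models
#'
#' Applies [upstream_region()] to each model and extracts the promoter
#' sequence from the scaffold, reverse-complementing for `-` strand genes so
#' that every promoter reads 5' to 3' toward the gene.
#'
#' @param models Named list of `gene_model` objects.
#' @param scaffolds Named character vector of scaffold sequences.
#' @param length Promoter length in bp.
#' @return Named character vector of promoter sequences (named by gene id;
#'   empty intervals are dropped with a warning from [upstream_region()]).
#' @export
extract_promoters <- function(models, scaffolds, length = 1000) {
  out <- character(0)
  for (m in models) {
    scaff <- scaffolds[[m$scaffold_id]]
    if (is.null(scaff)) stop("scaffold ", m$scaffold_id, " not supplied")
    reg <- upstream_region(m, length = length, scaffold_len = nchar(scaff))
    if (reg$length == 0L) next
    seq <- substr(scaff, reg$start, reg$end)
    if (reg$revcomp) {
      seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    }
    out[[m$gene_id]] <- seq
  }
  out
}
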