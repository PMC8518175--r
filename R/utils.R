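# Internal helpers shared across modules.

.camta_cache <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
extdata_path <- function(file) {
  path <- system.file("extdata", file, package = "camtakit")
  if (!nzchar(path)) {
    # during development (load_all) fall back to the source tree
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) stop("bundled data file not found: ", file)
  path
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package route their randomness through
# this so that results are a pure function of (inputs, seed).
with_seed <- function(seed, code) {
  if (is.null(seed)) stop("a seed is required; no hidden global randomness")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a stream-specific child seed from a master seed; keeps every
# sub-generator deterministic while decoupled from call order.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream) * 16807) %% 2147483399)
}

AA_CANONICAL <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

assert_protein_sequence <- function(sequence, allow_x = FALSE, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    stop(what, " must be a single character string")
  }
  if (!nzchar(sequence)) stop(what, " must be non-empty")
  letters_ok <- AA_CANONICAL
  if (allow_x) letters_ok <- c(letters_ok, "X")
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), letters_ok)
  if (length(bad)) {
    stop(what, " contains non-canonical residue(s): ", paste(bad, collapse = ", "))
  }
  invisible(chars)
}

assert_dna_sequence <- function(sequence, extra = "N", what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      !nzchar(sequence)) {
    stop(what, " must be a single non-empty character string")
  }
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), c("A", "C", "G", "T", strsplit(extra, "")[[1]]))
  if (length(bad)) {
    stop(what, " contains invalid letter(s): ", paste(bad, collapse = ", "))
  }
  invisible(chars)
}
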