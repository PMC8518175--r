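# Independent oracles used to check package computations. Each is written
# directly from the mathematical definition, without calling the package
# code paths it checks.

# --- translation (seqinr code table, independent of Biostrings) ----------

oracle_translate <- function(cds) {
  aa <- seqinr::translate(seqinr::s2c(tolower(cds)))
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

# --- Nei-Gojobori via direct enumeration ---------------------------------

oracle_aa <- function(codon) {
  seqinr::translate(seqinr::s2c(tolower(codon)))
}

oracle_is_stop <- function(codon) oracle_aa(codon) == "*"

oracle_syn_sites <- function(codon) {
  chars <- strsplit(codon, "")[[1]]
  aa <- oracle_aa(codon)
  total <- 0
  for (pos in 1:3) {
    syn <- 0
    sense <- 0
    for (b in setdiff(c("A", "C", "G", "T"), chars[pos])) {
      alt <- chars
      alt[pos] <- b
      alt_codon <- paste(alt, collapse = "")
      if (oracle_is_stop(alt_codon)) next
      sense <- sense + 1
      if (oracle_aa(alt_codon) == aa) syn <- syn + 1
    }
    total <- total + if (sense > 0) syn / sense else 0
  }
  total
}

oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

oracle_codon_diffs <- function(codon_a, codon_b) {
  ca <- strsplit(codon_a, "")[[1]]
  cb <- strsplit(codon_b, "")[[1]]
  pos <- which(ca != cb)
  if (!length(pos)) return(c(sd = 0, nd = 0))
  paths <- list()
  for (ord in oracle_perms(pos)) {
    cur <- ca
    sd <- 0
    nd <- 0
    stopped <- FALSE
    for (p in ord) {
      before <- paste(cur, collapse = "")
      cur[p] <- cb[p]
      after <- paste(cur, collapse = "")
      if (oracle_is_stop(before) || oracle_is_stop(after)) {
        stopped <- TRUE
        nd <- nd + 1
      } else if (oracle_aa(before) == oracle_aa(after)) {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
    }
    paths[[length(paths) + 1]] <- list(sd = sd, nd = nd, stopped = stopped)
  }
  ok <- !vapply(paths, `[[`, logical(1), "stopped")
  use <- if (any(ok)) paths[ok] else paths
  c(sd = mean(vapply(use, `[[`, numeric(1), "sd")),
    nd = mean(vapply(use, `[[`, numeric(1), "nd")))
}

oracle_ng86 <- function(seq_a, seq_b) {
  n <- nchar(seq_a)
  ca <- substring(seq_a, seq(1, n, 3), seq(3, n, 3))
  cb <- substring(seq_b, seq(1, n, 3), seq(3, n, 3))
  keep <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb) &
    !vapply(ca, oracle_is_stop, logical(1)) &
    !vapply(cb, oracle_is_stop, logical(1))
  ca <- ca[keep]
  cb <- cb[keep]
  S <- sum((vapply(ca, oracle_syn_sites, numeric(1)) +
              vapply(cb, oracle_syn_sites, numeric(1))) / 2)
  N <- 3 * length(ca) - S
  d <- mapply(oracle_codon_diffs, ca, cb)
  ps <- sum(d["sd", ]) / S
  pn <- sum(d["nd", ]) / N
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  list(ks = jc(ps), ka = jc(pn), S = S, N = N,
       Sd = sum(d["sd", ]), Nd = sum(d["nd", ]))
}

# --- exhaustive global-alignment score -----------------------------------

oracle_align_score <- function(a, b, gap_open = 10, gap_extend = 0.5) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  mat <- get("BLOSUM62", envir = environment())
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  best <- -Inf
  # enumerate every monotone path as a move string (M / A-gap / B-gap)
  recurse <- function(i, j, moves) {
    if (i > length(ca) && j > length(cb)) {
      # score the complete path with affine gap costs
      score <- 0
      run <- ""
      ii <- 1
      jj <- 1
      for (m in moves) {
        if (m == "M") {
          score <- score + mat[ca[ii], cb[jj]]
          ii <- ii + 1
          jj <- jj + 1
          run <- ""
        } else {
          if (run != m) score <- score - gap_open
          score <- score - gap_extend
          run <- m
          if (m == "A") jj <- jj + 1 else ii <- ii + 1
        }
      }
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb)) recurse(i + 1, j + 1, c(moves, "M"))
    if (j <= length(cb)) recurse(i, j + 1, c(moves, "A"))
    if (i <= length(ca)) recurse(i + 1, j, c(moves, "B"))
  }
  recurse(1, 1, character(0))
  best
}

# --- Fisher exact two-sided by hypergeometric summation ------------------

oracle_fisher_p <- function(tab) {
  m <- tab[1, 1] + tab[1, 2]
  n <- tab[2, 1] + tab[2, 2]
  k <- tab[1, 1] + tab[2, 1]
  support <- max(0, k - n):min(k, m)
  prob <- vapply(support, function(x) {
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  }, numeric(1))
  p_obs <- prob[support == tab[1, 1]]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# --- exact Wilcoxon signed-rank by sign-flip enumeration -----------------

oracle_signed_rank_p <- function(diffs) {
  stopifnot(all(diffs != 0), !anyDuplicated(abs(diffs)))
  r <- rank(abs(diffs))
  v_obs <- sum(r[diffs > 0])
  n <- length(diffs)
  mu <- n * (n + 1) / 4
  count <- 0
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    v <- sum(r[signs])
    if (abs(v - mu) >= abs(v_obs - mu) - 1e-9) count <- count + 1
  }
  count / 2^n
}

# --- Welch t-test from the textbook formulas -----------------------------

oracle_welch <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# --- overlapping IUPAC motif recount with plain regex --------------------

oracle_iupac_regex <- function(pattern) {
  sets <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
            S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
            D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  paste(sets[strsplit(pattern, "")[[1]]], collapse = "")
}

oracle_motif_count <- function(seq, pattern, both = TRUE) {
  rex <- paste0("(?=", oracle_iupac_regex(pattern), ")")
  count_one <- function(s) {
    hits <- gregexpr(rex, s, perl = TRUE)[[1]]
    if (hits[1] == -1) 0L else length(hits)
  }
  n <- count_one(seq)
  if (both) {
    rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]),
                                       collapse = ""))
    n <- n + count_one(rc)
  }
  n
}

# --- hydrophobic moment by direct complex summation ----------------------

oracle_moment <- function(window, angle_deg = 100, scale) {
  h <- scale[strsplit(window, "")[[1]]]
  theta <- (seq_along(h) - 1) * angle_deg * pi / 180
  Mod(sum(h * exp(1i * theta)))
}

random_peptide <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

random_promoter <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
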