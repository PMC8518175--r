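make_domtbl_line <- function(domain, query, score, from, to) {
  # 22 whitespace-separated columns of the hmmscan per-domain table
  sprintf("%s PF0001.1 100 %s - 900 1e-50 200.0 0.1 1 1 1e-50 1e-48 %s 0.1 5 110 %d %d %d %d 0.9 desc",
          domain, query, score, from, to, from, to)
}

test_that("domtblout parsing extracts ali coordinates and sorts by start", {
  path <- withr::local_tempfile(fileext = ".domtblout")
  writeLines(c("# comment", "#",
               make_domtbl_line("CG-1", "prot1", "150.2", 15, 160)), path)
  ann <- read_domtblout(path)
  expect_identical(nrow(ann), 1L)
  expect_identical(ann$domain_name, "CG-1")
  expect_identical(c(ann$start, ann$end), c(15L, 160L))
  expect_identical(ann$evidence, "hmm")

  writeLines("#", path)
  expect_identical(nrow(read_domtblout(path)), 0L)

  writeLines(c(make_domtbl_line("ANK", "prot1", "80.0", 400, 460),
               make_domtbl_line("CG-1", "prot1", "150.2", 15, 160)), path)
  ann <- read_domtblout(path)
  expect_identical(ann$domain_name, c("CG-1", "ANK"))

  writeLines("CG-1 only four fields", path)
  expect_error(read_domtblout(path), "malformed domtblout line 1")
})

test_that("CaMBD consensus matching is position-exact", {
  core <- "WSVGILEKVILRWRRKGSGLRG"  # one instantiation of the consensus
  set.seed(21)
  flank <- random_peptide(40)
  for (k in c(0, 7, 23)) {
    seq <- paste0(substr(flank, 1, 10 + k), core, random_peptide(30))
    hit <- find_cambd(seq, "p")
    expect_identical(nrow(hit), 1L)
    expect_identical(hit$start, 10L + as.integer(k) + 1L)
    expect_identical(hit$score, 0)
  }
  expect_identical(nrow(find_cambd(strrep("A", 100))), 0L)
  # mismatch budget: 2 substitutions inside the core still found, 3 not
  mut2 <- paste0("AAAAA", "ASVGILEKVILRWRRKGSGLRA", "AAAAA")
  expect_identical(nrow(find_cambd(mut2)), 1L)
  expect_identical(find_cambd(mut2)$score, 2)
  mut3 <- paste0("AAAAA", "ASVAILEKVILRWRRKGSGLRA", "AAAAA")
  expect_identical(nrow(find_cambd(mut3)), 0L)
})

test_that("functional CaM motif pattern matches exact instantiations", {
  planted <- "WAVAALAKAALRWRAKAAAFRA"
  seq <- paste0(strrep("G", 12), planted, strrep("G", 9))
  hits <- find_functional_cam_motif(seq)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start, 13L)
  expect_identical(nrow(find_functional_cam_motif(strrep("G", 80))), 0L)
  two <- paste0(strrep("G", 5), planted, strrep("G", 4), planted)
  expect_identical(nrow(find_functional_cam_motif(two)), 2L)
})

test_that("bipartite NLS rule needs two basics, a 10-12 spacer, 3 basics in 5", {
  hit <- find_bipartite_nls(paste0("AAAA", "KR", strrep("A", 10), "KKRKA"))
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$start, 5L)
  expect_identical(nrow(find_bipartite_nls(strrep("A", 60))), 0L)
  # spacer of 20 violates the 10-12 rule
  expect_identical(
    nrow(find_bipartite_nls(paste0("KR", strrep("A", 20), "KKRKA"))), 0L)
})

test_that("IQ motif matches the conventional pattern", {
  iq <- "IQAAARGAAARAAW"  # [FILV]Q xxx [RK] G xxx [RK] xx [FILVWY]
  expect_identical(nrow(find_iq_motif(paste0("GGGG", iq, "G"))), 1L)
  expect_identical(nrow(find_iq_motif(strrep("A", 50))), 0L)
})

test_that("hydrophobic moment vanishes on homopolymers and matches the oracle", {
  for (res in c("A", "L", "R", "G")) {
    expect_equal(hydrophobic_moment(strrep(res, 18))$hydrophobic_moment, 0,
                 tolerance = 1e-10)
  }
  scale <- camtakit:::EISENBERG_SCALE
  set.seed(22)
  for (i in 1:10) {
    w <- random_peptide(18)
    expect_equal(hydrophobic_moment(w)$hydrophobic_moment,
                 oracle_moment(w, 100, scale), tolerance = 1e-10)
  }
  # alternating extreme scale values (I max, R min)
  alt <- paste(rep(c("I", "R"), 9), collapse = "")
  expect_equal(hydrophobic_moment(alt)$hydrophobic_moment,
               oracle_moment(alt, 100, scale), tolerance = 1e-10)
  expect_error(hydrophobic_moment("AAAA"), "18 residues")
})

test_that("a designed amphipathic window reports its hydrophobics on the face", {
  # residue i sits at angle 100*(i-1) mod 360; choose hydrophobics at
  # wheel angles within one half-plane, polars opposite
  angles <- (100 * (0:17)) %% 360
  upper <- angles <= 90 | angles >= 270
  win <- ifelse(upper, "L", "E")
  hp <- hydrophobic_moment(paste(win, collapse = ""))
  expect_true(all(which(win == "L") %in% hp$hydrophobic_face))
  expect_false(any(which(win == "E") %in% hp$hydrophobic_face))
})

test_that("architecture classification follows the domain complement", {
  ann <- function(names) data.frame(domain_name = names)
  expect_identical(
    classify_architecture(ann(c("CG-1", "TIG", "ANK", "IQ", "CaMBD")))$class,
    "canonical")
  expect_identical(
    classify_architecture(ann(c("CG-1", "ANK", "IQ", "CaMBD")))$class,
    "non-TIG")
  res <- classify_architecture(ann("CG-1"))
  expect_identical(res$class, "incomplete")
  expect_setequal(res$missing, c("TIG", "ANK", "IQ", "CaMBD"))
  # order independence
  expect_identical(
    classify_architecture(ann(c("CaMBD", "IQ", "ANK", "TIG", "CG-1")))$class,
    "canonical")
})
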