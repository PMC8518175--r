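---
title: "Characterizing a CAMTA gene family: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a CAMTA gene family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camtakit)
```

## Scope

`camtakit` implements the complete desk-side computational workflow used in
genome-wide characterizations of the calmodulin-binding transcription
activator (CAMTA) family, with the ten-member durian (*Durio zibethinus*)
family as the worked case: protein physicochemistry, domain architecture,
exon–intron structure, paralogy with Ka/Ks dating, a distance-based
phylogeny, promoter motif scanning with enrichment testing, TMM-normalized
co-expression, and relative qPCR quantification. A seeded synthetic-data
generator emulates every input with known ground truth, so each stage is
testable end-to-end without downloads. This vignette records the models,
the tunable parameters, and the design decisions behind each stage.

## Protein physicochemistry

Protein length is derived from the open reading frame as
`aa = ORF/3 − 1` (the terminal stop codon encodes no residue). Molecular
weight is the sum of **average** (not monoisotopic) residue masses plus one
water (18.0153 Da), the ProtParam convention; the per-residue mass table is
shipped as plain data (`inst/extdata/residue_masses.tsv`) rather than
hard-coded. The theoretical pI solves `charge(pH) = 0` by bisection on
[0, 14] to an interval width below 0.005, with the Henderson–Hasselbalch
charge model over the two termini and the D/E/C/Y/H/K/R side chains using
the Bjellqvist pKa set (`inst/extdata/pka_bjellqvist.tsv`), again the
ProtParam convention. Net charge is strictly decreasing in pH, so the root
is unique. Both tables were validated against an independent
ProtParam-convention implementation on a frozen reference panel
(`inst/extdata/protparam_reference_panel.tsv`, 40 peptides); agreement is
within 0.005 Da and 0.005 pH units. Non-canonical letters (including X)
are an error — no silent mass or pKa is guessed.

## Domain architecture

CG-1, TIG and ankyrin hits are **ingested** from hmmscan per-domain
tabular output (`read_domtblout()`, ali coordinates); profile HMM search
itself is upstream of this package. The motifs the family literature
locates by consensus are matched natively:

* **CaMBD** — the 22-position degenerate consensus
  `WSVG[IV]LEK[VA][IV]LRWRRK[GR][SK]GLRG`, with up to `max_mismatch`
  (default 2) mismatching positions; family members carry near- but not
  fully-identical copies, and two mismatches admit every member while a
  random sequence of realistic length essentially never matches
  (per-window chance < 10⁻¹⁵).
* **CaM functional motif** — `WXVX(2)LXKX(2)[LF]RWRX[KR]X(3)[FL]RX`
  matched exactly (X = any residue).
* **IQ** — the conventional pattern `[FILV]Qxxx[RK]Gxxx[RK]xx[FILVWY]`;
  the family literature names the motif without printing a pattern, so the
  standard calmodulin-field pattern is used. Overlapping occurrences are
  all reported; whether overlapping IQ copies should be collapsed is
  genuinely open, and counting all matches is the deterministic choice.
* **Bipartite NLS** — the classical rule (two adjacent K/R, a 10–12
  residue spacer, then ≥ 3 K/R within 5 positions). Web NLS predictors do
  not publish their exact rules, so this classical rule is a stand-in and
  every hit is flagged `classical bipartite rule` in its `note` column.
  One hit is reported per start position (shortest matching spacer).

The amphipathic character of the CaMBD is quantified on an 18-residue
window mapped onto an ideal α-helix (100° per residue) with the Eisenberg
consensus hydrophobicity scale: the hydrophobic moment is the magnitude of
the vector sum of per-residue hydrophobicities at successive wheel angles,
and the apolar face is the set of positions within 90° of the resultant.
Because 18 × 100° is exactly five turns, any homopolymer has moment 0 — a
useful exact identity for testing. No scale is named in the family
literature for the published wheel figures; Eisenberg's consensus scale is
the field default.

Architecture classification is a set rule: `canonical` when CG-1, TIG,
ANK, IQ and CaMBD are all present, `non-TIG` when only TIG is absent (a
recognized family subtype), otherwise `incomplete` with the missing list.

## Gene structure and promoters

GFF3 gene models (gene/mRNA/exon/CDS linked by `ID=`/`Parent=`) are parsed
into one model per mRNA with line-precise validation errors. Coordinates
are kept **1-based inclusive** throughout — the GFF3/IRanges convention
native to R — and converted to 0-based half-open only in BED-style
exports. Intron *i* is the gap between exons *i* and *i+1*; exon and
intron lengths always sum to the gene span.

The promoter of a gene is the 1000 bp (configurable) immediately upstream
of the transcription start site, taken as the gene-feature 5′ end (draft
annotations carry no UTRs, so the gene start is the operational TSS). On
the minus strand the forward-coordinate interval starts just after the
gene end and the extracted sequence is reverse-complemented. Genes near a
scaffold edge get a clipped interval with the actual length flagged rather
than being skipped — clipping keeps every gene in the analysis and the
flag preserves the information.

## Paralogy, Ka/Ks and dating

Candidate paralogs are found by **reciprocal best hit** over all-vs-all
global (Needleman–Wunsch) protein alignments with BLOSUM62 and affine gaps
(open 10, extend 0.5). Deterministic alignment scores replace BLAST
e-values for best-hit ranking: e-value statistics depend on database size
and are not reproducible at desk scale, while the published thresholds —
identity > 70% and coverage > 70% **of the longer sequence** — are applied
exactly. Coverage is measured inside the terminal-gap-trimmed aligned
span. Ties in best-hit ranking break toward the lower input index, and the
output is independent of input order.

Each pair's protein alignment is back-threaded onto its CDS (one codon per
aligned residue, `---` for gaps), and Ka/Ks is computed by
**Nei–Gojobori (1986)**: fractional synonymous site counts per codon
(averaged over the two sequences), pathway averaging over all orderings
for codons differing at 2–3 positions, and the Jukes–Cantor correction
`d = −(3/4)·ln(1 − (4/3)p)` per class. Three conventions are fixed and
tested against an exhaustive-pathway oracle:

* changes to stop codons are excluded from both the numerator and the
  denominator of the per-position synonymous fraction;
* pathways passing through a stop codon are excluded from the averaging
  (if every pathway does, all are used with stop steps counted
  nonsynonymous);
* codon columns containing gaps or ambiguity are dropped pairwise, not by
  complete deletion, matching the pairwise-deletion preference used for
  the distance computations.

`p ≥ 3/4` in either class is a saturation error, and zero synonymous
sites is an error — both are reachable on short toy inputs and are tested.

Duplication dates use the molecular clock `T = Ks/(2λ)` with
λ = 6.1×10⁻⁹ substitutions/site/year (the eudicot rate; configurable).
Selection is classified by the usual rule (Ka/Ks below/above/equal to 1,
with a 10⁻⁹ equality tolerance).

## Phylogeny

The package deliberately provides a **distance-based stand-in** for
likelihood tree inference: pairwise p- or Poisson-corrected distances with
pairwise gap deletion, Saitou–Nei neighbor joining, and column-resampling
bootstrap supports (percentage of replicates containing each internal
bipartition). Published CAMTA trees are descriptive groupings; ML adds
heavy machinery with no testable number at desk scale, whereas NJ is exact
on additive matrices (a strong test oracle) and transparent. Trees written
by the pipeline carry a header comment stating the stand-in status.
Negative NJ branch lengths (possible on non-additive inputs) are clamped
to zero with a warning. Exact reproduction of published subgroup labels is
not claimed — those depend on the ML model and rooting.

## Promoter motif scanning and enrichment

Degenerate IUPAC motifs (e.g. the CAMTA recognition motifs `MCGCGB` and
`MCGTGT`; M = A/C, B = C/G/T) are scanned by sliding-window set matching
at every offset. Overlapping matches are counted — the deterministic,
order-free choice. Both strands are scanned by default ("complement and
reverse complement" in methods descriptions is interpreted as both-strand
scanning; the literal complement alone is biologically meaningless);
reverse-strand hits are reported at forward coordinates with strand `−`.
`N` in a promoter never matches. Enrichment between gene sets uses the
two-sided Fisher exact test on occurrences versus scanned positions
(`L − k + 1` windows per strand per promoter): the unit is motif
occurrences, matching frequency-of-occurrence comparisons; a per-gene
(genes-with-hit) 2×2 can be formed by the caller from the same count
table. The reported odds ratio is the sample odds ratio with a Haldane
correction of 0.5 on zero cells, not the conditional MLE.

## Co-expression

Raw counts are TMM-normalized (trimmed mean of M-values: reference by the
75th-percentile rule, genes zero in either sample excluded, 30% two-sided
trim on M and 5% on A, inverse-asymptotic-variance weights, factors
rescaled to geometric mean 1) and expressed as counts per million scaled
by the factors. Pearson correlation between each hub gene and every other
gene is computed on `log2(x + 1)` by default — log stabilization is the
defensible default for right-skewed expression, and a raw-scale flag is
provided. Partners partition at the signed thresholds r ≥ 0.95 and
r ≤ −0.95 (configurable; these are the conventional co-expression-network
defaults). Zero-variance genes are skipped with a warning; a zero-variance
hub is an error.

Cumulative expression of a gene set between two sample groups is compared
by per-gene group means and a two-sided **Wilcoxon signed-rank** test
paired by gene — chosen because pairing by gene is natural and no
normality is assumed; the test is named in the output. When every paired
difference has the same sign the exact two-sided p is `2/2^n` even under
tied magnitudes (the all-positive assignment is uniquely extreme among
sign flips), and the implementation uses this directly instead of falling
back to the normal approximation.

## qPCR quantification

Relative expression follows 2^−ΔΔCt: technical replicates are averaged
per biological replicate (the conventional reduction for a 3 biological ×
3 technical design), ΔCt is target minus reference per biological
replicate, ΔΔCt subtracts the calibrator group's mean ΔCt, and the group
fold change is `2^−mean(ΔΔCt)` — so the calibrator group is exactly 1 by
construction. The error bar is the standard error of the per-replicate
folds over **biological** replicates only (technical replicates measure
pipetting, not biology), and group differences are tested with a
two-sided **Welch** t-test on the per-replicate ΔCt values (the standard
for ΔΔCt data; ΔCt is closer to normal than the fold itself), flagged at
0.05 (`*`) and 0.01 (`**`). A whole-plate Ct shift affecting target and
reference alike cancels exactly.

## The synthetic-data generator

Everything above is exercised on generated inputs with known truth
(`synth_config()`, `make_gene_family()`, `simulate_counts()`,
`simulate_qpcr()`, orchestrated by `make_demo()`). All randomness flows
from the config seed through one generator; identical configs give
byte-identical files. The defaults encode the durian study conditions:

* 10 genes, 12–13 exons each, on 8 scaffolds with a realistic fraction on
  the minus strand; CDS lengths 892–1084 codons (the family's observed
  span); introns 80–300 bp (kept short for speed — intron length carries
  no signal for any stage under test).
* five paralog pairs with synonymous divergence targets set to
  `2λT` for T = 14.64…17.95 MYA and Ka/Ks ≈ 0.3, i.e. purifying
  selection of the strength typical for conserved transcription-factor
  paralogs.
* 1000 bp promoters, uniform A/C/G/T background. Uniform composition
  makes the accidental-occurrence rate analytic
  (`(L − k + 1)·degeneracy/4^k` per strand — itself a tested property)
  and keeps rejection sampling tractable. Planted motif occurrences are
  placed non-overlapping after the background is scrubbed of accidental
  matches on both strands, so scanner counts equal planted counts
  *exactly*; the generator verifies this with its own regex-based
  matcher, which is independent of the Biostrings-based scanner it is
  used to test.
* paralog divergence is introduced as point substitutions classified
  against the genetic code **at the moment of introduction** (no indels),
  which makes the realized per-site counts well-defined and turns Ka/Ks
  estimation into a recovery experiment with an exact truth.
* expression: 2 hubs shifted +2 log2 between the two stages (ripening
  induction), 30 positive and 30 negative partners per hub responding
  linearly to the hub's latent log2 signal, 3 samples per stage by
  default (the study's replicate structure). Partner noise is calibrated
  so the **observed** log-scale correlation — including Poisson shot
  noise at the baseline mean of 2⁸, with the lognormal mean-inverse
  correction — meets the target r (0.97 by default). Background genes
  have means spanning 2⁴–2¹⁰ and a between-replicate spread of 0.3 log2
  units, a typical biological-replicate variability; the hub signal
  variance (1.0 log2) is a separate parameter, since signal dynamics and
  replicate noise are unrelated quantities. Counts are Poisson with
  per-sample library factors; an optional composition offset multiplies a
  fraction of background genes in one sample.
* qPCR: three stages with fold changes (1, 3, 8), (1, 2, 6) and
  (1, 0.6, 0.3) — up- and down-regulated ripening patterns — reference-
  gene Ct ≈ 20, measurement noise 0.2 cycles, 3×3 replicates.

What the generator does **not** emulate, and hence what green tests do not
show about real data: amino-acid composition bias (uniform-codon proteins
are Arg-rich and hence high-pI — fine for alignment/Ka/Ks machinery,
not a physicochemistry benchmark, which is why the physicochemistry
reference panel is a separate fixture), GC/nucleosome structure of real
promoters, overdispersed (negative-binomial) counts, read-level effects
(mapping, positional bias), and indel divergence between paralogs.

## Numerical and testing notes

Known quantitative behaviors, measured at the study conditions and
asserted in the test suite:

* NG86 estimates recover the realized Ks of mutated pairs within ±15%
  (CDS length 3000, Ks ∈ [0.05, 0.5], 20 seeds; typical error ≤ 9%).
* Co-expression recovery at r ≈ 0.97 planted, 30 samples: ≥ 90% of
  planted partners on average with ≤ 2 false partners (measured ≈ 96%
  and 0). Recovery at the study's own 6-sample design is necessarily
  weaker — the r̂ sampling spread at n = 6 is wide — which the demo
  analysis shows honestly.
* TMM recovers a planted one-sample composition offset (10% of genes
  4-fold up) within ±5% of the analytic value `1/(1 + s(fold − 1))`
  (s = the planted genes' library share) **as a mean over seeds**; a
  single draw carries a trim-window asymmetry bias of about +4% because
  the one-sided shift skews the kept rank window relative to the
  unshifted M distribution. This bias is a property of TMM under
  one-sided composition shifts, not of the implementation; the factors
  used for normalization are edgeR's, and the recovery test recomputes
  the doubly-trimmed weighted mean independently.
* Bisection pI agrees with the ProtParam-convention oracle to ±0.005 on
  the bundled panel; the oracle's own search is clamped to [4.05, 12],
  so the panel contains only peptides with pI inside that range.

Test problem sizes were chosen so the full suite exercises the study-scale
configuration (10 proteins of ~1000 aa for RBH, 1000-codon CDS for Ks
recovery, 2000-gene matrices for TMM) while completing in a few minutes on
one CPU.

## Worked example

```{r demo, eval = FALSE}
demo <- make_demo("demo_inputs")                      # seeded synthetic inputs
res <- run_camta_pipeline("demo_inputs", "demo_out")  # all eight stages
res$paralogs[, c("gene_a", "gene_b", "ka", "ks", "ka_ks", "mya", "selection")]
```

The `analysis/` directory of the source repository runs the same stages as
nine numbered narrative scripts writing their tables under `results/`.

## Limitations

Real-data gaps are deliberate: no HMM profile training (hits are
ingested), no de-novo motif discovery, no ML phylogenetics, no
primer-efficiency (Pfaffl) correction, no isoform reconciliation, and no
attempt to reproduce transcriptome-scale partner counts, which depend on
external RNA-seq data and a de-novo assembly outside the package's scope.
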