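# camtakit

Genome-wide characterization of the CAMTA (calmodulin-binding
transcription activator) gene family, built around the ten-member durian
(*Durio zibethinus*) family as the worked case. The package is aimed at
plant genomicists characterizing a transcription-factor family from a
draft genome: it covers every desk-side stage of such a study —
physicochemistry, domain architecture, gene structure, paralogy and
dating, phylogeny, promoter motifs, co-expression and qPCR — and ships a
seeded synthetic-data generator so the whole pipeline is testable offline
with known ground truth.

## What it computes

* **Physicochemistry** (ProtParam conventions): protein length from the
  ORF (`aa = ORF/3 − 1`), average molecular weight (sum of residue masses
  + 18.0153 Da), theoretical pI by bisection of the Henderson–Hasselbalch
  net charge with the Bjellqvist pKa set.
* **Domain architecture**: hmmscan `--domtblout` ingestion (CG-1, TIG,
  ANK) plus consensus detection of the calmodulin-binding domain
  (`WSVG[IV]LEK[VA][IV]LRWRRK[GR][SK]GLRG`, ≤ 2 mismatches), the CaM
  functional motif, IQ motifs and the bipartite NLS; Eisenberg
  hydrophobic-moment helical-wheel analysis
  (μH = |Σᵢ hᵢ·e^(i·100°·(i−1))| over an 18-residue window).
* **Gene structure**: GFF3 gene models, exon–intron statistics, and
  strand-aware 1000-bp promoter extraction upstream of the TSS.
* **Duplication**: reciprocal-best-hit paralog pairs (global
  Needleman–Wunsch/BLOSUM62 alignments; identity > 70% and coverage > 70%
  of the longer sequence), PAL2NAL-style codon back-threading,
  Nei–Gojobori (1986) Ka/Ks with pathway averaging and Jukes–Cantor
  correction, clock dating T = Ks/(2λ) with λ = 6.1×10⁻⁹ site⁻¹ yr⁻¹,
  and selection classification (Ka/Ks ≶ 1).
* **Phylogeny**: p/Poisson distances with pairwise gap deletion,
  neighbor joining, column-resampling bootstrap supports, newick output
  (a documented distance-based stand-in for ML trees).
* **Promoters**: degenerate IUPAC motif scanning on both strands
  (overlaps counted, hits at forward coordinates) — including the CAMTA
  recognition motifs `MCGCGB`/`MCGTGT` — and two-sided Fisher exact
  enrichment of occurrence frequencies between gene sets.
* **Co-expression**: TMM normalization, Pearson partner sets at
  r ≥ 0.95 / r ≤ −0.95 on log2(CPM+1), and Wilcoxon signed-rank
  cumulative-expression comparison between stages.
* **qPCR**: 2^−ΔΔCt fold changes with biological-replicate SE and Welch
  t-test flags.

## Worked example

```r
library(camtakit)
demo <- make_demo("demo_inputs")                      # synthetic study inputs
res  <- run_camta_pipeline("demo_inputs", "demo_out") # all eight stages
res$paralogs[, c("gene_a","gene_b","identity_pct","ka","ks","ka_ks","mya","selection")]
```

On the default (seeded) demo family this prints:

```
  gene_a gene_b identity_pct     ka    ks ka_ks   mya selection
1 syng01 syng02         89.0 0.054 0.179  0.30  14.7 purifying
2 syng03 syng04         87.9 0.058 0.183  0.32  15.0 purifying
3 syng05 syng06         88.0 0.058 0.194  0.30  15.9 purifying
4 syng07 syng08         87.0 0.064 0.191  0.33  15.7 purifying
5 syng09 syng10         86.4 0.068 0.206  0.33  16.9 purifying
```

i.e. the five planted paralog pairs are recovered as reciprocal best hits
above both 70% thresholds, every pair is under purifying selection
(Ka/Ks ≈ 0.3 < 1), and the estimated duplication dates land on the
planted 14.6–18 MYA window. The `analysis/` directory runs the same
stages as nine numbered narrative scripts (`01_simulate.R` …
`09_qpcr.R`), each printing what it found and writing its tables under
`results/` — e.g. `07_promoter_motifs.R` reports that the scanned
`MCGTGT` counts equal the planted truth in 10 of 10 promoters and that
the motif is enriched in the high-frequency gene set (Fisher exact
p = 0.041), and `09_qpcr.R` recovers planted fold changes such as 6.0 as
5.88 ± 0.28 (`**`).

The methods vignette (`vignettes/camta-family-analysis.Rmd`) documents
every model, parameter and design decision, and what the synthetic data
do and do not emulate.

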