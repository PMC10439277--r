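# scmosaic

Single-cell analysis of somatic mosaicism in hematopoiesis: UMI-consensus
genotyping of expressed somatic variants, immune gene-program scoring, and
repertoire clonality — with seeded synthetic-data generators that carry
ground truth for every stage.

## The problem

In clonal hematopoiesis syndromes such as VEXAS (somatic *UBA1* mutations in
myeloid-biased stem cells), droplet scRNA-seq reads covering the mutated
position can genotype individual cells — but only noisily: transcripts drop
out, reads carry sequencing errors, and several reads share one molecule
(UMI). `scmosaic` implements the full downstream analysis such a study
needs, for computational biologists working from CellRanger-style outputs:

- **UMI-consensus genotyping.** Reads sharing a (cell barcode, molecular
  barcode) pair are collapsed: the modal base is accepted if it reaches a
  fraction τ (default 0.75) of the reads, otherwise the molecule is
  discarded. A cell with ≥ 1 mutant molecule is called `mutant`; with only
  reference molecules it is `wildtype` (hemizygous locus, e.g. X-linked
  *UBA1* in males) or `wildtype_likely` (diploid locus, second allele may be
  uncaptured); with no evidence, `unknown`.
- **QC / normalization / HVG selection** (keep cells with 500–3,000 detected
  genes and ≤ 10% mitochondrial reads; `log(1 + c·10⁴/colsum)`; binned
  dispersion z-scores at cutoff 0.5).
- **Cell-type assignment** of clusters by one-tailed Fisher's exact
  enrichment of cluster markers (Wilcoxon rank-sum) in top-250-style
  signature gene sets over the expressed-gene background.
- **Gene-program scores**: expression-bin-matched module scores
  (`mean(set) − mean(matched controls)`), set-recovery AUC scores, cell-cycle
  phase (S/G2M score argmax with G1 fallback), composite inflammatory scores
  over several hallmark sets, per-donor or per-cell Pearson score
  correlation.
- **Differential expression** (Wilcoxon, Bonferroni, significant iff
  `p < 0.05` and `|log2FC| > 0.1`) and **pre-ranked GSEA** — the weighted
  Kolmogorov–Smirnov running sum with a gene-label permutation null.
- **Ligand–receptor interaction scores**
  `S_L,R = mean_A(E_L^norm) × mean_B(E_R^norm)` on housekeeping-normalized
  expression, with per-cell summed scores against a partner population.
- **Pseudotime window curves**: case/control abundance log2-ratios,
  lineage-priming (AUC) ratios, transcription-factor ratios and
  mutant-fraction curves along a branch.
- **TCR/BCR clonality**: clonotypes from CDR3 nucleotide keys, Shannon
  entropy `H = −Σ pᵢ log2 pᵢ` (bits), Gini coefficient (pairwise-difference
  and Lorenz forms), expansion classes (1 / 2 / 3–9 / ≥ 10), inter-sample
  sharing.

Clustering, pseudotime inference and V(D)J assembly are upstream inputs, not
re-implemented.

## Worked example

Everything below runs on synthetic data with known truth:

```r
library(scmosaic)

cfg <- sim_config(seed = 42)                   # 3,000 genes, 8 donors, 2,000 cells
sim <- simulate_counts(cfg)                    # planted programs + genotypes
sim$meta <- simulate_trajectory(sim$meta, cfg, seed = 43)

variant <- data.frame(name = "UBA1_M41", chrom = "chrX", pos = 47190861,
                      ref_allele = "T", alt_allele = "C",
                      ploidy_mode = "hemizygous")
reads <- simulate_reads(sim$meta, variant, cfg, seed = 44)   # 20% capture
calls <- genotype_matrix(reads, variant, cell_universe = sim$meta$barcode)
table(calls$label)
#>   mutant  unknown wildtype
#>       54     1597      349
mutant_fraction(calls, sim$meta$barcode[sim$meta$group == "case"])
#> [1] 0.2547170      # truth in captured cohort: 0.304 (binomial noise at n = 212)

ln  <- normalize_log(sim$matrix)
inf <- module_score(ln, sim$truth$inflammation, seed = 1)
er  <- module_score(ln, sim$truth$er_stress, seed = 2)
score_correlation(inf, er)$r
#> [1] 0.4800115      # planted latent coupling rho = 0.6, attenuated by scoring noise

mean(inf[calls$cb[calls$label == "mutant"]])    # 0.329 — planted inflammation shift
mean(inf[calls$cb[calls$label == "wildtype"]])  # 0.011

d <- build_clones(simulate_clones(cfg, seed = 45)$table, "beta_nt")
diversity_summary(d)
#>    K    N        H         G singleton size_2 size_3_9 size_ge10
#> 1 38 1000 2.123262 0.8822105        15      7       10         6
```

So: 20% transcript capture leaves most cells `unknown` (as in real data); the
genotyped subset estimates the planted 30% mutant fraction within binomial
error; mutant cells show the planted inflammatory shift; and the power-law
clone table yields the expected high Gini with six highly expanded (≥ 10
cell) clones.

The whole chain — simulate → QC → genotype → annotate → score → DE/GSEA →
interactions → trajectory curves → clonality — runs as one call with a
manifest of output hashes:

```r
run_pipeline(run_config("out/", seed = 1))
```

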