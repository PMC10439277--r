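---
title: "Models and methods behind scmosaic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scmosaic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(scmosaic)
```

`scmosaic` analyzes single-cell RNA-seq cohorts in which a somatic point
mutation marks a clone of hematopoietic cells — the situation in VEXAS
syndrome and other clonal hematopoiesis disorders. This vignette explains
each model, the tunable parameters, what the synthetic generators do and do
not emulate, and the numerical decisions taken where the design was open.

## UMI-consensus genotyping

A 10x library covers an expressed variant with reads tagged by a cell
barcode (CB) and a molecular barcode (UB). Reads without either tag never
enter the analysis (`read_read_table()` drops and counts them). Reads
sharing a (CB, UB) pair derive from one mRNA molecule, so they are collapsed
to a consensus base:

* the modal observed allele is accepted if its fraction is **≥ τ**
  (`genotype_config(tau = 0.75)`); otherwise the molecule is discarded;
* a consensus on a base that is neither the reference nor the alternate
  allele is also discarded — only the two alleles defined by the variant
  specification are biologically interpretable.

Because τ > 0.5, at most one allele can reach the threshold, so no
tie-breaking rule is needed. A `strict` flag switches the boundary to
`> τ` for sensitivity analyses; the permissive `≥` reading is the default.

Cell labels follow from molecule counts: one alternate molecule suffices for
`mutant` (a specific substitution does not arise by chance at any
appreciable per-molecule rate, and the consensus step has already absorbed
read-level error); only-reference cells are `wildtype` when the locus is
hemizygous (one expressed allele, e.g. X-linked *UBA1* in males) and
`wildtype_likely` when diploid (the mutant allele may simply not have been
captured); cells with no surviving molecule are `unknown`, including cells
whose molecules were all discarded. `mutant_fraction()` uses only genotyped
cells in its denominator, since `unknown` reflects capture, not genotype.

## Preprocessing

QC keeps cells with a detected-gene count in `[min_genes, max_genes]`
(defaults 500 and 3,000 — below: fragments; above: doublet suspects) and a
mitochondrial read fraction at most `max_mito_frac` (default 10%, removal is
strictly above the bound). Normalization scales each cell to a common
library size (default 10,000) before `log1p`; zero-count cells stay zero
with a warning. Highly variable genes come from the classic mean/dispersion
procedure: per-gene dispersion `var/mean` of de-logged values, 20
equal-width bins of log mean expression, within-bin z-scores, cutoff 0.5.
Equal-width bins are kept because they are the procedure's convention; note
they degenerate when all genes share one mean (a synthetic edge case —
fixtures here use heterogeneous baselines, as real data always has).

## Cell-type assignment

Cluster labels are inputs. Markers of a cluster are genes ranked by a
two-sided Wilcoxon rank-sum test of that cluster against all other cells
(normal approximation with tie and continuity corrections — expression data
are tie-heavy, so exact small-sample p-values do not apply), with
`log2(mean(expm1)+1)` fold changes and Bonferroni adjustment. Thresholded
markers (defaults `p_adj < 0.05`, `log2fc > 0.25`, configurable — the marker
cutoff feeding the enrichment is a free choice) are tested against each
signature set by the hypergeometric upper tail (one-tailed Fisher's exact
test) over the background of genes expressed in more than 100 cells; the
smallest p wins, ties break by larger overlap then name, flagged.

## Gene-program scores

`module_score()` is the bin-matched control score: genes are placed in
`n_bins = 24` equal-frequency bins of mean expression; for every set gene,
`n_ctrl = 100` control genes are sampled from its bin with a dedicated seeded
RNG stream (caller RNG state is never touched); the score is
`mean(set) − mean(pooled controls)` per cell. Properties to know: it is
centered near zero for background-like sets; it inherits a mild coupling to
library composition (normalization makes all scores share the cell's scale
factor; only exactly log-linear genes cancel); and if a set of outlier mean
expression is as large as its bin, controls can coincide with the set
itself. These are properties of the method, not bugs; tests quantify them.

`auc_score()` ranks each cell's genes by decreasing expression (average rank
ties, hence deterministic) and integrates the set-recovery curve within the
top `top_frac = 0.05` of ranks, normalized so a cell whose top ranks are
exactly the set genes scores 1. It depends only on within-cell ranks and is
invariant to monotone transforms.

Cell-cycle phase is the argmax of S and G2M module scores, with G1 when
neither is positive. The composite (e.g. "VEXAS inflammatory") score is the
module score of the union of the supplied hallmark sets. Score correlation
is Pearson at cell level or after per-donor mean aggregation (means, not
medians — an open choice, configurable through the exported pieces).
`group_score_ratio()` shifts all scores by `−min + ε` before taking a ratio
of group means, because module scores may be negative and a raw ratio would
be undefined; the shift is reported alongside. `normalized_activity()`
centers each dataset on its own control cells so case activity can be
compared across cohorts with different baselines.

## Differential expression and GSEA

Two-group DE uses the same Wilcoxon machinery, skips genes detected in less
than 10% of the cells of both groups, adjusts by Bonferroni, and flags
significance by the joint rule `p < 0.05` and `|log2FC| > 0.1`. Under a null
this joint rule fires at ≤ 5% in expectation; any single realization
fluctuates by binomial noise, which the tests allow for.

Pre-ranked GSEA is the weighted Kolmogorov–Smirnov running sum: walking down
the ranking, a set gene raises the sum by `|stat|^p / Σ_hits |stat|^p`
(default `p = 1`; `p = 0` gives the classic unweighted statistic) and any
other gene lowers it by `1/(N − N_hits)`; the enrichment score is the signed
extreme. The null redraws the set's positions uniformly (`n_perm = 1000`
gene-label permutations — appropriate for a pre-ranked analysis, where no
phenotype labels exist to permute). NES divides ES by the mean magnitude of
same-sign permutation scores. The p-value is
`(1 + #{|ES_perm| ≥ |ES|}) / (n_perm + 1)`: the +1 smoothing avoids zero,
the magnitude-based tail keeps the null p uniform by exchangeability and
reaches `1/(n_perm+1)` for a maximally enriched set, which a sign-conditional
denominator cannot do.

## Ligand–receptor interaction scores

Expression is first housekeeping-normalized per cell:
`E^norm = E − mean(E[housekeeping])` (a small general-purpose list ships in
`inst/extdata/housekeeping.gmt`; supply your own via GMT). The score of pair
(L, R) from type A to type B is the product of type-averaged normalized
expressions. A single product has no replicates, so the test that the score
exceeds zero is run on the per-sender-cell contributions
`E^norm_L[i] · mean_B(E^norm_R)` — a one-sided Wilcoxon signed-rank test by
default, with a label-permutation alternative (`method = "permutation"`).
Per-cell scores for a focal population sum, over pairs, the focal cell's
ligand against the partner mean receptor **and** its receptor against the
partner mean ligand; progenitors genuinely carry both roles, and a
`direction` argument restricts to either one.

## Trajectory curves

Queries project onto a healthy reference by Pearson correlation over shared
highly variable genes, inheriting the best reference cell's pseudotime and
branch (ties flagged, zero-variance queries returned absent). Pseudotime
itself is an input: the package deliberately does not re-implement
diffusion-map trajectory inference.

All curves share equal-width half-open windows on `[0, 1]` (default 20;
`t = 1` joins the last window). The abundance curve compares within-group
percentages, so group sizes cancel and duplicating cells changes nothing:
`log2((n_case + pc)/(N_case + pc·W)) − log2((n_ctrl + pc)/(N_ctrl + pc·W))`
with pseudocount `pc = 0.5` per window so empty windows stay defined (both
empty ⇒ exactly 0). The priming curve takes `log(mean case score / mean
control score)` per window (absent when a mean is non-positive), the
transcription-factor curve the ratio of mean log-normalized expression
(`ε = 1e-9` on the denominator), and the mutant-fraction curve
`log((n_mut + pc)/(n_genotyped + pc))`. Natural log is used where the base
is a free choice, with a `log_base` argument. Windows in low-density tails
of the pseudotime distribution hold few cells and are intrinsically noisy;
analyses here read depletion off well-populated windows.

## Synthetic data: what it emulates, what it does not

The generators produce every input the pipeline reads, with truth columns,
so all recovery tests are self-contained. Counts are negative binomial with
lognormal per-gene baselines (meanlog 1, sdlog 1.5 — deep libraries of
roughly 25k UMIs whose mass sits with unrelated high expressers, keeping
program genes in the log-linear regime) and lognormal dispersions around
size 2. Planted structure: per-type signature programs (log-scale shift
1.0); inflammation and ER-stress programs of 100 genes whose per-cell latent
activities are bivariate normal with correlation ρ (default 0.6); mutant
cells (30% of case-donor cells, case donors only) get +1 on the inflammation
latent. Reads at the variant locus: per-cell capture probability 0.2, 1 +
Poisson(1) molecules, 1 + Poisson(3) reads per molecule, per-read error
0.005 (uniform over the two wrong tokens), 2% of reads with an empty
molecular barcode to exercise tag filtering. Pseudotime: two branches with
Beta densities (myeloid Beta(2,2), lymphoid Beta(2,5)); optional accept–
reject thinning of late case lymphoid cells models progressive lineage
loss, and an optional linear decline of mutant probability along a branch.
Clones: rank-size power law `size_k ∝ k^{−α}` (α = 2, 200 clones) — note
that under this rank-size parametrization a *larger* α concentrates cells
into the top clones and raises the Gini.

Not emulated: batch effects and donor-specific baselines, ambient RNA,
doublets, UMI collisions, isoform structure, and any real gene identity.
Passing tests therefore show the estimators are correct and calibrated under
the stated statistical model — not that the model captures every artifact of
real droplet data.

A note on recovered correlations: with 100-gene programs at loading 0.6, the
module-score estimate of a planted ρ = 0.6 coupling lands around 0.52–0.55.
The attenuation is real and expected — scores estimate latent activities
with finite reliability, all scores share the cell's library-size factor,
and bin-matched controls absorb a sliver of the other program — and the same
attenuation would affect the analysis on real data.

## Numerical choices and edge cases

* Classed conditions (`scmosaic_format_error`, `_usage_error`,
  `_parameter_error`) separate malformed files, misuse, and impossible
  parameters.
* MatrixMarket indices are 1-based per the standard; variant positions are
  1-based (VCF convention); in-memory work uses R's native indexing. Gene
  symbols match case-sensitively; gene-set members missing from a matrix are
  intersected away (an empty intersection errors).
* Seeded sampling in `module_score()` and `gsea_preranked()` runs on a
  private RNG stream, so calling them never perturbs the caller's RNG.
* Wilcoxon p-values use the tie-corrected normal approximation with
  continuity correction throughout (zero-variance genes return p = 1).
* Gini has two algebraically equal routes (pairwise mean absolute
  difference; Lorenz trapezoids), kept as mutual oracles and verified to
  1e-12 against each other; the `K/(K−1)` small-sample factor is off by
  default.
* Problem sizes in tests — 2,000-cell cohorts, 100-replicate coverage runs,
  exhaustive consensus enumeration to read depth 6, 1,000 random Gini
  distributions — were chosen so the whole suite runs in about a minute on
  one CPU while leaving the statistical assertions well-powered.

## Limitations

Genotyping assumes the variant is expressed and covered; silent clones are
invisible. No indel or phasing support. The Fisher assignment inherits the
arbitrariness of the upstream marker cutoff. The interaction score treats
types as homogeneous pools and ignores spatial structure. Curves depend on
the supplied pseudotime; no uncertainty propagates from it.
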