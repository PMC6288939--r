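---
title: "Exon-level differential expression and the sex-bias landscape"
author: "delandscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exon-level differential expression and the sex-bias landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delandscape)
library(dplyr)
```

# The analysis in one paragraph

`delandscape` implements an exon-level RNA-seq differential-expression
pipeline for a two-sex, two-condition (control vs perturbed) factorial
design, and classifies how the *landscape* of sex-differential expression
changes between conditions. Reads are attributed to unique exonic regions
(single exons, or merged overlapping exons of one gene; intervals shared
between genes are excluded as gene-ambiguous), regions pass an
average-per-nucleotide-coverage (APN) detection filter, expression is
quantified as natural-log RPKM, and four pairwise contrasts are tested per
region with group-specific-variance (Welch–Satterthwaite) statistics
followed by Benjamini–Hochberg FDR control within each contrast family. A
gene is called differentially expressed when at least one of its exons is.
Exons and genes are then classified into a nine-cell landscape — sex bias
maintained, gained, lost, or reversed, in either direction, or absent — and
DE gene lists are tested for gene-set over-representation with a
hypergeometric test against an annotation-restricted background.

# Regions: flattening the annotation

Exon records are read from GFF3 (1-based, inclusive coordinates) with gene
attribution taken from a `gene_id` attribute or resolved by walking the
`Parent` chain. Per gene, exons sharing at least one base are merged into
maximal intervals. Three deliberate choices:

* **Adjacency is not overlap.** Exons with `end + 1 == start` stay
  separate regions; merging requires a shared base. In interval terms the
  merge uses a minimum gap width of zero.
* **Whole-interval ambiguity exclusion.** When merged intervals of two
  genes share any base, the entire merged interval of *every* gene
  involved is excluded and reported as one ambiguity group. This is the
  simplest defensible reading of "ambiguous regions are excluded"; the
  alternative — trimming only the shared bases and keeping gene-unique
  remainders — is available as `trim_ambiguous = TRUE` and off by default.
* **Strand is carried, not used.** Overlap decisions ignore strand; a
  merged region whose source exons disagree on strand reports `.`.

Region identifiers are deterministic (`gene:start-end`) so outputs diff
cleanly across runs. BED6 export converts to 0-based half-open
coordinates; the conversion is covered by tests. Correctness of the
flattening is established against an independent per-base oracle that
labels every base with its covering gene set on random small annotations.

# Quantification and detection

APN is total mapped bases over region length. A region is **detected**
when at least one of the four sex-by-treatment groups has two or more
replicates with APN *strictly* greater than 5 (both the threshold and the
replicate floor are arguments). Only detected regions enter statistics.

Expression is
$\ln\text{-RPKM} = \ln\frac{c + c_0}{(L/10^3)\,(S/10^6)}$
with count $c$, region length $L$ bp, library size $S$ and pseudocount
$c_0 = 0.5$ by default. The pseudocount only matters for zero counts,
which are rare after detection filtering; setting it to 0 reproduces the
bare RPKM definition. The library size defaults to the per-sample total of
counts over the analysed regions and can be supplied externally (the
synthetic pipeline passes the nominal per-sample depth). Natural log is
used throughout, so contrast estimates are directly ln-fold changes.

# Testing: four contrasts, robust to variance heterogeneity

The four comparisons are (1) female control vs female perturbed, (2) male
control vs male perturbed, (3) female vs male in control, (4) female vs
male under perturbation; the estimate is always `mean(a) − mean(b)` in the
order named. Because the sexes can differ in expression variability, each
contrast uses group-specific variances:

$$t = \frac{\bar a - \bar b}{\sqrt{s_a^2/n_a + s_b^2/n_b}},\qquad
\nu = \frac{(s_a^2/n_a + s_b^2/n_b)^2}
  {\tfrac{(s_a^2/n_a)^2}{n_a-1} + \tfrac{(s_b^2/n_b)^2}{n_b-1}}$$

This Welch–Satterthwaite contrast is the one-way specialisation of
small-sample adjusted F-tests for models with heterogeneous covariance:
with a saturated cell-means model and no random effects, each pairwise
contrast reduces exactly to this two-group form (the squared statistic is
an F with one numerator degree of freedom). When the groups are balanced
with equal sample variances, $\nu = n_a + n_b - 2$ and the statistic
coincides with Student's t — a property asserted in the tests.

Degenerate regions (zero variance in both groups) are reported rather than
dropped: equal constants give $p = 1$, unequal constants give $p = 0$ with
a `degenerate` flag.

FDR control is Benjamini–Hochberg within each contrast family across all
detected regions (pooling the four families is a config option). Flags are
kept at FDR < 0.0001, 0.01 and 0.05, with 0.01 the headline level used by
classifications and reports, and the two-fold rule is
$|\ln\text{FC}| \ge \ln 2$, boundary inclusive.

On log counts with four replicates per group the normal-theory contrast is
mildly conservative (the observed null rejection rate at $p<0.05$ sits
near 0.04–0.05 rather than exactly 0.05); the test suite brackets the
nominal rate rather than pinning it.

# The landscape classification

Between-sex status per comparison: F-biased (significant, ln-FC(F−M) > 0),
M-biased (significant, < 0), or NS. The pair of statuses (control,
perturbed) maps bijectively onto nine labels: `unbiased`,
`maintained_F/M`, `gained_F/M`, `lost_F/M`, `reversed_F_to_M`,
`reversed_M_to_F`. A significant comparison with an exactly zero estimate
cannot arise in continuous data but is defensively mapped to NS.

Within-sex status: "up" means higher under perturbation; since the
contrast is control − perturbed, up corresponds to a negative estimate and
the classifier re-signs accordingly. The nine cells are both-up,
both-down, two opposing combinations, four single-sex responses, and null.

**Gene rollup.** A gene carries every label supported by at least one
exon, with per-label exon counts — multi-exon genes may genuinely sit in
several categories, and the default tabulation counts them in each
(`resolve_gene_categories()` optionally collapses to one label per gene
with priority maintained > reversed > gained > lost). Summary percentages
are reported against the tested-gene count and against the
significant-gene union, rounded half away from zero to one decimal — the
convention that reproduces report-style percentages exactly.

# Enrichment

Over-representation uses the upper-tail hypergeometric probability
$P(X \ge k)$ for $k$ DE genes in a set of $K$ background members, $n$ DE
genes among $N$ background genes. The background is restricted to tested
genes that carry at least one annotation of the tested type, which makes
the test invariant to unannotated genes — an invariant asserted in the
tests. Adjustment is BH across the sets of one annotation type for one
comparison; annotation input is plain GMT, and no ontology-graph
propagation is performed.

# The synthetic generator

The generator stands in for the study design the pipeline targets: four
groups (2 sexes × control/perturbed), four replicates each, 100 bp
single-end reads, with optional sample dropout mirroring the removal of
low-coverage libraries. Counts are negative binomial with mean
$\exp(\mu_{\text{cell}}) \times L_{kb} \times S_{M}$, so quantification
recovers the planted cell means (in ln-RPKM) in expectation; base coverage
is counts × read length. Variance heterogeneity between the sexes is
planted through sex-specific NB dispersions.

Each gene draws a bias category (all its exons share the gene's effects;
this mirrors gene-level regulation and makes gene rollup recovery
well-defined, while truth is still recorded per region). The category
determines the sex effects in the two conditions; within-sex treatment
effects follow from the factorial identity
$t_F - t_M = s_{\text{ctrl}} - s_{\text{pert}}$, centred on a
configurable shared treatment shift (default 0).

Defaults, chosen once as a realistic small-scale emulation: 1000 genes with
1–6 exons (region lengths 200–2000 bp), baseline ln-RPKM ~ N(5, 1),
library size 2×10⁷ reads, effect magnitude ln 4, NB dispersion 0.05 per
sex, and a category mix dominated by unbiased regions with gains
outnumbering maintained, lost and reversed bias (60% unbiased, 20%/12%
gained F/M, 3%/1% maintained, 1.2%/1.5% lost, 0.65% reversed each way) —
the qualitative signature of a perturbation that mostly *creates* sex
bias.

What the generator does **not** emulate: read-level effects (GC and length
bias, positional coverage), correlated expression between genes, library
composition effects, and annotation errors. Passing tests on synthetic
data therefore demonstrate the correctness of the statistical machinery
under its stated model, not robustness to those real-data artefacts.

## What small-sample recovery can and cannot show

With dispersion 0.05 and four replicates per group, the standard deviation
of a contrast estimate is about
$\sqrt{2 \times 0.05 / 4} \approx 0.16$ ln units (the variance of the log
of an NB count at high mean approaches the dispersion). Two consequences
worth knowing before reading the acceptance output:

* an estimated ln-fold change lands within ±0.2 of truth with probability
  about $2\Phi(0.2/0.16) - 1 \approx 0.8$, so roughly a fifth of estimates
  sit outside that window even when every call is correct;
* with ~6 error degrees of freedom the t statistic has a heavy-tailed
  noncentral distribution, so single-contrast power at the BH-0.01
  threshold is about 0.85–0.9 and two-contrast categories (maintained,
  reversed) recover at roughly the square of that. Category recovery on
  the default planted scenario measures ~85–89%, not ~99%.

These are properties of the small-sample design itself, not of the
implementation; both rates are recomputed, not assumed, by the acceptance
script.

# Pipeline, determinism and problem sizes

`run_pipeline()` validates its configuration before any computation
(ascending FDR levels, positive thresholds, a data source present),
executes regions → quantify → detest → landscape → enrichment, and writes
every stage artefact as TSV together with a run log holding the
configuration hash, the seed and per-stage counts. All randomness flows
from the single seed, and the persisted outputs contain no wall-clock
information, so a rerun with the same configuration is byte-identical —
asserted in the tests. Wall-clock stage timings go to the console only.

Test and acceptance runs use modest problem sizes chosen to keep the
suite quick while leaving the binomial noise on measured rates small:
2000 single-exon regions for null calibration (binomial SD on a 5%
rejection rate ≈ 0.5 percentage points), 1000 multi-exon genes
(~3500 regions) for recovery, and 60–200 random annotations per
oracle-comparison property.

# Known limitations

* Exactly one factorial layout (2 sexes × 2 conditions, the four named
  contrasts) is supported; other designs are out of scope.
* No moderated dispersion estimation (limma/DESeq2-style shrinkage); each
  region is tested from its own replicates only, which is what makes the
  small-sample power analysis above apply.
* Between-sample normalisation is RPKM only — no TMM/quantile
  alternatives.
* The ambiguity rule operates on merged intervals per gene; transcript
  isoform reconstruction and trans-spliced genes are not handled beyond a
  warning for multi-chromosome genes.
* GO-graph propagation is not applied before enrichment; sets are tested
  as given in the GMT.
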