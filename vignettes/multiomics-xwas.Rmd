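---
title: "Methods: multi-omics xWAS integration on synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics xWAS integration on synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multixwas)
```

# The problem

Summary-based association methods connect molecular quantitative trait
loci (QTL) to complex traits without individual-level phenotype data: a
reference panel supplies per-feature cis-QTL effects, a GWAS supplies
per-variant trait associations, and the two are combined per molecular
feature. With five molecular layers (eQTL, sQTL, pQTL, mQTL, m6AQTL),
several tissues, several GWAS releases and two tool families, the same
gene is tested many times under many designs. `multixwas` implements both
the feature-level statistics and the integration layer that turns a pile
of such results into *reliable* genes, *novel* genes, replication metrics
and multi-layer regulation patterns.

# Feature-level statistics

## Weighted imputation (FUSION-style)

For feature *g* with variant weight vector $w$, GWAS z-scores $z$ and LD
correlation $R$ over the weighted variants,

$$ z_{\mathrm{TWAS}} = \frac{w^\top z}{\sqrt{w^\top R w}} . $$

Two weight models are implemented, the minimum needed to exercise
summary-based imputation: **top1** (unit weight on the cis variant with
the smallest marginal p) and **ridge**
($w = (X^\top X/n + \lambda I)^{-1} X^\top y / n$ on standardized
dosages, default $\lambda = 0.1$). `cv_r2` is the k-fold cross-validated
squared correlation between predicted and observed molecular phenotype;
with `model = "best"` the better model is kept and tagged. Penalized
models beyond ridge (lasso, BSLMM) are deliberately out of scope.

When $w^\top R w \le 0$ or $R$ is not positive semi-definite (possible
with an empirical correlation matrix), the regularized
$R_{\mathrm{reg}} = (1-\lambda) R + \lambda I$ with $\lambda = 0.1$ is
substituted: it bounds the condition number without any external
shrinkage machinery, and leaves well-behaved features untouched.

## SMR and HEIDI

SMR uses the feature's most significant cis-QTL as an instrumental
variable (eligibility $p_{zx} < 5\times10^{-8}$, the conventional
default). The causal effect estimate is the Wald ratio
$\hat b_{xy} = b_{zy}/b_{zx}$ and the test statistic

$$ z_{\mathrm{SMR}}^2 =
   \frac{z_{zy}^2\, z_{zx}^2}{z_{zy}^2 + z_{zx}^2} \sim \chi^2_1 . $$

The statistic depends on the two studies only through their z-scores; the
test suite checks this metamorphically by rescaling effects and standard
errors together.

HEIDI distinguishes one shared causal variant from linkage of distinct
causal variants. For each selected non-instrument cis SNP $i$,
$d_i = \hat b_{xy}(i) - \hat b_{xy}(\mathrm{top})$. Under the
single-causal-variant null the vector $d$ is asymptotically multivariate
normal; its covariance follows from the delta method, with
$\mathrm{cov}(b_{zy,i}, b_{zy,j}) = r_{ij}\,\mathrm{se}_i\,\mathrm{se}_j$
(and likewise for $b_{zx}$; the GWAS and QTL cohorts are independent so
the two contributions add). Rather than an analytic approximation to the
distribution of $\sum_i (d_i/\mathrm{se}(d_i))^2$, the package samples
the null directly: 10,000 seeded Monte-Carlo draws from the fitted
multivariate normal (negative eigenvalues of the delta-method covariance
are clipped at zero before sampling — the reason a bespoke
eigen-decomposition sampler is used). This is simpler, testable, and
asymptotically equivalent; the p-value uses the add-one estimator
$(1 + \#\{T^* \ge T\})/(B+1)$, so it is never exactly zero.

SNP selection mirrors the cited software defaults: cis SNPs with
$p_{zx} < 1.57\times10^{-3}$, exclusion of SNPs with $r^2 < 0.05$ with
the instrument, greedy LD pruning at $r^2 > 0.9$ (most significant first,
instrument never pruned), and 3–20 SNPs. With fewer than 3 eligible SNPs
the feature is flagged "HEIDI not evaluable" and its p is missing; the
retention filter (below) does not discard such features, since absence of
evidence for heterogeneity is not evidence of it.

## Multiple testing

Bonferroni within a testing family, default family = one GWAS dataset x
one QTL dataset x one tool: `p < alpha / m` with `m` the family size and
`alpha = 0.05`. The family is configurable because published analyses are
ambiguous between per-panel, per-chromosome and global corrections;
per-panel-per-tool is the most common reading and is the default here.
SMR results with an evaluable HEIDI p additionally require
$P_{\mathrm{HEIDI}} > 0.05$.

Variants in the extended MHC (chr6:28477797–33448354, a 1-based closed
interval; configurable) are removed from the GWAS before any association,
because the region's long-range LD produces spurious weighted
associations. A feature whose entire instrument set lies in the excluded
region therefore vanishes from the SMR output — a property the tests
assert directly.

# Evidence integration

## The dictionary and reliable genes

Each significant result contributes one evidence line, keyed by exactly
five fields: *GWAS dataset — xQTL type — tissue group — tool — gene*.
Free-text tissue labels are collapsed to **brain / non-brain** by a
configurable keyword list before keying. Two consequences worth flagging:

* the QTL *dataset* is **not** part of the key — two eQTL panels with the
  same tissue group and tool contribute a single line;
* two raw tissue labels in the same group (e.g. two cortical regions)
  also collapse to one line.

A gene with at least `reliable_min_count = 2` distinct lines is reliable.
When curated (CG) and supplementary (SG) sources are combined, the
default "Total" mode **pools** lines before deduplication and
thresholding; the union of the separately-thresholded CG and SG sets is
also computed and reported, since pooling is a choice, not a given. The
pooled reliable set always contains the union (pooling can only add
lines), which the tests verify.

Gene symbols are canonicalized through a static alias table (exact, then
case-insensitive with hyphen/underscore folding); unmapped symbols pass
through verbatim and are reported, never dropped. The shipped table is a
small synthetic subset of well-known alias pairs, suitable for tests and
examples; production use should substitute a full nomenclature dump.

## Novelty

For each reliable gene the window
$[\mathrm{start} - 10^6,\ \mathrm{end} + 10^6]$ (gene-body anchored,
closed at both edges, clamped at 1) is scanned for the minimum GWAS p;
the gene is **novel** iff that minimum is strictly greater than
$5\times10^{-8}$. Gene-body anchoring is symmetric and strand-free, so
strand is ignored — TSS anchoring is a reasonable alternative and the
window half-width is configurable. The overlap join uses GenomicRanges;
a brute-force all-variant scan serves as the independent oracle in the
tests. Genes with no coordinates or empty windows are reported
"unclassifiable", never silently dropped — no window minimum exists, so
no call is made.

## Replication metrics and MMRP

Replication between gene sets is the directed ratio
$|A \cap B| / |A|$ — the denominator is the row set, so the matrix is
asymmetric and each entry times its denominator recovers the integer
overlap. Replication *times* of novel vs non-novel genes are compared by
group medians plus a two-sided Wilcoxon rank-sum test (normal
approximation with tie correction); the literature this mirrors reports
significance without naming a test, and the rank-sum choice suits small
counts with heavy ties. Groups of fewer than two genes, or all-tied
counts, flag the test degenerate rather than reporting a fragile p.

A gene mapped by $\ge 2$ QTL types belongs to exactly **one** MMRP: the
full set of its QTL types (not every subset) — so per-disorder pattern
counts partition the multi-QTL genes, an invariant the suite checks on
every synthetic run. Overlap and pattern accounting operate on canonical
gene symbols only; transcript-, probe- and peak-level identity is
deliberately collapsed.

# The synthetic cohort

The simulator provides the causal structure the statistics assume, not a
portrait of any real dataset.

* **Genotypes** — hard-call dosages from two latent-Gaussian haplotypes
  per individual, AR(1) correlation $r^{|i-j|}$ within contiguous blocks
  (default $r = 0.9$, block size 20), independent across blocks, MAF
  uniform on [0.05, 0.5], one variant per 5 kb. Defaults give 2,000
  individuals and 600 variants.
* **Molecular layers** — every layer runs through the same code path:
  anchor variant, ±500 kb cis window, one causal cis variant with
  N(0, 0.35²) effect, unit-variance Gaussian noise. 40% of features in
  non-eQTL layers reuse an eQTL feature's causal variants and gene symbol
  (cross-layer sharing) — the minimal structure that makes cross-QTL
  replication and MMRP outputs non-degenerate. m6A features are assigned
  a host gene symbol directly, like every other layer.
* **Trait** — a quarter of features mediate with N(0, 0.25²) effects,
  plus 10 direct variant effects N(0, 0.12²) and unit noise. Case-control
  disorders are emulated on this quantitative liability scale because
  every downstream statistic consumes z / beta / se only.

These sizes are chosen so that a default run finishes in seconds yet
yields a non-trivial handful of Bonferroni survivors. What the simulator
does **not** emulate: population structure, relatedness, imputation
noise, sex chromosomes, realistic effect-size spectra, or case-control
ascertainment — so passing tests demonstrate the statistical machinery
and its calibration, not robustness to those real-data complications.

All randomness flows from one integer seed; each stage (and each HEIDI
feature) derives a named substream, so stages are independently
reproducible and a full pipeline re-run is byte-identical — the suite
compares the serialized output tables of two runs directly.

# Numerical choices

* Residual sums of squares in the marginal scans are floored at
  $\max(\mathrm{SYY}\cdot 10^{-16}, 10^{-300})$ so that a noise-free
  feature yields a huge finite z with `z = beta/se` holding exactly.
* The HEIDI null covariance is symmetrized and its eigenvalues clipped at
  zero before sampling; per-SNP variances are floored at $10^{-12}$.
* Coordinates are 1-based closed throughout; the BED-style annotation
  reader converts its 0-based start column on read (the only 0-based
  field in any interface).
* Strand-ambiguous variants (A/T, C/G) are dropped during harmonization
  rather than frequency-resolved — the simplest auditable convention, and
  the simulator emits non-ambiguous pairs so nothing is lost by default.
* The sharing-enrichment check uses a Haldane–Anscombe corrected odds
  ratio (+0.5 per cell) so it stays finite when a cell is empty.

# Validation suite sizes

The acceptance checks run at fixed sizes chosen as the smallest that make
the binomial/Monte-Carlo tolerances meaningful: type-I error over 2,000
trait-null features (n = 2,000 individuals; acceptance band 0.03–0.07 at
$\alpha = 0.05$), HEIDI retention over 200 independent shared-causal
cohorts (≥ 0.90 expected), Wald-ratio recovery over 200 replicates at
n = 5,000 (±0.05 around the true 0.3), power monotonicity over 100
replicates per effect size, and oracle agreement on 1,000 random genes.
`scripts/acceptance.R` re-runs all of them from scratch.

# Known limitations

* No conditional/joint analysis, fine-mapping, colocalization or
  multi-tissue joint imputation; the package integrates marginal
  feature-level results only.
* The HEIDI delta-method null degrades when instrument effects are weak
  (the $1/b_{zx}$ expansion); the eligibility threshold guards this but
  does not remove it.
* Evidence-line semantics inherit the printed dictionary's coarseness:
  distinct QTL panels and distinct within-group tissues are not extra
  evidence.
* The alias table ships as a deliberately small fixture; symbol coverage
  is the user's responsibility in production.
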