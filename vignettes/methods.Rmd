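---
title: "Models and methods in pleioscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in pleioscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pleioscan implements a pipeline for dissecting the genetic correlation
between a focal complex trait (the motivating application is body mass
index) and a panel of endophenotypes (structural brain MRI measurements)
down to the level of genes and individual regulatory variants. The stages
are: cross-trait LD score regression; summary-based Mendelian
randomization with the HEIDI heterogeneity test; a circular permutation
test of gene-set overlap; elastic-net prediction of genetically regulated
expression (GReX) with individual-level confirmation; sum-of-single-effects
fine-mapping with pairwise colocalization, network assembly and
credible-set intersection; and epigenetic scoring of candidate variants by
gapped k-mer accessibility models and PWM motif-disruption calls. Every
stage is exercised end to end on synthetic data with known ground truth.
This vignette records the statistical models, the tunable parameters, the
numerical choices, and what the synthetic validation does and does not
establish.

## The synthetic-data generator

`simulate_ld_panel()` draws diploid dosages in LD blocks by a
haplotype-copying scheme: within a block each variant's allele copies a
shared base haplotype with probability `sqrt(within_block_corr)` and is
drawn fresh at the block's MAF otherwise. The allele correlation inside a
block is then *exactly* `within_block_corr`, which is why this scheme was
preferred over thresholding a latent Gaussian: thresholded indicators have
a (phi) correlation strictly below the latent (tetrachoric) one, so a
latent model cannot produce near-unit dosage LD, whereas real tightly
linked variants do reach r² above 0.95. For the same reason variants of a
block share one MAF (drawn per block from `maf_range`, default
(0.05, 0.5]): binary variables with different margins cannot be highly
correlated, and tightly linked real variants have near-identical allele
frequencies. Blocks are independent; positions are evenly spaced (default
10 kb) on one chromosome; allele pairs are drawn from the unambiguous set
(no A/T or C/G), emulating post-QC summary data.

`simulate_trait_pair()` draws per-variant causal effects, bivariate normal
at shared causal variants with per-pair correlation
`rho_g / shared_fraction`, so the genetic correlation of the two genetic
values targets `rho_g` (the usual rg scale, not the covariance scale).
Genetic values are rescaled to have sample variance exactly `h2` and
phenotypes are standardized — matching the z-score conventions of the
downstream summary-statistic methods. An environmental correlation
(`rho_e`) covers the same-cohort (sample-overlap) case, which the free
LDSC intercept absorbs. `compute_marginal_stats()` is the per-variant
simple-regression scan behind both GWAS summary statistics and
Matrix-eQTL-style cis-eQTL scans; on standardized data the slope is the
sample correlation and `z = r sqrt((n-2)/(1-r^2))`, the exact t statistic.

What this emulates — and what it does not: LD is block-exchangeable, with
no haplotype mosaics, recombination gradients, population structure,
imputation error or sex chromosomes. A test that passes here shows the
estimators are correct under their own assumptions, not that they are
robust to confounding present in real cohorts (the LDSC intercept exists
precisely because real data violate them).

## Cross-trait LD score regression

`compute_ld_scores()` sums squared correlations within a 2 Mb window with
the small-sample adjustment `r² − (1 − r²)/(n_ref − 2)`. The cross-trait
fit is `E[z1 z2] = sqrt(N1 N2) ρ_g l_j / M + intercept`, weighted least
squares with the standard two-step heteroskedasticity weights
(`1/l` first pass, then `1/(l ((1 + N1 h2_1 l/M)(1 + N2 h2_2 l/M) +
(c + sqrt(N1 N2) ρ l/M)²))`); univariate fits of `z²` supply the
heritabilities. The intercepts are free because the motivating study's
cohorts overlap. Standard errors come from a delete-one block jackknife
over contiguous variant blocks; `rg = ρ_g / sqrt(h2_1 h2_2)` is reported
raw with an out-of-bounds flag, and flagged undefined (never silently NaN)
when a heritability estimate is non-positive.

Two numerical points discovered during development and worth keeping in
mind. First, the jackknife block width must exceed the LD correlation
length: with 2,000 variants and the software-default 200 blocks the blocks
are smaller than an LD block and the SEs are anti-conservative; the
package keeps 200 as the function default (the convention at millions of
variants) but the validation studies use 50 blocks, and so should any
analysis at a few thousand variants. Second, the regression is only
identified when LD scores vary, so the validation genomes use
heterogeneous block sizes (1–20 variants).

The partitioned analysis stratifies the same regression over a full
annotation partition (`E[z1 z2] = sqrt(N1 N2) Σ_c (ρ_c/M_c) l_jc + c`);
gene annotations are ±2 Mb windows around each TSS (a 4 Mb window).
`mc_enrichment()` draws the annotation and total covariances from
independent normals at their (estimate, SE), reports the one-sided
p-value as the fraction of draws whose covariance fraction falls at or
below the SNP fraction, and the log2 of the median fraction over the SNP
fraction (50,000 draws by default). Independence of the two draws is an
assumption — the jackknife covariance between them is not propagated — and
draws in which the total covariance changes sign are excluded and counted.

## SMR, the approximate PPA and HEIDI

With the top cis-eQTL (|z| maximal, p below 5e-8 by default; positional
tie-break) as instrument, the Wald ratio `b_smr = b_gwas/b_eqtl` has test
statistic `T = z_gwas² z_eqtl²/(z_gwas² + z_eqtl²)` (1-df chi-square).
The posterior probability of association is a deliberate approximation:
the original multi-omics joint model is replaced by a Wakefield-style
approximate Bayes factor on the SMR statistic
(`ABF = sqrt(V/(V+W)) exp(WT/2(V+W))`, `V = se_smr²`, prior variance
`W = 0.15²`, prior probability `π = 0.01`), converted to a posterior.
Because the ABF is monotone in `T` at fixed `V`, the 0.5 PPA threshold
plays exactly its original gatekeeping role; the approximation preserves
ranking and thresholding, not the numerical PPA values of the joint model.

HEIDI tests whether the Wald ratios at companion cis variants (eQTL
chi-square > 10, r² to the instrument in [0.05, 0.9], at most 20 —
the reference-implementation defaults) are consistent with a single
shared causal variant. The covariance of the ratio differences comes from
the delta method, with each cohort's own LD supplying the correlation of
its effect estimates across variants (`panel` for the eQTL side,
`panel_gwas` for the GWAS side; the cohorts themselves are independent). The resulting sum of
squared standardized differences is a quadratic form in correlated
normals; its upper tail is evaluated by the four-moment (Liu–Tang–Zhang)
chi-square approximation on the eigenvalues of the correlation matrix,
which is better calibrated in the far tail than a two-moment
Satterthwaite match. HEIDI inherits a mild anti-conservatism from
sampling noise in the LD reference: with a ~700-sample reference the
shared-causal rejection rate at α = 0.05 is about 0.09, dropping to
~0.04 with a large reference. The validation studies therefore take LD
from the large GWAS cohort; with a small external reference (the
realistic setting) expect slightly inflated rejection. Genes with fewer
than 3 eligible companions are flagged untested and pass by default.

Discovery requires `PPA ≥ 0.5` and `p_HEIDI ≥ 0.05` for the focal trait
and for at least one endophenotype; no multiplicity correction is applied
at discovery (the threshold on PPA, not FDR, is the filter), and per-gene
values are reported for downstream correction.

## Circular permutation of gene labels

Genes ordered by TSS are split into K equal-size contiguous chunks
(chromosome boundaries are deliberately not respected — the observed list
is equally flat); the focal-trait labels are rotated within each chunk by
an independent uniform offset and the chunks reassembled in random order;
only the focal labels move. The empirical p-value uses the add-one
(permutation-inclusive) correction, so `p ≥ 1/(n_perm+1)` and rotations
preserve the multiset of label run lengths — the property that makes this
test respect genomic clustering where a naive label shuffle would not.
Chunk sizing is exposed as configuration (`K = 1, 5, 10` scanned by
`consistency_scan()`); note that a single K can be blind to structure at
its own period, which is exactly why the scan exists.

## GReX models and TWAS confirmation

Expression is first residualized on covariates, then an elastic net
(mixing 0.5, penalty by cross-validation on the training split — the
method family is fixed, the hyperparameters are conventional) is fit on
standardized cis dosages (±1 Mb) using a seed-deterministic 80/20 split.
Models pass when the *signed* holdout Pearson correlation is ≥ 0.1 with
nonzero prediction variance; the signed filter exists because a negative
correlation between predicted and measured expression signals a fitted
artifact, not predictive power. Under permuted expression the
cross-validated penalty usually selects the empty model (zero prediction
variance → automatic fail); the residual pass rate is the null
probability that a holdout correlation exceeds 0.1, so adequate holdout
size (≥ 200) matters. Imputation into a target cohort is a linear score
on the training standardization scale, with a1/a2-swapped encodings
aligned by dosage reflection and a 50% missing-variant refusal threshold;
the TWAS step is least squares of the phenotype on the imputed GReX plus
covariates, reporting sign concordance with the SMR effect.

## Fine-mapping, colocalization, network, intersection

`finemap_locus()` is a sum-of-single-effects decomposition on summary
statistics in the sufficient-statistics representation (`X'X = nR`,
`X'y = sqrt(n) z`, unit residual variance on the z scale): at most L = 10
effects, each refit coordinate-wise on residualized marginal estimates,
with the per-effect prior variance estimated by maximizing the
single-effect likelihood (an effect whose likelihood peaks at zero prior
variance is nulled — this is what keeps null loci at zero credible sets).
Convergence is a 1e-4 change threshold on the posterior-mean effects with
deterministic uniform initialization. The 95% credible set per effect is
the smallest descending-posterior prefix at coverage, discarded below 0.5
purity (minimum absolute within-set LD).

Colocalization combines per-variant log Bayes factors of two decomposed
signals into the five standard hypothesis posteriors with priors
`p1 = p2 = 1e-4`, `p12 = 1e-5`; a pair colocalizes when `PPH4 > PPH3`.
Computations are in log space; the H3 term uses the exact
`S1·S2 − S12` identity, so a three-variant locus matches brute-force
configuration enumeration to numerical precision.

The trait network has one node per decomposed signal in three classes
(expression / focal / endophenotype); near-duplicate endophenotypes (same
category, |rg| > 0.9) collapse to a representative sized by member count.
Cliques — triangles with one node of each class — carry strong evidence of
three-way colocalization; trios with exactly two edges are flagged weak.
For the credible-set intersection the expression signal anchors the
choice of effects: the expression effect with the strongest
colocalization against either trait is chosen first, then each trait's
effect maximizing PPH4 against it. (Choosing each trait's globally best
pair independently fails when a locus carries two genuine signals: the
two traits can anchor on the other gene's variant and the intersection
comes out empty.) The lead variant is the smallest GWAS p among
genome-wide-significant members; members are annotated with R² to the
lead and flagged high-LD above 0.5; an empty intersection demotes the
clique with the reason recorded.

## Accessibility models and delta scores

Peak sequences are classified against dinucleotide-shuffled backgrounds
(GC-matched i.i.d. background as the alternative) on explicit gapped
k-mer counts — all length-l windows with l−k wildcard positions, counted
on both strands so a sequence and its reverse complement give identical
features; windows containing N are skipped. The classifier is regularized
logistic regression by default (a linear SVM is available when e1071 is
present); the published scoring scheme this emulates is itself a linear
k-mer-weight lookup, so the substitution of explicit features for the
string kernel preserves the scoring semantics. The variant score is the
model-score difference between the alternate and reference windows
(±(l−1) around the SNV) — exactly additive over features, hence zero for
identical windows and invariant to edits outside the window. Defaults are
l = 6, k = 4 rather than the l = 10, k = 6 of full-scale practice: at
10/6 the explicit feature space (~860k gapped words per window set)
is far beyond what an interpreted feature counter should attempt, while
6/4 (≤ 3,840 features) trains in seconds and preserves every property the
scoring depends on. Cell types with fewer than `n_pos` peaks are skipped
and exactly `n_pos` are subsampled for training (default 5000, mirroring
common accessibility-model practice; the synthetic studies train on
400–800 60-bp peaks, which suffices for AUROC > 0.9 against a sharp
embedded motif).

The magnitude of a delta score lives on the classifier's weight scale, so
the |delta| > 2 flag should be read relative to the model: under the
synthetic training regime neutral substitutions score |delta| < 1 and
core-creating substitutions 2–4, making 2 a usable separation point; with
differently regularized models the threshold is configuration.

## Motif disruption calls

PWMs carry pseudocount-adjusted probabilities (1e-3 per base — motif
databases contain zeros) and log2-odds against a configurable background
(uniform by default). A variant is classified by scanning every placement
overlapping it on both strands and comparing ref and alt *at the same
placement*, the one scoring best under either allele — comparing each
allele's own best placement shifts the site and overstates effects. The
effect is a gain or loss by the score difference and "strong" exactly
when the two log-odds scores have opposite signs; no additional magnitude
threshold is imposed. Two synthetic PWMs ship with the package: an
ETS-like example (sharp GGAA core, weak flanks — designed so that
creating or destroying the core flips the score sign at the core-aligned
placement in essentially any context) and a sharp width-10 accessibility
motif for embedding discriminative signal in training peaks. They are
synthetic constructions, not database motifs; both are labelled as such.

## The end-to-end pipeline and validation scales

`run_pipeline()` wires the stages together on one synthetic genome: a
configurable number of genes, of which the first `n_pleiotropic` have a
single cis causal variant that also drives the focal trait (positively)
and the endophenotype (negatively, matching the predominantly negative
correlations that motivate the design); the remaining genes carry private
eQTLs. All thresholds live in one validated configuration that
round-trips through YAML; stage outputs are TSVs with a provenance
header, and a rerun with the same configuration is deterministic. The
epigenetic stage embeds the accessibility motif in the training peaks and
places the true causal variant in a context where the reference carries
AGAA and the alternate allele completes the motif's GGAA core, so the
planted variant should be flagged by the accessibility model and called a
strong ETS gain.

Validation problem sizes (chosen once as realistic desk-scale analogues
of the study conditions): genetic-correlation recovery uses 100 trait
pairs on a 20,000-individual, 2,000-variant genome (heritability 0.5,
rg −0.3, 400 shared causals); HEIDI calibration uses 200 shared-causal
and 60 linkage (r² = 0.5, GWAS n = 20,000) scenarios; credible-set
coverage uses 200 single-causal loci at n = 8,000; the end-to-end study
runs 20 seeds at n_gwas = 3,000 with one pleiotropic gene among four.
`scripts/acceptance.R` re-runs scaled versions of the same studies from
scratch and writes the resulting quantities as JSON.

## Known limitations

The generator's LD is exchangeable within blocks; estimators that exploit
fine-scale LD decay are not stressed. The PPA is an approximation with
the thresholding role of the original, not its value scale. HEIDI's
calibration degrades with small LD references. The Monte Carlo enrichment
treats the annotation and total covariance estimates as independent.
Delta-score magnitudes are classifier-scale-dependent. Binary traits
(liability scale), multi-ancestry analysis, functional-prior fine-mapping
and cross-tissue joint expression models are out of scope.
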