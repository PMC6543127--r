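---
title: "Methods and design notes for gutflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for gutflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

gutflow implements the downstream statistics of a case-control gut
metagenome + metabolome study as one tested pipeline. This vignette
records the models behind each stage, the parameters that matter, the
numerical conventions, and the choices we made where the field's usage is
genuinely ambiguous.

## Data model

All abundance data travel as an `AbundanceMatrix`, a
`SummarizedExperiment` with a single `abundance` assay and a `kind` flag
(`depth`, `count`, `relative`, `peak_area`). Validity enforces
non-negative values, unique identifiers, and column sums of 1 (within
1e-9) for relative profiles. Feature filtering deliberately does *not*
re-normalise the surviving rows — the filtered values are still relative
abundances of the original community, so the result is flagged `count`
and callers that need proper compositions (the Jensen-Shannon step)
re-close the columns explicitly.

## Ecology

Shannon diversity is computed in natural log; the literature uses both
nats and bits, so a `base` argument is exposed (`base = 2` for bits).
Chao1 uses the bias-corrected form S + F1(F1-1)/(2(F2+1)), which stays
defined when no doubletons are observed; it is an estimator on integer
counts, so fractional input is an error rather than silently rounded
(`diversityReport()` rescales relative abundances by 1e6 before
counting). Pielou evenness is H/ln(S) and requires at least two observed
taxa. Rarefaction draws samples *with replacement* — the accumulation
design for judging whether a cohort saturates the gene catalogue — and a
gene counts as identified when its depth is positive in at least one
drawn sample; 100 iterations is the default, exposed as a parameter.

## Enterotyping

The sample dissimilarity is the square root of the Jensen-Shannon
divergence in log base 2: a proper metric bounded in [0, 1], with
zero-probability terms contributing nothing. Clustering is partitioning
around medoids (BUILD + SWAP via `cluster::pam`), which is deterministic
for a fixed distance matrix; the `seed` argument exists only for API
symmetry. The cluster count is chosen by the Calinski-Harabasz index in
its distance-based form: the within mass is
W = sum over clusters of sum(D^2 within)/(2 n_c), the total analogue is
sum(D^2)/(2n), and CH(k) = [B/(k-1)]/[W/(n-k)]. No coordinates exist for
the textbook CH, and this squared-distance decomposition is the accepted
generalisation; note that on essentially one-dimensional data it can
favour splitting diffuse clusters, which is why the model-selection test
fixtures are multivariate. Genera enter the analysis after the standard
screen (mean relative abundance >= 1e-4, present in >= 6 samples,
"present" meaning strictly positive, evaluated once on the full cohort).
The 2x2 cluster-by-group association uses our own Fisher exact test —
two-sided by the "probability at most that of the observed table" rule
with a 1e-7 relative tie tolerance — cross-checked in the suite against a
full hypergeometric enumeration and against `stats::fisher.test`; with
more than two clusters the association falls back to Pearson chi-square.

## Differential abundance and clinical tables

Per-feature testing is the two-sided Wilcoxon rank-sum test: exact
enumeration when the pooled size is at most 20 and tie-free, otherwise
the normal approximation with tie and continuity corrections. Multiple
testing uses Benjamini-Hochberg with significance at q < 0.05. Direction
is simply the larger group mean. Heatmap z-scores standardise each
feature row by its *population* SD (divide by n); the sample-SD variant
is a switch. For baseline tables reported only as summary statistics, the
t-test is the pooled-variance form with df = n1+n2-2 (a Welch switch is
provided), and the 2x2 chi-square is Pearson *without* Yates continuity
correction — with the correction the standard sex-distribution example no
longer reproduces its printed p-value, so uncorrected is the convention
these tables use.

## Co-abundance gene groups

Marker genes are those differential between groups at q < 0.05. Canopy
clustering then groups marker genes by co-abundance: seeds iterate in
descending mean-abundance order (ties broken by gene id), a canopy is
every unclustered gene with Pearson correlation >= 0.9 to the seed
profile, the centre is re-set to the member-wise median profile and
membership re-evaluated to a fixed point (at most 20 rounds), and members
leave the pool. The deterministic seeding replaces the stochastic
ordering of classical canopy so identical inputs give identical
partitions. The 0.9 threshold is the canonical setting for depth-profile
co-abundance and is configurable. Clusters must exceed 50 genes to be
CAGs; smaller clusters are reported but never promoted.

CAG abundance is the length-weighted mean depth sum(d_g L_g)/sum(L_g).
Taxonomy follows the tracer-gene rules: a species call needs >= 90% of
member genes hitting one species at >= 95% nucleotide identity and
>= 70% query overlap; failing that, a genus call needs >= 80% of genes at
>= 85% identity in *both* DNA and protein; otherwise unassigned.
Candidates are ranked by (fraction of genes mapped, then mean nucleotide
identity). We read the species rule's "95% identity" as nucleotide-only
(it comes from a nucleotide-alignment context), while the genus rule
explicitly requires both columns. Hits are assumed pre-filtered by the
upstream e-value (< 1e-5) and coverage contract.

Enrichment is a presence odds ratio: the 2x2 of presence against group,
OR = ad/bc with the Haldane-Anscombe +0.5 on every cell when any cell is
zero, case-enriched above 2 and case-depleted below 0.5. The presence
threshold defaults to 0 ("detected at all"), but because length-weighted
CAG abundances in dense depth data are strictly positive, the end-to-end
`buildCAGs()` uses the CAG's median abundance as the split — a
median-presence reading of "based on the abundance in the compared
samples" that keeps the cutoffs meaningful; both options are exposed.

## Discrimination stage

The cohort is split 80/20 stratified by group. Features are ranked
*once* on the full training set by random-forest permutation importance
(mean decrease in accuracy, 500 trees); for each candidate count k the
misclassification error of a forest on the top-k features is estimated by
stratified 10-fold cross-validation repeated over 5 reshuffles, and the
selected k is the argmin with ties towards the smaller model. Ranking
once and truncating reproduces the usual "error versus number of
variables" curve design; the per-fold re-ranking alternative (which
avoids the known selection-bias optimism) can be had by calling
`cvErrorCurve()` per fold, but is not the default because the curve is a
model-selection device here, not an unbiased error estimate. AUC is the
rank (Mann-Whitney) formulation with half-credit for ties; confidence
intervals are DeLong's analytic estimator (the pROC default), truncated
to [0, 1], with the degenerate all-separated case flagged. Training-set
probabilities are out-of-bag so the reported training AUC is not
trivially 1.

## Metabolomics

Peak tables are normalised so each sample's total area is 1,000,000.
PLS-DA is NIPALS PLS1 on mean-centred, unit-variance-scaled features
against the centred +/-1 class response (the second factor level codes
+1), deflating X per component; with one response column the weight
update is a one-pass fixed point, and the iteration cap (500) and
tolerance (1e-10) guard the general update. Autoscaling is the
chemometrics default; centre-only is a switch. Constant features cannot
be scaled and are dropped with a warning. VIP is
sqrt(p * sum_a SS_a w_aj^2 / sum_a SS_a) with SS_a = q_a^2 t_a't_a, so
mean(VIP^2) = 1 exactly — an identity the suite asserts to machine
precision. OPLS-DA implements the Trygg-Wold orthogonal filter (w_orth
is the response-orthogonal remainder of the loading); its orthogonal
scores satisfy t_orth'y = 0 by construction and the fit with zero
orthogonal components reduces exactly to one-component PLS-DA.

Differential metabolites are the conjunction VIP > 1 (from a 2-component
PLS-DA, matching the dimensionality of the usual score plots) and
p < 0.05 from a two-sided Welch t-test on normalised areas; fold change
is the case/control ratio of group means. Compounds detected in both
ionisation modes keep the mode with the lower p. Serum/feces concordance
intersects the selected compound names and splits them by the sign of
log2 fold change; the heat matrix standardises each compartment's log2
fold changes to mean 0, SD 1 across the shared compounds (our reading of
a "t-score" transform of fold changes, for which no formula exists in
common usage).

## Microbe-metabolite integration

Spearman correlations (average ranks for ties; exact p for n <= 9
without ties, t-approximation otherwise) between selected taxa and
selected metabolites over the samples shared by both data sets. Stars
follow the heatmap convention on *raw* p (0.05 / 0.01) because that is
what such figures annotate; a BH-adjusted matrix is emitted alongside for
honest reuse. Serum values are used for the taxon correlations in the
pipeline, matching the common design where serum is the compartment of
clinical interest.

## The synthetic-data generator

The generator provides study-shaped inputs with known truth; its defaults
are the package's reference conditions and are not tuned per analysis:

* **Cohort** — 50 cases + 50 controls, the scale of a typical
  case-control metagenome cohort.
* **Gene study** — 800 genes: three planted blocks of 60 genes whose log
  depths share a lognormal latent factor (factor SD 0.6, within-block
  correlation 0.95, alternating-sign fourfold group effects), the rest
  independent noise. Depths below 0.25 are reported absent, giving
  realistic presence variation; with correlation 1 and zero noise the
  construction degenerates to exact scalar multiples, which the suite
  uses as a sanity case. Gene lengths are uniform on [300, 3000] nt. Each
  block's genes hit one synthetic species genome at rate 0.95 with
  identities satisfying the species rule.
* **Taxon study** — 60 genera from a fixed catalogue (with a
  genus-to-phylum map containing Firmicutes and Bacteroidetes); each
  sample is a Dirichlet draw whose parameter vector differs between the
  two enterotypes only in the dominant mass (Bacteroides 30 versus
  Prevotella 30, against 0.5 for the non-dominant driver). Cases are 82%
  enterotype 1, controls 50% (exact counts). Twenty planted genera carry
  alternating fourfold effects; up-shifted genera get baseline Dirichlet
  mass 1 and down-shifted mass 4 so the expected compositional mass moved
  in each direction cancels and non-planted genera stay null — and
  because the imbalanced enterotype mix genuinely shifts the two driver
  genera, the ground truth lists them as differential too.
* **Metabolome** — 300 lognormal features per compartment and mode over
  the same samples; 27 compounds differential in both compartments (16
  sign-concordant), 20 more per compartment differential there only,
  threefold effects, noise SD 0.4 on the log scale, a third of compounds
  present in both modes, and 8 compounds linearly coupled (coefficient
  0.8 on the log scale) to planted genera.
* **Clinical table** — group-specific normal/lognormal draws in the
  layout of a baseline-characteristics table; total cholesterol defaults
  to 4.13 +/- 1.05 versus 4.82 +/- 0.96 mmol/L and sex to male
  proportions 32/50 versus 41/50, so the printed-table statistics can be
  reproduced from re-simulated raw data as well as from the summaries.

What the generator deliberately does **not** emulate: sequencing reads,
assembly and catalogue construction; compositional count noise
(taxon profiles are exact Dirichlet draws, not multinomial subsamples);
batch effects and covariate confounding; retention-time drift, isotopes
and adducts in LC-MS. Passing the recovery tests therefore demonstrates
that the statistics are implemented correctly and behave as designed
under their stated model — not that real cohorts will yield effects this
clean, nor the cohort-specific counts a real study reports.

All generators are bit-deterministic under `seed`; each derives its
stream from a fixed offset of the configured seed so the studies can be
generated independently or together.

## Problem sizes and runtime

The default study (100 samples, 800 genes, 60 genera, 4 x 300 metabolite
features) runs the complete pipeline in seconds on one core, which is the
scale we chose for the reference conditions and the test suite; the
null-FDR simulation uses 50 replicates of a 200-genus cohort, and the
permutation check of the classifier averages 20 relabelled runs. All
sizes are configuration, not constants.

## Known limitations

* The canopy procedure evaluates membership against the current pool
  only; a gene captured by an earlier canopy is never reconsidered, so
  cluster boundaries depend on the (deterministic) seed order.
* The distance-based CH criterion inherits the sum-of-squares geometry;
  for elongated or heavy-tailed single clusters it can prefer splits.
* Presence odds ratios on strictly positive abundance vectors require a
  split choice; the median split is a design decision, and studies whose
  abundances contain genuine zeros should use the explicit threshold.
* DeLong intervals collapse to a point under perfect separation; the
  report flags this rather than widening the interval.
* FDR control is the BH guarantee under independence/PRDS; strongly
  correlated features (co-abundant genes by construction) make q-values
  conservative rather than anti-conservative, which is the usual trade.
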