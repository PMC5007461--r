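---
title: "Methods: proteomic stratification and signature derivation with protsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteomic stratification and signature derivation with protsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protsig)
```

`protsig` packages the analysis chain commonly used to stratify deep
label-free proteomes of tumours and cell-line panels: quantification,
filtering, imputation, clustering, discriminating-signature derivation,
signature application and survival comparison. This vignette documents the
models behind each stage, the parameters that matter, the numerical
conventions, and what the synthetic validation data do and do not
establish.

## Label-free quantification

The quantification core assumes peptide intensities are proportional to
protein abundance times a peptide-specific response factor. Ratios between
samples cancel the response factor, so for each protein and each sample
pair the protein-level log2 ratio is estimated as the **median of all
pairwise peptide log2 ratios**, using only peptides observed in both
samples (`build_ratio_graph()`). A minimum shared-peptide count per pair
(`min_ratio_count`, default 1) controls edge quality.

These pairwise ratios generally over-determine (and, with noise,
contradict) a single abundance profile, so the per-sample log2 profile $x$
is the least-squares solution of

$$\min_x \sum_{(a,b) \in E} (x_a - x_b - r_{ab})^2,$$

solved per connected component of the protein's sample graph via the graph
Laplacian normal equations with one node anchored at zero
(`reconstruct_profiles()`). The gauge freedom (an additive constant per
component) is fixed by requiring the summed linear abundance of the
component to equal the protein's summed observed peptide intensity, so
totals are preserved. Conventions for degenerate inputs: a sample with no
observation stays missing; a single-sample component keeps its observed
intensity (total preservation forces this); peptide intensities of zero
are treated as missing, matching the common missing-value sentinel.
Components are handled independently because ratios are undefined across
disconnected sample sets. The solver is exact linear algebra; tests
require agreement with an independent dense QR solve to 1e-9 and exact
recovery (up to the per-component constant) on noiseless tables. Fast
pairing heuristics and delayed normalization used by some implementations
are deliberately not modelled; the plain least-squares formulation is the
reference behaviour here. iBAQ abundance (`compute_ibaq()`) is summed
intensity divided by the count of theoretically observable peptides.

## Filtering, transformation and imputation

All analysis happens on log2 intensities with `NA` as the missingness
mask (`protein_matrix`). The canonical stage order, enforced by
`run_pipeline()` but with every operation also usable standalone:

1. **Flag removal** — decoy (reverse) and identified-only-by-site rows are
   always artefacts; contaminant rows are dropped by default but the flag
   is separable (`remove_flagged(contaminants = FALSE)`).
2. **Replicate filter** — within each cell line a protein must be
   quantified in at least 2 of 3 replicates (`min_quantified`, default 2);
   failing line-blocks are set missing, and rows missing everywhere are
   dropped. Lines with fewer replicates than the threshold are handled
   generically (the threshold is capped at the available replicates).
3. **Replicate averaging** — the mean of valid replicate log intensities
   per line; iBAQ values are averaged on linear scale.
4. **Minimum valid values** — a row must carry `n` quantifications
   (10 for whole-panel clustering; a stricter 30-of-41-style threshold is
   appropriate for integrated PCAs across cohorts).
5. **Plasma-protein removal** — for tissue-containing analyses, the ~200
   most abundant plasma proteins are removed. The packaged list
   (`plasma_proteins()`, `inst/extdata/plasma_proteins_synthetic.txt`) is
   a synthetic stand-in assembled from common plasma protein gene symbols;
   substitute a curated list for real analyses.

**Imputation** (`impute_downshifted()`) models left-censored missingness:
values are missing mostly because they fall below the detection limit, so
each missing entry in sample $j$ is drawn from
$N(\mu_j - 1.8\,\sigma_j,\ (0.15\,\sigma_j)^2)$ with $\mu_j, \sigma_j$ the
observed column moments. The `width` (0.15, fraction of the column SD) and
`down_shift` (1.8 column SDs) defaults are the established proteomics
convention for this imputation; imputation is per sample by default (a
whole-matrix mode exists behind `per_column = FALSE`), never alters
observed entries, records the imputed mask in `$imputed`, and is
deterministic under its seed. Columns with fewer than two observed values
are skipped with a warning.

**Standardization** (`zscore_matrix()`) z-scores each protein across
samples with the sample (n−1) SD; zero-variance rows become zeros with a
warning rather than an error, since constant rows are uninformative but
harmless downstream. When label-free and isobaric-tag cohorts are mixed,
`groupwise = TRUE` standardizes within each cohort so technology-specific
location/scale differences cannot drive a joint clustering. Isobaric-tag
reporter matrices are first normalized against the pooled control channel
of each run and median-centred per sample (`normalize_itraq()`).

## Variability profiling

`protein_variability()` computes, per protein quantified in at least
`min_valid` lines (default 10), the SD of its log intensity across lines
and its abundance as log10 of summed iBAQ. The SD is reported on log10
scale by default (the conventional variability axis; `log_base = 2` gives
log2 units), and `high_variability_set()` applies a strict SD cutoff
(default 0.5). Note the interaction between effect size and log base: a
planted log2 effect of $e$ in one of three groups contributes a
between-group SD of about $0.47\,e$ log2 units, i.e. $0.14\,e$ log10
units, so at small effects the 0.5 log10 cutoff intentionally captures
only the strongest regulation.

## Clustering and PCA

Sample similarity uses **Spearman correlation distance**
$d = 1 - \rho_s$ with average ranks on ties, making the distance invariant
under any strictly monotone per-sample transform; constant columns make
the correlation undefined and raise an error naming the offending column.
Agglomerative clustering (`hierarchical_cluster()`) defaults to **average
linkage** — the linkage is not dictated by the method, and average linkage
is the default of the established interactive software for this workflow;
`complete` and `ward.D2` are available. `cut_clusters()` cuts to exactly
$k$ groups. PCA (`pca_samples()`) treats samples as observations and
centred proteins as variables, via SVD; explained fractions are the
normalized squared singular values, and each component's sign is fixed so
its largest-magnitude loading is positive, making outputs reproducible
across platforms. Whether PCA runs on raw log or z-scored intensities is a
per-stage choice; the pipeline clusters and decomposes the z-scored
matrix.

## Moderated statistics and false-discovery control

`moderated_t()` computes the SAM-type statistic
$t = \frac{\bar a - \bar b}{se + s_0}$ with a pooled two-sample standard
error by default (the cited statistic's convention; Welch is available
behind `var = "welch"`). The constant $s_0$ damps features whose tiny
variance would otherwise make trivial differences significant: $s_0 = 4$
is used for signature ranking, where only large, robust differences should
lead, and $s_0 = 2$ for volcano-style pairwise comparisons. The p-value
evaluates the moderated statistic against the Student reference
distribution of the unmoderated one — a deliberate, conservative
convention; where calibration matters, `permutation_fdr()` compares
observed $|t|$ against label permutations and estimates, at each cutoff
$c$, $\widehat{FDR}(c) = \frac{\text{mean permuted count} \ge c}{\text{observed count} \ge c}$,
with monotone q-values by running minimum. When the number of distinct
label arrangements is at most `n_permutations` they are enumerated exactly;
otherwise random permutations are drawn under the seed. Fewer than 100
permutations triggers a warning.

`bh_fdr()` is the standard step-up adjustment. Fisher enrichment
(`fisher_enrichment()`) uses the two-sided convention that sums the
probabilities of tables as or less probable than the observed one, a
minimum in-background category size of 4, BH across tested categories and
a 0.02 threshold; the odds ratio reported is the sample odds ratio. The 1D
enrichment score (`enrichment_1d()`) for a category of $m$ proteins among
$n$ ranked values is $s = \frac{2}{n}(\overline{r}_{in} - \overline{r}_{out})$,
which is +1 exactly when members occupy the top $m$ ranks, −1 at the
bottom, 0 in expectation under random placement, and antisymmetric under
value negation; its p-value is the two-sided Mann–Whitney test. Categories
covering all scored proteins carry no information and are skipped.

## Signature derivation and application

`cv_feature_selection()` embeds feature selection in resampling so that
the reported error is an honest generalization estimate: in each of
`n_repeats` (default 250) repeats, a stratified random 85/15 train/test
split is drawn; proteins are ranked one-vs-all on the **training split
only** (`rank_proteins_ova()`, ascending moderated-t p with ties broken by
descending $|t|$ then id); and for each candidate list size $k$ a linear
SVM (cost 1 — the usual choice for high-dimensional low-n expression data)
is trained on the top-$k$ training features and scored on the held-out
samples. Splits are stratified even though plain random sampling would be
simpler, because small groups would otherwise vanish from training splits.
A leakage-guard test perturbs a protein only in held-out samples and
asserts its training-derived rank is unchanged.

Open design points, resolved as follows: the per-group list size is the
smallest $k$ whose mean held-out error is within one standard error of the
minimum (the 1-SE rule) — the "good tradeoff between minimal sets and
smallest error rates" is not otherwise operationalizable, and chosen sizes
are always overridable; ranks are aggregated across repeats by the median
(a selection-frequency mode would behave similarly for strong markers).
`assemble_signature()` unions the per-group top lists and reports per-group
contributions and the overlap count — e.g. lists of 53, 10 and 10 proteins
with six proteins overlapping in total yield a 67-protein union.

`apply_signature()` restricts a (z-scored; group-wise per cohort when
technologies are mixed) matrix to the signature, requires at least half of
the signature to be present, clusters samples by Spearman distance with
average linkage and cuts at two clusters. Cluster identities are arbitrary
integers; naming them (epithelial-like vs mesenchymal-like) is a
marker-direction convention applied downstream.

## Survival comparison

`km_estimate()` wraps the product-limit estimator; the median is defined
as the **earliest time at which the curve reaches 0.5 or below** (some
implementations average the interval endpoints when the curve sits exactly
at 0.5; the first-crossing rule is used here and is the documented
tie-break). `logrank_test()` is the Mantel–Cox observed-vs-expected
chi-square with one degree of freedom between exactly two clusters, each
required to contain at least one event.

## The synthetic-data generator

`generate_panel()` draws the structure the analysis assumes: per-protein
baseline log2 intensities $N(25, 2^2)$; three groups of 10 lines with 3
replicates each (replicate noise 0.3 log2 units, consistent with replicate
correlations around 0.95); 50 markers per group shifted by 4 log2 units in
their own group (strong subtype markers in deep proteomes separate by one
to 1.5 orders of magnitude; the effect size is a free parameter, not an
estimate); probit-style left-censored missingness whose threshold is
calibrated per sample so the overall missing fraction matches the
configured target (default 20%); annotation categories concentrated on the
marker sets (80% of each marker set in a dedicated category, the rest
random); and exponential survival times per group with planted medians
(defaults 58, 50 and 43.5 months — spanning the survival gap between
epithelial-like and mesenchymal-like tumour clusters — 28 patients per
group, and independent exponential censoring calibrated to the configured
censoring fraction). `generate_peptide_table()` produces the matching
peptide-level fixture: peptide base abundance × protein profile ×
multiplicative log-normal noise.

What the generator does **not** emulate: correlated protein modules and
pathway co-regulation, batch and run-order effects, shared peptides across
protein groups, missingness that is not intensity-driven, heavy-tailed
noise, or non-proportional survival hazards. Passing the recovery tests
therefore shows the pipeline is correct and powerful under its own model
assumptions — not that real cohorts will separate this cleanly. One
consequence of the symmetric design: with equal effect sizes in all three
groups, which group the two-cluster signature cut isolates is decided by
sampling noise, so recovery is scored against the best-matching
one-vs-rest planted partition.

## Problem sizes and numerical conventions

The validation suite runs panels of 100–1000 proteins and 12–90 samples,
250 resampling repeats for signature derivation, 250 label permutations
for FDR estimation, 50 generator seeds for the type-I study and 10³
simulations for test-size checks — sizes chosen so the full suite
completes in about a minute while keeping Monte-Carlo standard errors well
inside the asserted tolerances. Numerical conventions collected in one
place: sample (n−1) SDs throughout; oracle agreement for linear-algebra
paths asserted at 1e-9; distance symmetry required to 1e-12; p-values from
`fisher.test`/`wilcox.test` clamped at 1 (they can exceed 1 by a few ulp);
deterministic tie-breaks everywhere (rank ties by statistic then id, PCA
sign by largest loading); and every stochastic step seeded, with generator
and pipeline functions restoring the caller's RNG state.

## Known limitations

* Protein inference, identification FDR and match-between-runs are
  upstream of this package and not modelled.
* The plasma-protein list is a stand-in; supply a curated one for tissue
  work.
* Only two-arm survival comparisons are provided (no Cox regression, no
  multi-group tests).
* `apply_signature()` performs cohort-level clustering; it does not
  classify single new samples against a trained model.
* With many statistically equivalent markers and a smaller chosen list
  size, the selected subset is noise-determined; signature *membership*
  stability is only expected when the marker pool is not much larger than
  the chosen list.
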