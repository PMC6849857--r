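# gamihc

Quantification of glioma-associated microglia/macrophage (GAM)
immunohistochemistry on tissue-microarray (TMA) spots, with the cohort
and expression statistics that accompany such studies.

Gliomas are infiltrated by microglia and macrophages whose abundance —
measured by markers such as Iba1, CD68, CD163 and CD206 — is scored on
TMA cores and related to patient survival. Scoring by eye is slow and
rater-dependent, so an automated, threshold-based assessment of the
stained area is used to control its accuracy and precision. This
package implements that estimator and the statistical pipeline around
it, end to end and fully testable without any external data.

## What it computes

**Image quantification.** An H-DAB spot image is converted to optical
density (`OD = log10(I0/I)`, Beer–Lambert) and unmixed into
hematoxylin and DAB concentrations by colour deconvolution with
unit-norm stain vectors. Tissue is segmented from glass by a single
minimum cross-entropy (Li) threshold on the combined stain channel.
The DAB threshold is estimated in two steps: `t1` from all tissue
pixels, then the final `t2` re-estimated from only the pixels at or
above `t1` — which keeps the cut out of spatially varying background
staining. The per-spot readout is

```
r = DAB-positive area / tissue area
```

with all thresholds estimated per spot (Kapur's maximum-entropy
criterion is selectable).

**Cohort statistics.** First-core selection, exclusion of cores with
> 30% necrosis, exact/approximate Wilcoxon rank-sum tests with
Bonferroni–Holm adjustment, Spearman agreement, Kaplan–Meier curves
with log-rank and Gehan–Breslow–Wilcoxon tests, marker dichotomization
by median split (ties to the low arm) or best split (log-rank-maximal
cutpoint with scan table and a multiplicity warning), and
region-stratified analyses (T / IZ / NAB) with Kruskal–Wallis and
Dunn pairwise tests.

**Expression statistics.** `|log2FC| >= 2` DEG screen against a pooled
reference, Ward minimum-variance clustering, Pearson coexpression,
rank-product significance with permutation pfp, ΔΔCt qPCR
quantification and standard-curve efficiencies.

**Synthetic data.** Seeded generators produce ground-truthed H-DAB
spots (known positive-area fraction, configurable background haze),
survival cohorts with a planted marker-dependent hazard, and
expression matrices with planted fold changes — so every stage is
validated against known truth.

## Worked example

```r
library(gamihc)

# a synthetic TMA spot with 25 % DAB-positive tissue
spot <- generate_spot(spot_spec(positive_fraction = 0.25, seed = 7))
quantify_spot(spot)
#> DAB quantification (li, two-step): ratio 0.2406 (25545 / 106176 px);
#> t1 = 0.2734, t2 = 0.6055, tissue thr = 0.1758
```

The estimate (0.241) recovers the generator's ground truth (0.250) to
within one percentage point: `t1` separates tissue background from
DAB-ish pixels, `t2` refines the cut from the selected pixels, and the
ratio counts the final mask against all tissue pixels.

```r
# a 241-patient cohort with a protective high-marker effect (HR 0.6)
coh <- generate_cohort(cohort_spec(n_patients = 241,
                                   log_hazard_ratio_high_vs_low = log(0.6),
                                   seed = 11))
median_split(coh)
#> Survival split at cutpoint 25.64: high n = 120 (> cutpoint), low n = 121
#>   log-rank chi2 = 15.8760, p = 6.763e-05
#>   Gehan-Wilcoxon chi2 = 12.3665, p = 0.0004371
```

The cohort is filtered to first cores without extensive necrosis,
dichotomized at the marker median, and both survival tests are
reported; here the planted protective effect of a high GAM marker is
clearly detected.

```r
# a noiseless expression set recovers exactly its planted DEGs
es <- generate_expression(expression_spec(seed = 3))
sum(deg_filter(es)$pass)
#> [1] 40
```

An end-to-end run (`run_pipeline(pipeline_config(...))`) chains
simulate → quantify → filter → split and writes CSV/JSON artifacts.

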