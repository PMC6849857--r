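---
title: "Methods: DAB quantification and cohort statistics in gamihc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DAB quantification and cohort statistics in gamihc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gamihc implements an automated, threshold-based quantification of
glioma-associated microglia/macrophage (GAM) immunohistochemistry on
tissue-microarray (TMA) spots, together with the cohort-level and
expression-level statistics used around such measurements.  This
vignette is the package's own account of the underlying models, the
tunable parameters, the numerical conventions, and what the synthetic
data can and cannot show.

## 1. The image model

Brightfield H-DAB stains follow the Beer–Lambert law: each stain
attenuates transmitted light multiplicatively, so absorbances add.  For
channel intensity $I \in [0, 255]$ and blank reference $I_0 = 255$,

$$\mathrm{OD}_c = \log_{10}(I_0 / I_c), \qquad c \in \{R, G, B\},$$

and a pixel carrying hematoxylin and DAB at concentrations
$(c_H, c_D)$ has $\mathrm{OD} = c_H \mathbf{v}_H + c_D \mathbf{v}_D$
with unit-norm stain vectors $\mathbf{v}$.  `deconvolve_stains()`
inverts this 3×3 linear system per pixel (colour deconvolution in the
Ruifrok–Johnston sense) and clips small negative concentrations, which
arise from noise outside the stain span.  The default vectors are the
widely used H-DAB references, hematoxylin $(0.650, 0.704, 0.286)$ and
DAB $(0.269, 0.568, 0.778)$, with the residual channel as their
normalized cross product; calibrated batches can supply their own
matrix.  Intensities are clamped to $\ge 1$ before the logarithm so
saturated pixels keep a finite OD.

## 2. Entropy thresholds and the two-step DAB estimator

All segmentation thresholds are estimated per spot from 256-bin
histograms over $[0, \max(2.5, \mathrm{OD}_{\max})]$.  The fixed lower
edge and the 2.5-OD floor keep bin geometry comparable across the
spots of an 8-bit batch, so thresholds are not perturbed by a single
dark outlier.  The default criterion is Li's minimum cross-entropy:
for a split $t$ with below/above masses $m_1, m_2$ (grey-level-weighted)
and class means $\mu_1, \mu_2$, the reduced criterion

$$\eta(t) = -\bigl(m_1 \log \mu_1 + m_2 \log \mu_2\bigr)$$

is minimized by exhaustive scan over all admissible bin edges, so the
result is the global optimum by construction (the test suite checks
bin-exact agreement with an independent brute-force scan).  Kapur's
maximum-entropy criterion is selectable (`method = "kapur"`).

Tissue is defined by a single entropy threshold on the combined
hematoxylin + DAB concentration, separating stained tissue from glass;
annotated exclusion masks (e.g. necrosis) are removed from both the
histogram and the mask.

The DAB threshold is estimated in two steps: $t_1$ from all tissue
pixels of the spot, then $t_2$ re-estimated from only the pixels at or
above $t_1$.  The final mask applies $t_2$ to the whole tissue region;
since $t_2 \ge t_1$ is enforced (a lower re-estimate is raised and
flagged), this equals applying it within the step-1 region.  The
rationale for the second pass: when background staining varies across
a spot and approaches the stain intensity, the whole-spot threshold is
dragged into the background by its sheer mass; re-estimating from the
first-pass selection discards that mass and places the final cut
between residual background and true signal.  The per-spot readout is
$r = \text{DAB area} / \text{tissue area}$, and no threshold is ever
shared between spots.

Degenerate histograms (a single occupied bin, i.e. no DAB contrast)
cannot be split.  The package decides by level: a single occupied
level in the bottom bin (OD $\approx 0$) is an unstained spot (empty
mask, $t_1 = t_2 = \infty$); a single occupied level above it is
uniformly stained tissue (full mask).  A degenerate *second* step
falls back to $t_2 = t_1$, flagged.  Pixel comparisons use
$\ge$ threshold throughout.

The hematoxylin channel threshold is estimated and reported per spot
but does not enter $r$, which is defined from DAB and tissue area
only.  Tissue area (not full spot area) is the default denominator.

## 3. The synthetic spot generator

`generate_spot()` renders ground-truthed spots through the same
forward model the estimator inverts: a centred tissue disc (default
72% of a 384×384 px frame) on glass, DAB-positive cells as filled
discs with Gaussian-blurred edges ($\sigma = 1$ px), nuclei as
hematoxylin texture, and background DAB haze, either flat or a linear
gradient.  Haze describes non-specific background staining of tissue,
so it applies where cells are not: the rendered DAB OD is the blend
$d \cdot B + h \cdot (1 - B)$ of cell deposit $d$ and haze $h$ with
the blurred cell map $B$ — absorbances still add in OD space across
stains, per Beer–Lambert.  Per-pixel Gaussian OD noise (default
sd 0.03) is added and clipped at zero.

Cell radii default to 26–40 px, corresponding to stained microglial
somata of roughly 6–10 µm radius at a 0.25 µm/px scan.  This choice
matters: a threshold placed inside the blurred edge profile biases the
recovered area by about $2s/r$ for an offset $s$ of order one blur
$\sigma$, so cells must be large relative to the blur for area
recovery within 2 percentage points.  Discs are painted until the
target positive pixel count is met exactly (the last disc partially),
so the generator's `true_fraction` equals the requested
`positive_fraction` to within half a pixel.

What the generator does *not* emulate: nuclear texture and chromatin,
cell processes, scanner optics, stain variability between batches, or
tissue folding.  Passing the recovery properties therefore shows that
the estimator inverts its own forward model under realistic geometry
and noise — not that it matches a pathologist on real slides; for
real data the package reports agreement statistics (Spearman's rank
correlation) against manual counts instead.

Two study-scale properties are exercised by the tests and
`scripts/acceptance.R`:

* **Accuracy** — 200 spots with true fractions uniform on
  $[0.01, 0.60]$ and flat haze: mean absolute error of $r$ below
  0.02 (measured ≈ 0.011; the small negative bias is the edge-profile
  effect above).
* **Robustness** — 100 paired spots under a linear haze gradient
  OD 0→0.3 with moderate DAB intensity (0.45): the two-step absolute
  error is at or below the one-step error in ≥ 90 of 100 spots.  The
  moderate-intensity regime is deliberate: it is where background
  approaches signal and a single whole-spot threshold slides into the
  gradient (observed one-step errors ≈ 0.2 vs two-step ≈ 0.007).  At
  strong contrast (OD 0.8) the one-step threshold is already clean and
  the comparison is uninformative.

## 4. Cohort statistics

The cohort model mirrors a TMA study: per patient up to three repeat
cores per region (vital tumour core T, infiltration zone IZ,
normal-appearing brain NAB), a percent-positive marker score per core,
a necrosis fraction, and one survival record per patient.

**Filters.** The first core of each patient is used for analysis
(`first_core_select()`; if core 1 is missing the lowest present core
is kept and flagged).  Cores with necrosis strictly above 30% are
excluded (`exclude_necrotic()`; exactly 30% is retained).

**Comparisons.** Group comparisons use the two-sample Wilcoxon
rank-sum (= Mann–Whitney) test — the compared groups are independent,
so the signed-rank variant does not apply — with exact enumeration
when both groups have ≤ 10 untied observations and the tie-corrected
normal approximation otherwise, and Bonferroni–Holm adjustment across
marker panels.  Agreement (repeat cores, intra/inter-rater,
manual-vs-automated) uses Spearman's ρ as the Pearson correlation of
mid-ranks with a t-approximation p-value.  Across the three regions,
Kruskal–Wallis is followed by Dunn's pairwise z-tests with the
tie-corrected pooled variance and Holm adjustment.

**Survival.** Kaplan–Meier curves use the product-limit estimator
(censored subjects remain at risk at their censoring time; events are
processed first at ties; Greenwood standard errors are reported).  Two
arm comparisons are computed for every split: the log-rank test and
the Gehan–Breslow–Wilcoxon test — the number-at-risk-weighted variant,
the standard "Wilcoxon" of clinical survival software, which
emphasizes early deaths.  Both are weighted sums over distinct event
times of observed-minus-expected events with hypergeometric variance;
neither is designated primary, both are always reported.

**Dichotomization.** `median_split()` cuts at the sample median of
first-core, non-excluded values; the high arm is *strictly above* the
cutpoint, so values at the cutpoint fall to the low arm.
`best_split()` scans every distinct observed value leaving at least
10% of patients in each arm (both the candidate set and the 10% floor
are package conventions) and returns the log-rank-maximizing cutpoint
together with the full scan table.  Its p-value is maximally selected
and therefore printed with an explicit multiplicity warning — scanning
cutpoints inflates type-I error, and the package does not pretend
otherwise.

The synthetic cohort plants an exponential survival model: baseline
hazard $\log(2)/15$ per month (15-month median, a realistic
glioblastoma figure), multiplied by $e^{\beta}$ for patients whose
recorded first-core marker exceeds the dichotomization point — the
planted effect is defined on the variable the analysis splits, so the
planted hazard ratio is interpretable as the true effect of the
dichotomized marker.  Censoring is an independent competing
exponential calibrated to the requested censoring fraction, with a
240-month administrative cap.  Marker scores follow Beta(2, 5) scaled
to $[0, 100]$ — a right skew typical of percent-positive IHC — with
Gaussian core-to-core noise (sd 5).  Repeat cores of a patient share
the patient's latent score; for null calibration of *across-region*
tests the generator can draw regions independently
(`independent_regions = TRUE`), because the shared-latent
(repeated-measures) structure makes a naive Kruskal–Wallis across
regions conservative.

Calibration and power, measured by the suite at study scale: under
the null (HR 1, n = 100, 2000 cohorts) the median-split log-rank
rejects at 3.5–6.5% at $\alpha = 0.05$; a planted HR of 0.6 at
n = 240 (the scale of a ~240-patient GBM cohort) is detected in well
over 80% of 500 simulations; a planted hazard change-point at marker
30 (HR 0.3, n = 240) is recovered by the best split within ±5 units
in ≥ 90% of 200 simulations.

## 5. Expression statistics

The expression side consumes already-normalized log2 matrices
(upstream array preprocessing is out of scope).  The DEG screen is a
fold-change filter: $\mathrm{log_2FC} = \overline{\text{case}} -
\overline{\text{reference}}$ per gene against the (possibly pooled)
reference, passing at $|\mathrm{log_2FC}| \ge 2$ inclusive.
Hierarchical clustering uses Ward's minimum-variance criterion on
Euclidean distances (`hclust` ward.D2, which is Ward's method for
Euclidean input); coexpression is the gene-by-gene Pearson matrix.

Rank products provide a nonparametric significance measure: per-gene
fold changes against the reference mean are ranked within each case
sample (up- and down-regulation separately) and combined as the
geometric mean.  Significance is reported as the pfp (proportion of
false prediction): the expected number of null genes at least as
extreme — estimated by permuting expression values within each sample
— divided by the gene's observed rank, with step-up smoothing so pfp
is non-increasing in extremity, as for other FDR-type measures.  The
permutation scheme is a package convention (the standard
rank-product procedure), documented rather than reconstructed from any
reference implementation.  Its exact small-size oracle exploits that
under within-sample permutation a gene's rank vector is a tuple of
i.i.d. uniform ranks, whose $n^k$ combinations can be enumerated
exhaustively; the Monte-Carlo estimate agrees with that enumeration to
a few thousandths at 20 genes × 3 samples × 20 000 permutations.

qPCR quantification follows ΔΔCt: triplicates are averaged first
(wells > 0.5 cycles from the triplicate median are flagged — a
standard QC convention), then
$\mathrm{dCT} = \overline{CT}_\text{target} -
\overline{CT}_\text{reference gene}$,
$\mathrm{ddCT} = \mathrm{dCT} - \overline{\mathrm{dCT}}_\text{control}$,
and $R = 2^{-\mathrm{ddCT}} \times 100$ as percent of the control
group; $R$ assumes exact doubling and is invariant to any constant CT
shift within a sample.  Standard curves fit CT against
$\log_{10}(\text{dilution})$ by least squares over ≥ 3 points spanning
≥ 2 decades; the amplification efficiency is $10^{-1/\text{slope}}-1$
(slope $-3.32$ ↦ 100%).

## 6. Numerical conventions and degenerate inputs

* Histogram: 256 bins, fixed lower edge 0, upper edge
  $\max(2.5, \mathrm{OD}_{\max})$; thresholds are bin edges; "above"
  means $\ge$.
* Threshold search: exhaustive, global; ties in the best-split scan
  resolve to the smallest cutpoint.
* Empty tissue (all pixels excluded, or no stain contrast) is an
  error per spot; batch quantification flags the spot and continues.
* All-equal marker values cannot be split (degenerate-split error);
  regions with fewer than two patients are skipped with a warning.
* Constant genes have undefined correlations and are returned as
  `NA`; constant input to Spearman's ρ is an error.
* Every generator is driven by an explicit seed and restores the
  caller's RNG state; identical spec + seed reproduces outputs
  byte-identically.

## 7. Problem sizes used by the checks

The suite and the acceptance script run the quantifier on 200 + 100
spots of 384×384 px, 2000 + 500 + 200 simulated cohorts (n = 100 and
240), and the expression oracles at 500 and 20 genes.  These sizes
were chosen so each property is measured at the scale of the study
design it emulates while the whole battery stays comfortably
repeatable on a laptop.

## 8. Known limitations

* The area ratio is not a cell count; at equal stained area it cannot
  distinguish many small cells from few large ones.  Manual counting
  is modelled as data (percent-positive scores), never computed from
  images.
* Entropy thresholds need contrast: on truly unimodal DAB histograms
  (uniformly faint staining) the split is decided by the degenerate
  rule, and near-unimodal spots can over-segment noise.  The two-step
  refinement mitigates, but does not remove, this.
* The best-split p-value is maximally selected and unadjusted;
  downstream users should treat it as exploratory.
* The exponential survival model has constant hazards; it is
  sufficient for calibration/power checks of rank-based tests, which
  do not assume it, but it is not a model of glioblastoma biology.
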