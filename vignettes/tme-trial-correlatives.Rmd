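---
title: "Spatial TME biomarkers and trial endpoint statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial TME biomarkers and trial endpoint statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmmrtme)
```

# What this package computes

Single-arm phase 2 immunotherapy trials in mismatch-repair-deficient
(dMMR) gynecologic cancers increasingly pair their clinical endpoints
with correlative analyses of the tumor microenvironment (TME) and the
tumor genome. This package implements that correlative-analysis layer
as a tested pipeline over three kinds of input, all plain delimited
text:

1. **Segmented cell tables** from multiplexed immunofluorescence: one
   row per nucleated cell with coordinates in micrometres, a
   tumor/stroma compartment label, and binary calls for a six-marker
   panel (CD8, PD-1, TOX, FoxP3, PD-L1, Pax8). Staining, spectral
   unmixing, segmentation and intensity thresholding are upstream of
   this package; we consume their output.
2. **An outcomes table** with best overall response, PFS/OS times and
   event flags.
3. **Per-patient genomic profiles**: pathogenic-mutation flags per
   gene, nonsynonymous mutation counts, capture size, MSIsensor score,
   and mutational-signature exposures. Variant calling, signature
   inference and MSI scoring are likewise consumed, not implemented.

Because patient-level trial data cannot be redistributed, the package
ships a synthetic cohort generator whose outputs exercise every stage
with known ground truth. The generator is first-class, tested code;
its defaults define the study conditions used by the test suite.

# The spatial model and its estimators

## Phenotype gating

A phenotype is a conjunction of required-positive and
required-negative marker calls (`phenotype_def()`). The analysis
phenotypes nest: terminally dysfunctional T cells (CD8+PD-1+TOX+) are
a subset of dysfunctional T cells (CD8+PD-1+), which are a subset of
CD8+ T cells. PD-1 marks chronic antigen stimulation; TOX is the
transcriptional regulator of terminal T-cell dysfunction; FoxP3 gates
regulatory T cells; Pax8 marks Muellerian tumor-cell lineage.
Population fractions are reported as percentages out of total
nucleated cells unless the CD8 compartment is requested as the
denominator, and the default analysis compartment is the tumor
compartment — analyses of a table with the stroma rows deleted are
identical by construction (and tested). Patients with several archival
specimens contribute the unweighted mean of per-specimen values, not a
cell-weighted pool.

## Nearest neighbors and interaction fractions

For phenotype classes $A$ (anchor) and $T$ (target) on one slide, the
interaction fraction at radius $r$ is

$$ 100 \cdot \frac{\lvert\{ t \in T : \min_{a \in A} d(t,a) \le r \}\rvert}{\lvert T \rvert}, $$

a plain percentage with no edge correction, computed per slide and
never across specimens (coordinate origins are arbitrary per
specimen). The boundary is inclusive; with continuous coordinates the
choice is immaterial, but it is fixed and documented. A cell belonging
to both classes is never its own neighbor. The default radius of 50
um corresponds to a 2–3 cell neighborhood and the reported reach of
T-cell-derived interferon-gamma signalling (30–40 um). An empty anchor
class yields 0% by convention (with a warning); an empty target class
yields a missing value. Coincident-coordinate duplicates from
segmentation are kept and counted.

Two interchangeable search routes are implemented: a brute-force
$O(|A|\cdot|T|)$ double loop and a uniform-grid bucket search (ring
expansion for nearest-neighbor distances, 3x3-cell neighborhoods for
fixed-radius queries). Both are exact, and their equality — not
approximate agreement — is asserted on random fixtures in the test
suite. No spatial summary beyond these plain fractions and median
nearest-neighbor distances (Ripley's K, permutation nulls) is
computed, matching the estimator the analysis layer actually uses.

# Association statistics

All the association machinery is authored in this package; the
standard-library equivalents (`wilcox.test`, `fisher.test`,
`chisq.test`, `glm`, `cor`, `survival::survfit`) appear only as
independent cross-checks in the tests.

- **Mann–Whitney**: midrank ties; exact two-sided p by complete
  enumeration when the smaller group has at most 8 observations and no
  ties (twice the smaller tail, capped at 1), otherwise a normal
  approximation with tie-corrected variance and continuity correction.
- **Fisher exact**: hypergeometric enumeration with the
  minimum-likelihood two-sided rule (sum the probabilities of all
  tables no more probable than the observed one). This rule is fixed
  deliberately: it reproduces the published two-sided p = 0.027 for a
  6/19-versus-0/14 mutation table.
- **Chi-square**: the closed-form Pearson statistic on a 2x2 table,
  df = 1, Yates correction optional and off by default. The default
  2x2 test for dichotomized biomarkers is chi-square without
  correction; Fisher is available by configuration.
- **Tertile dichotomization**: the cutoff is the 33 1/3rd percentile
  by linear interpolation of order statistics (the type-7 quantile
  rule), with values strictly above the cutoff called high. Published
  cutoffs of this kind are data-derived, so the *rule* is the
  contract, not any particular value.
- **Logistic model**: maximum likelihood by iteratively reweighted
  least squares; convergence when the largest coefficient change drops
  below 1e-8 (at most 100 iterations); complete separation is detected
  from a diverging coefficient norm and flagged rather than returned
  silently.
- **ROC/AUC**: the rank (Mann–Whitney) formulation with ties counted
  one half; ROC points by threshold sweep, whose trapezoidal integral
  equals the rank AUC by construction.
- **No multiple-testing adjustment** is applied anywhere; this mirrors
  the exploratory reporting convention of the analyses the pipeline
  reproduces and is deliberately not configurable.

# Trial endpoints

Best overall response uses simplified RECIST 1.1 target-lesion rules
(CR at sum zero; PR at a 30% decrease from baseline; PD at a 20% and
5 mm increase from the nadir; SD otherwise; CR/PR achieved before
progression take precedence as best response). Nodal short-axis rules,
non-target and new-lesion logic, and response confirmation are not
modeled: per-patient radiology is never available to a correlative
package, and the simplification is documented at the function.

ORR and DCR use the evaluable denominator (non-NE patients). Exact
binomial intervals are Clopper–Pearson beta quantiles; the one-sided
97.5% lower bound equals the two-sided 95% lower bound, the convention
used for co-primary endpoint reporting. The 24-week progression-free
classification counts patients lost to follow-up or dead before the
24-week assessment as events. The landmark is converted once:
`weeks_to_months(24)` = 24·7/30.4375 = 5.5195 months.

The Kaplan–Meier estimator is the hand-computed product-limit with
Greenwood variance; landmark confidence intervals use the log(−log)
transform (the reporting method is rarely stated in trial reports;
log(−log) is the common default and is not treated as a reproduction
target). The median is the smallest time with survival at or below
one half, "not reached" otherwise; its confidence limits use the
pointwise-band crossing rule.

Simon two-stage operating characteristics are exact binomial
enumerations — no normal approximation: the promising probability sums
stage-1 outcomes above the futility bound against the stage-2 tail.
For the response-rate design (stage 1 of 23 with continuation iff at
least 2 responses; promising iff at least 6 of 40; null 5%,
alternative 25%) the attained type I and II errors are 0.0134 and
0.0480, consistent with nominal bounds of 0.025 and 0.05 read as upper
bounds. For the 24-week-PFS design the stage-1 denominator is the 17
evaluable of 23 enrolled (continuation iff at least 5; promising iff
at least 16 of 40; null 25%, alternative 50%), with attained errors
0.0249 and 0.0880 — sitting at the rounding boundary of nominal
0.025/0.09, which is why only the response-rate design's bounds are
treated as checkable claims.

# The synthetic cohort generator

The generator emulates exactly the structure the analysis must detect,
and nothing more:

- **Geometry**: a 1 x 1 mm region with 5 circular tumor nests of
  radius 150 um; tumor (Pax8+) cells are a homogeneous Poisson process
  (2,500 cells/mm^2) thinned to the nest union; CD8+ (300/mm^2), FoxP3+
  (100/mm^2) and unlabeled "other" cells (800/mm^2) cover the whole
  region, with compartment assigned by nest membership. The "other"
  lineage exists so that total-nucleated-cell denominators are not
  artificially small, since real slides contain many cells negative
  for every panel marker. This yields roughly 1,700–2,100 cells per
  specimen — deliberately smaller than real slides (median tens of
  thousands of cells) so the suite runs quickly; the estimators are
  n-independent percentages and distances.
- **Dysfunction gating**: PD-1 on CD8+ cells with probability 0.65
  (benefit archetype) versus 0.30 (no benefit); TOX on CD8+PD-1+ cells
  with probability 0.70 versus 0.35. No per-archetype rates are
  published; these values were chosen once so that benefit-archetype
  terminal-dysfunction fractions (out of CD8) land above the published
  bottom-tertile cutoff of 41% and no-benefit fractions land below it,
  preserving the direction and rough magnitude of the published
  contrast.
- **PD-L1 co-localization**: a tumor/other cell at distance $d$ from
  the nearest CD8+PD-1+ cell is PD-L1+ with probability
  $p_\mathrm{base} + (p_\mathrm{max}-p_\mathrm{base})e^{-d/\tau}$
  (0.15, 0.6, $\tau$ = 30 um) under the benefit archetype and a flat
  0.15 under no benefit. A distance-decay labeling on a Poisson
  pattern is sufficient to create the co-localization signal the
  estimators must detect; a Gibbs/attraction point process would add
  realism the estimators are insensitive to. Published marginal PD-L1
  rates per group are not available, so only the *sign* of the
  contrast (closer proximity and higher interaction fractions under
  benefit) is calibrated.
- **Outcomes**: PFS exponential with hazard 0.02/month (benefit,
  median 34.7 months) versus 0.20/month (no benefit, median 3.47
  months); OS adds an independent exponential residual so OS is never
  shorter than PFS; administrative censoring at 42 months (the
  published median follow-up of 42.1 months). Best response category
  probabilities give a cohort response rate near the published 59%.
- **Genomics**: per-gene Bernoulli flags at published frequencies
  (e.g. 32% versus 0% for the Hedgehog-pathway gene MEGF8, 11/19
  versus 2/14 for SETD1B, 76% PTEN, 82% ARID1A); lognormal TMB with
  group medians 18.1 and 14.4 mutations/Mb on a 30 Mb capture; 79%
  MSI-H; Dirichlet signature exposures with dominant mass on the
  dMMR-associated signatures 6/15/20 for MSI-H draws and on the
  aging-related signatures 1/5 otherwise. The aging set {1, 5} is an
  assumption (the clock-like signatures), configurable in
  `default_signature_classes()`.
- **Seeds**: one master seed; per-patient child seeds derived by fixed
  arithmetic (`(seed mod 100003)*10007 + 97*i`), so cohorts are
  reproducible under subsetting and every value stays within 32-bit
  integer range.

Archetype is the generator's ground-truth benefit label. Realized
24-week progression-free status is drawn from the archetype's hazard,
so it agrees with the archetype for most but not all patients — as in
a real trial, where the biomarker groups are defined by the observed
endpoint. Separation tests therefore use the archetype label; the
pipeline's own association stage dichotomizes by whichever label the
caller provides.

## What passing tests do and do not show

The generator produces marker logic that is clean by construction (no
TOX+PD-1− cells, no CD8+FoxP3+ cells, no Pax8+ stroma cells), perfectly
binary calls, homogeneous densities and circular nests. Real segmented
slides violate all of these: segmentation errors produce impossible
marker combinations, thresholding is noisy near the decision boundary,
and tissue architecture is irregular. Passing tests show that the
estimators and statistics are computed correctly and recover planted
structure; they do not show that 50 um or the bottom-tertile rule are
biologically optimal, nor that the effect sizes planted here match any
particular cohort. A notable divergence: in this generator the two
model parameters (terminal dysfunction fraction and PD-L1 interaction
fraction) are strongly correlated across patients because one
archetype drives both, whereas the published analysis selected them
for their minimal correlation; the logistic model separates the
archetypes regardless, but the generator should not be used to study
collinearity behavior.

# Numerical choices and degenerate inputs

- Fractions carry full precision; rounding happens only at report
  time.
- Empty denominators yield missing values with warnings, not errors
  (a slide with no CD8+ cells is data, not a bug); empty anchor
  classes yield 0% interaction by convention.
- Missing biomarker values propagate and are dropped pairwise with a
  logged count, so panels with different per-patient availability
  (n = 24 versus n = 25) remain comparable.
- Pairwise-complete Pearson correlation requires at least 3 complete
  pairs; constant columns are excluded from clustering with a warning.
  Clustering is average-linkage agglomeration on distance 1 − r.
- Signature-label ties break toward the smaller signature id,
  deterministically, and are flagged.
- All-equal tertile inputs produce a degenerate split and a warning.
- The validation report is order-independent: permuting input rows
  yields identical findings.

# Problem sizes in the test and acceptance suites

Unit tests run on 500 x 500 um specimens (a few hundred cells);
archetype-separation checks run the full default cohort (25 patients,
~2,000 cells per specimen) over 20 seeds; logistic parameter recovery
uses n = 2,000; interval coverage uses 10,000 binomial replicates;
exact-oracle spatial comparisons use 200–250 random cells. These sizes
were chosen as the smallest at which each property is statistically
decidable, keeping the whole suite in the low minutes on one CPU.

# Known limitations

- RECIST is target-lesion-only; BOR from real radiology review can
  differ.
- No cell-level QC/area filtering is applied after segmentation; if an
  upstream exporter emits debris rows, they count.
- The spatial estimator has no edge correction; interaction fractions
  near slide borders are biased low exactly as in the original
  estimator.
- The ROC p-value for the AUC is not computed (it was not a
  reproduction target); if needed it follows from the Mann–Whitney
  null of the rank AUC.
- The generator draws one specimen per patient; multi-specimen
  averaging is exercised by unit tests rather than by the default
  cohort.
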