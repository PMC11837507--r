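---
title: "Estimating microbial 15N assimilation from density gradients: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating microbial 15N assimilation from density gradients: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
quantitative stable isotope probing (qSIP) model for ¹⁵N, the estimation
chain from gradient fractions to excess atom fraction, the field-vs-lab
method comparison, the forward simulator used for recovery testing, and the
places where the design was genuinely open and we had to choose.

## The measurement

In a qSIP experiment, DNA extracted from soil incubated with a ¹⁵N label
(here (¹⁵NH₄)₂SO₄) is spun to equilibrium in a CsCl gradient and fractionated
(~25 fractions per tube). Each fraction has a buoyant density (refractometer)
and a total 16S rRNA gene copy number (qPCR); the fractions dense enough in
DNA to sequence — about 1.67–1.74 g/mL — get amplicon counts. A taxon that
assimilated ¹⁵N into new DNA bands slightly denser than its unlabeled DNA, so
the shift of its abundance-weighted position along the gradient measures its
isotope incorporation.

## Estimation chain

**Weighted average density (WAD).** For genus $i$ in tube $j$, with
per-fraction relative sequence abundance $p_{ik}$, fraction totals $f_k$ and
densities $x_k$ over the analyzed window:

$$y_{ik} = p_{ik} f_k, \qquad
  W_{ij} = \frac{\sum_k x_k\, y_{ik}}{\sum_k y_{ik}}.$$

WAD is translation-equivariant and bounded by the retained fraction
densities. A genus with no copies in a tube has no WAD (missing, never
zero).

**Taxon filters.** ASVs are removed when they occur fewer than 200 times
*and* in fewer than 20 fractions across the whole data set (the permissive
conjunction; the strict disjunction is available via `rule = "either"`).
ASVs sharing a full six-rank lineage are summed into genus-level taxa;
unresolved genera are labeled by their finest resolved rank plus `"gen."`,
keyed on the full lineage so homonyms under different families stay
distinct. Genera with mean copies-weighted relative abundance below 10⁻⁴, or
detected in fewer than 5 of the 7 replicate plots at either site, are
dropped. Where the thresholds' aggregation rule was unstated we chose the
mean across all samples (documented in `filter_genera()`), and "present in a
sample" means at least one read in at least one analyzed fraction of that
plot's tubes.

**Light WAD and GC.** The pre-incubation (unlabeled) tubes give each genus
its natural-abundance WAD; its genomic GC content follows from the linear
density–GC relationship $W_\text{light} = 0.083506\,GC + 1.646057$. The GC
in turn sets the mean nucleotide molecular weight of unlabeled DNA
($M_\text{light} = 0.496\,GC + 307.691$) and the maximum weight gain at full
¹⁵N substitution ($\Delta_{\max} = 0.5024\,GC + 3.517$). These constants are
not restated in every qSIP paper; they live in `isotope_constants()`,
versioned and overridable, and the simulator uses the same values so
recovery tests are self-consistent regardless of their provenance.

**Tube correction.** CsCl gradients vary slightly tube to tube, shifting
every taxon's apparent density by a common per-tube offset comparable in
size to the enrichment signal itself. Following standard qSIP practice the
correction anchors on the ~50 least-shifted genera as internal unenriched
references: each labeled tube's offset is the median raw WAD shift of the
reference genera in that tube. Two implementation choices matter and were
made after forward-simulation showed the naive versions fail:

* *Signed, not absolute, ranking.* Enrichment can only increase density, so
  the unenriched floor is the genera with the smallest signed mean shift.
  Ranking by $|$mean shift$|$ is confounded by the study-average tube
  offset: whenever the labeled tubes' offsets do not average to exactly
  zero (they never do in a finite study), the genera *closest to zero
  apparent shift* are those whose true enrichment cancels that common
  offset, and anchoring on them propagates the common offset into every
  EAF.
* *Leave-one-tube-out ranking.* Ranking references on all tubes at once
  selects genera partly for their negative measurement noise in the very
  tubes whose medians become the offsets, biasing all offsets downward by a
  constant. Each tube's reference set is therefore ranked on the other
  labeled tubes only (`scope = "loo"`; `"global"` reproduces the simpler
  scheme).

`n_ref = 0` disables the correction, appropriate when tubes share one
calibration. The correction estimates enrichment *relative to the
least-enriched genera*: if even those assimilated label (e.g. a non-zero
lab-to-field intercept applies to every taxon), that floor is absorbed into
the offsets and all EAFs are shifted down by it. This is a property of the
reference-taxa idea itself, not of an implementation.

**Excess atom fraction.** With the corrected labeled WAD $W_\text{lab}$,

$$M_\text{lab} = M_\text{light}\frac{W_\text{lab}}{W_\text{light}}, \qquad
  E = \frac{M_\text{lab} - M_\text{light}}{\Delta_{\max}}
      \,(1 - 0.003663),$$

the excess atom fraction of ¹⁵N — the *relative N assimilation rate* over
the incubation. $E$ is strictly increasing in $W_\text{lab}$ and cannot
exceed $1 - 0.003663$. Negative estimates (noise around zero enrichment)
are replaced by zero, with the count reported. EAFs are computed per
(genus, plot, method, site) pair — the plot's own control is the reference,
never a site average — and summarized across the 7 plots by medians.

**Percent N assimilated.** A genus's abundance-weighted share of community
assimilation:
$$P_i = \frac{RA_i\,E_i}{\sum_j RA_j\,E_j},$$
with $RA_i$ the genus's copies-weighted relative abundance in the labeled
sample (summed over analyzed fractions). $P$ sums to one within a sample
whenever any product is positive, and is invariant to rescaling all EAFs.

## Field-vs-lab comparison

Paired genus-level medians (field vs lab) are compared with Passing–Bablok
regression, a nonparametric method-comparison estimator based on the median
of pairwise slopes. Two estimators are provided:

* `method = "equivariant"` (default): the slope is the tangent of the median
  pairwise *angle* $\mathrm{atan2}(\Delta y, \Delta x)$ mapped to
  $(-\pi/2, \pi/2]$. Exchanging the axes maps every angle to its complement,
  so the fit maps exactly to its inverse on data whose pairwise slopes share
  a sign; vertical pairs contribute $\pi/2$.
* `method = "classical"`: the shifted median of pairwise slopes, excluding
  slopes equal to $-1$ and offsetting the median by the count of slopes
  below $-1$; pairs with equal $x$ are excluded (a documented divergence
  from the angle variant). The shift offset is clamped to the valid index
  range, which matters only for data with predominantly negative
  association — outside the method's intended use.

Numerical fine print, verified by tests: the angle median is a single order
statistic when the pair count is odd (then scale equivariance and axis
exchange are exact); for even counts it interpolates between the two central
angles and both properties hold to ~10⁻⁵. The classical estimator's $-1$
exclusion breaks exact scale equivariance whenever a pairwise slope crosses
$-1$ under scaling — irrelevant for positively associated data.

Confidence intervals come from a quantile bootstrap (default B = 1999)
resampling genus pairs — the genus is the exchangeable unit, matching a
comparison of genus medians. Degenerate resamples (all $x$ equal) are
redrawn, counted, and capped at 10·B attempts. Intervals are treated as
closed for interpretation: a *proportional difference* is declared when the
slope CI excludes 1, a *constant difference* when the intercept CI excludes
0; a bound exactly touching the null value declares no difference.
Per-genus field-vs-lab differences use one-way fixed-effects ANOVA
(n = 7 plots per method), with tiers •/*/**/*** at 0.10/0.05/0.01/0.001.

## The forward simulator

`simulate_study()` generates the whole experiment — 2 sites × 7 plots ×
(pre-incubation control + field and lab labeled tubes) = 42 tubes, 25
fractions each spanning 1.61–1.78 g/mL — so every estimator can be tested
against known truth. Per taxon it draws GC, a lognormal baseline abundance,
and a true lab EAF from a zero-inflated scaled Beta; the field EAF is a
linear map of the lab EAF (default slope 0.81, intercept 0.01, taxon-level
Gaussian noise, clamped at zero). Each tube adds a Gaussian per-tube density
offset (σ = 0.002 g/mL); each taxon's DNA is spread over fraction bins by a
Gaussian kernel integrated over bin edges; fraction totals get multiplicative
lognormal qPCR noise (CV 0.1); sequencing counts are multinomial (10,000
reads per fraction) over the analyzed window only — fractions outside it are
generated with qPCR totals but no reads, mirroring a study that sequences
only the high-DNA window.

Default choices, with reasons:

* `gc_range = c(0.45, 0.65)`, Beta(2, 2): the realistic span of soil
  prokaryote genomic GC, and chosen so that every taxon's DNA — unlabeled or
  labeled up to EAF 0.6 — keeps > 3 kernel SDs of clearance from both edges
  of the analyzed window. Taxa whose kernels cross a window edge have
  truncated, biased WADs (an intrinsic property of windowed gradients, shared
  with real experiments); keeping the community inside the window is what
  makes noise-free enrichment exactly identifiable, and matches the
  observation that the sequencable window contains essentially all community
  DNA.
* `kernel_sd = 0.006` g/mL: a taxon spans 3–6 fractions, as in published
  gradient profiles.
* `eaf_pi0 = 0.1`, positives Beta(1.8, 5.4) scaled to [0, 0.6] (mean 0.15):
  most soil taxa show some assimilation after a 5-day labeled-ammonium
  incubation, with top rates around 0.2.
* `abund_sdlog = 1.2`: a few hundred genera spanning ~3 orders of magnitude;
  roughly 1% fall below the 10⁻⁴ relative-abundance filter, similar to the
  small fraction such filters remove in practice.
* `map_noise_sd = 0.01`: taxon-level scatter around the lab-to-field map,
  small relative to the map's intercept.
* Abundances are identical across methods (community composition does not
  differ by incubation method); a site effect hook exists but defaults off.

What the simulator does **not** emulate: sequencing error and chimeras,
taxonomy misclassification, compositional biases of extraction/PCR,
correlation between GC and abundance or enrichment, and any real
biogeochemical structure across sites. Passing recovery tests therefore
shows the estimation chain is correct and robust to counting, qPCR and
calibration noise at realistic magnitudes — not that real data meet these
assumptions.

## Recovery behavior and test problem sizes

The test suite checks, among others: exact identifiability without noise
(50 taxa, exact proportions, no offsets, correction disabled — every
genus-level EAF within 0.01 of truth, the bin-discretization scale);
recovery at default noise (300 taxa, 5 studies — median absolute error of
genus-median EAFs ≤ 0.02, lab-to-field Passing–Bablok slope within ±0.05 of
the configured 0.81); removal of injected tube offsets (≥ 90% reduction of
the per-tube mean shift bias in unenriched studies); equality of the
classical estimator with brute-force enumeration on 1000 small instances;
and bootstrap CI coverage at a reduced size (n = 120 pairs, B = 399, 20
replicates) chosen so the whole suite runs in about a minute — the coverage
property being scale-free. The residual EAF bias at default noise
(~ −0.01) is the reference-floor effect described above: the field map's
intercept enriches even the floor genera, and that floor is subtracted by
the tube correction.

## Known limitations

* Percent N assimilated weights by 16S relative abundance, which is not
  biomass: small fast dividers are overweighted relative to large
  slow-growing cells.
* EAF estimates for taxa banding near the window edges are biased by
  truncation; the estimator does not attempt a correction.
* The tube correction measures enrichment relative to the least-enriched
  genera; a community in which *every* taxon assimilates label will have
  that common floor absorbed into the offsets.
* The classical Passing–Bablok variant assumes a predominantly positive
  association; with mostly negative pairwise slopes its shifted median is
  clamped rather than undefined.
* Absolute N fluxes per gram of soil are out of scope; the biogeochemistry
  module provides the scalar rate calculators (net nitrification and
  immobilization, plant ¹⁵N recovery and uptake, amendment unit conversions)
  but no pool-dilution (gross) rates.
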