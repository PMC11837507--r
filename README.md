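# qsipn

Quantitative stable isotope probing (qSIP) with ¹⁵N for soil microbial
communities: who assimilates nitrogen, how fast, and do lab incubations
tell you the same thing as the field?

When soil is incubated with a ¹⁵N label (e.g. (¹⁵NH₄)₂SO₄), taxa that
assimilate the nitrogen build it into new DNA, which becomes measurably
denser. After CsCl density-gradient ultracentrifugation and fractionation,
each taxon's position along the gradient — its **weighted average density**
(WAD), the mean fraction density weighted by the taxon's 16S copies
`y_ik = p_ik f_k` (relative sequence abundance × qPCR total) — shifts in
proportion to its isotope incorporation. `qsipn` turns fraction tables,
qPCR totals, amplicon counts and sample metadata into:

* per-genus **¹⁵N excess atom fraction** (EAF, the *relative N assimilation
  rate*), via the density→GC→molecular-weight chain
  `M_lab = M_light · W_lab / W_light`,
  `E = (M_lab − M_light) / Δ_max · (1 − 0.003663)`,
  with tube-level density offsets removed using the least-shifted genera as
  internal unenriched references, and negative estimates clamped to zero;
* per-genus **% N assimilated**, the abundance-weighted share of community
  assimilation `P_i = RA_i E_i / Σ_j RA_j E_j`;
* a field-vs-lab **method comparison** by equivariant Passing–Bablok
  regression with quantile-bootstrap CIs (slope CI excluding 1 ⇒
  proportional difference; intercept CI excluding 0 ⇒ constant difference),
  plus per-genus one-way ANOVAs across replicate plots;
* scalar **soil N biogeochemistry** calculators (net nitrification and
  immobilization rates, plant ¹⁵N recovery and uptake, fertilizer amendment
  unit conversions);
* a **forward simulator** of the whole experiment (taxa, tubes, fractions,
  qPCR and sequencing noise, paired field/lab design) with a truth table,
  so every stage is testable without raw sequence data.

The estimation defaults follow a paired rhizosphere study design: 2 sites ×
7 replicate plots × (pre-incubation control + field and lab labeled
samples), ~25 fractions per tube, analyzed density window 1.67–1.74 g/mL,
ASV filter (< 200 reads and < 20 fractions), genus filters (mean relative
abundance < 10⁻⁴; detected in < 5 of 7 plots at either site), and a
50-genus tube correction. See the methods vignette
(`vignettes/qsip-15n-methods.Rmd`) for the model, the estimator choices and
their rationale, and known limitations.

## Worked example

Simulate a full study with a known lab→field map (slope 0.81, intercept
0.01), fit the model, and compare methods:

```r
library(qsipn)

sim <- simulate_study(sim_config(seed = 42))
fit <- qsip_fit(sim$fractions, sim$counts, sim$samples)
print(fit)
#> qSIP 15N enrichment fit
#>   genera: 299 (300 before genus filters)
#>   labeled samples: 28  sites: Ridge, Valley
#>   median EAF (field): 0.0985
#>   median EAF (lab): 0.1201

cmp <- compare_methods(fit, metric = "eaf", boot = 1999, seed = 42)
print(cmp)
#> Passing-Bablok regression (equivariant estimator), n = 299
#>   slope:      0.8018  95% CI [0.7799, 0.8233]
#>   intercept:  0.0007851  95% CI [0, 0.00427]
#>   Pearson r:  0.9717
#>   proportional difference (slope CI excludes 1):  TRUE
#>   constant difference (intercept CI excludes 0):  FALSE
```

The fitted slope recovers the configured 0.81 map: genus-level field
assimilation rates are proportionally lower than lab rates (a proportional
difference), with no constant offset — i.e. the lab incubation overstates
per-genus N assimilation by a roughly constant factor rather than by an
additive shift. `fit$enrichment` holds the per-(genus, plot, method, site)
table (GC, light and labeled WADs, raw and clamped EAF, relative abundance,
% N assimilated); `genus_medians()`, `genus_method_tests()`, `coef()`,
`summary()` and `plot()` summarize it.

Field-scale unit conversions:

```r
u <- amendment_units(3, depth = 15.24, bulk_density = 1.3)
#> 3 umol N/g soil = 42.0 ug N/g soil = 83.3 kg N/ha
```

Real data enter through `read_fraction_table()`, `read_taxon_counts()` and
`read_sample_table()` (TSV/CSV, auto-detected), or `run_qsip(dir)` for a
directory holding `fractions.tsv`, `counts.tsv`, `taxonomy.tsv`,
`samples.tsv`.

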