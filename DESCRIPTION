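Package: qsipn
Title: Quantitative Stable Isotope Probing of Microbial Nitrogen Assimilation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative stable isotope probing (qSIP) with 15N in
    soil microbial communities. Computes per-genus weighted average buoyant
    densities from CsCl density-gradient fractions, qPCR totals and 16S
    amplicon counts; applies tube-level density corrections; converts weighted
    average density shifts to 15N excess atom fraction (relative nitrogen
    assimilation rate) and abundance-weighted percent nitrogen assimilated;
    compares field and laboratory incubation methods with equivariant
    Passing-Bablok regression and quantile-bootstrap confidence intervals; and
    provides scalar soil nitrogen biogeochemistry calculators. A forward
    simulator of the full gradient experiment supports parameter-recovery
    testing without raw sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
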