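Package: funnelomics
Title: Secretome Candidate Prioritization and Lung Regeneration Assay Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A proteomics-guided drug-discovery toolkit for paired
    extracellular-vesicle (EV) and soluble-fraction (SF) secretome protein
    tables. Implements a multi-stage candidate prioritization funnel
    (replicate-consistency filtering, EV/SF set partition, growth-factor and
    cytokine annotation, secretion-prediction filtering, ligand-receptor
    matching against target-cell receptor expression) with per-stage
    provenance, an EV marker-enrichment check, colony-forming-efficiency
    statistics for lung organoid assays (normality battery, Dunnett
    many-to-one comparisons, two-sample Kolmogorov-Smirnov with Bonferroni
    display conventions, paired effect estimation with bootstrap intervals),
    immunohistochemistry quantification (stain unmixing, positive-area
    percentage, reciprocal mean intensity) and mean-linear-intercept
    stereology for lung-injury scoring, plus synthetic fixture generators
    with planted, bookkept ground truth for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    png,
    multcomp,
    nortest,
    fgsea,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
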