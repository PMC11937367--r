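# funnelomics

Secretome candidate prioritization and lung regeneration assay
quantification in R.

## What problem this solves

The mesenchymal niche instructs alveolar epithelial repair: lung
fibroblasts release extracellular vesicles (EVs) and soluble factors
(SFs) that activate alveolar progenitor cells, and this secretome is a
hunting ground for regenerative drug candidates in diseases like COPD.
`funnelomics` is for computational biologists and pharmacologists who
need to turn paired EV/SF proteomics into a short, auditable candidate
list and then quantify the assays used to validate those candidates —
lung organoid colony formation, immunohistochemistry of human lung
sections, and stereological injury scoring of precision-cut lung
slices.

## The methods at its core

**Prioritization funnel** (`run_funnel()`), applied in order per
compartment with full provenance:

1. identified in ≥ 1 replicate → 2. consistent in all R replicates of a
fraction → 3. EV-only / shared / SF-only partition → 4. growth-factor /
cytokine annotation (user-supplied GMT) → 5. predicted secreted
(any-of-predictors by default) → 6. has a receptor partner expressed in
the target cells (AT1/AT2 by default).

An EV marker-enrichment check (`marker_enrichment()`) tests the 2×2
marker × fraction table with a hypergeometric exact p.

**Organoid statistics**: colony-forming efficiency
`CFE = 100 · n_organoids(>50 µm) / n_seeded`; four-test normality
battery with the 3-of-4 parametric rule; one-way (optionally paired)
ANOVA with Dunnett many-to-one contrasts; two-sample Kolmogorov–Smirnov
`D = sup_t |F̂_x(t) − F̂_y(t)|` with Bonferroni display conventions
(`α/m`); paired effect estimation
`mean_i 100·(CFE_t,i − CFE_c,i)/CFE_c,i` with a bootstrap interval.

**Histology**: optical-density stain unmixing
(`OD = −log₁₀(I/255)`, least squares onto two stain vectors);
`Area(%) = Area(positive)/Area(total) × 100`;
reciprocal mean intensity `255 − mean(I_positive)`;
mean linear intercept (mean airspace chord length along parallel test
lines, border chords excluded; a disk of diameter d has mean chord
πd/4).

**Synthetic fixtures** plant a bookkept ground truth for all of the
above, so the whole pipeline is testable without any external data.

## Worked example

```r
library(funnelomics)

cfg <- secretome_fixture_config(n_proteins = 200, n_planted_candidates = 5, seed = 1)
fx  <- generate_secretome_fixture(cfg)
run_funnel(fx$table, fx$bundle)
#> secretome prioritization funnel
#>   identified        EV=108  SF=171
#>   consistent        EV=86  SF=146
#>   partition         EV_only=17  both=69  SF_only=77
#>   growth_factors    total=60  EV_only=5  both=25  SF_only=30
#>   secreted          total=41  EV_only=5  both=15  SF_only=21
#>   receptor_matched  total=5  EV_only=0  both=2  SF_only=3
#> candidates:
#>   GENE00001 [SF_only] via RCPT_GENE00001
#>   GENE00002 [both] via RCPT_GENE00002
#>   GENE00003 [SF_only] via RCPT_GENE00003
#>   GENE00004 [both] via RCPT_GENE00004
#>   GENE00005 [SF_only] via RCPT_GENE00005
```

Reading the output: of 200 simulated proteins, 108 (EV) and 171 (SF)
were seen at least once; 86 and 146 were consistent across all four
replicates; the consistent sets share 69 genes; annotation, secretion
and receptor filters then reduce to exactly the five planted
candidates, each reported with its compartment provenance and matched
receptor — the generator's bookkept truth, recovered end to end.

```r
g <- generate_ihc_image(histology_fixture_config(positive_fraction = 0.3, seed = 2))
ihc_quantify(g$image)
#> IHC quantification [synthetic_ihc_seed2]
#>   positive area            : 30.00%
#>   reciprocal mean intensity: 155.0
#>   positive / tissue pixels : 15870 / 52900

d <- generate_alveolar_mask(histology_fixture_config(
  airspace_mode = "disks", disk_diameter = 80, n_disks = 1,
  image_shape = c(200L, 200L), seed = 4))
lmi(d$mask, pixel_size = 1, line_spacing = 1)
#> LMI: 62.81 um (160 chords on 400 both lines, spacing 1 um)
```

The planted 30% stained fraction is recovered exactly after unmixing
and Otsu thresholding; the reciprocal intensity 155 = 255 − 100 matches
the planted positive intensity; and the measured LMI of the 80 µm disk
matches the analytic mean chord π·80/4 ≈ 62.83 µm.

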