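---
title: "Methods: secretome candidate prioritization and regeneration assay quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: secretome candidate prioritization and regeneration assay quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funnelomics)
```

## The problem

Lung fibroblasts support alveolar epithelial repair in a paracrine
fashion, through extracellular vesicles (EVs) and soluble factors (SFs)
released into their environment. Mining this secretome for regenerative
drug candidates requires (i) a reproducible prioritization funnel from
mass-spectrometry detection tables to a short list of testable ligands,
and (ii) quantitative readouts for the assays used to validate
candidates: lung organoid colony formation, immunohistochemistry (IHC)
of human lung sections, and stereological injury scoring of
precision-cut lung slices (PCLS). `funnelomics` implements all three,
together with synthetic-data generators that plant a known ground truth
so that every computation can be verified end to end at desk scale.

## The prioritization funnel

The funnel consumes a detection table — one record per (protein,
fraction, replicate), fractions EV and SF, typically four biological
replicates each — and an annotation bundle, and applies binary filters
in a fixed order:

1. **Identified**: detected in at least one replicate of a fraction.
2. **Consistent**: detected in *every* replicate of that fraction
   (configurable via `min_replicates`). Requiring full replication is
   the main guard against one-off identifications in data-independent
   acquisition proteomics.
3. **Partition**: the consistent EV and SF sets are split into
   EV-only / shared / SF-only compartments; every later count is also
   reported per compartment, and final candidates carry this
   provenance.
4. **Growth factors and cytokines**: intersection with a user-supplied
   gene set (GMT). The set is deliberately not bundled: curated
   collections drift between database versions, and the choice of
   collection is an analysis decision that should be visible in the
   configuration, not frozen into the package.
5. **Secreted**: per-predictor boolean calls (e.g. a signal-peptide
   predictor and a transmembrane-topology predictor) combined with an
   `any` / `all` switch. The default is `any`: requiring a single
   positive call keeps factors that use non-classical secretion routes
   detectable by only one tool, and which filter was used is recorded in
   the result. Missing calls default to "not secreted" (conservative),
   switchable via `missing_policy`.
6. **Receptor-matched**: a factor survives when at least one of its
   receptor partners (ligand–receptor pair table) is expressed in at
   least one target cell type (alveolar type 1/2 cells by default).
   Receptor expression is a boolean input rather than a computed
   threshold; for users starting from a fraction-of-cells-expressing
   matrix, `expression_flags()` applies a 10%-of-cells default cutoff.

Gene symbols are uppercased and whitespace-stripped, with no alias
resolution — symbol identity stays literal and deterministic; a synonym
table can be applied upstream if needed. For intensity-valued tables,
"detected" means intensity strictly greater than zero by default
(label-free quantities from non-imputing pipelines are positive exactly
when observed); the threshold is configurable.

`marker_enrichment()` complements the funnel with the community
EV-characterization check: a 2×2 table of marker membership against
EV-/SF-consistency, with a Fisher (hypergeometric) exact p-value and an
infinite-odds sentinel plus Haldane-corrected estimate when a margin is
empty.

## Organoid statistics

Colony-forming efficiency is defined as
`CFE = 100 × organoids(>50 µm, day 14) / cells seeded`, the standard
organoid-field definition with the strict `>50 µm` scoring rule; the
denominator is the number of seeded epithelial progenitor cells (10,000
in the reference design).

- **Normality battery**: the four tests of the analysis protocol
  (D'Agostino–Pearson, Anderson–Darling, Shapiro–Wilk,
  Lilliefors-corrected Kolmogorov–Smirnov) at α = 0.05, with the 3-of-4
  rule deciding parametric versus nonparametric analysis. The
  D'Agostino–Pearson K2 statistic is computed from the standard
  skewness (D'Agostino 1970) and kurtosis (Anscombe–Glynn 1983) normal
  approximations and requires n ≥ 8; smaller samples are an error
  directing the user to a nonparametric test.
- **Dunnett comparisons**: one-way ANOVA with many-to-one contrasts via
  the multivariate-t distribution (`multcomp`), assuming equal
  variances as in the standard procedure. The paired variant fits a
  randomized-block model (replicate term) before the contrasts. A
  zero-residual-variance design (identical constants) is reported as
  "nothing significant" rather than an error.
- **Kolmogorov–Smirnov**: the two-sided two-sample D with the
  asymptotic effective-sample-size p-value; exact small-sample p on
  request. Diameter distributions are compared on the raw scale — D is
  invariant under the log transform used for display.
- **Bonferroni display**: the corrected α is reported at full precision
  together with a display value: four decimals by default, three when
  the fourth decimal changes the value by less than 2.5e-4 (it then
  carries essentially no information). This reproduces the legend
  conventions 0.0167 (m = 3), 0.0125 (m = 4), 0.004 (m = 12), 0.025
  (m = 2) at family α = 0.05.
- **Effect estimation**: per matched replicate pair,
  `100 × (CFE_t − CFE_c)/CFE_c`; the summary is the mean over pairs
  with a seeded percentile bootstrap interval (2,000 resamples).
  Pairs with zero control CFE are excluded with a warning — a ratio to
  zero is undefined, and silently substituting a pseudo-count would
  bias small experiments.

## Histology quantification

**Stain separation.** RGB intensities are converted to optical density
(`OD = −log10(I/255)`, with 0 clamped to 1 before the log) and unmixed
by least squares onto two unit absorbance vectors — hematoxylin and a
red peroxidase chromogen by default, following the widely used
published RGB absorbance coefficients — with concentrations clamped at
zero. The basis is configurable; collinear vectors are rejected.

**Positive area and intensity.** The stained-area percentage is
`100 × Area(positive)/Area(total)`, with the total (tissue) mask
obtained by white-background removal (mean luminance < 0.95 of 255,
configurable) and optional manual exclusion masks for airways and
vessels — mirroring workflows in which such regions are removed by
hand. Positivity is thresholded within tissue, by Otsu's method on the
within-tissue histogram by default (a constant histogram yields an
empty mask) or by a fixed cutoff; the threshold used is always
reported. The reciprocal mean intensity is
`255 − mean(intensity of positive pixels)` on the 8-bit scale where 0
is darkest, so the value grows with staining strength. The "separated
stain image" whose intensities enter this formula is reconstructed from
the unmixed concentration at unit absorbance, `I = 255 × 10^(−c)` —
the one parameter-free convention available when the original
single-stain images are produced interactively.

**Mean linear intercept (LMI).** Parallel test lines are laid across
the binary airspace mask at a configurable spacing; each maximal run of
airspace pixels along a line is one chord; chords touching the image
border are excluded because their full extent is unknown; the field LMI
is the mean chord length in µm, and the per-animal LMI the unweighted
mean over fields (five per animal in the reference protocol; other
counts warn). Chord measurement — rather than line-length divided by
intercept count — is used because the quantity of interest is the
average free-airspace distance. Horizontal and vertical line families
are pooled by default to reduce orientation bias. Paired designs
(each animal its own control) are compared by paired t-test for two
conditions and paired Dunnett for more.

## Synthetic fixtures and what they show

The generators define the test conditions; their defaults are fixed
once and not tuned per test.

- **Secretome fixture**: four replicates per fraction; decoy
  consistency rates 0.45 (EV) and 0.79 (SF), the rates observed in the
  reference experiment (564/1262 and 1658/2090). Planted candidates are
  consistent (SF-only or shared — the compartments in which real
  candidates were found), annotated, secreted by both predictors, and
  receptor-matched; every decoy is assigned a controlled failure stage.
  Expected stage counts and the expected candidate set are recorded by
  bookkeeping *during* generation (dropout noise updates the ledger
  before the truth is frozen), never re-derived from the emitted
  tables. This makes planted-truth recovery a genuine end-to-end check
  of the funnel, though on perfectly coherent annotations — it cannot
  detect problems that only arise with real, noisy annotation sources
  (aliases, incomplete pair databases).
- **Organoid fixture**: counts are binomial in (10,000 seeded, CFE);
  control CFE 0.01 (about a hundred organoids per culture — the paper
  prints no absolute baseline, so this is a realism choice giving
  adequate counting statistics); treatment CFE ratio 1.75 (the
  calibrated ≈ +75% candidate effect); cigarette-smoke-extract ratio
  0.6 with a +0.15 diameter log-mean shift, qualitatively matching
  fewer-but-larger organoids under smoke stress. Diameters are
  lognormal (log-mean log(120 µm), log-sd 0.4 — organoid sizes are
  right-skewed and compared on a log scale) truncated at the >50 µm
  scoring rule by rejection sampling. The binomial model omits
  between-animal overdispersion, so real paired experiments will show
  wider intervals than the fixture suggests.
- **Histology fixtures**: the stained slide is synthesized by *forward*
  optical-density mixing with the package's own stain basis and a
  planted fraction of positive tissue pixels (with mild lognormal
  concentration jitter), so unmixing inverts a known model; this
  validates the algebra, not robustness to stains deviating from the
  assumed basis. Airspace masks are a band (every chord equals the
  band width) or non-overlapping disks (mean chord over uniform
  parallel secants = πd/4, the closed form the stereology tests check
  against). Disk placement is rejection sampling with a 10,000-attempt
  cap that fails loudly rather than overlapping silently.

## Numerical and design choices

- All randomness flows from one master seed through fixed per-module
  substream offsets (`substream seed = (seed mod 2e6) × 1000 +
  offset`), so modules rerun independently still reproduce a joint run,
  and derived seeds stay below 2^31.
- Otsu thresholds are computed on 256 levels over the observed
  within-tissue range; the optimum is a plateau when a gap separates
  the classes, and any plateau point is accepted as optimal.
- Areas are computed in pixels and converted with `pixel_size`;
  coordinates are row-major.
- The orchestration layer (`run_all()`, `validate_inputs()`,
  YAML configuration with unknown-key rejection, JSON run reports) is
  exposed as functions rather than a shell executable: the package is a
  library used from R scripts and notebooks, and a thin CLI would add a
  dependency surface without adding capability.

## Problem sizes used in the shipped checks

The test suite runs the funnel on tables up to ~3,400 proteins
(the study-scale synthetic fixture built to the published stage
cardinalities), 100 randomized fixture configurations of 30–150
proteins, organoid simulations of 8–50 paired cultures of 10,000 seeded
cells, stained fields of 256×256 px and masks up to 300×300 px with
1 px line spacing. These sizes give sub-minute suites while keeping
every statistical check inside its stated tolerance.

## Known limitations

- The funnel is a composition of binary filters; it deliberately does
  not rank candidates (the reference strategy evaluates all survivors
  experimentally).
- Stain separation assumes exactly two stains and Beer–Lambert
  additivity; heavily saturated pixels (intensity 0) lose concentration
  information to the 8-bit clamp.
- LMI on PCLS is a relative injury measure: inflation pressure varies
  between animals, which is why the comparison layer is paired
  (each animal its own control) rather than absolute.
- The D'Agostino–Pearson approximations are asymptotic; at n just
  above the minimum of 8 the battery leans on the other three tests.
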