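---
title: "Evaluating pepper varieties for mechanized transplanting and harvesting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating pepper varieties for mechanized transplanting and harvesting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechadapt)
```

## The problem

Processing peppers (*Capsicum annuum*) bred for yield and quality often fail
under machines: transplanter claws scatter loose root balls, harvesting drums
snap brittle fruiting branches, and lodged plants are simply missed. Screening
varieties for *mechanization adaptability* therefore has to combine ordinary
morphology (plant height, canopy spread) with biomechanical traits (stem and
branch toughness, lodging grade, pedicel separation force) and population
uniformity (fruit shape and size CVs) — traits that trade off against each
other, so no single-trait threshold can rank varieties sensibly.

`mechadapt` implements a complete evaluation pipeline for this setting:

1. a canonical **21-indicator registry** — 8 seedling (transplanting-stage)
   and 13 harvest-stage indicators, each a *benefit* (larger better) or
   *cost* (smaller better) indicator;
2. **formula-level trait scoring** for the indicators that are derived rather
   than read off an instrument;
3. **variation summaries** (max/min/mean/SD/CV per indicator);
4. **CRITIC** objective weighting;
5. **VIKOR** compromise ranking;
6. auxiliary **multivariate views** (hierarchical clustering, PCA with
   comprehensive scores, Pearson correlation with significance flags);
7. a **synthetic cohort generator** calibrated to published cohort summaries
   of 56 erect-fruit and 49 pendent-fruit varieties, so the whole pipeline is
   testable without field data.

## The indicator system

```{r}
reg <- default_registry()
table(reg$stage, reg$direction)
```

Two conventions deserve a note. The lodging grade PLR is a *cost* indicator:
a larger grade means a more inclined stem, i.e. *worse* lodging resistance.
The fruit-setting-position score FSP (1 = inner-upper … 6 = outer-lower
canopy region) is kept as a *benefit* indicator, following its established
designation in this evaluation system; the registry records the designation
without reinterpreting it, and a user who disagrees can supply a modified
registry document to `load_registry()`.

## Trait scoring

Derived indicators come from explicit, unit-tested formulas:

* **SSDR** (substrate disintegration rate): a plug seedling free-falls from
  60 cm; SSDR = 100·W₁/(W₁+W₂) where W₁ is the scattered and W₂ the
  retained substrate mass. Scale-invariant in the masses.
* **PLR** (lodging grade): 0 if the stem–ground angle α ≤ 15°, 1 if
  15° < α ≤ 30°, 2 if 30° < α ≤ 45°, 3 if α > 45°. Boundary angles belong
  to the lower grade.
* **FMU / FSU** (fruit uniformity): the CV% of the fruit shape index
  (length/diameter) and of the 2D projected area over a fruit sample
  (conventionally 30 fruits). Sample SD (n−1) is used — the standard for CV
  reporting on samples of this size. One CV is computed per provided fruit
  set; plot-level aggregation is left to the caller since the field protocol
  for it varies.
* **FSP**: the canopy region with the largest fruit share; ties resolve to
  the smallest region index, a deterministic and documented choice.
* **Replicate aggregation**: mechanical-property replicates (typically nine)
  are averaged after excluding one occurrence of the maximum and one of the
  minimum — exactly one of each even when extremes are duplicated.

## CRITIC weighting

With n varieties and p indicators, the matrix is Min–Max normalized per
column with direction folded in (benefit: (x−min)/(max−min); cost:
(max−x)/(max−min)), so 1 is always the favourable end. Each indicator j then
gets

* contrast intensity σⱼ — the **population** SD (1/n under the root, as the
  method's formula specifies; the descriptive tables deliberately use the
  sample SD instead, and the two conventions are not unified);
* conflict Rⱼ = Σₖ (1 − r_jk) with plain Pearson r (not |r|): negative
  correlation means *less* redundancy and raises conflict;
* information quantity Cⱼ = σⱼ·Rⱼ and weight Wⱼ = Cⱼ/ΣCⱼ.

Two genuinely open choices were resolved as follows. Correlations are
computed on the **normalized** matrix by default (`cor_on = "raw"` is
available): direction alignment prevents the cost-column reflection from
flipping correlation signs, which is the standard CRITIC construction.
Degenerate (zero-range) columns get weight 0 and are excluded from the
conflict sums of other indicators — a constant column carries no information
and has undefined correlations. Numerically, correlations within 1e−12 of 1
are snapped to 1 so that exactly collinear indicators get exactly zero
conflict rather than floating-point dust.

## VIKOR ranking

Per indicator, the ideal f⁺ is the best attained value (max for benefit, min
for cost) and f⁻ the worst. The weighted normalized distance of variety i to
the ideal on indicator j is d_ij = Wⱼ(fⱼ⁺ − x_ij)/(fⱼ⁺ − fⱼ⁻) ∈ [0, Wⱼ].
Group utility Sᵢ = Σⱼ d_ij and individual regret Rᵢ = maxⱼ d_ij; the
compromise value

Qᵢ = v·(Sᵢ−S⁺)/(S⁻−S⁺) + (1−v)·(Rᵢ−R⁺)/(R⁻−R⁺),  v = 0.5 by default,

ranks varieties ascending. The regret term is what makes VIKOR suitable
here: in a harvesting scenario one fatal defect (extensive lodging, brittle
branches) voids all other virtues, so a variety must not be able to buy its
way to the top by excelling elsewhere — Liebig's law of the minimum as a
ranking principle. `compare_models()` makes this operational by comparing
the worst defect-trait value inside the VIKOR top-k against the top-k of a
compensatory PCA comprehensive score.

Implementation decisions:

* VIKOR consumes the **raw** matrix with direction handled by the ideal
  solutions; for non-degenerate columns this is algebraically identical to
  scoring the normalized matrix (asserted as a test).
* Ties in Qᵢ break by ascending Sᵢ, then Rᵢ, then variety ID —
  deterministic output.
* If all varieties have identical S (or R), that Q term is defined as 0 and
  the other term alone ranks.
* The classical "acceptable advantage / acceptable stability" compromise-set
  conditions are not part of the ranking, which is by Qᵢ alone.

## Multivariate views

Clustering and PCA operate on z-standardized columns: the 21 indicators mix
units spanning orders of magnitude, and correlation-matrix PCA is the
convention in trait studies. Clustering is agglomerative under Euclidean
distance with average linkage (UPGMA) by default and single/complete/Ward
selectable; because published cut heights are only meaningful under the
original (unreported) linkage, cluster *counts*, not heights, are the
reliable interface — `hierarchical_clusters()` accepts either. PCA retains
components with eigenvalue > 1 (Kaiser rule); each loading vector is flipped
so its largest-magnitude entry is positive, making scores sign-reproducible.
The comprehensive score is the contribution-weighted sum over retained
components, with weights contribution/cumulative-contribution summing to 1 —
the standard construction for a "comprehensive PCA score", isolated in
`pca_ranking()` so it can be swapped. Correlation p-values come from the t
distribution with n−2 df, flagged at 0.05 and 0.01.

## The synthetic cohort generator

`default_cohort_spec()` packages the published per-indicator
max/min/mean/SD quadruples for the erect (n = 56) and pendent (n = 49)
cohorts; `generate_trait_matrix()` draws each column from a normal
distribution with the published mean/SD **truncated** to the published
[min, max], via the inverse-CDF transform. The published moments are used as
the *untruncated* parameters — the simplest faithful emulation — so the
realized moments are shifted slightly toward the interval's interior; tests
therefore compare generated moments against truncated-normal oracle values
computed by numerical quadrature, not naively against the configured
mean/SD. Columns are independent by default; a Gaussian copula couples them
when a latent correlation matrix is supplied, and `preset_correlation()`
encodes the strongest known seedling-vigour associations (SPH–SSD–SCS block,
SSDR–SHL) at magnitude 0.5 for exercising the correlation stage.

Discrete-ish indicators (the PLR grade, the FSP score) are generated as
continuous values on their published ranges, because cohort trait matrices
treat them as numeric plot means; `generate_measurement_records()` provides
the raw-record route instead (drop-test masses, lodging angles with
expectation-preserving randomized rounding into grade bands, canopy counts,
replicate blocks) for end-to-end tests of the scoring operators. One spec
seed governs everything through deterministic sub-seeds per record kind, so
each table is reproducible independently of generation order. The published
SDs are treated as across-variety SDs, since the evaluation matrix has one
row per variety.

What the generator does **not** emulate: the real trait correlation
structure beyond the optional preset, genotype-specific multimodality,
plot-level measurement error, and the identity of any real variety. Passing
tests on synthetic cohorts therefore validate the *machinery* — formulas,
weighting, ranking, their invariants — not field conclusions about actual
cultivars.

## Problem sizes and runtime

The test suite works at the cohort sizes of the study design (56/49 × 21)
for end-to-end runs, n = 5000 for generator moment recovery, and 100 random
8×5 matrices for oracle equivalence of the CRITIC–VIKOR chain against an
independently coded naive reference (agreement to 1e−9). Statistical checks
on 21 simultaneous columns use a Bonferroni-adjusted per-column bound at the
family-wise level of a single 3 SE test.

## Known limitations

* CRITIC weights are data-driven, hence cohort-relative: adding or removing
  varieties changes the weights and thus, potentially, the ranking of the
  rest. This is inherent to the method, not a defect; `run_evaluation()`
  recomputes weights per cohort and says so in its manifest.
* With every pairwise correlation exactly 1, all information quantities are
  0 and the weight vector collapses to zeros rather than to a simplex point.
* The rankings produced on synthetic cohorts are draws from a calibrated
  distribution, not reconstructions of any published per-variety ranking,
  which would require the unpublished raw data.
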