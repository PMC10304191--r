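---
title: "Methods: dietary organochlorine exposure and individual risk modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dietary organochlorine exposure and individual risk modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocprisk)
```

## Scope and data model

`ocprisk` operationalises a combined cohort- and individual-level risk
assessment for populations chronically ingesting organochlorine pesticides
(OCPs) and heavy metals with locally produced food. The unit of analysis is a
surveyed person: village, sex, age, body weight, smoking and alcohol use,
daily consumption of seven foods (meat, cucumbers, tomatoes, peppers, apples,
pears, milk), genotypes at a 21-variant susceptibility panel, and two
outcomes — an ordinal count of registered chronic diseases ("health rank")
and the percentage of aberrant lymphocyte metaphases. Contamination arrives
as mean concentrations per (village, food, contaminant group): six pesticide
groups pooled by chemical structure (DDT, HCB, HCH, aldrin, endosulfan,
heptachlor) and eight heavy metals (Cu, Zn, Ni, Co, As, Pb, Cd, Cr).

## Exposure indices

The chronic estimated daily intake is `EDI = C · Cons / Bw`
(mg/kg-bw/day), summed over foods within a contaminant group. The
lifetime-averaged form multiplies by exposure frequency and duration and
divides by the averaging time (default 25,550 days, the 70-year carcinogenic
convention). One dimensional choice deserves note: as commonly printed, the
lifetime formula multiplies a day-count EF by a day-count ED, which changes
the units. `compute_edi_lifetime()` therefore enters EF as the dimensionless
fraction EF/365, keeping the result in mg/kg-bw/day and directly comparable
to an ADI; with EF = 365 days/year and ED equal to the averaging time it
reduces exactly to the plain daily form.

Hazard indices divide intakes by reference doses: `HQ = HI = EDI/ADI`, with
the percentage variants `cHQ = HI% = 100·EDI/ADI` (the two chronic
definitions coincide identically — the package exposes both names and tests
the identity) and the acute `aHQ = 100·ESTI/ARfD`, where
`ESTI = Σ F·HR:P / mean Bw` is the single-sitting intake of a full portion at
the highest residue level. A food or group is flagged hazardous when the
`EDI/ADI` ratio strictly exceeds 1.0; exactly 1.0 is not flagged (the
convention is "< 1.0 practically no probability of adverse impact, > 1.0
hazardous", and the boundary is resolved toward non-hazard). No ADI exists
for the HCB and HCH groups; every index whose reference dose is absent is
returned as `NA` ("not computable"), never as zero, and the same rule applies
to missing concentration cells — a missing cell only propagates to an
individual's group intake if the individual actually consumes that food.

Milk is surveyed in L/day and treated as kg/day with density 1.0; the source
survey performs no conversion either, and the approximation is below 4%.

## Genotype statistics and cluster scores

Allele frequencies use gene counting, `p = (2n_AA + n_AB)/(2n)`. The
Hardy–Weinberg test is the Pearson chi-square of observed genotype counts
against `n·p², 2npq, n·q²` without continuity correction. The reference
distribution defaults to **2 degrees of freedom**: the conventional
asymptotic df for this statistic is 1, but the survey whose summary table the
package reproduces evaluates it at df = 2, and its printed p-values (e.g.
chi-square 15.445 with p = 0.0004, or 3.878 with p = 0.144) reproduce only
under that convention. `hwe_test(..., df = 1)` restores the standard choice.
At df = 2 the test is conservative for true-HWE data, which is why simulated
cohorts pass it essentially always at alpha = 0.01 (a tested property).

Two printed cells of the original genotyping summary are inconsistent with
the table's own integer counts, as exact recomputation shows: one chi-square
(132.552 computed vs 132.532 printed — a transposed digit) and one allele
frequency (0.71854 computed, truncated rather than rounded in print). Tests
assert the recomputed values there and the printed values everywhere else.

The GSTT1/GSTM1 whole-gene deletions are phenotype-only assays: null (−/−)
versus positive (+/+ or +/−). The null-allele frequency is the HWE
square-root estimator `q = sqrt(n_null/n)`; the raw null-phenotype proportion
is reported alongside. For GSTM1 (110/110) the estimator gives q = 0.707
while the source table prints 0.500/0.500 — an internal inconsistency of the
source, so neither GSTM1 number is treated as a check value.

Genotype risk scoring is **dominant** by default: a variant scores 1 if at
least one non-functional allele is present, 0 otherwise, matching the
scoring definition ("0 is full functionality … 1 is the presence of a
non-functional allele"); an additive 0/0.5/1 coding is available
(`coding = "additive"`) for sensitivity analysis. Deletion markers score 1
only for the null phenotype, since a heterozygous deletion is
indistinguishable from +/+ in the assay. Cluster scores are per-system means
over non-missing variants (4 DNA-repair, 9 detoxification, 8
antioxidant-defence markers), hence lie in [0, 1]; an entirely missing
cluster is an error, not a silent zero. Samples with call rate strictly
below 98% are dropped (`sample_qc()`), the boundary 0.98 being kept.

## The nine-factor risk model

Both outcomes are fitted by ordinary least squares on: age (X1), the mean
pesticide MPC fold-excess (X2), the mean ADI fold-excess of the individual's
group-wise intakes (X3), the heavy-metal MPC fold-excess analogue (X4), the
three cluster scores (X5–X7), smoking (X8) and alcohol (X9). The source
describes X2–X4 only as "exceeding the permissible levels"; this package's
default operationalisation weights each food's fold-excess by the
individual's consumption share and averages over contaminant groups with a
defined limit, so the summary is dimensionless, individual-specific, and
excludes not-computable cells. `summary = "max"` and `"count"` (number of
limits exceeded) are provided because the original choice is unrecoverable.

OLS uses `stats::lm()`; the test suite verifies it against an independent
normal-equations solver to 1e-8 relative on random well-conditioned designs
of the analysis shape (n = 151, m = 9). Classical homoskedastic standard
errors are the default (an HC1 sandwich option exists but is off, mirroring
the reference analysis); `t_i = b_i/SE_i` exactly, and adjusted
`R² = 1 − (1 − R²)(n−1)/(n−m−1)`. Coefficient significance compares |t|
with **fixed critical values** 2.263 (health model) and 2.693 (genetic
model): these are carried as supplied constants rather than recomputed
Student quantiles because their derivation in the source is unclear (2.263
is described there as a "number of degrees of freedom", and the two models
share n and m yet use different values). Both are overridable.

Per-factor **influence shares** decompose the explained variability: squared
semipartial correlations `sr_i² = t_i²(1−R²)/(n−m−1)` rescaled to sum to
100·R². With orthogonal predictors each share equals the predictor's
marginal 100·r² (a tested closed-form property). The original decomposition
method is not recorded; a sequential (Type I) alternative is available via
`influence_shares(fit, method = "sequential")`.

**Predictive ability** binarizes predicted scores at their arithmetic mean
and observed outcomes at theirs, and reports the concordant fraction. The
mean–mean reading is an interpretation (the source does not state which
threshold the observed outcome uses) and is flagged as such; the measure is
invariant under positive affine transforms of the scores and undefined
(returned `NA`) for zero-variance inputs. Ordinary least squares is used for
the ordinal health rank deliberately — the reference equations and their R²
are linear-model quantities — and no multiple-testing correction is applied
across coefficients, again mirroring the reference analysis.

## The synthetic cohort: what it emulates and what it does not

The simulator's defaults are the survey's published structure: seven villages
with 32/26/31/25/27/25/25 blood donors (191 total) of which a random subset
of 151 carries the detailed questionnaire and forms the analysis set (the
donors-vs-questionnaires discrepancy is treated as missingness); per-village
sex ratios, ages (normal truncated to [18, 85] years, matching the published
mean ± sd per village; birth-year bookkeeping is omitted), body weights by
sex (normal truncated at 40 kg), and per-food consumption from a
moment-matched lognormal — chosen because the published consumption sds are
of the order of the means (strong right skew) and intake is non-negative; the
source states no distribution. Genotypes are drawn under HWE at the
risk-allele frequencies estimated from the published genotype counts (for
GSTM1, the square-root estimate 0.707, keeping the generator internally
consistent). Smoking and alcohol prevalences are not published; 0.25 and
0.30 were fixed once as realistic adult rates for the region and are profile
parameters.

Pesticide concentrations per (village, food, group) are **synthetic**: the
original chemistry lives in a companion publication and is not public. They
are back-calculated so that, at village mean consumption and body weight,
the group-wise intakes equal the published per-village chronic intake means,
and are spread over foods by a fixed relative residue pattern (higher for
pears, cucumbers, peppers, meat — the foods the survey names as driving
risk). Heavy-metal concentrations and MPCs, and the ARfD values, are likewise
synthetic defaults (typical food-survey magnitudes; ARfD = 10 × ADI where an
ADI exists), all user-replaceable. Consequently per-village hazard tables
have realistic structure and scale but are not reproductions of the original
tables — those depend on non-public sample-level data.

Outcomes are generated from the published nine-coefficient equations:
`Y = β·X + ε`, `ε ~ N(0, σ)`. The reported variables are transforms of the
continuous latent — health rank is rounded and clipped below at 0,
aberration % clipped to [0, 100] — and parameter-recovery properties are
defined on the latent, because the transforms are reporting conventions, not
part of the linear model. With σ = 0 the refit recovers the generating
coefficients to 10 significant digits (tested). When σ is not supplied it is
**calibrated**: Monte-Carlo design replicates are pre-simulated, noise
directions fixed (common random numbers), and σ is found by root finding so
that the mean refitted R² equals the published determination coefficient
(24.74% health, 14.24% genetic). The calibrated σ is deterministic under the
master seed; all stages draw from child seeds derived from that one seed, so
a fixed configuration reproduces every output byte for byte.

Because the predictor scales (notably X3, dominated by the aldrin group's
very low ADI) are large, the latent outcomes inherit a large scale and the
clipped aberration percentage saturates for many synthetic individuals. This
is a faithful consequence of combining the published coefficients with
exposure scales of this population, and is immaterial for the properties the
simulator exists to demonstrate (which operate on the latent), but synthetic
`aberration_pct` values should not be read as realistic cytogenetics.

What passing tests show, therefore, is that the pipeline's statistics are
correct and that the estimation machinery recovers known generating
parameters at the survey's size and noise level — not that the package
reproduces the original cohort's fitted coefficients, influence percentages
or predictive-ability counts, which require the non-public individual data
and are carried only as calibration anchors (`calibration_anchors()`).

## Numerical and interface choices

Report columns round frequencies and chi-squares to 3 decimals (the source
table's precision); all internal computation is full precision. Problem
sizes used by the checks were chosen to keep the whole suite fast while
leaving Monte-Carlo margins wide: 10,000 individuals for law-of-large-numbers
and allele-frequency recovery checks, 100 random designs for the OLS oracle
comparison, 200 replicates of n = 151 for coefficient coverage, 40 design
replicates with 15–40 for calibration. All tables are plain CSV with the
explicit token `NA`; readers validate schemas and report offending rows by
number. Individual identifiers are opaque strings. The pipeline is driven
from R (`simulation_config()` + `run_pipeline()`), which covers the
orchestration surface — simulate, exposure, genetics, fit, predict — with
stage toggles and dependency checks; a shell wrapper would add nothing for
the package's intended interactive use.

## Known limitations

- X2–X4 are one of several defensible summaries of "exceeding permissible
  levels"; conclusions can be sensitive to this choice, which is why it is a
  parameter.
- The health rank is ordinal; OLS is used by design fidelity, not because it
  is the best model for such outcomes.
- The critical values 2.263/2.693 are opaque constants; users wanting
  conventional inference should compare |t| with `qt(0.975, n - m - 1)`.
- The dominant 0/1 gene scoring discards dosage information; the additive
  option is provided but was not the reference coding.
- Synthetic contamination, MPC and ARfD defaults are placeholders with
  realistic magnitudes, not measurements; substantive use requires real
  tables.
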