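# ocprisk

Individual and cohort health-risk assessment for populations chronically
exposed to organochlorine pesticides (OCPs) through locally grown food.

Rural communities living near legacy stores of obsolete pesticides ingest
persistent organochlorines (DDT, HCB, HCH, aldrin, endosulfan and heptachlor
groups) and heavy metals with everyday foods. `ocprisk` implements, as a
reusable and fully tested pipeline, the risk-assessment methodology used in a
seven-village field survey of such a population: dietary exposure indices,
genotype-based susceptibility scores, and a nine-factor multivariate model of
health and genetic (chromosomal-aberration) risk. Because the original
individual-level data are available only on request, the package ships a
seeded synthetic-cohort simulator that reproduces the survey's statistical
structure, so every stage can be exercised and validated end to end.

It is aimed at biostatisticians and environmental-health researchers who want
to apply or stress-test this individual-risk methodology on their own
questionnaire + genotype + food-chemistry data.

## The methods

**Dietary exposure.** For contaminant concentration `C` (mg/kg), daily
consumption `Cons` (kg/day) and body weight `Bw` (kg):

```
EDI  = C * Cons / Bw                        (chronic daily intake, mg/kg-bw/day)
EDI* = C * IR * (EF/365) * ED / (Bw * AT)   (lifetime-averaged form)
ESTI = sum_f (F_f * HR:P_f) / mean Bw       (acute single-sitting intake)
```

Hazard indices compare intakes with toxicological reference values:
`HQ = HI = EDI/ADI` (food hazardous when `HI > 1.0`), the percentage forms
`cHQ = HI% = 100*EDI/ADI` and `aHQ = 100*ESTI/ARfD`, and the
regulatory-residue fold-excess `C/MPC`.

**Genetics.** Allele frequencies by gene counting, Hardy–Weinberg equilibrium
tested by a Pearson chi-square against `n·p², 2npq, n·q²` referred to a
chi-square with 2 degrees of freedom (the survey's convention; df = 1 is
available), a square-root null-allele estimator for the GSTT1/GSTM1 deletion
phenotypes, and a 98% call-rate sample QC rule. Each of 21 variants in 14
genes scores 0 (fully functional) or 1 (carries a non-functional allele);
cluster scores are the per-system means over DNA-repair, xenobiotic-
detoxification and antioxidant-defence genes.

**Risk model.** Ordinary least squares of an outcome Y (chronic-disease rank,
or % aberrant lymphocyte metaphases) on nine factors:

```
Y = b0 + b1*age + b2*pestMPC + b3*pestADI + b4*metalMPC
       + b5*repair + b6*detox + b7*antiox + b8*smoking + b9*alcohol + e
```

with t-statistics `t_i = b_i/SE_i` compared against fixed critical values,
adjusted `R² = 1 − (1 − R²)(n−1)/(n−m−1)`, a per-factor influence
decomposition (rescaled squared semipartial correlations), a mean-threshold
predictive-ability score, and the two published coefficient vectors shipped
as constants for direct prediction.

## Worked example

```r
library(ocprisk)

# Genotype-table statistics from the bundled survey counts
sm <- genotype_summary(genotype_counts_table())
head(sm[, c("rsid", "gene", "freq_A_report", "freq_B_report", "chi2_report")], 3)
#>        rsid  gene freq_A_report freq_B_report chi2_report
#> 1  rs861539 XRCC3         0.755         0.245      15.445
#> 2 rs1799782 XRCC1         0.811         0.189       1.940
#> 3   rs25487 XRCC1         0.540         0.460       3.878

# Hazard classification: DDT intake 0.40 mg/kg-bw/day against ADI 0.01
hazard_indices(edi = 0.40, adi = 0.01)
#>   hq hi_ratio hi_pct chq_pct ahq_pct hazardous
#> 1 40       40   4000    4000      NA      TRUE

# Full synthetic pipeline: simulate 191 donors / 151 questionnaires,
# compute exposures and cluster scores, fit both risk models
cfg <- simulation_config(seed = 42)
rep <- run_pipeline(cfg, out_dir = "out")
rep$fit_health
#> Nine-factor linear risk model (n = 151, m = 9)
#> ... pest_adi_excess  0.72428  0.14107  5.134 ...
#> R^2 = 0.2508, adjusted R^2 = 0.2029
round(rep$predictive_ability, 3)
#>  health genetic
#>   0.675   0.589
```

The first table reproduces the survey's genotyping summary exactly from its
integer genotype counts (rs861539: risk-allele frequency 0.245, HWE
chi-square 15.445, p = 0.0004 at df = 2). The hazard row says a DDT intake of
40 times the acceptable daily intake is flagged hazardous, with the chronic
hazard quotient at 4000%. In the pipeline fit, the individual pesticide
intake factor (`pest_adi_excess`) is the dominant, significant predictor of
the simulated health rank (t = 5.13 against the critical value 2.263), the
model explains ~25% of outcome variability (the simulator's calibration
target is the 24.74% reported for the real cohort), and the mean-threshold
prediction agrees with the observed outcome for ~68% of individuals.

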