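# defensinCNV

Gene copy number at the beta-defensin locus on chromosome 8p23.1 (which
contains *DEFB4*, encoding the antimicrobial peptide HBD2) varies between 1
and 12 copies per diploid genome. `defensinCNV` implements the full analysis
chain linking that copy number to mucosal HBD2 protein and bactericidal
activity in cervicovaginal samples:

1. **PRT genotyping** — the paralogue ratio test (PRT) co-amplifies a test
   locus inside the copy-number-variable region and a reference locus
   outside it; the peak-area ratio *r* is proportional to copy number. Each
   assay/dye channel is calibrated by ordinary least squares on a reference
   panel of known integer copy numbers, *r = a + b·CN*, inverted to a
   continuous estimate *(r − a)/b* with dispersion taken from the panel
   residuals. Dye channels are averaged within each assay, and the assay
   estimates *x_i ± s_i* are pooled by a Gaussian maximum-likelihood scan:

   log L(k) = Σᵢ [ −log(sᵢ√(2π)) − (xᵢ − k)² / (2sᵢ²) ],  k = 1…12

   The call is argmax L(k) (ties to the smaller integer), with confidence
   L(k*)/Σₖ L(k). The continuous inverse-variance-weighted mean
   Σ(xᵢ/sᵢ²)/Σ(1/sᵢ²) is the copy-number axis for correlation analyses.
2. **Assay processing** — ELISA HBD2 readings below the 16 pg/ml limit of
   detection are substituted by LOD/√2; concentrations are normalized to
   total protein (pg/ml ÷ µg/ml → pg/µg). Bactericidal activity is
   `%kill = 100·(1 − cfu_test/cfu_control)` with the buffer control as 100%
   survival, from triplicate cfu readings, then normalized to total protein
   (%kill/µg).
3. **Association analysis** — pairwise Spearman rank correlations (mid-ranks
   for ties; exact permutation p-values for n ≤ 9 without ties, otherwise
   the t approximation), cohort exclusion rules with an audit trail,
   term/preterm stratification, and Mann–Whitney U group comparisons with
   exact assignment enumeration for small groups.
4. **Synthetic cohorts** — a seeded generator reproducing the statistical
   structure such data exhibit (copy numbers 1–8 with mode 4, log-linear
   HBD2 and kill models, ~12% censoring, ~4.4% typing failure, outcome and
   exclusion flags), so the entire pipeline is testable without clinical
   data.

It is aimed at researchers analysing multiallelic CNV genotyping data with
downstream biomarker phenotypes, and at anyone needing a reference
implementation of PRT integer calling.

## Worked example

```r
library(defensinCNV)

man <- run_pipeline("run1", seed = 11,
                    sim_config = cohort_config(n_subjects = 80),
                    quiet = TRUE)
read.csv("run1/calls.csv")[1:3, ]
#>   sample_id n_units weighted_mean_cn ml_integer_cn confidence qc_flags
#> 1     S0001       3         3.985683             4          1
#> 2     S0002       3         3.069575             3          1
#> 3     S0003       3         7.257233             7          1

subset(read.csv("run1/correlations.csv"), stratum == "all")[, 2:6]
#>                 var_x                var_y  n        rho      p_value
#> 1    weighted_mean_cn  hbd2_norm_pg_per_ug 72  0.3727571 1.261235e-03
#> 2    weighted_mean_cn     kill_per_protein 72  0.2575085 2.897972e-02
#> 3    weighted_mean_cn gestational_age_days 72 -0.1776284 1.355034e-01
#> 4 hbd2_norm_pg_per_ug     kill_per_protein 74  0.5172455 2.373556e-06
#> 5 hbd2_norm_pg_per_ug gestational_age_days 74 -0.4177566 2.127577e-04
#> 6    kill_per_protein gestational_age_days 74 -0.2675929 2.117003e-02
```

Each row is one variable pair: `rho` is the Spearman coefficient on the
pairwise-complete subjects `n`, `p_value` its two-sided p-value. Copy
number correlates positively with normalized HBD2 and with kill activity,
HBD2 strongly with kill activity, and gestational age negatively with
HBD2 — the structure the generator is calibrated to produce. `run1/` also
contains the calibration report, processed assay table, exclusion audit,
group comparisons, scatterplot-matrix data, and a manifest with checksums
and per-stage row counts.

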