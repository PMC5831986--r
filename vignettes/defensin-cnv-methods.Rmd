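---
title: "Methods: PRT copy-number calling and cervicovaginal antimicrobial analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PRT copy-number calling and cervicovaginal antimicrobial analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(defensinCNV)
```

## Scientific setting

The beta-defensin locus on chromosome 8p23.1 — containing *DEFB4*, the gene
for the mucosal antimicrobial peptide HBD2 — is multiallelic copy-number
variable, with diploid copy numbers from 1 to 12. The scientific question
this package's analysis chain addresses is whether gene dosage at that locus
propagates to HBD2 protein abundance and to functional bactericidal
activity at the cervical mucosa during pregnancy, where the cervical mucus
plug is the antimicrobial barrier against ascending infection and preterm
birth is the clinical outcome of interest. The chain has four stages:
paralogue-ratio-test (PRT) genotyping, assay processing, rank-correlation
association analysis, and a synthetic-cohort generator that makes the first
three testable end to end.

## PRT genotyping model

A PRT assay co-amplifies a test locus inside the CNV and a reference locus
outside it with the same primer pair, so the capillary-electrophoresis
peak-area ratio $r$ is, up to assay-specific scale, proportional to copy
number. The default channel set is two dyes each for the PRT107A and HSPD21
assays plus a third single-channel assay — five channels, three assays.

**Calibration.** For each channel, a reference panel of samples with known
integer copy number is fitted by ordinary least squares with the ratio as
the response, $r = a + b \cdot CN + \varepsilon$ (this orientation — ratio
on copy number — is deliberate; prediction inverts it). The channel's
dispersion `residual_sd` is the standard deviation, in copy-number units,
of the back-calibrated panel estimates $(r - a)/b$ around their known
integers; a channel whose residual degrees of freedom fall below
`min_resid_df = 3` borrows the dispersion pooled across channels. A fitted
slope that is not strictly positive, or a panel with fewer than two
distinct copy numbers in a channel, fails that channel; calling proceeds on
the survivors and aborts only if every channel fails.

**Pooling and calling.** Dye channels are averaged within each assay (SD of
the mean of independent estimates, $\sqrt{\sum s_j^2}/n$), because the
natural unit of replication is the assay: the dyes of one assay share a PCR.
A configuration switch (`pool = "channel"`) pools raw channels instead,
since the historical practice is ambiguous on this point. Given assay
estimates $x_i \pm s_i$, each integer $k$ in the support 1–12 is scored by
the independent-Gaussian log-likelihood
$\log L(k) = \sum_i [-\log(s_i\sqrt{2\pi}) - (x_i-k)^2/(2 s_i^2)]$, and the
call is the arg-max with ties resolved to the smaller integer
(deterministic, hence reproducible). The Gaussian form is an assumption:
only calibration residuals are available as dispersion information, and
independent Gaussian channel error is the standard operating model for PRT
data. The confidence is the normalized likelihood weight
$L(k^\*)/\sum_k L(k)$, computed after subtracting the maximum
log-likelihood so the exponentials cannot underflow. The continuous
inverse-variance-weighted mean $\sum x_i/s_i^2 \big/ \sum 1/s_i^2$ is kept
alongside the integer call and is the copy-number axis used downstream,
matching how such data are conventionally plotted.

**Numerical guards.** SDs are floored at $10^{-3}$ copies (a noise-free
panel would otherwise produce degenerate likelihoods); estimates outside
$[\mathrm{min}-1, \mathrm{max}+1]$ of the support are flagged
`OUT_OF_SUPPORT` but not clamped — clamping would silently bias the
weighted mean; samples with fewer than two usable assay estimates get no
call (`TOO_FEW_CHANNELS`), which is the mechanism behind realistic typing
failure; confidence below 0.60 flags `LOW_CONFIDENCE` without suppressing
the call.

## Assay processing

**Censoring.** ELISA readings below the lower limit of detection
(16 pg/ml) — including outright undetectable readings — are replaced by
$\mathrm{LOD}/\sqrt{2} \approx 11.31$ pg/ml, the conventional substitution
for left-censored biomarker data. Censoring happens *before* protein
normalization, in a fixed order, and the censored flag propagates to all
derived variables. The operation is idempotent and every censored sample
carries exactly the same substituted value.

**Normalization.** Concentrations are divided by the total-protein
concentration of the same sample: pg/ml ÷ µg/ml → pg/µg for HBD2, and
likewise %kill ÷ µg/ml for bactericidal activity (reported as %kill/µg).
Normalizing by the concentration rather than by the protein mass in the
assay aliquot keeps the two normalizations on the same footing and keeps
percent-kill values within the dynamic range a cfu assay can resolve.
Samples with non-positive protein have their normalized values withheld
(`NA`), never imputed.

**Percent kill.** With the buffer control defining 100% survival,
$\%kill = 100\,(1 - cfu_{test}/cfu_{control})$, from triplicate cfu
readings aggregated by arithmetic mean (fewer than two usable replicates:
no estimate, `REPLICATES_INSUFFICIENT`; replicate CV above 0.30:
`HIGH_CV`). Negative kill — net growth over the control — is kept by
default (`allow_negative`): downstream statistics are rank-based, and
clipping only the low tail would discard ordering information. A
`clip_to_zero` policy is available and flags `GROWTH_OBSERVED`.

## Association analysis

Spearman's rank correlation is the sole inferential statistic of the main
analysis: it is invariant to the log scales on which these skewed
biomarkers live, and robust to the heavy ties of an integer-valued
copy-number variable (mid-ranks are used). Two-sided p-values come from
full permutation enumeration when $n \le 9$ and neither variable has ties,
and otherwise from the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of freedom; the method
used is recorded per result, since the original choice of software leaves
it unspecified. No multiple-testing adjustment is applied by default (the
analysis reports unadjusted pairwise p-values); users can adjust downstream.

Exclusions are rule-based and audited: subjects who started progesterone
before sampling are excluded from every analysis set (their biomarkers may
reflect treatment); subjects with post-sampling cerclage or progesterone,
or pregnancies ending in miscarriage or termination, are excluded only from
the outcome-stratified analyses, where delivery outcome must be
interpretable. The audit trail lists every excluded subject and its
triggering rule, and the arithmetic identity
|all-comers| + |pre-sampling exclusions| = |input| is asserted in tests.

Group comparison uses the Mann–Whitney U test, two-sided. For small groups
the p-value is computed by exact enumeration of all
$\binom{n_1+n_2}{n_1}$ assignments of the pooled values, comparing
$|U - n_1 n_2/2|$ — this handles ties exactly and gives $p = 1$ for
identical groups. Enumeration is used when $\min(n_1,n_2) \le 8$ *and* the
assignment count is below 250,000; the spec-level rule based only on the
smaller group would demand $\binom{200}{8} \approx 5\times10^{13}$
assignments for unbalanced cohorts, so the cap is a practical guard, and
the tie-corrected normal approximation (recorded in `method_note`) is used
beyond it.

## The synthetic-cohort generator

The generator emulates the statistical structure of a 203-subject
antenatal cohort so that every stage has a ground truth to be tested
against. Per subject it draws:

* copy number from 1–8 with mode 4 (probabilities
  0.02/0.08/0.22/0.33/0.20/0.10/0.04/0.01 — only the range and mode are
  anchored; the shape is a calibration choice);
* gestational age at sampling uniform on 61–192 days. A uniform law cannot
  simultaneously honour a median of ~107 days (15 weeks), which real
  recruitment skews toward; the generator keeps the uniform draw for
  simplicity and uses 107 days only as the centering constant of the HBD2
  model. This is one explicit way the generator is *less* realistic than
  clinic data;
* total protein log-normal (median 100 µg/ml, log-SD 0.5);
* HBD2 per µg protein from the log-linear model
  $\log h = \mu_0 + \beta_{cn}(CN-4) + \beta_{ga}(ga-107)/7 + \varepsilon$,
  $\varepsilon \sim N(0, \sigma_h^2)$, with the raw ELISA value
  $h \times protein$ emitted as the undetectable token when below the
  16 pg/ml LOD (censoring itself is the pipeline's job);
* kill per µg protein from
  $\log k = \alpha + \gamma \log h + \delta(CN-4) + \eta$,
  $\eta \sim N(0,\sigma_k^2)$ — the direct copy-number effect $\delta$ is
  kept small but positive so that the mediated-plus-direct structure can
  reach a copy-number–kill correlation around 0.17 where mediation through
  HBD2 alone would give only ≈ 0.10;
* PRT ratios per channel, $0.5\,CN\,(1+\epsilon)$ with multiplicative
  noise of CV 5%, a six-sample reference panel spanning copies 2–7, and a
  4.4% typing-failure mechanism that degrades all but one assay's
  channels;
* triplicate cfu readings (control 10⁵ cfu/ml, replicate CV 2%), delivery
  outcomes (preterm 14/167 among continuing pregnancies, miscarriage and
  termination 1/203 each) and exclusion flags (cerclage 20/203,
  post-sampling progesterone 2/203, pre-sampling progesterone 6/209),
  generated independently of the biology because the emulated study found
  no term/preterm biomarker differences.

Log-linear Gaussian forms are a modelling choice: the simplest
positive-valued model with tunable Spearman structure. The coefficient
defaults ($\beta_{cn}=0.27$, $\beta_{ga}=-0.081$, $\sigma_h=1.55$,
$\mu_0=0.40$, $\gamma=0.285$, $\delta=0.05$, $\sigma_k=0.62$,
$\alpha=-3.07$) were derived analytically from the target rank
correlations (+0.21 copy-number–HBD2, −0.25 gestational-age–HBD2, +0.49
HBD2–kill, +0.17 copy-number–kill), the ~12% censored fraction, and the
median anchors (1.2 pg/µg, 0.049 %kill/µg), then verified once by
simulation through the full pipeline before being frozen.
`calibration_report()` recomputes the emergent statistics over replicate
cohorts so users can audit the defaults at any time:

```{r calibration, eval = FALSE}
calibration_report(cohort_config(), n_replicates = 200, seed = 1)
```

Every random component (copy numbers, gestational ages, protein, HBD2,
kill, panel, ratios, typing failure, outcomes, flags, cfu noise) draws from
its own seed-derived substream, so the same master seed is reproducible
byte for byte and changing one component's rate leaves all other
components' draws untouched.

**What passing tests do and do not show.** The generator produces clean
log-linear dose–response, independent Gaussian channel noise, and
missingness that is completely at random. Real cervicovaginal data bring
batch effects, inflammation-driven HBD2 spikes, non-random assay failure,
a skewed gestational-age distribution, and a copy-number prior that need
not match the calibration shape. Tests passing on synthetic cohorts
therefore demonstrate that the *pipeline computes its statistics
correctly and recovers structure that is present*, not that the biological
effect sizes generalize.

## Validation problem sizes

The test suite validates the maximum-likelihood caller against a
brute-force enumeration oracle on 1,000 randomized inputs, the rank
statistics against rank-then-Pearson and full-permutation oracles on 500
random tied vectors, parameter recovery on three 200-subject cohorts at 5%
channel CV (≥95% correct integer calls for true copy number ≤ 6), and
generator self-consistency over 200 replicate cohorts (mean recovered
correlations within ±0.05 of their configured targets). These sizes give
stable checks at interactive runtimes; users exploring power questions can
raise `n_replicates` and `n_subjects` freely.

## Known limitations

* The likelihood pools assay estimates with equal prior weight; if one PRT
  assay is systematically less reliable, only its calibration residual SD
  down-weights it.
* Exact Spearman p-values are enumerated only for tie-free vectors with
  $n \le 9$; tied small samples fall back to the t approximation, which is
  anti-conservative at very small $n$.
* The ELISA and protein standard curves, OD600-to-cfu conversion, and raw
  electropherogram processing are upstream of this package: it begins at
  peak-area and concentration tables.
* `percent_kill` is undefined for a failed buffer control and may exceed
  −∞..100 only on the low side; values below −100% are biologically
  implausible and worth upstream QC, but are not rejected.
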