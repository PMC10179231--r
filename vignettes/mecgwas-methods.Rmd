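---
title: "Modeling MEC phenotypes and the staged GWAS: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling MEC phenotypes and the staged GWAS: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mecgwas)
```

## The phenotype: minimum effective concentration from dosing behaviour

Patient-controlled analgesia turns dosing behaviour into a concentration
assay. A patient presses the demand button when pain returns, i.e. when the
opioid concentration at its site of action has fallen to that patient's
minimum effective concentration (MEC). Given the timed record of fentanyl
boluses, a pharmacokinetic model reconstructs the concentration curve, and
the value immediately **before** each demand is an MEC reading. Readings are
averaged over 0–6 h, 0–12 h and 0–24 h postoperative windows, per site
(plasma and effect compartment), and analysed as `ln(1 + MEC [ng/mL])`,
which symmetrizes the right-skewed concentration scale while mapping zero to
zero.

### The kinetic model and why it is solved in closed form

Disposition is a linear mammillary three-compartment model (central volume
`v1`, micro constants `k10`, `k12`, `k21`, `k13`, `k31`) plus a negligible-
volume effect compartment equilibrating at rate `ke0`. `hybrid_constants()`
diagonalizes the 3×3 rate matrix: a unit bolus gives
`Cp(t) = A e^{-λ1 t} + B e^{-λ2 t} + C e^{-λ3 t}` with `A + B + C = 1/v1`,
`Σλ = k10 + k12 + k21 + k13 + k31` and `λ1 λ2 λ3 = k10 k21 k31`, and the
effect site adds a fourth exponential channel at `ke0`. Arbitrary dosing
histories are evaluated by superposition.

The closed form matters because "immediately before a demand" is a left
limit at an event instant: a gridded ODE solution blurs exactly the value
the phenotype is defined by. The analytic evaluator returns both one-sided
limits at every event time; an ODE integration (deSolve, `rtol = 1e-11`) is
retained purely as a test oracle, and the suite requires agreement below
1e-6 relative error on random parameter/dosing draws.

Numerical choices: a structurally absent peripheral compartment
(`k12 = k13 = 0`) is floored at 1e-12 so the eigendecomposition stays
generic — mammillary systems with strictly positive constants have distinct
real eigenvalues, so exact exponent collisions can only enter through these
floored limits or through `ke0`; coincidences at relative spacing below 1e-9
are resolved by a 1e-9 relative perturbation with a warning. Units are fixed
package-wide (minutes, μg, L, ng/mL; 1 μg/L ≡ 1 ng/mL).

The default parameter block `shafer_fentanyl`
(`inst/extdata/pk_params.yaml`) is a representative adult fentanyl
parameterization of this model family. It is configuration, not ground
truth: the engine accepts any valid `pk_params()`, an optional linear
body-weight scaling of `v1` is available and off by default, and analyses
should report the block they used.

### Windowing and missingness

Windows are half-open `(0, h]` hours; a demand at exactly the bound belongs
to the window. A window containing no demands yields a missing mean — never
zero — and subjects missing the chosen phenotype are dropped from the
corresponding regressions (complete-case; no imputation rule is defined).
If the reservoir empties before a window closes, the demands observed up to
exhaustion still enter the average with no censoring adjustment; this is
why 0–6 h and 0–12 h endpoints are preferred to 0–24 h, where exhaustion is
common.

## The association engine

Per SNP, the phenotype is regressed by OLS on an intercept, the coded
genotype (additive = minor-allele count, dominant = carrier, recessive =
homozygote) and the clinical covariates; the reported β, SE and two-sided
t-test p are for the genotype term. Covariates default to those passing the
clinical screen (`covariate_screen()`: one joint OLS of the phenotype on
age, mean remifentanil infusion rate, end-of-surgery fentanyl dose and 2-h
pain score, flagging p < 0.05). Missing genotypes are handled per-SNP
complete-case; monomorphic or collinear designs are flagged and skipped.
X-chromosome markers exclude all male subjects (females coded 0/1/2; no
hemizygous coding).

The staged design: stage 1 tests every SNP and keeps p < α (default 0.05);
each later stage k keeps a SNP only if its single-stage p **and** its pooled
combined p over stages 1..k are both below α. The combined analysis is a
single pooled OLS over the concatenated stage subjects with the same
covariates and no stage indicator — matching a design that reports one
combined β per SNP — with stage fixed effects available behind an argument.
Stage assignment defaults to a contiguous split in input order (117/117/117
at the default cohort size), with a seeded random split as an option; the
allocation actually used by any given study is rarely stated, and a
contiguous split keeps runs reproducible without extra state. No effect-
direction consistency across stages is required (none is defined for the
procedure being modeled).

### Pruning, FDR and significance

The candidates entering the final stage are pruned greedily: sorted by
final combined p ascending (ties by position then id), a SNP is kept iff
its EM-estimated r² with every kept SNP is below 0.8, and dropped SNPs
record which index SNP removed them. q-values are then computed for the
kept candidates from their final combined p-values.

A deliberate and consequential choice is the multiplicity those q-values
charge. BH over the pruned candidate list alone (a handful of SNPs) would
make any lone null survivor automatically "significant" (m = 1, q = p < α),
and simulation confirms a ~10–20% per-run false-positive rate under a pure
null. The procedure modeled here instead pays for the whole panel: the
published arithmetic it follows shows q/p ratios on the order of the full
marker count at rank 1, so `staged_gwas()` computes
`q = min_{j≥i} p_(j) · m / j` with m equal to the number of SNPs tested in
stage 1 (`fdr_qvalues(..., m =)`). Genome-wide significance requires
surviving every stage, surviving pruning, and q below the threshold
(default 0.05). A within-stratum variant is available via the `strata`
argument; the default is a single stratum.

`hwe_chi2()` is the 1-df Pearson goodness-of-fit test against expectations
from the sample allele frequency (monomorphic samples return χ² = 0 by
convention); `hwe_exact()` is the standard non-mid-p exact conditional test,
computed by parity-respecting recurrence and checked against full
enumeration. `ld_em()` estimates two-locus haplotype frequencies from
unphased diplotypes, splitting double heterozygotes by current phase odds;
its log-likelihood is non-decreasing by construction and tested as such.

## Power

`power_linear_f2()` evaluates P(F′ > F_crit) for a noncentral F with
`(df1, n − df1 − 1)` degrees of freedom and noncentrality `f²·n`;
`required_f2()` inverts it by bisection to power tolerance 1e-6. `df1`
defaults to 1 tested predictor with error df `n − 2`, the convention that
reproduces the standard worked examples at n = 117 (98.6% at f² = 0.15,
32.9% at f² = 0.02, f² = 0.0682 for 80% power); other designs can set
`df1`. Power for the full three-stage filter has no closed form and is out
of scope — the Monte-Carlo cross-check in the test suite instead verifies
the single-stage power empirically against `snp_regression()`.

## The synthetic cohort: what it emulates, and what it does not

`gen_cohort()` generates the complete input set the pipeline assumes:

* **Genotypes** — independent SNPs as two Bernoulli allele draws at a MAF
  uniform on [0.05, 0.5] (Hardy–Weinberg by construction). LD blocks share
  one MAF; haplotypes come from exchangeable latent Gaussians thresholded
  at the MAF quantile, with the latent correlation solved (tetrachoric) so
  the *allele-level* correlation equals the requested block ρ — naive
  thresholding at latent ρ would undershoot substantially (ρ = 0.95 yields
  allele r² ≈ 0.6, not ≈ 0.9).
* **Covariates** — age uniform 20–85 y; remifentanil rate normal around the
  0.25 μg/kg/min protocol rate (SD 0.05, truncated positive); end-of-surgery
  fentanyl 100 μg + 50 μg increments (Poisson, mean 1), echoing titration
  in 0.05 mg steps collapsed to one bolus at t = 0; integer 2-h pain score
  centred near 3.
* **Latent MEC** — `log MEC = intercept + Σ β_snp·count + Σ β_cov·x + ε`,
  `ε ~ N(0, 0.3)`. Covariate coefficients default to the reported clinical
  regression values (age 0.004, remifentanil 0.409, fentanyl dose 0.001,
  pain 0.019 — all positive). The intercept (−0.5) centres the latent MEC
  near 1 ng/mL: chosen once so that only a few percent of subjects draw an
  MEC unreachable by the initial bolus (mirroring a cohort where 350 of 351
  subjects were analysable) while roughly two-thirds still exhaust the
  1000 μg reservoir by 24 h but not by 12 h.
* **Dosing** — closed-loop: a demand fires at the first *down-crossing* of
  the effect-site curve through the subject's threshold (effect-site, not
  plasma, because opioids act at the effect site; a plasma-triggered mode
  exists), delayed if needed by the 5-min lockout since the last delivered
  dose, a ≤12-per-rolling-60-min cap (sliding window over delivered
  demands), and the 1000 μg cumulative cap. Trigger times come from a
  bracketed root search on the analytic curve (0.5-min scan, `uniroot`
  refinement to 1e-9 min); if a dose fails to restore the threshold the
  subject presses again at lockout expiry. Behavioural noise, off by
  default, multiplies the per-demand threshold by a lognormal factor —
  with it off, every unconstrained demand reads back the latent MEC
  exactly, which is what makes the round-trip test sharp (within 2%
  deviations arise only from constraint-forced demands).

All generators are pure functions of `(spec, seed)`.

What passing tests on this generator do **not** show: the demand model is a
deterministic threshold rule, not human behaviour (no dose-stacking
impatience, no sleep, no rescue analgesia); covariates are independent,
whereas real age/infusion-rate/pain profiles correlate; genotyping error,
relatedness and population structure are absent (the pipeline deliberately
has no kinship or PC correction); and the PK parameters are fixed rather
than individually variable beyond the optional weight hook. Effect recovery
is therefore assessed as ranking and monotonicity, not as unbiased β
estimation — indeed the fitted β on the `ln(1+MEC)` scale is attenuated by
roughly `M/(1+M)` relative to a generative effect on `ln(MEC)`.

## Problem sizes used in the checks

The packaged checks run at sizes chosen to exercise the full design while
remaining desk-scale: ODE agreement on 100 random draws; round trip on a
50-subject cohort; null calibration with 5,000 SNPs × 351 subjects × 20
seeds (expected three-stage survivor count ≈ 5000·0.05³ before combined-
test attrition, and no genome-wide significant SNP in ≥95% of runs);
planted-effect recovery (β = 0.3, MAF 0.3) over 20 seeds with a 200-SNP
panel. The micro-statistics (BH, pruning, EM, exact tests, Mann–Whitney)
are checked against brute-force enumeration on toy instances.

## Known limitations

* The combined statistic is a pooled OLS; an inverse-variance meta-analysis
  across stages would differ slightly and is not provided.
* The exact stratification of the stratified-FDR software being emulated is
  unpublished; charging the full tested panel in one stratum is the closest
  reconstructible choice and is mildly conservative.
* `hwe_exact` is the plain (non-mid-p) formulation.
* VCF support covers biallelic diploid GT records; half-calls become
  missing, multiallelic and non-SNP records are skipped with counts.
* The dosing simulator's 0.5-min scan could in principle step over a
  sub-half-minute dip of the effect-site curve between doses; with
  clinically plausible parameters the curve has at most one interior
  maximum between doses and the scan is exact in practice.
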