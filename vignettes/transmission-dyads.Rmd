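---
title: "Dyad-based transmission-pattern analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dyad-based transmission-pattern analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadscan)
```

## The problem

Alzheimer's disease (AD) heritability is high, yet the catalogued autosomal
variants explain only part of it. Two under-explored transmission channels
are the sex chromosomes and autosomal-recessive (autozygous) risk. Neither
requires genotype data to probe at the population level: both leave
footprints in *who* in a family is affected.

`dyadscan` implements that population-level probe for case--control cohorts
with systematic family-history questionnaires:

* **Parent→offspring dyads.** For each pairing of a parent category
  (father, mother, exactly-one-parent) with an offspring sex, exposure is
  "that parent had dementia". If risk rides on the Y chromosome,
  father→son dyads should show stronger case enrichment than father→daughter
  dyads; if X-linked risk is silenced in heterozygous females by
  X-inactivation, mother→son dyads should outrun mother→daughter dyads.
* **Remote consanguinity.** Parents born in the same town are, on average,
  more distantly related than parents from different towns. Same-birthplace
  parental pairs therefore proxy offspring autozygosity, which should raise
  disease risk if recessive alleles matter, and inflate homozygosity at any
  marker locus (APOE serves as the sentinel).
* **Endophenotypes.** Within female patients with CSF biomarkers, linear
  models relate parental history and the same-town proxy to onset age and
  CSF amyloid-beta 42, total tau and phosphorylated tau.

## The dyad statistics

For a dyad, let `a/n` be the exposure proportion in eligible cases and
`c/n'` in eligible controls. The package reports the exposure-prevalence
ratio ("relative risk" in the conventional table layout)

> RR = (a/n) / (c/n')

and the Woolf odds ratio `(a d)/(b c)` with log-scale SE
`sqrt(1/a + 1/b + 1/c + 1/d)`. Two dyads are contrasted through the relative
ratio `Phi = effect(dyad 1) / effect(dyad 2)` and the normal deviate

> z = ln(Phi) / sqrt(v1 + v2),

where each dyad's log-scale variance `v_i` follows the chosen rule.

**Variance rules.** The `paper_literal` rule takes
`v = 1/(n p (1-p)) + 1/(n' p' (1-p'))` with `(n, p)` the eligible case total
and case exposure proportion and `(n', p')` the control counterparts. This
expression is algebraically Woolf's variance of that dyad's log *odds*
ratio, because `n p (1-p) = a b / n`; the identity is enforced by a
property test to 1e-12. The `pooled_woolf` rule instead uses the log-scale
variance of the effect measure actually being compared (log-RR variance for
risk ratios). Monte-Carlo calibration under a null simulator shows the test
holds its nominal 5% size with either rule at cohort sizes in the hundreds
per dyad.

**Why Phi defaults to the risk-ratio scale.** In the published table this
package mirrors, the printed Phi cells equal ratios of the printed
relative-risk column (e.g., 2.58/3.38 = 0.76), not ratios of odds ratios,
although the accompanying text says "odds ratios". Both modes are available
and every report labels which was used.

**Eligibility.** Subjects with *both* parents affected are excluded from all
univariate dyads; single-parent dyads additionally require that parent's
history to be known, and the "any parent" dyad requires both histories known
(exposure = exactly one affected parent). This reproduces the published
denominator pattern in which the any-parent denominators are slightly
smaller than the single-parent ones. In the regression stages, both-affected
subjects are retained with both indicator covariates set to 1.

**p-values.** Two-sided, from the standard normal, uncorrected for multiple
comparisons (mirroring the exploratory design; Bonferroni/BH adjustment of a
comparison list is left to the caller). We could not reproduce the p-values
printed in the source table under any interpretation of its z equation
(paper-literal, pooled Woolf on either scale, exposed-only sample sizes);
the printed equation is unambiguous for one dyad but ambiguous for a
two-dyad contrast. The package therefore reports its own well-defined z and
p, and their correctness is established by the Woolf identity and by null
calibration rather than by matching printed p-values.

**Degenerate tables.** Zero cells raise errors rather than silently
producing infinities; the Haldane--Anscombe +0.5 correction is available
behind an explicit `correct = TRUE`. Inside a full comparison matrix a
degenerate cell is flagged and the rest of the matrix is still returned.

## The regression stages

Four OLS models run in the subset of female cases with complete CSF data,
one per outcome (onset age, amyloid-beta 42, total tau, phosphorylated tau),
each with ten predictors: paternal history, maternal history, same-town
flag, age at lumbar puncture, education, APOE e4 carriership, the other
three outcome variables (mutual adjustment), and year of birth. At n = 160
this yields residual df 149, matching the published model dimensionality.
APOE enters as a binary e4-carrier indicator by default (genotype-level
coding behind a flag), matching the published logistic table's coding.

The disease-risk logistic model (case status on sex, age, education, APOE e4
and the same-town flag) is fit by our own IRLS with a score-norm tolerance
of 1e-8, reporting Wald CIs, -2 log-likelihood and Nagelkerke R². The
published table's "age of onset" cannot exist for controls; we use onset age
for cases and assessment age for controls and document this as an
assumption. Perfect separation and rank deficiency are hard errors: no Wald
table is reported in either case.

The published regression *coefficients* are not reproduction targets: the
underlying cohort is available only on request. The substituted acceptance
evidence is parameter recovery on synthetic data (exact at zero noise to
1e-8; 95% CI coverage in [0.92, 0.98] over 500 replicates at n = 160;
logistic recovery of a true same-town OR of 1.3 at n = 2600).

## The generative model

The simulator's central modelling choice: parents express dementia through
the *same* logistic liability as offspring, evaluated at their death age.
That is exactly what makes "parental history" an informative proxy for
parental genotype, which is the premise of the whole dyad design.

* **Loci.** Autosomal (dominant/recessive/additive), X or Y, each with risk
  allele frequency `q` and log-odds increment `gamma`. Heterozygous X
  females express `lambda_x * gamma` (X-inactivation attenuation);
  hemizygous males and homozygous females express `gamma`.
* **Transmission.** One random allele per autosomal parent; sons draw one
  maternal X and the paternal Y; daughters draw one maternal X plus the
  paternal X.
* **Consanguinity.** Rather than tracking pedigrees, same-town parental
  pairs give the offspring identical-by-descent alleles with probability
  `F = kinship_phi`, so homozygote frequency is `q² + F q(1-q)` --- the
  classical inbreeding closed form, verified at 1e5 draws. The same
  mechanism inflates APOE homozygosity, reproducing the sentinel-locus
  signature of remote consanguinity. Autozygous-risk carriers get earlier
  onset (`delta_autozygous` years) and the configured CSF shifts.
* **Ascertainment.** Emitted controls are unaffected and strictly older
  than 75; cases are affected, with onset drawn around 72 ± 9 years.
  Exactly the requested group sizes are emitted; generation is a
  batch-rejection sampler, deterministic given the seed (single stream per
  cohort; replicate harnesses derive child seeds by fixed offsets).

### What the presets state, and why

* `null` --- all genetic effects zero; the type-I-error world.
* `x_linked` --- a single common X variant (q = 0.2) with `gamma = 5.5` and
  `lambda_x = 0` (fully silenced in heterozygous females). This is
  deliberately a *strong-mechanism* world: the preset exists to demonstrate
  the directional signature (mother→son RR exceeding mother→daughter RR)
  decisively at n ≈ 3000, not to estimate a plausible human effect size. The
  source study offers no quantitative X effect size to emulate.
* `y_linked` --- a paternal Y variant; maternal dyads behave like the null,
  which is the preset's testable signature.
* `recessive_consanguinity` --- an autosomal recessive locus with same-town
  kinship 1/16, earlier onset for autozygous-risk carriers.
* `paperlike` --- calibrated (a prescribed calibration, fixed before any
  acceptance run) so that parental-history exposure frequencies land within
  ±3 percentage points of the published margins (controls 4.7% paternal /
  8.9% maternal; cases 13.5% / 26.3%) with ~59% same-town pairs at
  n = 3090. Reaching the published threefold case enrichment requires rare,
  high-penetrance alleles (two dominant loci at q = 0.05, gamma = 3.4, an X
  locus at q = 0.15, gamma = 3.7, lambda 0.7, a recessive locus) on a low
  baseline (beta0 = -5.2 at age 75), with fathers dying earlier (71 ± 8 y)
  than mothers (80 ± 8 y) to reproduce the paternal/maternal asymmetry.
  Common-variant worlds (gamma ≈ 1) cannot produce the published contrast:
  parent--offspring allele sharing is one allele per locus, capping the
  induced family-history enrichment.

### What a green test does not establish

The simulator emulates the *statistical structure* the analysis assumes ---
sex-linked transmission, liability-mediated parental phenotypes,
inbreeding-inflated homozygosity, case-control ascertainment with an age
floor. It deliberately omits: multi-generation pedigrees, age-dependent
incidence beyond a linear log-odds term, assortative mating, questionnaire
recall bias, non-paternity, and any linkage between APOE and the risk loci.
A passing acceptance suite therefore certifies the pipeline's arithmetic and
its frequentist operating characteristics under the stated world; it cannot
certify the epidemiological hypotheses themselves.

## Numerical and design choices

* Unknowns are an explicit `NA` token end to end; "no" and "missing" are
  never conflated (the source distinguishes negative history from history
  that could not be recollected).
* Controls aged exactly 75 are excluded ("more than 75 years"); controls
  with missing age are excluded and counted in the filter log (the source
  does not state their handling).
* Early/late onset is derived from onset age (≤ 65 vs ≥ 66), never read
  from a file, keeping the invariant testable.
* Birthplace matching is exact string equality after case folding,
  whitespace squeezing and diacritic stripping; neighboring-but-distinct
  places count as different, and no gazetteer or distance logic is used.
* Report tables round ratios to 2--3 decimals and proportions to 3;
  internal arithmetic is full precision, and JSON outputs carry full
  precision beside the rounded TSVs.
* The mother→son cell of the published comparison table prints a relative
  risk of 3.72 while its own printed counts give ≈ 3.61; all its Phi cells
  are consistent with 3.72. The package reproduces from counts, so
  mother→son-dependent cells are excluded from the reproduction criteria.
  One further cell (mother→daughter vs any-parent→daughter) computes 1.0546
  from counts but prints 1.054, an apparent truncation; it is asserted to
  |diff| ≤ 0.001 rather than to printed rounding.
* The published male-case margins (52/325 paternal, 92/332 maternal,
  128/322 any-parent, 342 male cases) are mutually inconsistent under the
  stated eligibility rules --- no non-negative joint history distribution
  satisfies all three at once --- so reproduction runs from per-dyad printed
  counts rather than from a single reconstructed cohort.

## Limitations

The dyad z test is asymptotic; with exposed cell counts below ~10 its size
is not guaranteed (the calibration harness makes this measurable). The
same-town proxy is coarse --- city-born parents dilute it, as the source
acknowledges. The endophenotype models assume linear, homoscedastic effects
and mutual adjustment among correlated CSF markers, inherited from the
design being mirrored, not endorsed as the best possible model.
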