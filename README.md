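# dyadscan

Family-history transmission-pattern analysis for case–control dementia
cohorts.

## What problem this solves, and for whom

A case–control cohort with a systematic family-history questionnaire can
probe inheritance channels that genotype-array studies usually skip: the
sex chromosomes and autosomal-recessive (autozygous) risk. The signal lives
in **parent→offspring dyads** — if X-linked risk is silenced in
heterozygous females by X-inactivation, a mother's dementia should predict
disease more strongly in her sons than in her daughters; if risk rides on
the Y, father→son dyads should stand out. **Remote consanguinity** leaves a
parallel footprint: parents born in the same town are on average more
related, their children more autozygous, so recessive risk shows up as a
same-birthplace effect (and as excess homozygosity at a sentinel locus such
as APOE).

`dyadscan` is for epidemiologists and neurogenetics groups who have such a
cohort table (or want to plan one): it builds the dyad exposure tables,
estimates the ratios, tests dyad contrasts, fits the endophenotype and
disease-risk regressions, and ships a generative simulator that makes every
stage verifiable without access to any real cohort.

## The statistics

For one dyad, with `a/n` the exposure proportion in eligible cases and
`c/n'` in eligible controls:

* relative risk (exposure-prevalence ratio) `RR = (a/n)/(c/n')`, Wald CI on
  the log scale;
* Woolf odds ratio `OR = ad/bc`, log-SE `sqrt(1/a + 1/b + 1/c + 1/d)`;
* dyad contrast `Phi = effect(dyad1)/effect(dyad2)`, tested with
  `z = ln(Phi)/sqrt(v1 + v2)` where `v_i = 1/(n p(1-p)) + 1/(n'p'(1-p'))`
  is each dyad's log-odds-ratio (Woolf) variance.

Subjects with both parents affected are excluded from univariate dyads (but
retained, with both indicators set, in regressions); the "any parent" dyad
requires both histories known. Missing is always an explicit `NA` token,
never conflated with "no".

The regression stages are the endophenotype OLS models (onset age and CSF
Aβ42 / total tau / phosphorylated tau in female cases with CSF, ten
predictors each) and an IRLS logistic model of case status on sex, age,
education, APOE ε4 and the same-birthplace flag, reported as ORs with Wald
CIs, −2LL and Nagelkerke R².

The simulator draws parental genotypes in Hardy–Weinberg proportions,
transmits alleles Mendelianly (X/Y aware), gives parents their phenotype
through the *same* logistic liability as offspring (that is what makes
history informative), and models consanguinity by identical-by-descent
offspring alleles with probability F, so homozygosity is `q² + Fq(1−q)`.
Presets: `null`, `x_linked`, `y_linked`, `recessive_consanguinity`,
`paperlike`. See `vignettes/transmission-dyads.Rmd` for every parameter,
default and rationale.

## Worked example

The package ships the dyad exposure counts of a large published Portuguese
AD case–control study (907 cases, 2183 controls over 75) as a plain
data.frame, so the whole ratio pipeline can be run without subject-level
data:

```r
library(dyadscan)
tabs <- as_dyad_tables(ad_dyad_counts())
dyad_matrix(tabs)
```

```
<dyad_matrix> 7 dyads, 21 comparisons (risk_ratio, paper_literal)
            dyad   a n_case p_case   c n_ctrl p_ctrl estimate
      father_son  52    325  0.160  36    761  0.047    3.382
 father_daughter  64    537  0.119  64   1383  0.046    2.575
    any_daughter 184    533  0.345 189   1382  0.137    2.524
 mother_daughter 140    551  0.254 134   1404  0.095    2.662
      mother_son  92    332  0.277  59    768  0.077    3.607
         any_son 128    322  0.398  90    757  0.119    3.344
         any_any 312    855  0.365 279   2139  0.130    2.798
             row             col   phi      z     p note
 father_daughter      father_son 0.761 -0.928 0.353
    any_daughter      father_son 0.746 -1.135 0.256
 ...
      mother_son mother_daughter 1.355  1.342 0.180
 ...
```

Reading it: every dyad shows strong case enrichment for parental dementia
history (RR ≈ 2.5–3.6). The father→son RR (3.38) does not significantly
exceed the other dyads (no Y-chromosome signal: Phi(father→daughter vs
father→son) = 0.761, p = 0.35), while the mother→son RR (3.61 from counts)
exceeds mother→daughter (2.66), the X-inactivation-consistent direction
(Phi = 1.355). The estimates and Phi cells match the published table at its
printed rounding wherever the printed numbers are internally consistent;
the published p-values use an ambiguous two-dyad variance and are not
reproduction targets (the test's size is instead verified by Monte-Carlo
calibration — see the vignette).

End-to-end on synthetic data:

```r
co  <- generate_cohort(scenario_preset("paperlike", seed = 42))
co  <- apply_control_eligibility(co)
dyad_matrix(co)                 # builds the 7 tables from subject rows
fit_ad_logistic(co)             # OR table, -2LL, Nagelkerke R2
fit_endophenotype_models(co)    # 4 OLS fits in female cases with CSF
calibrate("null", reps = 200)   # type-I error of the dyad z test
```

Command line (same operations): `exec/dyadscan
simulate|dyads|models|describe|run|calibrate`, e.g.

```sh
exec/dyadscan simulate --scenario paperlike --seed 42 --out synth.tsv
exec/dyadscan dyads --input synth.tsv --mode rr --variance paper --out matrix.tsv
```

Input format: UTF-8 CSV/TSV, header row, `NA` for missing; the
machine-readable schema is `inst/extdata/cohort_schema.json`.

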