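# grmcat

Graded response model calibration and computer-adaptive-testing (CAT)
simulation for short ordinal clinical questionnaires.

## The problem

Mental-health questionnaires are routinely administered online, where every
extra item costs completion rates. For instruments whose clinical use is a
*classification* — is this respondent above or below a risk threshold? —
most items add nothing once the classification is already certain. Item
response theory (IRT) makes this precise: each item is a noisy measurement
of a latent severity trait θ, and an adaptive algorithm can pick, person by
person, only the items that still carry information, stopping as soon as
the classification is settled.

`grmcat` implements the standard five-step psychometric pipeline for such
an instrument, end to end:

1. **Descriptives & reliability** — category counts, item-rest
   correlations, Cronbach α (`descriptives()`).
2. **IRT assumption screens** — principal-components and one-factor CFA
   unidimensionality checks, residual local-independence flags (|r| > .2),
   Mokken scalability (flag H_j < .3) (`assumption_report()`).
3. **Graded response model (GRM)** — Samejima's model for ordered
   categories. Item *i* has discrimination α_i and ordered thresholds
   β_{i1} < … < β_{im}; the boundary curves are
   P*_{ik}(θ) = 1 / (1 + exp(−α_i(θ − β_{ik}))), and category
   probabilities are differences of adjacent boundaries. Calibration is
   marginal maximum likelihood via EM with Gauss–Hermite quadrature
   (`fit_grm()`); trait scores by EAP or MLE (`estimate_theta()`).
4. **Differential item functioning (DIF)** — nested cumulative-logit
   models matched on θ̂ (M1: y ~ θ̂; M3: + group + θ̂×group), 2-df
   likelihood-ratio flags at α = .01, McFadden pseudo-R² effect bands at
   .13 / .26 (`dif_screen()`).
5. **Post-hoc CAT simulation** — replay recorded responses through
   maximum-Fisher-information item selection, stopping once the 99%
   confidence interval around θ̂ clears the classification cut-off
   (θ = −1 by default), with a minimum of 3 and a cap of 6 items
   (`simulate_cohort_cat()`, `compare_stopping_rules()`,
   `export_decision_tree()`).

The package ships a 19-item suicide-ideation bank (three response
categories 0/1/2 per item) as its default instrument
(`default_item_bank()`), and a GRM-consistent synthetic cohort generator
(`generate_cohort()`) whose default latent-trait mixture
0.2·N(−2.2, 0.4²) + 0.8·N(0.6, 1²) emulates a right-heavy clinical
severity distribution with a large floor group (~20% of total scores are
0). No patient data are included or required.

## Worked example

```r
library(grmcat)
bank <- default_item_bank()

# one synthetic clinical cohort, same size as the motivating study
coh <- generate_cohort(cohort_spec(n_persons = 505, seed = 2024))
d <- descriptives(coh$matrix)
a <- assumption_report(coh$matrix)
compare_stopping_rules(bank, coh$matrix)
run_cat_post_hoc(bank, coh$matrix$responses[5, ], cat_config())
```

which prints (numbers produced by exactly this code):

```
Cronbach alpha: 0.97; total score mean (SD): 13.6 (12.4)
PCA: first component 64% of variance, ratio 15.3
CFA: CFI 0.982, RMSEA 0.043, SRMR 0.021; Mokken H 0.70

  min_items max_items mean_items sd_items n_low n_elevated agreement
1        19        19     19.000    0.000   140        365     1.000
2         3        19      9.214    7.647   140        365     1.000
3         3         6      4.277    1.440   140        365     0.956

CAT: 3 items [4,7,15], theta 1.25 (se 0.34), stop: classified, elevated risk
```

Reading the stopping-rule table: administering everything (19/19) is the
reference; under the confidence-interval rule with the full bank available
(3–19) the classification never changes but low-severity respondents
exhaust many items; capping at 6 items (3–6) cuts the average
administration to ~4.3 items while agreeing with the full test for 95.6%
of this cohort. The last line shows one high-severity respondent
classified as elevated risk after only 3 items — the adaptive test starts
with item 4, the most informative item at the entry level θ = 0.

## Command line

An `Rscript` front-end with subcommands `simulate-data`, `describe`,
`assumptions`, `fit-grm`, `score`, `dif`, `cat-sim`, and `report` is
installed at `inst/cli/grmcat`:

```sh
Rscript inst/cli/grmcat simulate-data --spec spec.yaml --out cohort.csv
Rscript inst/cli/grmcat report --in cohort.csv --out report.md --seed 1
```

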