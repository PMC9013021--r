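---
title: "Pattern discovery for imbalanced clinical outcomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pattern discovery for imbalanced clinical outcomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskpattern)
```

## The model

A *risk pattern* is a set of m conditions, each a single variable–value
comparison (`<=` or `>` against a numeric cutoff, `=` against a category),
plus an integer matching threshold k. A record is predicted positive when it
satisfies at least k of the m conditions. This k-of-m rule sits between a
conjunction (k = m) and a disjunction (k = 1) and is what makes the model
both expressive enough for multifactorial risk and readable enough for a
clinician to edit condition by condition.

Three semantics are fixed throughout the package:

- **Boundaries.** `<=` is inclusive and `>` exclusive, exactly as the
  conditions read.
- **Missing values never match.** A record with a missing value for a
  condition's variable simply fails that condition; it is not an error and
  not imputed. This is the conservative choice for registry data, where
  missingness is endemic: an incomplete record can still fire the pattern
  through its observed variables, but absence of evidence never counts as
  evidence of risk.
- **Matching ratio.** Users see k as the percentage ⌊100·k/m⌋; a ratio r is
  parsed back as k = ⌈r·m⌉. The floor/ceiling pairing is deliberate: it is
  the unique convention under which display and parse are mutually inverse
  for every 1 ≤ k ≤ m ≤ 50 (the property suite checks this exhaustively).
  Plain rounding breaks round-tripping (k = 2, m = 7 displays as 29% but
  ⌈0.29·7⌉ = 3). The integer k stored in pattern files is always
  authoritative; the percentage is cosmetic.

As a continuous score (for ROC curves) a pattern emits its *matched
fraction*, match count / m. This is an (m+1)-level score; it is the natural
choice but it is a package decision — the published description of the
method reports pattern AUCs without naming a score. Thresholding the
matched fraction at k/m reproduces the binary prediction exactly.

## Binarization by information gain

Numeric variables enter conditions through a single cutoff x chosen to
maximize the information gain (base-2 Shannon entropy reduction) of the
induced `<= x` / `> x` partition of the training labels. Records with a
missing value are excluded from the scan rather than forming a third block,
consistent with the matching semantics above.

Candidate cutoffs are the midpoints between consecutive distinct sorted
values, not the observed values themselves. On integer-valued inputs this
yields the half-unit cutoffs characteristic of decision-tree output (58.5,
79.5, ...). Ties in gain are broken toward the smaller cutoff; a variable
with fewer than two distinct values, or whose best split has zero gain,
produces no candidate. The gain of the returned split never exceeds the
label entropy, with equality exactly at a class-separating split; both
properties are tested against a brute-force oracle that rescans every
midpoint with a contingency-table entropy formula.

## Greedy discovery (pre-mode)

Candidate conditions are generated once per training cohort: each numeric
variable contributes its best-gain cutoff, with the comparator pointing at
the side with the higher positive-class rate (so conditions read as risk
factors); each categorical or binary variable contributes one equality
condition per observed category; constant variables contribute nothing.

The search is plain greedy forward selection. Starting from the empty set,
every unused candidate is tentatively added, the threshold k is re-optimized
by exhaustive scan over 1..m′ for the enlarged set, and the addition with the
best training objective is kept. The search stops when the improvement falls
below `min_improvement` (default 1e-6, i.e. any strict improvement counts),
when candidates are exhausted, or at `max_conditions` (default 16, one per
input variable of the motivating case study). The first condition is always
accepted so that the result is a valid pattern even on signal-free data.

Everything is deterministic. Ties in the objective are broken by the
candidate's Yates-corrected chi-square association with the target, then by
variable name, then by candidate index. Threshold ties go to the larger
(stricter) k.

The default objective is the training **F-score**: with a rare outcome,
accuracy is vacuous and F balances precision against sensitivity; **G-mean**
(√(sensitivity·specificity)) is selectable. If no threshold achieves a
nonzero objective, the exported threshold optimizer returns k = m with a
warning rather than failing.

The heuristic itself is this package's reconstruction — the published tool
defers its search algorithm to earlier work and specifies only the
representation and the optimized threshold — so all stopping and tie rules
above are documented here as package decisions, and the recovery suite
(below) is what justifies them empirically.

## Association arcs

For display alongside a pattern, every unordered pair of pattern conditions
is tested for independence of their per-record *match indicators* (not the
raw variable values) over all supplied records, with the 2×2 chi-square test
under Yates continuity correction. Degenerate pairs (a condition matching
nothing or everything) report a statistic of 0 and p = 1. Testing indicators
rather than raw values is a package decision: the indicators are what the
pattern actually uses, and they are well defined for mixed types and missing
data. Under the null the corrected test is conservative; the acceptance
suite verifies a flag rate near, and not above, the nominal 5% across 1000
simulated independent pairs.

## Knowledge incorporation

- **In-mode** applies a clinician's edit list (add/remove variable, change
  value or comparator) verbatim and then re-optimizes *only the threshold k*
  on the training data. No condition the edit list did not touch is ever
  revised. "Re-discovery" after an edit is deliberately interpreted as
  threshold re-optimization because the published account of the in-mode
  session reports the edited pattern keeping the same variable–value pairs
  with only the matching ratio updating; a `rediscover = TRUE` switch runs
  the full greedy search with the edited conditions pinned, for users who
  want the stronger behavior. Adding a numeric variable without an explicit
  cutoff pulls the best-gain cutoff from the training data; an explicit
  value always wins. `set_min_matches` is rejected here — in this mode the
  threshold belongs to the data.
- **Post-mode** is a pure function of the pattern and the edit list: values,
  comparators, and optionally k are overridden with no cohort in scope and
  no re-optimization. A k falling outside [1, m] after the edits is an
  error, never clamped.

Both modes append exactly one entry to the pattern's history. The first
entry is always the discovery snapshot (it stores the discovered conditions
and threshold); later entries store the edits and the resulting k, so
`replay_history()` reconstructs the final pattern from the log — the
round-trip the mode-contract tests check.

## Evaluation

Point metrics follow the standard confusion-matrix formulas with explicit
degenerate-case conventions: precision is 0 when TP+FP = 0, F-score is 0
whenever TP = 0, and any metric with a zero denominator reports 0 so the
panel stays in [0, 1]. The ROC curve places one vertex per distinct score
(ties grouped) with the rule *score ≥ cutoff*, and the AUC is the
trapezoidal area, which under tie grouping equals the Mann–Whitney pairwise
concordance with ties counted ½ — the identity the oracle tests exploit.
External risk scores are evaluated either at a supplied cutoff or at the
Youden-optimal vertex (max sensitivity + specificity − 1, ties toward higher
specificity), so that scores developed on other populations are not
understated by their published thresholds.

`compare_cohorts()` reproduces the usual baseline table of a
chronological-split study: mean (SD) with a two-group one-way ANOVA
(equal-variance F test) for numeric variables; n (%) with the chi-square
test of independence for categorical variables and the outcome, applying
Yates continuity correction on 2×2 tables. The correction is not optional:
recomputing the published cohort-comparison p-values for outcome prevalence
(0.007), anemia (0.016) and urgent PCI (0.019) from their printed counts
matches the corrected statistic at 3 decimals, while the uncorrected test
gives 0.006 for the first — this recomputation fixed the choice.

Outcome labeling from creatinine pairs uses the AKIN-style criterion:
positive when peak − baseline ≥ 0.3 mg/dL or peak ≥ 1.5·baseline, with
micromolar inputs converted at 88.4 µmol/L per mg/dL (the standard factor).
The chronological split takes the first ⌊fraction·n⌋ records; the published
split was date-based and is one record off an exact 70%, so the fractional
rule is the reproducible generalization.

## The synthetic generator

`generate_cohort()` draws each variable independently from its configured
marginal (normal for numeric, Bernoulli for binary), with separate test
period parameters for covariate drift, and then draws the outcome per
record with probability

> baseline_risk + risk_per_match · match_count(planted pattern)

clamped to [0, 1] (a warning fires if clamping touches more than 5% of
records). The additive risk-per-matched-condition form is chosen over a
logistic link because it makes the planted pattern exactly the structure a
k-of-m matcher detects and keeps prevalence arithmetic transparent:
expected prevalence = baseline + risk_per_match · E[match count], which is
how the default configuration was calibrated.

`aki_synth_config()` mirrors the motivating 16-variable catheterization
cohort: the published training/test means, SDs and category percentages for
all 16 variables (for the one variable whose printed count and percentage
disagree, the percentages are used), sizes 1791/769, a planted 4-condition
pattern (contrast volume > 200 ml, LVEF ≤ 45%, baseline creatinine >
140 µmol/L, anemia), risk_per_match = 0.2, and baseline risks of 0.026
(train) and 0.007 (test). With the planted conditions' marginal match
probabilities this puts expected prevalence at ≈8.3% training and ≈5.2%
test — the published concept drift. What the generator deliberately does
*not* emulate: correlated covariates (independence by default), informative
missingness, temporal dynamics within a period, and site effects. Passing
recovery tests on this generator therefore demonstrates that the search
finds planted k-of-m structure under realistic imbalance and drift, not
that it would recover the published pattern on the real (unavailable)
cohort.

## Problem sizes and numerical choices

The validation suite runs at deliberately modest sizes chosen to exercise
the asymptotics that matter without ceremony: oracle equivalences on random
instances up to n = 100 (splits), m = 12 (thresholds) and n = 50 (AUC
concordance); planted-pattern recovery over 20 seeds at n_train = 2000 with
three planted conditions of ~10% marginal match probability,
risk_per_match = 0.9 and baseline risk 0.01 (a strong, nearly
deterministic signal — the regime in which recovery is a meaningful
pass/fail property); a 1000-replicate null simulation for the arc flag
rate; and a 5000-record check of generator marginals against 3-standard-
error bands. Floating-point ties in the search are compared at 1e-12;
ratio arithmetic adds 1e-9 guards so that exact products like 0.4·5 do not
ceiling up through representation error.

## Known limitations

- One pattern, not an ensemble: the package models a single k-of-m rule,
  with no per-condition weights and no engineered interactions.
- The matched fraction gives at most m+1 score levels, so pattern ROC
  curves are coarse; AUC comparisons against continuous scores should keep
  that in mind.
- Numeric binarization is single-cutoff; U-shaped risk (common for, e.g.,
  blood pressure) needs the clinician to edit in the second boundary or
  pre-transform the variable.
- `compare_cohorts()` applies the ANOVA row to every numeric variable; it
  does not test normality, matching common baseline-table practice rather
  than strict inference.
- The generator's independence assumption means discovered arc structure on
  synthetic data is trivial unless correlations are configured explicitly.
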