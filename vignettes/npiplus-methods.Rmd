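---
title: "NPI+ methods: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NPI+ methods: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npiplus)
```

`npiplus` implements the Nottingham Prognostic Index Plus: a two-tier
stratification of early-stage breast cancer in which a ten-biomarker
immunohistochemistry panel first assigns a biological class, and a
class-specific clinicopathological index then assigns a prognostic
group. This vignette documents the model and its assumptions, the
tunable parameters and why their defaults are what they are, what the
synthetic-cohort generator does and does not emulate, and the design
choices made where the published description leaves the details open.

## Tier 1: biomarker scoring and biological class

### H-scores and cut-offs

Each marker is scored semi-quantitatively as
$H = \sum_{i=0}^{3} i \, p_i \in [0, 300]$, with $p_i$ the percentage of
cells staining at intensity $i$. `compute_hscore()` validates that the
percentages sum to 100 within an absolute tolerance of 0.5 — enough to
absorb percentages rounded to one decimal, strict enough to catch a
forgotten category.

Cut-offs dichotomising each marker follow a two-policy scheme:

* **cohort median** for ER, PgR, CK7/8, HER3, HER4 and MUC1, derived
  once on a *training* series (`compute_median_cutoffs()`) and then
  applied as fixed configuration to any validation series — the
  validation cohort's own medians are never substituted;
* **expert values** for CK5/6, EGFR and p53, whose medians are
  typically zero. The shipped defaults (CK5/6 ≥ 10, EGFR ≥ 10,
  p53 ≥ 20 H-score units) are plausible positivity thresholds chosen by
  this package, *not* published values, and are expected to be edited
  per laboratory (`default_expert_cutoffs()`, YAML round-trip via
  `write_cutoffs()`).

HER2 carries no H-score cut-off. Its status comes from the ASCO/CAP IHC
category (`resolve_her2()`): 3+ positive, 0/1+ negative, and 2+
equivocal — excluded under the default `exclude_equivocal` policy
(mirroring a validation series without reflex testing) or settled by
in-situ hybridisation under `ish_resolve`. Excluded patients are carried
through every report as an explicit category.

A value exactly at a cut-off counts as *high*: an inclusive positivity
threshold is deterministic and errs toward calling expression present.
A `boundary = "gt"` switch inverts this in `dichotomize()`.

### Fuzzy classification

Membership of an H-score $v$ against cut-off $c$ with width $w$ is a
trapezoidal shoulder,
$\mu_{high} = \mathrm{clamp}\!\big(\tfrac{v - (c - w)}{2w}, 0, 1\big)$,
$\mu_{low} = 1 - \mu_{high}$, so both sides meet at 0.5 at the cut-off.
Rules combine antecedents by min-conjunction, scaled by a rule weight;
a class's score is the max over its rules; the argmax class wins unless
its score falls below the activation threshold, in which case the tumour
is *Unclassified*. Exact ties break deterministically in the fixed class
order (Luminal A, N, B; Basal p53 altered, normal; HER2+/ER+, HER2+/ER−)
with a warning — reproducibility over elegance.

The original induced rule set is not published, so
`default_rulebase()` ships an editable approximation of the class
logic: luminal classes need CK7/8-high, ER-high, HER2-negative, split by
the PgR/HER3/HER4 pattern (A: PgR high; N: all three low; B: PgR low
with HER3 or HER4 high); basal classes need CK5/6-or-EGFR-high with
ER-low and HER2-negative, split by p53; HER2+ classes need resolved HER2
positivity, split by ER. Missing markers contribute zero activation:
missing evidence can push a tumour to Unclassified but never into a
named class.

**Defaults**: activation threshold 0.5, membership width 20 H-score
units — wide enough that scoring noise of a few H-score points moves
memberships smoothly, narrow relative to the ~100–200-unit separation
between expression modes.

**A width-invariance property worth knowing.** With one width shared by
all markers, memberships are $0.5 + \mathrm{margin}/2w$ (clamped), so
the *ordering* of rule activations and the position of the best score
relative to a 0.5 threshold depend only on the signs and ranking of the
margins, not on $w$. Class labels are therefore exactly width-invariant
at the default threshold; the width only changes labels when the
threshold exceeds 0.5 (the demanded margin then scales with $w$) or when
widths differ per marker. The test suite checks both regimes, and the
crisp limit $w \to 0$ agrees with boolean evaluation of the dichotomised
profile.

## Tier 2: prognostic index and groups

`default_formulas()` transcribes the seven per-class index formulae,
e.g. Luminal A $= 0.8\,\mathrm{Mitosis} + 0.5\,\mathrm{Size} +
1.8\,\mathrm{NodalRatio}$ and HER2+/ER− $= 0.9\,\mathrm{Stage} -
0.6\,\mathrm{NodalRatio}$ (the panel's one protective coefficient:
within HER2-positive/ER-negative disease a higher sampled-node ratio
lowers the index). Coding: grade components as their 1–3 scores, stage
1–3, nodal ratio the exact quotient, and **size as the binary category**
1 (< 1.5 cm) / 2 (≥ 1.5 cm). The original coding of size is not stated;
the binary form matches how the source cohorts tabulate size, and a
`size_coding = "continuous"` switch uses centimetres instead.

Group assignment cuts the index at fixed, ascending cutpoints; an index
exactly at a cutpoint goes to the *worse* group (conservative risk
assignment). Because the published cutpoints are not available, the
shipped defaults were calibrated once on the default synthetic cohort so
that within-class group proportions resemble the development series'
group sizes (three groups for Luminal A, two elsewhere); they are
synthetic placeholders and `derive_cutpoints()` exists to replace them
on real data.

### Deriving formulae and cutpoints

`derive_formula()` reproduces the derivation procedure: fit a Cox
proportional-hazards model of breast-cancer-specific survival (BCSS) on
the candidate clinicopathological variables within one class, retain
variables with Wald $p < 0.05$ (the published account names "most
significant variables" without a level; 0.05 per variable is the
conventional reading), refit on the retained set, and round to one
decimal — the precision at which the formulae are printed. Efron's
approximation handles tied event times (standard default, good
small-sample behaviour; the source is silent). Non-convergence or
separation aborts with the iteration count rather than returning a
doubtful fit.

`derive_cutpoints()` grid-searches candidate cutpoints (index quantiles,
10%–90% in 5% steps) for the set maximising the between-group log-rank
chi-square, subject to each group holding at least 10% of patients.
Degenerate splits — identical curves, singular log-rank variance — score
zero so that the deterministic tie rule (the median admissible
candidate) applies; homogeneous survival therefore yields the median
cutpoint rather than an arbitrary one.

## Survival and association machinery

BCSS encoding scores death from breast cancer as the event and censors
other-cause death and live patients at last follow-up — other-cause
death is *not* modelled as a competing risk, matching the source
convention. Kaplan–Meier estimation, the log-rank test and Cox fitting
stand on the `survival` package; curve evaluation is right-continuous
(an event time returns the post-drop value), and evaluation beyond last
follow-up returns the final estimate with an explicit extrapolation
warning. Log-rank p-values are chi-square upper tails with
groups − 1 degrees of freedom; the validation pipeline applies
Bonferroni control at a family-wise 0.01 across the tests it reports.

Contingency tables use plain Pearson chi-square — no Yates correction
even at 2×2, so that Cramer's V,
$V = \sqrt{\chi^2 / (n(\min(r,c)-1))}$, is consistent across table
sizes — and the classical (uncorrected) V, since that is the statistic
the validation literature reports. Expected counts below 5 warn but do
not switch to an exact test. All-zero rows/columns are dropped with a
warning before testing.

## The synthetic-cohort generator

`generator_config()` defines the default study conditions:

* **1073 patients** with class proportions fixed at the development
  series' distribution (26.8 / 19.1 / 17.3 / 10.5 / 8.9 / 5.8 / 7.9 /
  3.5% including Unclassified);
* **markers** as truncated normals on [0, 300], two parameters per
  (class, marker) so the table is easy to edit by hand. Class
  archetypes put each rule-relevant marker far on its intended side of
  the default cut-offs (e.g. luminal ER 210 ± 45 vs basal 15 ± 15
  against a cut-off of 100). The *Unclassified* archetype is
  deliberately rule-ambiguous — CK7/8 mostly below its cut-off with
  basal markers near zero — so that its truth label means what it says;
* **HER2**: IHC 3+ for the HER2 classes and 0/1+ otherwise, with a 7%
  equivocal (2+) fraction whose ISH result reflects the true class;
* **clinicopathology** from class-conditional categoricals calibrated
  so that grade, size and stage margins resemble a development-series
  cohort (basal and HER2 classes skew to higher grade and larger size);
  lymph-node stage derives from the positive-node count (0 → 1, 1–3 →
  2, ≥ 4 → 3), which keeps stage, nodal ratio and node counts mutually
  consistent;
* **survival**: exponential BCSS with rate
  $\lambda_c \exp(\mathrm{index})$ — each class's own formula is the
  linear predictor, so higher-index patients genuinely die sooner and
  derived coefficients have a known truth. Baselines are set so
  luminal classes have the best and HER2+ classes the worst ten-year
  BCSS. Other-cause death is an independent exponential (rate
  0.012/year) and administrative censoring reflects a 12-year accrual
  window closed out at 25 years; both are encoded as censoring, exactly
  as the pipeline assumes.

Hidden truth columns (`true_class`, `true_index`, `true_group`,
`true_lp`) accompany every cohort, and `truth_recovery_report()` scores
classification and grouping agreement against them, flagging
*borderline* profiles (any class-relevant marker within one membership
width of its cut-off) separately, since near-cut-off assignments are
genuinely ambiguous rather than wrong.

What the generator does **not** emulate: tissue-microarray core
sampling artefacts, inter-laboratory staining variation, inter-scorer
disagreement, treatment effects (therapy is descriptive only),
non-exponential baseline hazards, and correlation between markers
within a class beyond what the class structure induces. Passing
recovery tests therefore demonstrate internal consistency of the
pipeline under clean, well-separated conditions — not classifier
performance on real stained material.

## Test design and problem sizes

The suite freezes independent oracles next to every non-trivial
computation: sorted-midpoint medians, direct product-limit products,
observed-minus-expected log-rank tabulations, and expected-count
chi-square summations, each coded separately from the package path it
checks. Simulation sizes are chosen to keep the full suite fast while
leaving comfortable statistical margins: Kaplan–Meier/log-rank oracle
equivalence on 100 random datasets of 10–40 patients, Cox coverage over
200 replicates of n = 150, formula-derivation recovery over 50
replicates of n = 1000, and classifier truth-recovery on a 1000-patient
cohort. Statistical bounds on simulated rates are asserted with
binomial-noise margins rather than at knife-edge expected values.

## Known limitations

* The expert cut-offs, fuzzy rule base and group cutpoints are editable
  approximations standing in for unpublished originals; results on real
  cohorts depend on supplying the locally validated versions.
* The classifier applies rules; it does not induce them — rule learning
  from labelled data is out of scope.
* Cramer's V recomputed from published cross-tabulations can differ in
  the third decimal from printed values because per-variable totals
  vary with missing data.
* Competing-risks estimators are intentionally absent: other-cause
  death is censored by design, so cumulative-incidence questions need a
  different tool.
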