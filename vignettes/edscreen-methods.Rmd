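---
title: "Methods: rule-based screening of broad eating-disorder categories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based screening of broad eating-disorder categories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edscreen)
```

## The screening problem

Eating disorders (ED) are common, under-detected in primary care, and
benefit greatly from early treatment. The SCOFF questionnaire — five
yes/no items (Sick, Control, One stone, Fat, Food) with two or more
positive answers indicating a positive screen — is an established
first-line screen, but a positive SCOFF only says *an* ED is likely, not
which kind. The decision rule implemented here refines a positive screen
into one of four broad DSM-5-derived categories by adding a single,
universally available datum: the body-mass-index (BMI) class.

* **RD** — restrictive disorders: anorexia nervosa, restrictive food
  intake disorder, atypical anorexia nervosa;
* **BD** — bulimic disorders: bulimia nervosa, including low-frequency /
  limited-duration presentations;
* **HD** — hyperphagic disorders: binge eating disorder, including
  low-frequency presentations;
* **OED** — other eating disorders: purging disorder, night eating
  syndrome, any other ED.

The rule is pure table lookup. There are 26 SCOFF answer patterns with at
least two positives (out of `2^5 = 32`) and four WHO BMI classes, giving
104 combinations; each cell holds one broad category, assigned by expert
consensus in the original instrument. A respondent scoring 0 or 1 is
screen-negative and receives no category — screen-negativity is a status,
never a fifth category.

## BMI classes and boundary conventions

The WHO cutoffs are quoted in the literature as underweight < 18.5,
normal 18.5–24.9, overweight 25.0–29.9, obese > 30, which leaves the gaps
(24.9, 25.0), (29.9, 30.0) and the point 30.0 formally unassigned. The
package uses the contiguous half-open convention `[0, 18.5)`,
`[18.5, 25)`, `[25, 30)`, `[30, Inf)`: BMI 25.0 is overweight and 30.0 is
obese. This is a declared convention, not something recoverable from the
original study data. BMI must be finite, positive and at most
100 kg/m² — the cap guards against weight values passed as BMI.

## The rule table: published constraints and reconstruction

The original 104-cell expert table is copyrighted and unpublished. What
is on record is:

* the marginal counts per BMI class — underweight 26/0/0/0,
  normal 3/18/1/4, overweight 0/8/7/11, obese 0/8/7/11 over
  (RD, BD, HD, OED), with category totals 29/34/15/26;
* three worked assignments — (one stone + fat, BMI 16.5) → RD,
  (sick + control, BMI 21) → BD, (control + food, BMI 34) → HD.

`default_rule_table()` therefore ships a **reconstruction**, not the
original: every underweight cell is RD (forced by the marginals), the
three worked cells hold, and the remaining cells are filled by fixed,
deterministic clinical-heuristic rankings with greedy quota filling:

* *normal class*: the three RD cells go to patterns carrying the
  restrictive signature (recent weight loss + feeling fat) with the
  fewest bulimic items; the single HD cell is loss-of-control +
  food-dominates without vomiting; the 18 BD cells take the most bulimic
  remaining patterns (vomiting first, then loss of control); four
  leftovers are OED;
* *overweight and obese* (identical rows): the seven HD cells take
  control-and-food patterns (the binge signature), non-vomiting patterns
  first; the eight BD cells take the most bulimic of the rest; RD never
  occurs; eleven leftovers are OED.

Ties are broken by the canonical lexicographic order of the
(sick, control, one_stone, fat, food) bit tuple, so the table is
byte-reproducible. Beyond the 26 underweight cells and 3 worked
examples, the other 75 cells are *our* reconstruction: any analysis of
cell-level content should treat them as plausible, constraint-satisfying
stand-ins. A user-supplied table in the documented CSV format can be
swapped in with `load_rule_table()`, and `validate_rule_table()` /
`cli_check_table()` report its fidelity to the published constraints.

## Validation statistics

Validation compares the algorithm against the physician's DSM-5
diagnosis (the gold standard) on screen-positive, diagnosed patients,
tallied into a 4×4 confusion matrix with physician rows and algorithm
columns in (RD, BD, HD, OED) order.

For each category, one-vs-rest **sensitivity** is TP / (TP + FN) with the
three other categories pooled as negatives; **specificity** is
TN / (TN + FP); the **Youden index** is sensitivity + specificity − 1,
computed on unrounded estimates. **Cohen's kappa**
\((p_o - p_e)/(1 - p_e)\) summarises global chance-corrected agreement.

### Confidence intervals

The original report does not name its CI method. Recomputing all eight
printed 95% intervals from the printed numerators and denominators shows
they are **continuity-corrected Wald** intervals,
\(p \pm (z\sqrt{p(1-p)/n} + 1/(2n))\) truncated to \([0, 1]\) — plain
Wald does not reproduce them, continuity-corrected Wald reproduces every
one to the printed decimal. CC-Wald is therefore the default; plain Wald,
Wilson and Clopper–Pearson are available via `method =` for users who
prefer them on statistical grounds (CC-Wald is conservative and can be
vacuous at extreme proportions).

For kappa the standard error uses the common asymptotic form
\(\sqrt{p_o(1-p_o)/(n(1-p_e)^2)}\). On the embedded validation counts
this gives a 95% interval of about (0.50, 0.68), which does **not**
exactly match the printed "(0.51–0.67)"; the upstream formula is
unstated (exact asymptotic variants differ in the second decimal), so
the kappa interval is documented as approximate and is not part of the
reproduction checks — only the kappa point estimate (0.59) is.

### Display rounding

Percentages are displayed to one decimal and indices to two, rounding
half away from zero; internal values are never rounded. The published
table itself is not internally consistent in this respect: 67/84 =
79.76% is printed as 79.7 and 136/141 = 96.45% as 96.4 (truncation),
while 3/18 = 16.67% is printed 16.7 and a CI bound of 70.57 as 70.6
(rounding). No display rule reproduces all printed digits from the
printed fractions, so `reproduce_validation()` asserts agreement to one
unit in the last printed digit; 28 of the 30 compared values in fact
agree digit-for-digit under half-up rounding, and the two truncated
cells differ by exactly one final-digit unit.

## The synthetic cohort generator

The original study is observational and implies no generative model, so
the generator is this package's own construction, built to (a) emulate
the published cohort's marginal structure and (b) provide sharp,
testable anchors for the validation machinery.

Per record it draws:

* a **true category** from the prevalences 65/39/84/18 out of 206;
* a **BMI class** from the category's published class distribution
  (e.g. 78.5% of restrictive patients underweight, 95.2% of hyperphagic
  patients obese; the bulimic row prints 99.8% in the source and is
  renormalised);
* a **BMI value** uniform within the class interval, with boundaries
  12 | 18.5 | 25 | 30 | 60 kg/m². Uniform is the default because only
  the class, never the value, enters the rule; a truncated-normal
  option parameterised by the published per-category means and SDs
  (17.6 (3.8), 25.9 (8.1), 39.1 (7.0), 30.8 (8.3)) is available via
  `bmi_sampler = "normal"`;
* **sex** from the per-category female proportions (98.4/100/91.7/94.4%)
  and **age** from the per-category normals (30.4 (12.1), 28.5 (9.8),
  43.9 (13.9), 37.1 (15.6) years) truncated at 18, the study's inclusion
  bound;
* a **DSM-5 label** uniformly from the category's member diagnoses;
* a **SCOFF pattern** from the response model below.

### The response model

With probability \(1 - \epsilon\) the pattern is drawn uniformly from
the eligible patterns that the rule table maps, in the drawn BMI class,
to the true category; when that set is empty (a structural
incompatibility — e.g. no bulimic cell exists in the underweight class)
the draw falls back to a uniform eligible pattern, so such records are
misclassified by construction, which is exactly how discordance arises
in the real cohort (underweight bulimic patients are forced into RD).
With probability \(\epsilon\) the pattern is drawn uniformly from the
*other* eligible patterns. Consequences used as test anchors:

* \(\epsilon = 0\) with class distributions restricted to compatible
  classes (`compatible_config()`) gives perfect agreement, kappa = 1,
  exactly;
* agreement degrades monotonically in \(\epsilon\);
* per-category sensitivities have closed-form expectations obtainable by
  enumeration over (class, cell-set) pairs, which the test suite checks
  against simulation.

The default \(\epsilon = 0.1\) represents modest item-response noise —
enough to make simulated cohorts imperfect (kappa ≈ 0.8 at n = 206)
while keeping the structural signal dominant. It was chosen once as a
realistic default, not fitted to the published kappa: the real cohort's
discordance mixes response noise with clinical boundary cases that the
pattern-level model does not represent.

What the generator does **not** emulate: inter-item SCOFF correlation
beyond the pattern level, the joint BMI distribution within classes
(the published per-category means/SDs and class percentages are mildly
inconsistent as a joint model; the percentages are taken as
authoritative), secular or site effects, and diagnostic uncertainty in
the gold standard. Passing simulation tests therefore demonstrate the
correctness of the pipeline's logic and statistics, not clinical
performance on real patients.

## Numerical and design choices

* Category order is (RD, BD, HD, OED) and BMI-class order
  underweight < normal < overweight < obese everywhere.
* Answer encodings 1/0, yes/no, y/n, true/false are accepted on input
  and normalised to 1/0 on output.
* Cohorts violating the inclusion criteria (age < 18, missing sex) are
  rejected unless `permissive = TRUE`.
* Sensitivity (specificity) for a category with an empty truth (rest)
  margin is an error, not NaN; the recovery harness records NA for such
  replicates.
* All RNG flows through a single seed; identical (config, table) pairs
  produce byte-identical cohort CSVs. Generated BMI values are rounded
  to two decimals and then clamped inside their class so rounding can
  never flip a class boundary.
* Test problem sizes: the exhaustive checks cover all 104 cells and all
  32 answer patterns; stochastic checks use cohorts of n = 50 (1,000
  replicates for the per-record/matrix equivalence), n = 2,000–5,000 for
  noise monotonicity, and n = 206 for prevalence recovery — sizes chosen
  to make sampling variability negligible relative to the asserted
  effects while keeping the suite quick.

## Limitations

The cell-level reconstruction is not the original instrument; only its
published constraints are guaranteed. The kappa interval is asymptotic.
The CC-Wald interval, while faithful to the source, is not the best
modern choice for small n (Wilson is offered). The generator is a
validation harness, not an epidemiological simulator.
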