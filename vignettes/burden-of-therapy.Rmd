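---
title: "Weekly burden-of-therapy scoring: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weekly burden-of-therapy scoring: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aeburden)
```

## The model

`aeburden` quantifies how burdensome a treatment's adverse events are over
time, rather than how frequent they are overall. The primitive quantity is
the per-patient weekly burden score

$$ b_{iw} \;=\; \sum_{t} v_t \, g_{\max}(i, t, w)\, \mathbf{1}\{t \text{ active in week } w\}, $$

the sum over distinct adverse-event terms $t$ of the highest CTCAE grade
$g_{\max} \in \{1..5\}$ of that term active in study week $w$, times an
optional positive clinical-relevance weight $v_t$ (unit by default). A
patient with grade-2 diarrhea and grade-1 skin rash in one week scores
$(2 \times 1) + (1 \times 1) = 3$.

Weekly arm totals are normalized by the risk set — the number of the arm's
patients still on study for at least one day of the week — and the
normalized weekly values are summed into the arm's cumulative AUC
(rectangular rule). The AUC difference between two arms is tested by
permuting arm labels over patients.

Assumptions worth stating plainly:

* **Binary weekly presence.** An episode active on a single day of a week
  counts for the whole week. The weekly estimate deliberately has no
  sub-week resolution; shortening `week_length` is the supported way to
  refine it.
* **Terms are independent contributions.** Two concurrent grade-2 events
  score 4; no interaction or dominance between terms is modelled.
* **The risk set ignores cause.** A patient off study contributes neither
  burden nor denominator, whether they left for progression, toxicity or
  withdrawal. No competing-risk adjustment is attempted.
* **Grades are used as integer multipliers**, i.e. grade 4 is "twice"
  grade 2. This linearity is inherited from the score's definition; the
  per-term weights $v_t$ are the provided lever when it is clinically
  inappropriate.

## Conventions and parameters

| Parameter | Default | Meaning |
|---|---|---|
| `week_length` | 7 days | week $w$ covers study days $(w-1)L+1 \dots wL$; day 1 = first treatment day |
| `weights` | all 1 | positive per-term multipliers (clinical relevance) |
| `min_risk_set` | 0 (off) | drop weeks whose risk set is smaller; see below |
| `n_permutations` | 9999 | label permutations for the comparison |
| `seed` | required | every resampling result is reproducible |

AE intervals are inclusive on both ends. An AE reported as *ongoing* at
study end is imputed to end on the patient's last study day; an episode
whose recorded end runs past that day is truncated to it, so no burden is
ever counted outside the observed on-study window. The week grid is
anchored to study day 1 globally; since start days are already relative to
first treatment, per-patient and global anchoring coincide.

Two readings of the weekly denominator are possible: subjects at risk in
the arm, or in the whole study. Per-arm denominators are used, because they
are the only reading under which the two arms' curves may have different
lengths and remain interpretable per arm.

A patient is at risk in a week if they are on study for at least one day of
it. The alternative — requiring full-week residence — would discard every
patient's final partial week and was rejected.

## The comparison test

The published applications of burden scoring report p-values without naming
the test. Here the test is constructed explicitly: a two-sided permutation
test on the difference of arm-level AUCs, the AUC being the method's own
comparison statistic. Arm labels are permuted over patients; both arm AUCs,
*including the per-week risk sets*, are recomputed per shuffle; the add-one
corrected p-value $(1 + \#\{|d_\pi| \ge |d_{obs}|\})/(1 + B)$ can never be
zero and is bounded below by $1/(B+1)$. The label vector itself is permuted,
which makes the p-value exactly invariant to swapping the arm labels.
Permutation was chosen over a parametric test because per-patient burdens
are zero-inflated and heavily skewed; a Wilcoxon rank-sum test on
per-patient AUCs (`method = "wilcoxon"`) is provided as a sensitivity
check — note it weights patients, not patient-weeks, and ignores risk-set
normalization.

Per-term reports are unadjusted for multiplicity by default, matching how
per-term toxicity p-values are conventionally reported; Holm adjustment is
available (`adjust = "holm"`) and flagged in the output.

## Numerical and degenerate-input choices

* Weeks with an empty risk set have normalized burden 0, are flagged
  `empty`, and contribute nothing to the AUC.
* As a trial empties late on, a handful of remaining patients can swing the
  weekly estimate wildly. The weekly `n_at_risk` column is always reported
  so readers can judge this, and `min_risk_set` optionally truncates the
  series; the default keeps every week.
* If both arms have zero burden everywhere the p-value is 1, with a
  warning, rather than an error.
* Permutation-count comparisons use a `1e-12` absolute tolerance when
  testing $|d_\pi| \ge |d_{obs}|$ so that exact ties (e.g. mirror-image
  arms) are counted as ties regardless of floating-point noise.
* Grade-5 (fatal) events contribute for their recorded interval only; no
  persistent post-death ceiling is imposed. Term matching is by case-folded,
  whitespace-trimmed string only — no MedDRA or synonym mapping.

## What the simulator emulates — and what it does not

`simulate_trial()` draws a two-arm AE dataset: per patient a geometric
number of on-study weeks (weekly dropout probability, capped at
`max_weeks`, with a uniform final day within the last week), and per
on-study week and term a Bernoulli onset on a uniform day of the week, a
categorical CTCAE grade, and a geometric episode duration (mean in days).
Episodes outlasting the patient's observation are flagged ongoing with
probability `ongoing_prob`, otherwise truncated — exactly the two forms an
AE listing records. Bernoulli onsets and geometric durations were chosen
for analytic tractability (expected episode counts have closed form, which
the tests exploit); per-week hazard vectors provide time trends.

`preset_rash_like()` is the bundled study condition: 123 + 27 patients over
24 weeks, five terms (skin rash, sensory neuropathy, diarrhea, neutropenia,
alopecia), weekly dropout 0.045 (median time on study of roughly three to
four months, realistic for metastatic pancreatic cancer). Its hazards
encode the qualitative two-regimen toxicity pattern: rash concentrated in
the gem/erlotinib-like arm (onset 0.18/week vs 0.01, long-lived episodes),
neuropathy ramping linearly from 0.02 to 0.35/week on the FOLFIRINOX-like
arm with 28-day mean persistence, diarrhea and neutropenia decaying over
time under FOLFIRINOX (dose-reduction-like) while stable under
gem/erlotinib, and slightly more alopecia under FOLFIRINOX. Under these
hazards the overall accumulated burden is similar in the two arms, slightly
higher in the gem/erlotinib-like arm.

The simulator does **not** model grade transitions within an episode
(overlapping same-term episodes stand in for them, exercising the
max-severity rule), correlated AE onsets, toxicity-dependent dropout, dose
modifications, or efficacy. Passing tests on simulated data therefore
demonstrate the *arithmetic and statistical machinery* — interval
projection, normalization, resampling calibration — not the clinical
realism of any particular hazard value.

## Verification strategy and problem sizes

The burden engine is verified against an independent brute-force oracle
that expands every episode to individual days, takes per-day per-term
maxima, collapses days to weeks, and sums — on 50 random studies of up to
50 patients and 30 weeks. The permutation test's type-I error is measured
on 200 null trials (identical arms, 30 per arm, 12 weeks, 999 permutations
each) against the exact binomial band around 0.05, and its power on 100
trials with one arm's hazards doubled (50 per arm). These sizes keep the
full suite around a minute on one core while giving the Monte-Carlo checks
standard errors small enough to be meaningful.

## Known limitations

* Identical medical concepts spelled differently are distinct terms.
* The AUC compares arms, not patients; individual-level covariate
  adjustment is out of scope.
* Late-trial weeks with small risk sets remain noisy unless truncated.
* Burden attributes equal weight to a week regardless of how many days of
  it the AE was actually present.
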