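---
title: "Methods: dietary heavy-metal exposure and hazard decision trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dietary heavy-metal exposure and hazard decision trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquarisk)
```

## The assessment model

`aquarisk` assesses chronic, non-carcinogenic risk from heavy metals in
seven categories of aquatic products (pelagic fishes, inshore fishes,
other fishes, crustaceans, shellfish, cephalopods, algae) for adults aged
19–64. Three quantities drive everything:

* **EDI** (estimated daily intake, mg/kg bw/day):
  $EDI_{ij} = C_i \cdot CR_{ij} \cdot 10^{-3} / BW_j$, where $C_i$ is the
  metal concentration in the cooked product (mg/kg wet weight), $CR_{ij}$
  the subject's consumption rate (g/day) and $BW_j$ the body weight (kg).
* **HQ** (hazard quotient): $HQ_{ij} = EDI_{ij} / RfD$. The reference dose
  RfD and a health-based guidance value (HBGV) are the same quantity under
  this model; the package uses one field named `rfd` and documents HBGV as
  an alias. An exposure is *hazardous* iff $HQ > 1$, strictly: the
  boundary $HQ = 1$ is acceptable.
* **ADI** (acceptable daily intake, g/day): the consumption rate at which
  HQ reaches exactly 1, obtained by inverting the HQ formula:
  $ADI = RfD \cdot BW / (C \cdot 10^{-3})$. The inversion is a design
  choice — the source framing of "maximum intake" never prints a formula —
  and it carries an exact round-trip property,
  `compute_hq(compute_edi(c, adi, bw), rfd) == 1`, which the test suite
  checks to $10^{-12}$ on $10^4$ random inputs. A zero concentration
  admits no finite ADI and is signalled as a classed error condition
  rather than returned as `Inf`.

Reference doses are *not* part of the scientific claim of this package:
the shipped `reference_dose_table()` is a clearly-labelled screening
default (USEPA IRIS where an oral RfD exists, PPRTV/HEAST provisional
values otherwise, and the former JECFA PTWI ÷ 7 for lead, which has no
current RfD). Each entry carries its source label, and any study use
should pass an explicitly reviewed table (`read_rfd()`).

## The hazard decision tree

For each metal, a binary classification tree is grown over the feature
vector `(category, body weight, intake)` with the hazard flag as label.
HQ, EDI and ADI are deliberately excluded from the feature set even
though they travel with each record: the label *is* a threshold on HQ, so
splitting on them would leak the label and produce a trivially perfect,
scientifically empty tree.

Split selection uses the gain-ratio criterion in bits:

$$Gain(S,A) = Entropy(S) - \sum_j \frac{|S_j|}{|S|}\,Entropy(S_j), \qquad
SplitInfo_A(S) = -\sum_j \frac{|S_j|}{|S|}\log_2\frac{|S_j|}{|S|},$$
$$GainRatio(A) = Gain(S,A)/SplitInfo_A(S).$$

`Entropy(S)` is the standard Shannon entropy of the class proportions,
base 2, matching the $\log_2$ of the split-information formula. The
pseudocode tradition this follows names an "entropy" classifier while
evaluating gain ratio; the package follows the printed formulas and
selects by gain ratio, with plain information gain exposed as
`tree_config(criterion = "gain")` for comparison.

Candidate generation:

* **Continuous attributes** (`bw`, `intake`): one threshold at each
  midpoint between consecutive distinct sorted values; "≤ threshold" goes
  left, matching the "less than or equal to" phrasing of the rule
  sentences. A value exactly at the threshold therefore routes left.
* **Categorical attribute**: every binary partition of the categories
  present at the node — at most $2^{c-1}-1 = 63$ candidates for 7
  categories, so exhaustive enumeration is cheap and makes the
  brute-force test oracle exact. The canonical left side is the subset
  containing the alphabetically first category, which names each
  partition once.
* Candidates that send all instances one way would divide by zero in the
  gain ratio; they are never generated, and `gain_ratio()` refuses a zero
  split information with a classed condition.

Ties on the criterion (within $10^{-12}$) are broken by a fixed attribute
order (category, then body weight, then intake), then by smaller
threshold, then by lexicographically smaller subset — determinism is worth
more here than any marginal accuracy difference. A node becomes a leaf
when it is pure, at `max_depth`, smaller than `2 * min_leaf`, or when the
best criterion value falls below `min_gain_ratio`.

Defaults: `max_depth = 3` (the published trees are this shallow),
`min_leaf = 5`, `min_gain_ratio = 1e-4`. No pruning is implemented (none
is described for the method this reimplements), no multiway categorical
splits, and no missing-value surrogates — instances are complete by
construction.

**Two-stage protocol.** The topology is fitted on a *construction* case
set; an independent *evaluation* case set is then routed through the
fixed tree and every leaf's `(n, k_hazard, risk_pct)` is recomputed from
the cases it receives (`evaluate_leaves()`). A leaf reached by no
evaluation case reports `n = 0` with an explicit `empty` flag rather than
a silent 0 %. The leaf risk percentage is $100k/n$ rounded **half-up** to
one decimal; rounding is done in integer arithmetic
(`(2000k + n) %/% (2n) / 10`) so the half-up rule is exact and immune to
binary floating-point representation of values like 6.25.

Rules are extracted one per populated leaf, root-first, and rendered with
the sentence template "For an adult whose …, the risk of causing
〈endpoint〉 was X %". Intake thresholds are learned in g/day (the EDI
unit) and rendered in g/week (× 7) by default to match the sentence
style of the published rules; `g/day` is available via argument. The
endpoint map ships exactly the seven unambiguous pairings (iAs →
hyperpigmentation and keratosis follicularis, Cd → kidney diseases, Co →
goiter, Fe → gastrointestinal disorders, Sr → adult rickets, Tl →
perifollicular atrophy, Zn → reduced erythrocyte superoxide dismutase
activity) and is config-extensible for the remaining metals, whose
pairings are not stated unambiguously. `highest_risk()` picks each
metal's maximal-risk rule, breaking ties by larger evaluation count and
then path order; that tie-break is a convention, not an inference.

## What the synthetic survey emulates — and what it does not

The consumption survey behind the original analysis is not deposited, so
the package generates one with the stated statistical structure
(`population_spec()` / `generate_population()`):

* **Body weight**: Normal(64, 11) kg truncated to [35, 120] kg, sampled
  by inverse-CDF. The source never describes its weight distribution;
  these values are a realistic adult range chosen so that the published
  split points (36.5–87 kg) all fall inside the support. The generator's
  truncated-normal mean is verified against a numeric-integration oracle.
* **Intake**: per-category zero-inflated lognormal in g/day.
  Non-consumption probabilities of 0.25–0.60 and medians of roughly
  2–12 g/day give median weekly intakes of order grams to around a
  hundred grams, consistent with a population whose total aquatic-product
  consumption is a few tens of grams per day. These are explicit
  stand-ins, not inferences about the real survey.
* **Concentrations**: the published 12 × 7 table of mean ± SD (mg/kg wet
  weight) is built in. Draws use a lognormal matched to those moments
  ($\sigma^2 = \log(1 + s^2/m^2)$, $\mu = \log m - \sigma^2/2$): tissue
  concentrations are right-skewed, and several cells have SD > mean,
  which no positive normal distribution can produce. A zero-truncated
  normal is available for sensitivity checks; note truncation shifts its
  realised mean above the target, which is why moment-recovery tests
  apply to the lognormal default.
* **Seeding**: every generator takes one integer seed
  (Mersenne-Twister, fixed draw order), so equal seeds give byte-identical
  CSV output across runs and platforms.

Case counts default to the published scale — 422 construction and 2,107
evaluation consumption cases (a *case* is one subject × category pair
with positive intake). `run_study()` sizes the population so the expected
case count slightly exceeds the target and truncates the case list
exactly, keeping both stages at the stated sizes.

What passing tests on these data do **not** show: that the published
trees or their thresholds are recovered. Those depend on the real,
non-deposited survey and are treated as descriptive. With the shipped
screening RfDs and the published mean concentrations, simulated HQ rarely
exceeds 1 — most diets in this population are simply safe — so several
per-metal trees legitimately collapse to a single 0 % leaf. The Monte
Carlo concentration mode (`concentration = "sample"`, the `run_study()`
default) draws a fresh concentration per case from the matched lognormal,
which is what surfaces hazardous tails for the high-concentration
metal/category pairs (Cd or Fe in shellfish, for instance). The published
risk percentages (40–100 % at leaves) are not reproducible from the
published summary inputs alone; the package's acceptance layer therefore
checks what *is* checkable — exact leaf-percentage arithmetic from the
published counts, oracle-exact split selection, planted-rule recovery,
moment recovery and the exposure algebra — rather than chasing those
percentages.

## Numerical and testing choices

* Entropy terms use $0\log 0 = 0$; gains are clamped at 0 against
  floating-point cancellation.
* The exhaustive-search test oracle re-derives entropy and gain ratio
  independently and scans *all* thresholds and *all* category subsets; the
  learner must match its optimum to $10^{-10}$ on 200 random datasets of
  up to 12 instances and 3 categories — small enough that the oracle is
  exact, large enough to hit ties and degenerate layouts.
* Planted-rule recovery uses noise-free single-threshold labels
  (n = 200, 20 seeds, both continuous attributes): the learner must pick
  the planted attribute and a threshold strictly between the straddling
  observations.
* Moment recovery is tested for all 84 profiles at $n = 10^4$ within 4
  standard errors; the two headline shellfish profiles (Fe: 71.46 ± 67.25,
  Cd: 1.25 ± 3.06 mg/kg) are additionally pinned in the acceptance suite.
* The end-to-end study (7 metals × (422 + 2,107) cases, tree fitting,
  leaf re-evaluation, full reporting) runs in a few seconds on one CPU;
  these problem sizes are the package's standard demonstration scale.

## Known limitations

* Per-metal HQ only: no hazard-index summation across metals and no
  carcinogenic slope-factor model.
* The categorical split search is exhaustive, which is exact for 7
  categories but exponential in general; a larger vocabulary would need
  the classical sorted-proportion shortcut.
* The default RfD table is a screening convenience, not a toxicological
  position; several provisional values (Co, Tl, Fe) carry substantial
  uncertainty, and lead has no defensible RfD at all.
* The synthetic survey reproduces marginal structure (weights, intake
  zero-inflation and tails) but no within-subject correlation across
  categories, no age/sex structure beyond the adult band, and no
  seasonality — real survey data would carry all of these.
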