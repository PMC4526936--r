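---
title: "Variant report designs, comprehension scoring and the between-condition analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variant report designs, comprehension scoring and the between-condition analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varreport)
```

`varreport` has three layers: a validated data model for annotated
gene-variant reports, deterministic visual layouts and renderers for seven
report designs, and the measurement side — a comprehension quiz with
automatic grading plus the ANOVA/Tukey–Kramer machinery for comparing
designs. This vignette records the modelling choices, the tunable
parameters, and what the synthetic-data tests do and do not establish.

## The data model

A variant carries three ordinal/categorical annotation axes — impact
(pathogenic, benign, protective), evidence certainty (well-established,
likely, uncertain) and clinical importance (low < medium < high) — plus an
allele frequency in [0, 1], linked condition names, a free-text summary and
external links. Validation is strict: enumeration tokens are matched
case-insensitively with space/hyphen tolerance ("Well established" is
accepted) but anything else is an error, never a guess — silent coercion of
annotation tokens is how data corruption hides. All violations in a file are
reported together in a machine-readable table.

Serialization is canonical so golden-file tests are bit-exact: fixed TSV
column order, lowercase enums, `;`-joined lists, `.` for empty fields, and
frequencies carried at six decimals (`parse ∘ write` is the identity because
the model rounds frequencies to that precision on entry; six decimals is far
finer than any population-frequency estimate is accurate). Sorting is total
and deterministic everywhere: any sort key is tie-broken by potential-effect
rank, then label in code-point order, then variant id.

## The potential-effect scale and the palette

The nine (impact, evidence) cells are ordered into ranks 1–9: the pathogenic
block first, then benign, then protective, and within each block
well-established > likely > uncertain. The relative order of benign vs
protective on this axis is not dictated by anything in the data; we place
benign between the two signed blocks so that the axis reads "harmful →
neutral → beneficial". Layouts that encode effect as a position or height
(bar, bubble) use this rank directly; bar height is `(10 − rank)/9` of the
panel height so the strongest-evidence pathogenic variant is tallest (the
axis direction is a package choice).

The primary palette maps impact to hue — pathogenic red (hue 0°), benign
neutral white/gray, protective blue (hue 220°) — and evidence certainty to
saturation, 0.90 / 0.55 / 0.25 for well-established / likely / uncertain.
The neutral family has no usable saturation, so benign cells step lightness
instead (0.92 / 0.95 / 0.98). Red–blue is deliberately safe for red–green
color-vision deficiency; the older red–green palette is retained only for
reproducing the two-level treemap prototype and is not offered for the
seven study designs. The exact hex values are committed constants (the
design source names colors, not hex codes), which is what makes rendering
tests byte-exact.

## Layout geometry

All geometry lives on the unit square (origin top-left); renderers scale to
a 1200×800 viewBox. Spacing constants (panel gap 0.02, frame inset 0.012,
heat-map cell inset 10%, bubble shrink 0.8) are named package constants:
no published pixel dimensions exist for the original screenshots, so all
spacing is a documented decision rather than a recovered fact.

* **Squarified treemap.** Rows are laid greedily along the shorter side of
  the remaining free rectangle and a row is fixed when adding the next item
  would worsen its worst aspect ratio. Areas are computed from cumulative
  edges, so sibling rectangles share edges exactly: area conservation holds
  to ~1e-12 relative error and interiors never overlap. Weights must be
  strictly positive.
* **Importance weights.** "Rectangle size proportional to importance" needs
  numbers: low = 1, medium = 2, high = 4 per variant. Monotone, visually
  distinct, and documented; nothing downstream depends on the exact values.
* **Zoomable treemap.** Three-level hierarchy importance → effect cell →
  variant, squarified at every level; a node's weight is the sum of its
  descendants' importance weights, so leaves within one cell get equal
  areas. The zoom state machine allows at most two descents; `select` of a
  non-child is an error, `back ∘ select` is the identity.
* **Zoomable partition (icicle).** Three stacked bands; widths are
  proportional to descendant variant counts and are computed from cumulative
  count fractions, so child widths sum *exactly* (not just approximately) to
  the parent width.
* **Bubble / bar panels.** Three equal-width importance panels. Bubbles sit
  in one of nine vertical rank bands with deterministic grid slots
  (`ceiling(sqrt(m))` columns); radius is 0.8 × half the smaller cell
  dimension, which makes non-overlap true by construction.
* **Table.** Emits row geometry plus the sortable-column metadata so the
  HTML renderer and quiz overlays share one contract; each row also carries
  the variant's encoded color as a swatch.

Empty datasets still produce the three labelled importance frames (split
into equal thirds) wherever the design has them, with zero variant shapes.

## Rendering

Documents are assembled from static templates: no timestamps, no randomness,
identical inputs give identical bytes. Every zoom state of a design is
pre-rendered as an SVG and embedded in one HTML file; interactivity (view
switching, hover details, table sorting) only toggles precomputed content,
and nothing is fetched from the network. Variant details render into a fixed
side panel rather than a floating tooltip: overlaying detail boxes on the
plot hides context (a known failure mode of hover tooltips in dense
visualizations), and a fixed panel is also trivially testable. Glossary
terms occurring in detail text are wrapped in anchors into the clickable
glossary; a small starter glossary covering the terms non-expert readers
most often ask about (allele frequency, homozygous, pathogenic, benign, ...)
ships as a convenience fixture, not as canon.

## The quiz and the grading rubric

The nine-item battery is fixed in shape: two count fill-ins, three count
comparisons with options {Greater than, Equal to, Less than, I don't know},
an open item asking which variants the subject should discuss with a health
care provider, two condition-risk items with the same four options, and one
select-all-that-apply item over condition names. Prompts are templated on
the dataset's subject name. The answer key is *derived*, never authored:
counts and comparisons are recomputed from the variant table, the
discuss-with-a-clinician set is the high-importance pathogenic variants
(restricting to well-established evidence would make the item a subset of
the well-established-pathogenic count item and degenerate on small
datasets), and the select-all key is the option conditions linked to at
least one pathogenic variant of medium or high importance.

The risk items need a rule for "risk vs the average person", which no
annotation field states directly. We use a signed score per condition: the
sum over linked variants of sign(impact) × importance weight (pathogenic +,
protective −, benign 0); positive means "Greater than", negative "Less
than", zero or unlinked "Equal to". The battery instantiates the two risk
items on the conditions with the largest positive and most negative score
(ties alphabetical); datasets intended for the battery — like the packaged
`jamie_fixture()` — are constructed so those two are unambiguous. The rule
is only ever exercised on such synthetic data.

Scores live on a 0–10 scale. The published design states the range and that
the select-all item earned separate points, but not the split, so the rubric
is a documented constant: one point each for the seven exact-match items,
one point for the open item with partial credit
`max(0, hits − false names)/|key|` (gene symbols matched
case-insensitively), and two points for the select-all item scaled by
option-level agreement with the key. Blanks score zero, as does any response
token outside an item's option set; "I don't know" earns nothing. One edge
case is worth recording: when an item's key is the *empty set*, an empty
response is graded as correct for the open and select-all items (it matches
the key); against a non-empty key an empty response is a blank. The
pre-task tutorial gate includes a participant when at least three of the six
tutorial answers are correct; the tutorial content itself is out of scope —
only the gate is implemented.

## Synthetic data

`generate_dataset()` emulates the kind of fictional single-subject dataset
used to compare report designs on identical data. Per-cell
(importance × impact × evidence) counts are met exactly; gene symbols come
from a fictional pool (GENE001…GENE400 — real gene names are deliberately
avoided so fixtures cannot be mistaken for medical content); allele
frequencies are uniform within per-impact ranges (pathogenic
U(0.0001, 0.05), protective U(0.001, 0.10), benign U(0.05, 0.50) — plausible
in tooltips, irrelevant to every scored computation). All sampling flows
through one explicitly configured PRNG stream (Mersenne-Twister, inversion
normals, rejection sampling), so a seed pins the output to the byte across
platforms.

`simulate_responses()` plants a per-design accuracy p: each item is answered
correctly with probability p, otherwise with a uniformly random wrong answer
(counts get integer noise truncated at zero and never equal to the key;
choice items pick another option; the open/select items perturb the key by
one element). The default accuracies are the published per-design
comprehension means divided by ten (table 0.565, bar 0.621, bubble 0.630,
treemap 0.574, heatmap 0.625, zoomable treemap 0.463, zoomable partition
0.508) — i.e. the study conditions themselves. Likert items are
`1 + Binomial(4, p)`. Condition assignment is balanced round-robin after a
seeded shuffle of the design order.

What the simulator does *not* emulate: per-participant ability
heterogeneity, item-difficulty structure, fatigue or ordering effects,
demographic covariates, or any dependence of accuracy on the *content* of
the dataset. Passing recovery tests therefore show that the pipeline is
correct and well calibrated under its own planted model — not that real
readers behave this way.

## Statistics

Per-condition summaries use the sample SD (n−1 denominator; published
summary tables rarely state the denominator, and n−1 is the field default).
One-way ANOVA is the standard between/within decomposition, with explicit
degenerate semantics: all values identical gives F = 0, p = 1; zero
within-group variance with unequal means is an error ("infinite F") rather
than a silent division.

Tukey–Kramer comparisons are computed from summaries alone: pooled
MSE = Σ(nᵢ−1)sᵢ²/Σ(nᵢ−1), SE = √(MSE/2 · (1/nᵢ + 1/nⱼ)) for the unequal-n
pair, q = |mean difference|/SE, and p_adj from the studentized range with k
groups and Σ(nᵢ−1) degrees of freedom. The studentized range CDF is
integrated directly: conditioned on the pooled scale s, the range
probability is `k ∫ φ(z) [Φ(z) − Φ(z − q·s)]^{k−1} dz`, and the outer
integral averages over the density of √(χ²_df/df). Both integrals use fixed
Gauss–Legendre rules (192 location nodes on [−8.5, 8.5 + q·s], 128 scale
nodes between the 1e−12 tail quantiles of the scale density), giving
absolute accuracy well below 1e−6; at k = 2 the result matches the
|t|-distribution identity to ~1e−12. Adjusted p-values are computed from
the *survival-form* integrand rather than as 1 − CDF, so p-values of order
1e−15 — which the headline comparisons produce — do not drown in floating
point cancellation. (Base R's `ptukey` exists and is used as an independent
cross-check in the tests; its own absolute accuracy bottoms out around 1e−4
at small df, which is why the distribution is integrated here rather than
delegated.)

Defaults: α = 0.05, two-sided; p-values are reported raw with significance
flags at the caller's α.

## Problem sizes used by the test suite

The suite exercises: 10,000 random weight vectors for squarified
conservation/overlap audits; 200 seeded synthetic datasets × all seven
designs × every zoom state for completeness; exhaustive single-cell datasets
plus 200 sampled small multisets plus 1,000 seeded synthetic datasets for
quiz-oracle equivalence against an independently written naive counter;
100,000-draw Monte-Carlo checks for the studentized range CDF and a
100,000-permutation oracle for the ANOVA p; and 200 replicates at 100
participants per condition for end-to-end recovery of the planted condition
ordering (the planted bubble-vs-table ordering and the Tukey flag on the
largest planted gap are both recovered in well over 95% of replicates).
These sizes are the package's reproducibility statement: rerunning the suite
recomputes all of them.

## Known limitations

* The quiz's risk rule and rubric point split are package decisions where
  the published design is silent; both are constants, documented above.
* Geometry aims at determinism and testability, not at pixel-faithful
  reproduction of the original screenshots.
* The packaged per-condition summary fixture records a provenance wrinkle:
  the source reports 730 participants in one place and 731 in another, while
  the per-condition ns sum to 730. The fixture carries the per-condition ns
  verbatim.
* Borderline published contrasts (e.g. table vs bubble at p ≈ .04) need not
  reproduce exactly from rounded summary data; recomputation from the
  fixture is treated as a check on the clearly significant contrasts only.
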