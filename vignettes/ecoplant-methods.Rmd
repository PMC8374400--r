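---
title: "Eco-Plant analysis of dispersed sporomorph assemblages: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eco-Plant analysis of dispersed sporomorph assemblages: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoplant)
```

## The model

A dispersed sporomorph — a fossil spore or pollen grain found loose in
sediment — carries no direct record of the plant that shed it. Its parent
plant must be inferred from wall ultrastructure and comparison with *in
situ* material, and for most Mesozoic genera that inference is only safe at
a coarse taxonomic level: phylum, order, or family. Once a genus is linked
to a parent plant, the parent's ecological tolerance can be attached too:
an Eco-Plant humidity group (EPH — hydrophytes, hygrophytes, mesophytes,
xerophytes, euryphytes) and a temperature group (EPT — megathermic,
mesothermic, microthermic, eurythermic). Relative abundances of these
groups downcore are then a proxy for humidity and temperature change.

`ecoplant` implements the bookkeeping of that method. Two genus-keyed
reference tables — a *taxonomy* (genus → Kingdom…Family) and an *ecogroup*
table (genus → EPH, EPT) — are joined to a long-format assemblage of
observations $(s_i, g_i, a_i)$: sample, genus, abundance. Under an analysis
mode $m \in \{\mathrm{phylum}, \mathrm{order}, \mathrm{family},
\mathrm{eph}, \mathrm{ept}\}$, each genus resolves to a category
$\mathrm{cat}_m(g)$, and the result is the percentage matrix

$$P(s, c) \;=\; 100 \cdot
  \frac{\sum_{i:\, s_i = s,\ \mathrm{cat}_m(g_i) = c} a_i}
       {\sum_{i:\, s_i = s} a_i}.$$

Two modelling commitments matter:

* **Uncertain is a category, not an error.** A genus absent from the
  relevant table — or present but blank at the requested rank — resolves to
  the sink category `Uncertain`. Its abundance stays in the denominator, so
  a sample dominated by unlinkable taxa shows small linked percentages and
  a large Uncertain column rather than a misleadingly clean composition.
  The complementary view (`denominator = "linked"`) renormalises over
  linked observations only and is off by default.
* **Counts and percentages are interchangeable.** Because each sample is
  divided by its own total, uploading raw grain counts or pre-computed
  percentages gives the same result. The worked example makes this
  observable: one sample's abundance column totals 100.2, and its largest
  taxon (34) comes out as $100 \times 34 / 100.2 = 33.9$, not 34.

No cross-rank fallback is invented: a genus linked at order level but with
no family stays `Uncertain` in family mode. Refusing to fabricate a family
is conservative and keeps the three taxonomy modes independent claims.
Kingdom and class are stored but have no analysis mode. The method stops at
grouped percentages: climate indices, ratios, ordinations and confidence
intervals are deliberately out of scope — interpretation of the relative
abundances is the palynologist's task.

## Reference data and their limits

The bundled tables are small published excerpts (17 taxonomy genera, 16
ecogroup genera) of a much larger curated database; they are fixtures and a
schema, not a research-grade reference. Real analyses should supply full
tables via `default_reference(taxonomy = ..., ecogroup = ...)` or overlay
corrections with `merge_reference()` (last writer wins, supporting the
usual update model where a new study revises a single genus). EPH and EPT
are closed five- and four-member sets; anything else (e.g. "halophytes",
which Mesozoic workers subsume under xerophytes) is rejected at load time
rather than silently carried. Genus matching trims whitespace and folds
case — the reference data promise case tolerance for headers, and extending
it to keys avoids inflating `Uncertain` through capitalisation typos — but
no synonym resolution is attempted: users must supply advisable genus
names. Angiosperm and Paleozoic ecogroup assignment is unsupported, as the
underlying affinities are.

## Numerical design

**Exact decimal aggregation.** Abundances originate as decimal text in a
CSV. Within each sample the aggregation therefore snaps the abundances to
exact decimals — an integer numerator over a common power-of-ten
denominator, trying 0–12 decimal places with a relative snap tolerance of
$10^{-9}$ — sums groups and the total as exact integers (representable in
doubles below $2^{53}$), and computes each percentage as a single correctly
rounded division $100 \cdot G / T$. Two properties follow by construction:

* per-sample conservation: the category values of a sample sum to 100
  exactly in exact arithmetic (the floating sum of the divided values is
  within one or two ulp of 100);
* scale invariance: multiplying all of a sample's abundances by any
  positive decimal factor leaves the output row bit-identical, because the
  integer ratio $G/T$ is unchanged. A plain sum-then-divide in doubles does
  *not* have this property (the rescaled inputs are perturbed in their last
  bits, and roughly a quarter of cells change in the final ulp; the test
  suite's invariance checks would catch such an implementation).

Values with no short decimal form (e.g. programmatically generated
irrational proportions), or samples whose integer scaling would exceed
$2^{53}$, fall back to ordinary double sums; conservation then holds to
$\sim 10^{-13}$ and invariance to ordinary rounding error.

**Display rounding.** Tables print at one decimal by default, rounded half
away from zero, with trailing `.0` dropped (`25`, not `25.0`) — matching
how such result tables are conventionally printed. Rounding is display
only; matrices always carry full precision, and tests against printed
values allow ±0.05 since no printed cell can discriminate between
half-even and half-up rules.

**Ordering and ties.** Categories are sorted alphabetically
(case-insensitive, C-locale radix order) with `Uncertain` forced last;
samples keep first-appearance order. A category observed anywhere in the
data materialises as 0 in samples that lack it, so all samples share one
column set. Depth is carried for diagram ordering but never enters
aggregation.

**Degenerate inputs.** Zero-total samples are refused by name (a
percentage of nothing is undefined); blank abundance cells are rejected
rather than guessed at; duplicate (sample, genus) rows are legal and sum —
consistent with count semantics, and the enumeration tests cover them
explicitly.

## The synthetic generator

`random_assemblage()` emulates a palynologist counting a fixed number of
grains per sample: per-genus proportions from a symmetric Dirichlet (unit
shape, i.e. uniform on the simplex), a fixed share `unlinked_fraction`
diverted to invented genera absent from any reference table, and counts
from a multinomial over the combined proportions. Defaults — 10 samples,
300 grains per sample (a routine counting target), no unlinked taxa — are
meant as a realistic small study; `total_per_sample = "percent"` emits
exact Dirichlet percentages instead. The generator reproduces compositional
structure only: it does not model taphonomy, differential pollen
productivity, transport bias, or downcore autocorrelation, so passing tests
demonstrate the arithmetic and plumbing on realistic *shapes* of data, not
ecological realism.

## Diagrams

`pollen_diagram()` draws the classic stratigraphic diagram: one panel per
category in matrix order, one horizontal track per sample on a shared
vertical axis, sample order either as-input or by depth (requiring a depth
for every sample). Panels are scaled independently to their maximum rounded
up to the next multiple of 5, or to a fixed `scale_max` (e.g. 100) for
comparable axes; bars are the default with a filled-silhouette alternative,
both conventional in pollen diagrams. The `Uncertain` panel is drawn last,
slightly separated and greyed. Layout (panel and track structure) is
computed by `diagram_layout()` independently of any graphics device, which
is what the structural tests introspect; rendering goes to PDF (default),
SVG or PNG. `draw_curve()` plots a user-supplied wide matrix exactly as
given — no lookup, no added `Uncertain`, no renormalisation — for combining
or pruning result tables by hand.

## Problem sizes used in the tests

The suite checks the worked two-sample example exactly; conservation on
200 simulated assemblages (2 samples × 300 grains, 20% unlinked) in all
five modes at $10^{-9}$; bitwise scale invariance on 50 assemblages ×
factors $\{0.01, 3, 1000\}$; and equivalence with a brute-force
integer-arithmetic oracle on all 18,563 multisets of up to six
(genus, abundance ∈ {1,2,3}) rows over a four-genus pool (one of them
unlinkable). These sizes exercise every code path — including duplicate
rows and empty categories — while keeping the default test run fast.

## Known limitations

* The quality of any reconstruction is bounded by the reference tables;
  with the bundled excerpts most real-world genera resolve to `Uncertain`.
* One category set per run: EPH/EPT groups never display at zero abundance
  unless some observation maps to them, so different datasets can yield
  matrices with different column sets.
* No nomenclatural adjudication: synonyms and broadly defined form-genera
  are the user's responsibility; the run log lists unlinked genera to make
  the consequences visible.
* Diagrams are static documents; there is no zonation (CONISS), curve
  exaggeration, or interactive viewer.
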