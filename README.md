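# ecoplant

Eco-Plant analysis of dispersed sporomorph assemblages: genus-keyed
botanical-affinity lookup, per-sample percentage aggregation with an
explicit *Uncertain* sink, and multi-panel stratigraphic pollen diagrams.

## The problem

Fossil spores and pollen grains (sporomorphs) are found dispersed in
sediment, detached from the plant that produced them. To read vegetation or
climate from a counted assemblage, each sporomorph genus must first be
linked to its most likely parent plant — feasible for many Mesozoic genera
at **phylum**, **order** or **family** level — or, for Triassic–Jurassic
floras, to an **Eco-Plant** group describing the parent plant's climatic
tolerance: humidity (EPH: hydrophytes, hygrophytes, mesophytes, xerophytes,
euryphytes) and temperature (EPT: megathermic, mesothermic, microthermic,
eurythermic).

`ecoplant` does this mechanically. Two plain-CSV reference tables keyed by
genus (a taxonomy of parent-plant ranks; an ecogroup table of EPH/EPT
classes) are joined to a long-format assemblage table (`Sample`, `Genus`,
`Abundance`, optional `Depth`). For a chosen mode *m* the percentage of
category *c* in sample *s* is

```
P(s, c) = 100 · Σ_{i ∈ s, cat(g_i) = c} a_i / Σ_{i ∈ s} a_i
```

where `cat(g)` maps a genus to its category under *m* and genera with no
(or disputed) affinity map to the sink category **Uncertain**, which stays
in the denominator: unlinkable grains dilute the signal visibly instead of
silently inflating the linked shares. Because each sample is renormalised
by its own total, raw grain counts and percentage input are equivalent.
Internally the sums are carried out on exact decimal representations of the
abundances, so each sample's percentages total exactly 100 and are
bit-for-bit invariant to rescaling a sample.

The package is aimed at palynologists doing (high-resolution) Mesozoic
palaeoenvironmental reconstruction; the bundled reference tables are a
small published excerpt (17 taxonomy genera, 16 ecogroup genera) and are
meant to be replaced by a full curated set via `default_reference()` path
overrides, `reference_set()` or `merge_reference()`.

## Worked example

The bundled assemblage holds two Triassic samples, HJG 01 and HJG 02:

```r
library(ecoplant)
asm <- read_assemblage(ep_example_path("assemblage"))
m <- eco_plant(asm, "order")
m
#> Abundance matrix (order mode): 2 samples x 14 categories
#>                  HJG 01 HJG 02
#> Bennettitales      33.8    8.9
#> Corystospermales   25.0   33.9
#> Cyatheales          6.6    4.7
#> Equisetales         0.0    2.0
#> Ginkgoales          4.4    7.5
#> Gleicheniales      13.2    7.7
#> Isoetales           7.4    2.4
#> Lycopodiales        0.0    8.4
#> Marattiales         0.0   11.3
#> Notothyladales      5.9    0.7
#> Osmundales          0.7    0.0
#> Peltaspermales      0.0    1.3
#> Pinales             1.5    9.8
#> Uncertain           1.5    1.5
```

Each column sums to 100. *Quadraeculina* has no agreed parent plant, so its
1.5 ends up in `Uncertain`. Note Corystospermales in HJG 02: the input
column totals 100.2, so 34 grains of *Pteruchipollenites* become
100 × 34 / 100.2 = 33.9 — the pipeline renormalises even percentage-style
input. The humidity view of the same data:

```r
eco_plant(asm, "eph")
#> Abundance matrix (eph mode): 2 samples x 5 categories
#>             HJG 01 HJG 02
#> hydrophytes    7.4    2.4
#> hygrophytes   16.1   28.8
#> mesophytes    42.6   49.8
#> xerophytes     1.5   10.4
#> Uncertain     32.4    8.6
```

(HJG 01's Uncertain share is large because *Bharadwajipollenites* is absent
from the small bundled ecogroup excerpt.) Write the table or draw the
classic diagram:

```r
write_matrix(m, "orders.csv")                  # categories × samples CSV
pollen_diagram(m, "orders.pdf")                # one panel per category
draw_curve(ep_example_path("wide"), "my.pdf")  # plot a wide CSV as-is
```

The same pipeline from a shell (see `inst/cli/ecoplant`):

```sh
ecoplant vegetation --rank order assemblage.csv -o out.csv --pdf out.pdf
ecoplant eph assemblage.csv -o eph.csv
ecoplant draw-curve wide.csv --pdf curves.pdf
```

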