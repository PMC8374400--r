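Package: ecoplant
Title: Eco-Plant Analysis of Dispersed Sporomorph Assemblages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Links dispersed-sporomorph (fossil spore and pollen) assemblage
    counts to their putative parent plants at phylum, order, or family level
    and to Eco-Plant humidity (EPH) and temperature (EPT) groups via
    genus-keyed reference tables, computes per-sample percentage abundances
    per category with an explicit "Uncertain" sink for taxa of unknown
    affinity, and renders multi-panel stratigraphic pollen diagrams.
    Aggregation uses exact decimal arithmetic so that per-sample percentages
    sum to 100 and are invariant to uniform rescaling of a sample (counts
    versus percentages). Bundled reference excerpts cover a Mesozoic
    sporomorph flora; full tables can be supplied as plain CSV files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
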