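refs <- default_reference()
asm <- ep_example("assemblage")

test_that("annotate joins each observation to its category in row order", {
  ann <- annotate(asm, "order", refs)
  expect_equal(nrow(ann), nrow(asm))
  expect_equal(ann$category[ann$genus == "Bharadwajipollenites"][1],
               "Bennettitales")
  expect_equal(ann$category[ann$genus == "Quadraeculina"][1], "Uncertain")
  ann_eph <- annotate(asm, "eph", refs)
  # linked in taxonomy but absent from the ecogroup excerpt
  expect_equal(ann_eph$category[ann_eph$genus == "Bharadwajipollenites"][1],
               "Uncertain")
})

test_that("percentages renormalise by each sample's own total", {
  m <- eco_plant(asm, "order", refs)
  # the discriminating cell: 34 grains over a column total of 100.2, so the
  # pipeline renormalises even percentage-style input (33.9, not 34.0)
  expect_equal(m$values["HJG 02", "Corystospermales"], 100 * 34 / 100.2)
  one <- eco_plant(assemblage("S1", "Cyathidites", 7), "order", refs)
  expect_equal(unname(one$values[1, "Cyatheales"]), 100)
  # conservation on the worked example, exactly
  expect_equal(unname(rowSums(m$values)), c(100, 100), tolerance = 1e-12)
})

test_that("duplicate (sample, genus) rows sum into one contribution", {
  a1 <- assemblage(rep("S1", 3), c("Cyathidites", "Cyathidites", "Calamospora"),
                   c(2, 3, 5))
  a2 <- assemblage(rep("S1", 2), c("Cyathidites", "Calamospora"), c(5, 5))
  expect_identical(eco_plant(a1, "order", refs)$values,
                   eco_plant(a2, "order", refs)$values)
})

test_that("rows sharing a category merge into one synthetic row unchanged", {
  # Hamulatisporis and Foveolatitriletes are both Lycopodiales/Lycopodiaceae
  a1 <- assemblage(rep("S1", 3),
                   c("Hamulatisporis", "Foveolatitriletes", "Cyathidites"),
                   c(4, 6, 10))
  a2 <- assemblage(rep("S1", 2), c("Hamulatisporis", "Cyathidites"),
                   c(10, 10))
  expect_identical(eco_plant(a1, "order", refs)$values,
                   eco_plant(a2, "order", refs)$values)
})

test_that("row order never affects the result (permutation invariance)", {
  set.seed(7)
  for (k in 1:5) {
    sh <- asm[sample(nrow(asm)), ]
    m1 <- eco_plant(as_assemblage(sh), "order", refs)
    m2 <- eco_plant(asm, "order", refs)
    # same samples, possibly discovered in a different order
    expect_identical(m1$values[rownames(m2$values), , drop = FALSE],
                     m2$values)
  }
})

test_that("rescaling one sample leaves its percentages bit-identical", {
  a <- random_assemblage(n_samples = 4, unlinked_fraction = 0.2, seed = 11)
  base <- eco_plant(a, "order", refs)
  for (c_ in c(0.01, 3, 1000)) {
    sc <- as.data.frame(a)
    sc$abundance[sc$sample == "S2"] <- sc$abundance[sc$sample == "S2"] * c_
    m <- eco_plant(as_assemblage(sc), "order", refs)
    expect_identical(m$values["S2", ], base$values["S2", ])
    # other samples untouched entirely
    expect_identical(m$values["S1", ], base$values["S1", ])
  }
})

test_that("family columns roll up to the order matrix", {
  # every genus in the bundled taxonomy has both order and family
  a <- random_assemblage(n_samples = 5, seed = 3)
  fam <- eco_plant(a, "family", refs)
  ord <- eco_plant(a, "order", refs)
  parent <- refs$taxonomy$order[match(tolower(colnames(fam$values)),
                                      tolower(refs$taxonomy$family))]
  rolled <- t(rowsum(t(fam$values), parent))
  expect_equal(rolled[, colnames(ord$values)], ord$values, tolerance = 1e-9)
})

test_that("category ordering is alphabetical with Uncertain forced last", {
  m <- eco_plant(asm, "order", refs)
  cats <- categories(m)
  expect_equal(cats[length(cats)], "Uncertain")
  head_cats <- cats[-length(cats)]
  expect_identical(head_cats,
                   head_cats[order(tolower(head_cats), method = "radix")])
  # no Uncertain column materialises when every genus links
  linked <- asm[asm$genus != "Quadraeculina", ]
  m2 <- eco_plant(as_assemblage(linked), "order", refs)
  expect_false("Uncertain" %in% categories(m2))
  # single-category matrix passes through format_matrix unchanged
  single <- eco_plant(assemblage("S1", "Cyathidites", 5), "order", refs)
  expect_identical(categories(format_matrix(single)), "Cyatheales")
})

test_that("linked-only denominator excludes the Uncertain share", {
  m <- eco_plant(asm, "eph", refs, denominator = "linked")
  expect_false("Uncertain" %in% categories(m))
  expect_equal(unname(rowSums(m$values)), c(100, 100), tolerance = 1e-12)
  # HJG 01 linked total is 67.6, so mesophytes 42.6/67.6
  expect_equal(m$values["HJG 01", "mesophytes"], 100 * 42.6 / 67.6,
               tolerance = 1e-12)
})

test_that("zero-total samples are refused by name", {
  ann <- data.frame(sample = "S9", genus = "X", abundance = 0,
                    category = "Uncertain")
  expect_error(aggregate_percent(ann, "order"), "S9",
               class = "ecoplant_validation_error")
})

test_that("aggregation matches the brute-force oracle on fixtures", {
  for (mode in c("phylum", "order", "family", "eph", "ept")) {
    m <- eco_plant(asm, mode, refs)
    oracle <- oracle_percent(asm$sample, asm$genus, asm$abundance, mode,
                             refs$taxonomy, refs$ecogroup, scale = 10L)
    for (s in rownames(m$values)) {
      got <- m$values[s, ]
      want <- oracle[[s]]
      for (cc in names(got)) {
        ref_val <- if (cc %in% names(want)) unname(want[cc]) else 0
        expect_equal(unname(got[cc]), ref_val, tolerance = 1e-9)
      }
    }
  }
})
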