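test_that("taxonomy loader parses the bundled excerpt", {
  tax <- ep_example("taxonomy")
  expect_s3_class(tax, "taxonomy_ref")
  expect_equal(nrow(tax), 17L)
  cy <- tax[tax$genus == "Cyathidites", ]
  expect_equal(cy$order, "Cyatheales")
  expect_equal(cy$family, "Cyatheaceae")
  # gymnosperm rows carry no class in the excerpt
  expect_true(is.na(tax$class[tax$genus == "Pteruchipollenites"]))
})

test_that("taxonomy loader honours header case, BOM, and extra columns", {
  f <- tempfile(fileext = ".csv")
  con <- file(f, open = "wb")
  writeBin(c(as.raw(c(0xEF, 0xBB, 0xBF)),  # UTF-8 byte-order mark
             charToRaw("genus,ORDER,Family,Note\nCyathidites,Cyatheales,Cyatheaceae,x\n")),
           con)
  close(con)
  tax <- read_taxonomy(f)
  expect_equal(tax$order, "Cyatheales")
  expect_false("note" %in% names(tax))
})

test_that("taxonomy loader rejects malformed tables", {
  expect_error(read_taxonomy(tmp_csv(c("Kingdom,Phylum,Order,Family",
                                       "Plantae,Pteridophytes,X,Y"))),
               "Genus", class = "ecoplant_format_error")
  expect_error(read_taxonomy(tmp_csv(c("Genus,Order",
                                       "Cyathidites,Cyatheales",
                                       "Cyathidites,Cyatheales"))),
               "Cyathidites", class = "ecoplant_validation_error")
  # duplicate detection folds case
  expect_error(read_taxonomy(tmp_csv(c("Genus,Order",
                                       "Cyathidites,Cyatheales",
                                       "CYATHIDITES,Cyatheales"))),
               "duplicate", class = "ecoplant_validation_error")
  # a record with no phylum/order/family carries no information
  expect_error(read_taxonomy(tmp_csv(c("Genus,Kingdom,Order",
                                       "Mysteriosporites,Plantae,"))),
               "no phylum", class = "ecoplant_validation_error")
  # header-only file is a legal empty mapping
  expect_equal(nrow(read_taxonomy(tmp_csv("Genus,Phylum,Order,Family"))), 0L)
})

test_that("ecogroup loader validates the closed EPH/EPT sets", {
  eco <- ep_example("ecogroup")
  expect_equal(nrow(eco), 16L)
  pin <- eco[eco$genus == "Pinuspollenites", ]
  expect_equal(pin$eph, "mesophytes")
  expect_equal(pin$ept, "microthermic")
  # every bundled record is a member of the closed enums (exhaustive)
  expect_true(all(eco$eph %in% c("hydrophytes", "hygrophytes", "mesophytes",
                                 "xerophytes", "euryphytes")))
  expect_true(all(eco$ept %in% c("megathermic", "mesothermic",
                                 "microthermic", "eurythermic")))

  # mixed-case group names normalise to lowercase members
  ok <- read_ecogroup(tmp_csv(c("Genus,EPH,EPT", "X,Hygrophytes,MEGATHERMIC")))
  expect_equal(ok$eph, "hygrophytes")
  expect_equal(ok$ept, "megathermic")

  # out-of-set value names the row; halophytes are folded into xerophytes
  # upstream, never a category here
  expect_error(read_ecogroup(tmp_csv(c("Genus,EPH,EPT",
                                       "Y,halophytes,megathermic"))),
               "halophytes", class = "ecoplant_validation_error")
  expect_error(read_ecogroup(tmp_csv(c("Genus,EPH,EPT",
                                       "A,hygrophytes,megathermic",
                                       "A,mesophytes,eurythermic"))),
               "duplicate", class = "ecoplant_validation_error")
})

test_that("reference tables round-trip through CSV unchanged", {
  tax <- ep_example("taxonomy")
  eco <- ep_example("ecogroup")
  ft <- tempfile(fileext = ".csv")
  fe <- tempfile(fileext = ".csv")
  write_taxonomy(tax, ft)
  write_ecogroup(eco, fe)
  expect_identical(as.data.frame(read_taxonomy(ft)), as.data.frame(tax))
  expect_identical(as.data.frame(read_ecogroup(fe)), as.data.frame(eco))
})

test_that("lookup_category resolves ranks, ecogroups, and the Uncertain sink", {
  refs <- default_reference()
  expect_equal(lookup_category("Aratrisporites", "order", refs), "Isoetales")
  expect_equal(lookup_category("Aratrisporites", "eph", refs), "hydrophytes")
  expect_equal(lookup_category("Quadraeculina", "order", refs), "Uncertain")
  # absence is a value in every mode, not an error
  expect_equal(lookup_category("Bharadwajipollenites", "eph", refs),
               "Uncertain")
  # genus matching trims and folds case; repeated calls agree
  expect_equal(lookup_category("  aratrisporites ", "order", refs),
               "Isoetales")
  expect_identical(lookup_category(c("Cyathidites", "Nobody"), "family", refs),
                   lookup_category(c("Cyathidites", "Nobody"), "family", refs))
  # a genus linked at order level only stays Uncertain in family mode
  part <- reference_set(taxonomy = as_taxonomy(
    data.frame(Genus = "Ordonlyspora", Order = "Pinales")))
  expect_equal(lookup_category("Ordonlyspora", "order", part), "Pinales")
  expect_equal(lookup_category("Ordonlyspora", "family", part), "Uncertain")
  expect_error(lookup_category("X", "kingdom", refs),
               class = "ecoplant_validation_error")
})

test_that("merge_reference applies last-writer-wins overlays", {
  refs <- default_reference()
  expect_identical(merge_reference(refs, reference_set())$taxonomy,
                   refs$taxonomy)
  overlay <- reference_set(taxonomy = as_taxonomy(data.frame(
    Genus = c("Annulispora", "Novispora"),
    Phylum = c("Bryophytes", "Pteridophytes"),
    Family = c("Sphagnaceae", "Osmundaceae"))))
  merged <- merge_reference(refs, overlay)
  expect_equal(lookup_category("Annulispora", "family", merged), "Sphagnaceae")
  expect_equal(lookup_category("Novispora", "family", merged), "Osmundaceae")
  expect_equal(nrow(merged$taxonomy), nrow(refs$taxonomy) + 1L)
})

test_that("unlinked_genera reports Uncertain genera in first-appearance order", {
  asm <- ep_example("assemblage")
  expect_equal(unlinked_genera(asm, "order"), "Quadraeculina")
  expect_equal(unlinked_genera(asm, "eph"),
               c("Bharadwajipollenites", "Quadraeculina"))
  empty <- assemblage(character(), character(), numeric())
  expect_equal(unlinked_genera(empty, "order"), character(0))
})
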