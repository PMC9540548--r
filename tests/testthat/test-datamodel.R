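# Domain container, SMILES canonicalization and the on-disk formats.

test_that("canonicalization is spelling-invariant and idempotent", {
  expect_equal(canonicalizeSmiles("OCC"), canonicalizeSmiles("CCO"))
  expect_equal(canonicalizeSmiles("C1=CC=CC=C1"),
               canonicalizeSmiles("c1ccccc1"))
  can <- canonicalizeSmiles(c("Brc1ccc(C)cc1", "CC(C)(C)O[Na]", "CCNCC"))
  expect_identical(canonicalizeSmiles(can), can)
})

test_that("invalid SMILES are rejected by name and validSmiles screens them", {
  expect_error(canonicalizeSmiles("C("), "C\\(")
  expect_error(canonicalizeSmiles("XX"), "XX")
  expect_error(canonicalizeSmiles("C1CC"), "C1CC")  # unmatched ring bond
  expect_identical(validSmiles(c("CCO", "C(", "c1ccccc1", "")),
                   c(TRUE, FALSE, TRUE, FALSE))
})

test_that("stereo stripping removes chirality and double-bond marks", {
  with_st <- canonicalizeSmiles("C/C=C/[C@H](N)C")
  no_st <- canonicalizeSmiles("C/C=C/[C@H](N)C", stripStereo = TRUE)
  expect_false(grepl("[/@\\\\]", no_st))
  expect_true(grepl("[/@\\\\]", with_st))
})

test_that("Pd/Pt detection matches bracket atoms only", {
  expect_true(all(containsPdPt(c("CC(=O)O[Pd]OC(=O)C", "[Pt](Cl)Cl",
                                 "O=C(/C=C/c1ccccc1)/C=C/c1ccccc1.[Pd]"))))
  expect_false(any(containsPdPt(c("c1ccccc1", "CC(C)P(C)C", "[Pb]"))))
})

test_that("reading a CSV groups variations into records", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(toy_variations(), path, row.names = FALSE)
  ds <- readDataset(path)
  expect_s4_class(ds, "ReactionDataset")
  expect_equal(nRecords(ds), 3)
  expect_equal(nVariations(ds), 5)
  expect_equal(sum(variations(ds)$record_id == "R1"), 3)
})

test_that("grouping is independent of the input row order", {
  v <- toy_variations()
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(v[c(4, 2, 5, 1, 3), ], path, row.names = FALSE)
  shuffled <- readDataset(path)
  utils::write.csv(v, path, row.names = FALSE)
  straight <- readDataset(path)
  key <- function(d) {
    vv <- variations(d)
    vv[order(vv$record_id, vv$date), ]
  }
  expect_equal(key(shuffled), key(straight), ignore_attr = TRUE)
})

test_that("schema violations are reported precisely", {
  v <- toy_variations()
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(v[, setdiff(names(v), "yield_percent")], path,
                   row.names = FALSE)
  expect_error(readDataset(path), "yield_percent")

  v2 <- toy_variations()
  v2$yield_percent <- as.character(v2$yield_percent)
  v2$yield_percent[3] <- "abc"
  utils::write.csv(v2, path, row.names = FALSE)
  expect_error(readDataset(path), "row\\(s\\): 3")

  writeLines("record_id,reactant_smiles", path)  # header only
  expect_error(readDataset(path), "empty")
})

test_that("rows with broken SMILES are named, or dropped on request", {
  v <- toy_variations()
  v$product_smiles[2] <- "C1CC"
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(v, path, row.names = FALSE)
  expect_error(readDataset(path), "row\\(s\\): 2")
  ds <- readDataset(path, onInvalid = "drop")
  expect_equal(nVariations(ds), 4)
  expect_equal(provenance(ds)$dropped_rows, 2)
})

test_that("write/read round-trips CSV and JSON to the same dataset", {
  ds <- toy_dataset()
  csv <- withr::local_tempfile(fileext = ".csv")
  json <- withr::local_tempfile(fileext = ".json")
  writeDataset(ds, csv)
  writeDataset(ds, json)
  back_csv <- readDataset(csv)
  back_json <- readDataset(json)
  expect_equal(variations(back_csv), variations(ds), ignore_attr = TRUE)
  expect_equal(variations(back_json), variations(back_csv),
               ignore_attr = TRUE)
})

test_that("reaction-SMILES input is accepted with agents as unassigned species", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(
    record_id = "R1",
    rxn_smiles = "Brc1ccccc1.C1CCNCC1>CC(C)(C)O[Na].C1CCOC1>C1CCN(c2ccccc2)CC1",
    yield_percent = 77, date = "2017-06-01"), path, row.names = FALSE)
  ds <- readDataset(path)
  v <- variations(ds)
  expect_equal(v$species_roles, "unassigned;unassigned")
  expect_equal(length(strsplit(v$reactant_smiles, ".", fixed = TRUE)[[1]]), 2)
})

test_that("validity rejects out-of-range yields, dates and bad roles", {
  v <- toy_variations()
  v$yield_percent[1] <- 140
  expect_error(ReactionDataset(v), "yield_percent")
  v <- toy_variations()
  v$date[1] <- "1890-01-01"
  expect_error(ReactionDataset(v), "1990")
  v <- toy_variations()
  v$species_roles[1] <- "unassigned;oxidant;unassigned;unassigned"
  expect_error(ReactionDataset(v), "role")
  v <- toy_variations()
  v$reactant_smiles[4] <- "NCCCC"  # single reactant is not a coupling
  expect_error(ReactionDataset(v), "2 reactants")
})

test_that("datasets with multi-fragment species refuse CSV but survive JSON", {
  v <- toy_variations()[4, ]
  v$species_smiles <- "O=C(/C=C/c1ccccc1)/C=C/c1ccccc1.[Pd]"
  v$species_roles <- "catalyst"
  path_json <- withr::local_tempfile(fileext = ".json")
  # in the flat table this species cannot align with one role, so the
  # validity check refuses it; the JSON reader/writer path keeps species
  # as objects and is exercised via readDataset on a hand-written file
  expect_error(ReactionDataset(v), "align")
  writeLines(jsonlite::toJSON(list(list(
    record_id = "R9", reactant_smiles = list("Clc1ccccc1", "NCCCC"),
    product_smiles = "CCCCNc1ccccc1",
    variations = list(list(
      species = list(list(smiles = "O=C(/C=C/c1ccccc1)/C=C/c1ccccc1.[Pd]",
                          role = "catalyst"),
                     list(smiles = "C1CCOC1", role = "solvent")),
      yield_percent = 50, date = "2012-02-02")))), auto_unbox = TRUE),
    path_json)
  expect_error(readDataset(path_json), "align")
})
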