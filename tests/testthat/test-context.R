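# Role assignment, context keys, label space and the training tables.

test_that("role precedence: curated lists, then the Pd/Pt flag, then reagent", {
  cl <- curatedLists()
  sp <- data.frame(
    smiles = c(cl$precatalysts[1],                   # curated pre-catalyst
               "O=C(/C=C/c1ccccc1)/C=C/c1ccccc1.[Pd]",  # Pd flag only
               cl$bases[1],                          # curated base
               cl$solvents[1],                       # curated solvent
               cl$ligands[1],                        # curated ligand
               "CC(=O)OCC"),                         # matches nothing
    role = "unassigned", stringsAsFactors = FALSE)
  out <- assignRoles(sp, cl)
  expect_equal(out$role, c("pre-catalyst", "catalyst", "base", "solvent",
                           "ligand", "reagent"))
})

test_that("pre-assigned roles are kept untouched", {
  cl <- curatedLists()
  sp <- data.frame(smiles = c(cl$bases[1], cl$solvents[2]),
                   role = c("reagent", "unassigned"),
                   stringsAsFactors = FALSE)
  out <- assignRoles(sp, cl)
  expect_equal(out$role, c("reagent", "solvent"))
  expect_error(assignRoles(sp[0, ], cl), "at least one species")
})

test_that("context keys are order-invariant and injective on content", {
  cl <- curatedLists()
  sp <- data.frame(
    smiles = c(cl$precatalysts[1], cl$ligands[1], cl$bases[1], cl$solvents[1]),
    role = c("pre-catalyst", "ligand", "base", "solvent"),
    stringsAsFactors = FALSE)
  key1 <- buildContextKey(sp)
  key2 <- buildContextKey(sp[c(3, 1, 4, 2), ])
  expect_identical(key1, key2)
  # four populated categories in the catalyst+ligand+base+solvent quartet
  expect_equal(sum(lengths(contextSpecies(key1)) > 0), 4)
  sp2 <- sp; sp2$smiles[3] <- cl$bases[2]
  expect_false(buildContextKey(sp2) == key1)
  expect_error(buildContextKey(sp[0, ]), "at least one species")
  sp3 <- sp; sp3$role[1] <- "unassigned"
  expect_error(buildContextKey(sp3), "assigned")
})

test_that("contextSpecies inverts buildContextKey", {
  cl <- curatedLists()
  sp <- data.frame(smiles = c(cl$ligands[2], cl$bases[1], cl$bases[3]),
                   role = c("ligand", "base", "base"),
                   stringsAsFactors = FALSE)
  parsed <- contextSpecies(buildContextKey(sp))
  expect_equal(parsed$base, sort(c(cl$bases[1], cl$bases[3])))
  expect_equal(parsed$ligand, cl$ligands[2])
  expect_equal(parsed$catalyst, character(0))
})

test_that("yield filter keeps 20.0 and drops 19.9; label space is counted after it", {
  v <- toy_variations()
  v$yield_percent <- c(19.9, 20.0, 60, 90, 55)
  ds <- ReactionDataset(v)
  fl <- filterAndLabel(ds, k = 3)
  expect_equal(unname(fl$report$variations["dropped_yield"]), 1)
  expect_equal(unname(fl$report$variations["kept"]), 4)
})

test_that("single-label table keeps the highest-yield variation with weight yield/100", {
  fl <- filterAndLabel(toy_dataset(), k = 3)
  r1 <- fl$single[fl$single$record_id == "R1", ]
  expect_equal(nrow(r1), 1)
  expect_equal(r1$weight, 0.80)
  expect_equal(r1$year, 2016)
  # R2 dropped entirely (yield 15 < 20)
  expect_false("R2" %in% fl$single$record_id)
  expect_equal(nrow(fl$single), 2)
})

test_that("multi-label vectors are the bitwise-or of distinct surviving contexts", {
  fl <- filterAndLabel(toy_dataset(), k = 3)
  i <- which(fl$multi$record_id == "R1")
  expect_equal(sum(fl$multiLabels[i, ]), 2)  # contexts A and B, A repeated
  expect_true(all(fl$multi$weight == 1))
  # repeating a variation never changes the vector
  v <- variations(toy_dataset())
  v2 <- rbind(v, v[v$record_id == "R1", ][1, ])
  fl2 <- filterAndLabel(ReactionDataset(v2), k = 3)
  expect_equal(fl2$multiLabels[which(fl2$multi$record_id == "R1"), ],
               fl$multiLabels[i, ])
})

test_that("label space ordering is deterministic: count desc, then key", {
  fl <- filterAndLabel(toy_dataset(), k = 3)
  expect_s4_class(fl$labelSpace, "LabelSpace")
  cnt <- labelCounts(fl$labelSpace)
  expect_true(all(diff(cnt) <= 0))
  keys <- labelKeys(fl$labelSpace)
  ties <- which(cnt[-1] == cnt[-length(cnt)])
  for (i in ties) expect_true(keys[i] < keys[i + 1])
  # byte-identical on a re-run
  fl2 <- filterAndLabel(toy_dataset(), k = 3)
  expect_identical(labelKeys(fl2$labelSpace), keys)
})

test_that("k larger than the number of contexts truncates with a warning", {
  expect_warning(fl <- filterAndLabel(toy_dataset(), k = 10), "truncated")
  expect_equal(nLabels(fl$labelSpace), 3)
})

test_that("report stage counts conserve the input totals", {
  rep <- suppressWarnings(datasetReport(toy_dataset(), k = 10))
  v <- rep$variations
  expect_equal(unname(v["input"]),
               unname(v["dropped_yield"] + v["dropped_rare_context"] +
                        v["kept"]))
  r <- rep$records
  expect_equal(unname(r["input"]), unname(r["kept"] + r["dropped"]))
  expect_equal(sum(rep$record_context_counts), unname(r["kept"]))
  # toy: of the 2 kept records, R1 has two distinct contexts
  expect_equal(unname(rep$record_context_proportions["2"]), 0.5)
})

test_that("all variations below the yield floor leaves an empty, accounted result", {
  v <- toy_variations()
  v$yield_percent <- rep(5, 5)
  fl <- filterAndLabel(ReactionDataset(v), k = 3)
  expect_equal(nLabels(fl$labelSpace), 0)
  expect_equal(nrow(fl$single), 0)
  expect_equal(unname(fl$report$variations["dropped_yield"]), 5)
  expect_equal(unname(fl$report$records["dropped"]), 3)
})

test_that("label space round-trips through JSON", {
  fl <- filterAndLabel(toy_dataset(), k = 3)
  path <- withr::local_tempfile(fileext = ".json")
  writeLabelSpace(fl$labelSpace, path)
  back <- readLabelSpace(path)
  expect_identical(labelKeys(back), labelKeys(fl$labelSpace))
  expect_identical(labelCounts(back), labelCounts(fl$labelSpace))
})
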