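# Shared fixtures, built once per test session and memoised. Everything is
# generated in code; the heavier synthetic dataset is kept small so the
# whole suite stays fast.

.fixtures <- new.env()

# a tiny hand-built variation table with known structure: three records,
# single-fragment context species drawn from the shipped curated lists
toy_variations <- function() {
  cl <- curatedLists()
  ctxA <- c(cl$precatalysts[1], cl$ligands[1], cl$bases[1], cl$solvents[1])
  ctxB <- c(cl$precatalysts[1], cl$ligands[2], cl$bases[1], cl$solvents[1])
  ctxC <- c(cl$precatalysts[2], cl$ligands[3], cl$bases[2], cl$solvents[2])
  mk <- function(ctx) paste(ctx, collapse = ".")
  roles4 <- paste(rep("unassigned", 4), collapse = ";")
  data.frame(
    record_id = c("R1", "R1", "R1", "R2", "R3"),
    reactant_smiles = c(rep("Brc1ccccc1.C1CCNCC1", 3),
                        "Clc1ccccc1.NCCCC", "Ic1ccc(C)cc1.CCNCC"),
    product_smiles = c(rep("C1CCN(c2ccccc2)CC1", 3),
                       "CCCCNc1ccccc1", "CCN(CC)c1ccc(C)cc1"),
    species_smiles = c(mk(ctxA), mk(ctxA), mk(ctxB), mk(ctxA), mk(ctxC)),
    species_roles = rep(roles4, 5),
    yield_percent = c(45, 80, 60, 15, 55),
    date = c("2015-03-01", "2016-05-10", "2016-07-01", "2018-01-15",
             "2019-11-30"),
    stringsAsFactors = FALSE)
}

toy_dataset <- function() {
  if (is.null(.fixtures$toy)) {
    # via the reader so all SMILES are canonical (round-trip fixed point)
    path <- tempfile(fileext = ".csv")
    utils::write.csv(toy_variations(), path, row.names = FALSE)
    .fixtures$toy <- readDataset(path)
    unlink(path)
  }
  .fixtures$toy
}

# small planted-rule dataset + features, shared by model/evaluate tests
small_synthetic <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- generatorConfig(nRecords = 600, nContexts = 6, seed = 3,
                           ruleNoise = 0.05)
    ds <- generateDataset(cfg)
    fl <- filterAndLabel(ds, k = 6)
    X <- featurizeReactions(fl$single)
    Xm <- featurizeReactions(fl$multi)
    .fixtures$small <- list(cfg = cfg, ds = ds, fl = fl, X = X, Xm = Xm)
  }
  .fixtures$small
}
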