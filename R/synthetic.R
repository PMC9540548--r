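# Synthetic ELN-like Buchwald-Hartwig dataset generator.
#
# Reactions are aryl halide + amine couplings assembled from SMILES
# templates (substituted aryl chlorides/bromides/iodides crossed with four
# amine classes); the product is the C-N coupled molecule, built by
# template substitution and valence-checked through the toolkit. Each
# reaction's context follows a planted rule on interpretable reactant
# features (halide identity, amine class, ortho hindrance), corrupted with
# configurable label noise, so the mapping is learnable by construction:
# all three features alter circular and path fingerprint environments.
# Popularity is long-tailed, the multi-variation distribution and yields
# mimic medicinal-chemistry ELN statistics, and optional context
# active-year windows plant the temporal replacement signature.

.HALIDES <- c("Cl", "Br", "I")
.AMINE_CLASSES <- c("primary_aliphatic", "secondary_aliphatic", "aniline",
                    "cyclic_secondary")

# aryl cores: substituents at ortho/meta/para positions; attachment first.
# Ring digit is parameterized so the same core serves halide (digit 1) and
# product (digit 2); substituent rings use digit 3.
.coreFragment <- function(ortho, meta, para, digit) {
  seg <- function(x) ifelse(nzchar(x), paste0("c(", x, ")"), "c")
  paste0("c", digit, seg(ortho), seg(meta), seg(para), "cc", digit)
}

.CORE_SUBS <- list(
  ortho = c("", "C", "OC"),
  meta = c("", "C", "OC", "F"),
  para = c("", "C", "OC", "CC", "C(C)C", "F", "C(F)(F)F", "-c3ccccc3"))

# amines: parse SMILES plus a product pattern whose %s receives the aryl
# fragment (ring digit 2)
.AMINES <- list(
  primary_aliphatic = list(
    c("NCCCC", "N(%s)CCCC"),
    c("NCC(C)C", "N(%s)CC(C)C"),
    c("NC1CCCCC1", "N(%s)C1CCCCC1"),
    c("NCc1ccccc1", "N(%s)Cc1ccccc1"),
    c("NCCc1ccccc1", "N(%s)CCc1ccccc1")),
  secondary_aliphatic = list(
    c("CCNCC", "CCN(%s)CC"),
    c("CCCCNCCCC", "CCCCN(%s)CCCC"),
    c("CNCCCC", "CN(%s)CCCC"),
    c("CNCc1ccccc1", "CN(%s)Cc1ccccc1"),
    c("CCNC(C)C", "CCN(%s)C(C)C")),
  aniline = list(
    c("Nc1ccccc1", "N(%s)c1ccccc1"),
    c("Nc1ccc(C)cc1", "N(%s)c1ccc(C)cc1"),
    c("Nc1ccc(OC)cc1", "N(%s)c1ccc(OC)cc1"),
    c("Nc1cccc(F)c1", "N(%s)c1cccc(F)c1"),
    c("CNc1ccccc1", "CN(%s)c1ccccc1")),
  cyclic_secondary = list(
    c("C1CCNCC1", "C1CCN(%s)CC1"),
    c("C1CCNC1", "C1CCN(%s)C1"),
    c("O1CCNCC1", "O1CCN(%s)CC1"),
    c("C1CCCNCC1", "C1CCCN(%s)CC1"),
    c("CC1CCNCC1", "CC1CCN(%s)CC1")))

#' Generator configuration
#'
#' The defaults emulate the statistical character of a medicinal-chemistry
#' ELN extract of Buchwald-Hartwig reactions: two dozen distinct contexts
#' (one per cell of the 3 x 4 x 2 reactant feature grid) with a
#' long-tailed popularity distribution whose mean imbalance ratio sits
#' near 7, low multi-label character (86% of
#' records with a single variation, 11% with two, 3% with three or more),
#' extra variations that mostly repeat the first context, yields mostly at
#' or above 20% with a small sub-20% tail, and records dated 2004-2020.
#'
#' @param nRecords number of reaction records.
#' @param nContexts number of distinct chemical contexts (default 24, the
#'   size of the reactant feature grid, so every context is reachable by
#'   the planted rule).
#' @param seed RNG seed for data generation.
#' @param ruleSeed separate seed for the planted rule, so the rule is
#'   stable across datasets generated with different \code{seed}.
#' @param ruleNoise probability that a variation's context ignores the
#'   planted rule and is drawn from the popularity distribution instead.
#' @param multiVariationProbs probabilities of a record having 1, 2, or 3+
#'   variations.
#' @param sameContextRepeatProb probability that an extra variation reuses
#'   the record's first context (keeps label cardinality near 1 despite
#'   multi-variation records).
#' @param popularityDecay geometric decay of context popularity; tuned so
#'   the default configuration lands near a mean imbalance ratio of 7.
#' @param driftSpec \code{NULL} (no drift) or a data.frame with columns
#'   \code{context}, \code{from}, \code{to}, \code{successor} giving each
#'   context's active-year window and the context used in its place
#'   outside the window; see \code{\link{defaultDriftSpec}}.
#' @param yieldParams list: \code{matchMean}/\code{otherMean} (mean percent
#'   yield when the context does/does not match the rule),
#'   \code{concentration} (Beta concentration), \code{sub20Prob}
#'   (probability of a sub-20% yield, for filter testing).
#' @param yearRange two-element integer vector of calendar years.
#' @return a validated generator-configuration list.
#' @export
generatorConfig <- function(nRecords = 5000L, nContexts = 24L, seed = 42L,
                            ruleSeed = 7L, ruleNoise = 0.1,
                            multiVariationProbs = c(`1` = 0.86, `2` = 0.11,
                                                    `3+` = 0.03),
                            sameContextRepeatProb = 0.9,
                            popularityDecay = 0.835,
                            driftSpec = NULL,
                            yieldParams = list(matchMean = 75,
                                               otherMean = 45,
                                               concentration = 8,
                                               sub20Prob = 0.08),
                            yearRange = c(2004L, 2020L)) {
  cfg <- list(nRecords = as.integer(nRecords),
              nContexts = as.integer(nContexts), seed = as.integer(seed),
              ruleSeed = as.integer(ruleSeed), ruleNoise = ruleNoise,
              multiVariationProbs = multiVariationProbs,
              sameContextRepeatProb = sameContextRepeatProb,
              popularityDecay = popularityDecay, driftSpec = driftSpec,
              yieldParams = yieldParams,
              yearRange = as.integer(yearRange))
  stopifnot(cfg$nRecords >= 1, cfg$nContexts >= 1,
            cfg$ruleNoise >= 0, cfg$ruleNoise <= 1,
            abs(sum(cfg$multiVariationProbs) - 1) < 1e-8,
            cfg$sameContextRepeatProb >= 0, cfg$sameContextRepeatProb <= 1,
            cfg$popularityDecay > 0, cfg$popularityDecay <= 1,
            cfg$yearRange[1] <= cfg$yearRange[2])
  if (!is.null(cfg$driftSpec)) {
    d <- cfg$driftSpec
    stopifnot(all(c("context", "from", "to", "successor") %in% names(d)))
    if (any(d$from > d$to))
      stop("driftSpec contains a context with an empty active window",
           call. = FALSE)
    if (any(d$from > cfg$yearRange[2]) || any(d$to < cfg$yearRange[1]))
      stop("driftSpec window outside the dataset year range", call. = FALSE)
  }
  cfg
}

#' Default temporal-drift specification
#'
#' Plants the replacement signature seen in real context usage: the most
#' popular context only enters use at \code{replacementYear} and supplants
#' the second-most popular context, which leaves use at the same time.
#'
#' @param cfg a generator configuration.
#' @param replacementYear calendar year of the replacement (default:
#'   two-thirds into the year range, e.g. 2015 for 2004-2020).
#' @return a drift data.frame suitable for \code{generatorConfig}'s
#'   \code{driftSpec}.
#' @export
defaultDriftSpec <- function(cfg, replacementYear = NULL) {
  yr <- cfg$yearRange
  if (is.null(replacementYear))
    replacementYear <- yr[1] + round(2 * (yr[2] - yr[1]) / 3)
  data.frame(context = c(1L, 2L),
             from = c(replacementYear, yr[1]),
             to = c(yr[2], replacementYear - 1L),
             successor = c(2L, 1L))
}

# deterministic context library: one catalyst/ligand/base/solvent combo per
# context, drawn without replacement from the curated species
.contextLibrary <- function(nContexts, ruleSeed, curated) {
  cats <- c(curated$precatalysts, curated$catalysts)
  ligs <- curated$ligands
  bases <- curated$bases[seq_len(min(3, length(curated$bases)))]
  solvs <- curated$solvents
  combos <- expand.grid(cat = seq_along(cats), lig = seq_along(ligs),
                        base = seq_along(bases), solv = seq_along(solvs))
  if (nContexts > nrow(combos))
    stop("cannot build ", nContexts, " distinct contexts from the curated ",
         "lists (", nrow(combos), " combinations available)", call. = FALSE)
  pick <- .withSeed(ruleSeed, sample(nrow(combos), nContexts))
  vapply(pick, function(i) {
    cm <- combos[i, ]
    sp <- data.frame(
      smiles = c(cats[cm$cat], ligs[cm$lig], bases[cm$base], solvs[cm$solv]),
      role = "unassigned", stringsAsFactors = FALSE)
    buildContextKey(assignRoles(sp, curated))
  }, "")
}

# all template molecules: aryl halides (with steric flag) and amines
.moleculeLibrary <- function() {
  cores <- expand.grid(ortho = .CORE_SUBS$ortho, meta = .CORE_SUBS$meta,
                       para = .CORE_SUBS$para, stringsAsFactors = FALSE)
  halides <- do.call(rbind, lapply(.HALIDES, function(h) {
    data.frame(halide = h,
               smiles = paste0(h, .coreFragment(cores$ortho, cores$meta,
                                                cores$para, 1L)),
               aryl2 = .coreFragment(cores$ortho, cores$meta, cores$para, 2L),
               steric = ifelse(nzchar(cores$ortho), "ortho", "unhindered"),
               stringsAsFactors = FALSE)
  }))
  amines <- do.call(rbind, lapply(names(.AMINES), function(cl) {
    do.call(rbind, lapply(.AMINES[[cl]], function(a)
      data.frame(amineClass = cl, smiles = a[1], productFmt = a[2],
                 stringsAsFactors = FALSE)))
  }))
  list(halides = halides, amines = amines)
}

#' The planted context rule
#'
#' Returns the exact rule used by \code{\link{generateDataset}}: a total
#' function over the 3 x 4 x 2 reactant feature grid (halide, amine class,
#' steric flag) giving each cell's preferred context index and its
#' popularity rank. The rule depends only on \code{ruleSeed} and
#' \code{nContexts}, so datasets generated with different data seeds share
#' the same rule.
#'
#' @param cfg generator configuration from \code{\link{generatorConfig}}.
#' @return data.frame: halide, amineClass, steric, rank, context, weight
#'   (the cell's sampling probability).
#' @export
plantedTruth <- function(cfg) {
  cells <- expand.grid(halide = .HALIDES, amineClass = .AMINE_CLASSES,
                       steric = c("ortho", "unhindered"),
                       stringsAsFactors = FALSE)
  n <- nrow(cells)
  rank <- .withSeed(cfg$ruleSeed, sample(n))
  cells$rank <- rank
  cells$context <- (cells$rank - 1L) %% cfg$nContexts + 1L
  # the cell's second-choice context: the context of the next cell in
  # popularity order (wrapping), used by repeat variations that try an
  # alternative set of conditions
  nxt <- cells$rank %% n + 1L
  cells$altContext <- cells$context[match(nxt, cells$rank)]
  w <- cfg$popularityDecay^(cells$rank - 1)
  cells$weight <- w / sum(w)
  cells
}

# is context c active in year y under the drift spec?
.activeContexts <- function(K, year, driftSpec) {
  act <- rep(TRUE, K)
  if (!is.null(driftSpec))
    for (i in seq_len(nrow(driftSpec))) {
      c <- driftSpec$context[i]
      act[c] <- year >= driftSpec$from[i] && year <= driftSpec$to[i]
    }
  act
}

# rule-preferred context of a cell in a given year: the cell's primary
# context if active, else the primary's designated successor, else the most
# popular active context
.preferredContext <- function(primary, year, K, driftSpec, popWeights) {
  act <- .activeContexts(K, year, driftSpec)
  if (act[primary]) return(primary)
  if (!is.null(driftSpec)) {
    succ <- driftSpec$successor[driftSpec$context == primary]
    if (length(succ) && act[succ[1]]) return(succ[1])
  }
  which(act)[which.max(popWeights[act])]
}

#' Generate a synthetic Buchwald-Hartwig dataset
#'
#' Fully reproducible from the configuration seeds. Every generated SMILES
#' parses and canonicalizes; products differ from both reactants, so
#' difference fingerprints are never the zero vector.
#'
#' @param cfg generator configuration from \code{\link{generatorConfig}}.
#' @param curated curated role lists supplying the context species.
#' @return a \code{ReactionDataset}; the provenance records the
#'   configuration, the context library and the per-record reactant
#'   features (\code{recordCells}) for rule-recovery testing.
#' @export
generateDataset <- function(cfg = generatorConfig(),
                            curated = curatedLists()) {
  rule <- plantedTruth(cfg)
  contexts <- .contextLibrary(cfg$nContexts, cfg$ruleSeed, curated)
  lib <- .moleculeLibrary()
  K <- cfg$nContexts
  popW <- cfg$popularityDecay^(seq_len(K) - 1)
  popW <- popW / sum(popW)
  yp <- cfg$yieldParams

  # canonicalize the template molecules once (also a valence check)
  hal_can <- canonicalizeSmiles(lib$halides$smiles)
  am_can <- canonicalizeSmiles(lib$amines$smiles)

  ctx_species <- lapply(contexts, contextSpecies)

  rows <- .withSeed(cfg$seed, {
    out <- vector("list", cfg$nRecords)
    cell_idx <- sample(nrow(rule), cfg$nRecords, replace = TRUE,
                       prob = rule$weight)
    years <- sample(seq(cfg$yearRange[1], cfg$yearRange[2]),
                    cfg$nRecords, replace = TRUE)
    nvar_draw <- sample(c(1L, 2L, 3L), cfg$nRecords, replace = TRUE,
                        prob = cfg$multiVariationProbs)
    cells_rec <- vector("list", cfg$nRecords)
    for (r in seq_len(cfg$nRecords)) {
      cell <- rule[cell_idx[r], ]
      year <- years[r]
      hsel <- which(lib$halides$halide == cell$halide &
                    lib$halides$steric == cell$steric)
      hi <- hsel[sample.int(length(hsel), 1)]
      asel <- which(lib$amines$amineClass == cell$amineClass)
      ai <- asel[sample.int(length(asel), 1)]
      product <- sprintf(lib$amines$productFmt[ai], lib$halides$aryl2[hi])
      nvar <- nvar_draw[r]
      if (nvar == 3L) nvar <- nvar + stats::rgeom(1, 0.7)
      pref <- .preferredContext(cell$context, year, K, cfg$driftSpec, popW)
      alt <- .preferredContext(cell$altContext, year, K, cfg$driftSpec, popW)
      act <- .activeContexts(K, year, cfg$driftSpec)
      draw_ctx <- function(preferred) {
        if (stats::runif(1) >= cfg$ruleNoise) preferred
        else sample.int(K, 1, prob = popW * act)
      }
      ctxs <- integer(nvar)
      ctxs[1] <- draw_ctx(pref)
      if (nvar > 1) for (j in 2:nvar) {
        ctxs[j] <- if (stats::runif(1) < cfg$sameContextRepeatProb)
          ctxs[1] else draw_ctx(alt)
      }
      yields <- vapply(ctxs, function(cx) {
        if (stats::runif(1) < yp$sub20Prob) return(stats::runif(1, 1, 20))
        mu <- if (cx == pref) (yp$matchMean - 20) / 80
              else (yp$otherMean - 20) / 80
        20 + 80 * stats::rbeta(1, mu * yp$concentration,
                               (1 - mu) * yp$concentration)
      }, numeric(1))
      dates <- sprintf("%04d-%02d-%02d", year,
                       sample.int(12, nvar, replace = TRUE),
                       sample.int(28, nvar, replace = TRUE))
      record_id <- sprintf("R%05d", r)
      cells_rec[[r]] <- data.frame(record_id = record_id,
                                   halide = cell$halide,
                                   amineClass = cell$amineClass,
                                   steric = cell$steric, year = year,
                                   ruleContext = cell$context,
                                   preferredContext = pref,
                                   stringsAsFactors = FALSE)
      out[[r]] <- data.frame(
        record_id = record_id,
        reactant_smiles = paste(sort(c(hal_can[hi], am_can[ai])),
                                collapse = "."),
        product_smiles = product,
        species_smiles = vapply(ctxs, function(cx)
          paste(unlist(ctx_species[[cx]]), collapse = "."), ""),
        species_roles = vapply(ctxs, function(cx) {
          sp <- ctx_species[[cx]]
          paste(rep(names(sp), lengths(sp)), collapse = ";")
        }, ""),
        yield_percent = round(yields, 1),
        date = dates,
        context_index = ctxs,
        stringsAsFactors = FALSE)
    }
    list(vars = do.call(rbind, out), cells = do.call(rbind, cells_rec))
  })

  v <- rows$vars
  prod_can <- canonicalizeSmiles(unique(v$product_smiles))
  names(prod_can) <- unique(v$product_smiles)
  v$product_smiles <- unname(prod_can[v$product_smiles])
  ctx_idx <- v$context_index
  v$context_index <- NULL

  ds <- ReactionDataset(v, provenance = list(
    source = "bhcontext synthetic generator", config = cfg,
    contextLibrary = contexts, recordCells = rows$cells,
    variationContextIndex = ctx_idx))
  methods::validObject(ds)
  ds
}

#' Check a dataset against the target realism envelopes
#'
#' Recomputes the imbalance summary and (when drift is present) the
#' per-year usage matrix and verifies the configured envelopes: mean
#' imbalance ratio inside \code{meanIRBand} (the lower edge, 1.5, is the
#' usual imbalanced-dataset criterion), label cardinality inside
#' \code{cardinalityBand}, and a long-tailed popularity distribution (most
#' popular context used at least \code{tailRatio} times more than the
#' rarest kept one).
#'
#' @param ds a \code{ReactionDataset}.
#' @param k,minYield,curated filtering parameters.
#' @param meanIRBand,cardinalityBand,tailRatio acceptance envelopes.
#' @return list: \code{checks} (data.frame criterion/value/pass) and
#'   \code{pass} (all criteria met).
#' @export
validateRealism <- function(ds, k = 30, minYield = 20,
                            curated = curatedLists(),
                            meanIRBand = c(1.5, 20),
                            cardinalityBand = c(1.0, 1.2),
                            tailRatio = 3) {
  fl <- filterAndLabel(ds, k = k, minYield = minYield, curated = curated)
  im <- imbalanceSummary(fl$multiLabels, fl$labelSpace)
  cnt <- labelCounts(fl$labelSpace)
  checks <- data.frame(
    criterion = c("meanIR", "cardinality", "longTail"),
    value = c(im$meanIR, im$cardinality, cnt[1] / cnt[length(cnt)]),
    pass = c(im$meanIR >= meanIRBand[1] && im$meanIR <= meanIRBand[2],
             im$cardinality >= cardinalityBand[1] &&
               im$cardinality <= cardinalityBand[2],
             cnt[1] / cnt[length(cnt)] >= tailRatio))
  list(checks = checks, pass = all(checks$pass))
}
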